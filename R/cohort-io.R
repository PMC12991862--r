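#' Read and write cohorts in the oBDS-lite interchange format
#'
#' The package exchanges cohorts as a compact JSON schema ("oBDS-lite"): a
#' top-level array of patients, each with `patient_id`, `diagnosis_date`,
#' `death_date` (or null), a `covariates` object (`age`, `grading`, `uicc`,
#' `uicc_substage`, `histology_code`, `lobular`) and an `events` array. Each
#' event carries `type` (`"diagnosis"`, `"surgery"`, `"radiotherapy"`,
#' `"systemic"`), `date` (ISO-8601 or null) and the type-specific fields of
#' the [event constructors][events]. Nulls and absent fields become missing
#' attribute values; categorical payloads outside an attribute's domain
#' become unrelated. Dates are ISO-8601, encoding UTF-8.
#'
#' @param records list of [patient_record()] objects
#' @param path file path
#' @return `parse_cohort()` returns a list of `tc_patient`;
#'   the writers return `path` invisibly
#' @name cohort_io
NULL

nn <- function(x) if (is.null(x) || length(x) == 0L || all(is.na(x))) NULL else x

# serialize the comparable payload, or the preserved raw source value for
# missing/unrelated states so that write -> parse round-trips exactly
av_payload <- function(x) {
  if (is_present(x)) x$value else x$raw
}

event_to_list <- function(e) {
  base <- list(type = e$type,
               date = if (is.na(e$date)) NULL else format(e$date))
  extra <- switch(e$type,
    diagnosis = list(uicc = av_payload(e$uicc), ecog = av_payload(e$ecog),
                     age_group = av_payload(e$age_group),
                     histology = av_payload(e$histology),
                     grading = av_payload(e$grading)),
    surgery = list(procedure_codes = as.list(e$procedure_codes),
                   residual = av_payload(e$residual),
                   complications = if (is_present(e$complications))
                     as.list(e$complications$value) else NULL),
    radiotherapy = list(radiations = lapply(e$radiations, function(r)
                          list(application_type = nn(r$application_type),
                               target_region = nn(r$target_region))),
                        temporal = av_payload(e$temporal)),
    systemic = list(therapy_type = av_payload(e$therapy_type),
                    temporal = av_payload(e$temporal)))
  c(base, extra)
}

patient_to_list <- function(p) {
  cv <- p$covariates
  list(patient_id = p$patient_id,
       diagnosis_date = format(p$diagnosis_date),
       death_date = if (is.na(p$death_date)) NULL else format(p$death_date),
       covariates = list(age = nn(cv$age), grading = nn(cv$grading),
                         uicc = nn(cv$uicc), uicc_substage = nn(cv$uicc_substage),
                         histology_code = nn(cv$histology_code),
                         lobular = nn(cv$lobular)),
       events = lapply(p$course$events, event_to_list))
}

#' @rdname cohort_io
#' @export
write_cohort <- function(records, path) {
  stopifnot(all(vapply(records, inherits, logical(1), "tc_patient")))
  json <- jsonlite::toJSON(lapply(records, patient_to_list),
                           auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

parse_event <- function(ev, where) {
  type <- ev$type
  if (is.null(type) || !type %in% names(EVENT_TYPES)) {
    stop(sprintf("%s: event has unknown type '%s'", where,
                 if (is.null(type)) "<absent>" else type), call. = FALSE)
  }
  date <- ev$date
  tryCatch(switch(type,
    diagnosis = diagnosis_event(uicc = nn(ev$uicc), ecog = nn(ev$ecog),
                                age_group = nn(ev$age_group),
                                histology = nn(ev$histology),
                                grading = nn(ev$grading), date = date),
    surgery = surgery_event(procedure_codes = unlist(ev$procedure_codes) %||% character(0),
                            residual = nn(ev$residual),
                            complications = if (is.null(ev$complications)) NULL
                                            else unlist(ev$complications) %||% character(0),
                            date = date),
    radiotherapy = radiotherapy_event(radiations = ev$radiations %||% list(),
                                      temporal = nn(ev$temporal), date = date),
    systemic = systemic_event(therapy_type = nn(ev$therapy_type),
                              temporal = nn(ev$temporal), date = date)),
    error = function(err) {
      stop(sprintf("%s (%s event): %s", where, type, conditionMessage(err)),
           call. = FALSE)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_patient <- function(pl, idx) {
  id <- pl$patient_id
  where <- if (is.null(id)) sprintf("record #%d", idx) else sprintf("patient %s", id)
  if (is.null(id) || !nzchar(id)) {
    stop(sprintf("%s: missing patient_id", where), call. = FALSE)
  }
  if (is.null(pl$diagnosis_date)) {
    stop(sprintf("%s: missing diagnosis_date", where), call. = FALSE)
  }
  events <- lapply(seq_along(pl$events), function(i) {
    parse_event(pl$events[[i]], sprintf("%s, event #%d", where, i))
  })
  cv <- pl$covariates %||% list()
  tryCatch(
    patient_record(treatment_course(as.character(id), events),
                   diagnosis_date = pl$diagnosis_date,
                   death_date = pl$death_date,
                   covariates = list(age = nn(cv$age), grading = nn(cv$grading),
                                     uicc = nn(cv$uicc),
                                     uicc_substage = nn(cv$uicc_substage),
                                     histology_code = nn(cv$histology_code),
                                     lobular = nn(cv$lobular))),
    error = function(err) {
      stop(sprintf("%s: %s", where, conditionMessage(err)), call. = FALSE)
    })
}

#' @rdname cohort_io
#' @export
parse_cohort <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(err) {
                    stop(sprintf("cannot parse cohort file %s: %s", path,
                                 conditionMessage(err)), call. = FALSE)
                  })
  if (!is.list(raw)) stop("cohort file must hold a JSON array of patients", call. = FALSE)
  records <- lapply(seq_along(raw), function(i) parse_patient(raw[[i]], i))
  ids <- vapply(records, `[[`, character(1), "patient_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate patient_id in cohort: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  records
}

join_or_na <- function(x) if (length(x) == 0L) NA_character_ else paste(x, collapse = ";")

#' @rdname cohort_io
#' @details `write_cohort_csv()` exports the same information in long
#'   format, one event per row, with list-valued fields joined by `;` and
#'   radiations coded `application:region`. This export is one-way; the
#'   JSON file is the round-trip format.
#' @export
write_cohort_csv <- function(records, path) {
  rows <- lapply(records, function(p) {
    cv <- p$covariates
    ev <- p$course$events
    if (length(ev) == 0L) ev <- list(NULL)
    do.call(rbind, lapply(seq_along(ev), function(i) {
      e <- ev[[i]]
      pay <- function(x) if (!is.null(e) && is_present(x)) paste(x$value, collapse = ";") else NA_character_
      data.frame(
        patient_id = p$patient_id,
        diagnosis_date = format(p$diagnosis_date),
        death_date = if (is.na(p$death_date)) NA_character_ else format(p$death_date),
        age = cv$age, grading = cv$grading, uicc = cv$uicc,
        uicc_substage = cv$uicc_substage, histology_code = cv$histology_code,
        lobular = cv$lobular,
        event_index = if (is.null(e)) NA_integer_ else i,
        event_type = if (is.null(e)) NA_character_ else e$type,
        event_date = if (is.null(e) || is.na(e$date)) NA_character_ else format(e$date),
        ev_uicc = if (!is.null(e) && e$type == "diagnosis") pay(e$uicc) else NA_character_,
        ev_ecog = if (!is.null(e) && e$type == "diagnosis") pay(e$ecog) else NA_character_,
        ev_age_group = if (!is.null(e) && e$type == "diagnosis") pay(e$age_group) else NA_character_,
        ev_histology = if (!is.null(e) && e$type == "diagnosis") pay(e$histology) else NA_character_,
        ev_grading = if (!is.null(e) && e$type == "diagnosis") pay(e$grading) else NA_character_,
        ev_procedure_codes = if (!is.null(e) && e$type == "surgery") join_or_na(e$procedure_codes) else NA_character_,
        ev_residual = if (!is.null(e) && e$type == "surgery") pay(e$residual) else NA_character_,
        ev_complications = if (!is.null(e) && e$type == "surgery") pay(e$complications) else NA_character_,
        ev_radiations = if (!is.null(e) && e$type == "radiotherapy") {
          join_or_na(vapply(e$radiations, function(r)
            paste0(r$application_type %||% "?", ":", r$target_region %||% "?"),
            character(1)))
        } else NA_character_,
        ev_therapy_type = if (!is.null(e) && e$type == "systemic") pay(e$therapy_type) else NA_character_,
        ev_temporal = if (!is.null(e) && e$type %in% c("radiotherapy", "systemic")) pay(e$temporal) else NA_character_,
        stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
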