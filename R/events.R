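#' Registry treatment events
#'
#' Constructors for the four event kinds that make up a treatment course:
#' the initial diagnosis, surgeries, radiotherapies and systemic therapies.
#' Raw field values are coerced to tri-state [attribute values][attr_value]
#' against the attribute's declared domain: absent fields become missing,
#' out-of-domain payloads become unrelated.
#'
#' @name events
NULL

# Attribute domains -----------------------------------------------------

#' Domain constants for event attributes
#'
#' @format Character / integer vectors naming the value sets used when
#'   coercing raw registry fields.
#' @name tc_domains
NULL

#' @rdname tc_domains
#' @export
HISTOLOGY_CODES <- c("8510/3", "8540/3", "8530/3", "8211/3", "8480/3", "8500/3")

#' @rdname tc_domains
#' @export
AGE_GROUPS <- c("Under50", "From50to69", "Over69")

#' @rdname tc_domains
#' @export
SURGERY_GROUPS <- c("BCS", "Mastectomy", "OtherBreast")

#' @rdname tc_domains
#' @export
TEMPORAL_RELATIONS <- c("A", "N", "I", "O")

#' @rdname tc_domains
#' @export
APPLICATION_TYPES <- c("Percutaneous", "Metabolic", "Contact", "Other")

#' @rdname tc_domains
#' @export
THERAPY_TYPES <- c("CH", "HO", "IM", "TS", "CI", "CT", "CIT", "IT",
                   "SC", "AS", "WS", "WW", "OT")

# type rank used for same-day ordering: diagnosis < surgery < radio < systemic
EVENT_TYPES <- c(diagnosis = 1L, surgery = 2L, radiotherapy = 3L, systemic = 4L)

#' Age screening band for an age at diagnosis
#'
#' Ages are grouped by mammography-screening eligibility: under 50, 50 to 69
#' inclusive, over 69.
#'
#' @param age integer age in years (NA allowed)
#' @return one of `"Under50"`, `"From50to69"`, `"Over69"`, or `NA`
#' @export
age_group_of <- function(age) {
  if (is.null(age) || length(age) == 0L || is.na(age)) return(NA_character_)
  if (age < 50) "Under50" else if (age <= 69) "From50to69" else "Over69"
}

new_event <- function(type, fields, date) {
  date <- if (is.null(date) || length(date) == 0L || all(is.na(date))) {
    as.Date(NA)
  } else {
    as.Date(date)
  }
  structure(c(list(type = type, date = date), fields),
            class = c(paste0("tc_", type), "tc_event"))
}

#' @export
print.tc_event <- function(x, ...) {
  flds <- setdiff(names(x), c("type", "date", "radiations", "procedure_codes"))
  vals <- vapply(x[flds], function(f) if (is_av(f)) format(f) else paste(format(f), collapse = ","),
                 character(1))
  cat(sprintf("<%s @ %s> %s\n", x$type,
              if (is.na(x$date)) "?" else format(x$date),
              paste(flds, vals, sep = "=", collapse = " ")))
  invisible(x)
}

#' @rdname events
#' @param uicc UICC stage mapped 0 (stage 0) to 4 (stage IV)
#' @param ecog ECOG performance score 0 (fully active) to 4 (completely disabled)
#' @param age_group one of `AGE_GROUPS`, or an age in years via `age =`
#' @param histology ICD-O morphology code; only the six codes in
#'   `HISTOLOGY_CODES` are comparable, all others become unrelated
#' @param grading differentiation scale 0 (melanoma of the conjunctiva) to
#'   8 (undifferentiated); G1/G2/G3 style gradings live on this scale too
#'   (low grade 3, moderately differentiated 4, poorly differentiated 6)
#' @param date event date (`Date` or ISO-8601 string; may be NA)
#' @param age optional integer age at diagnosis used to derive `age_group`
#' @export
diagnosis_event <- function(uicc = NULL, ecog = NULL, age_group = NULL,
                            histology = NULL, grading = NULL, date = NA,
                            age = NULL) {
  if (is.null(age_group) && !is.null(age)) age_group <- age_group_of(age)
  new_event("diagnosis", list(
    uicc = as_av_ordinal(uicc, 4L, "uicc"),
    ecog = as_av_ordinal(ecog, 4L, "ecog"),
    age_group = as_av(age_group, AGE_GROUPS),
    histology = as_av(histology, HISTOLOGY_CODES),
    grading = as_av_ordinal(grading, 8L, "grading")
  ), date)
}

#' Classify OPS procedure codes into a breast-surgery group
#'
#' Codes starting 5-870 are breast-conserving surgery (BCS); 5-872, 5-874 and
#' 5-877 are mastectomies; 5-879 other breast surgery. Codes outside the four
#' prefix families (e.g. accessory lymphadenectomy codes) are ignored. A
#' surgery matching exactly one group is assigned to it; matching zero or
#' several distinct groups makes the surgery type unrelated.
#'
#' @param codes character vector of OPS codes
#' @return `tc_attr` over `SURGERY_GROUPS`
#' @export
classify_surgery_group <- function(codes) {
  if (is.null(codes) || length(codes) == 0L) return(av_unrelated())
  codes <- as.character(codes)
  grp <- character(0)
  if (any(startsWith(codes, "5-870"))) grp <- c(grp, "BCS")
  if (any(startsWith(codes, "5-872") | startsWith(codes, "5-874") |
          startsWith(codes, "5-877"))) grp <- c(grp, "Mastectomy")
  if (any(startsWith(codes, "5-879"))) grp <- c(grp, "OtherBreast")
  if (length(grp) == 1L) av_present(grp) else av_unrelated()
}

# residual status: R0 -> 0, R1(is)/R1(cy+) -> 1, R1 -> 2, R2 -> 3
residual_to_ordinal <- function(x) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) return(NULL)
  if (is.numeric(x)) return(x)
  map <- c("R0" = 0, "R1(is)" = 1, "R1(cy+)" = 1, "R1" = 2, "R2" = 3)
  key <- as.character(x)
  if (!key %in% names(map)) return(NA)  # e.g. "RX" -> missing
  unname(map[[key]])
}

#' @rdname events
#' @param procedure_codes character vector of OPS codes for the surgery
#' @param residual residual tumor status: `"R0"`, `"R1(is)"`, `"R1(cy+)"`,
#'   `"R1"`, `"R2"` or the ordinal 0..3 directly
#' @param complications character vector of complication codes;
#'   `character(0)` means "documented: none" (an informative agreement),
#'   `NULL`/`NA` means not documented
#' @export
surgery_event <- function(procedure_codes = character(0), residual = NULL,
                          complications = NULL, date = NA) {
  res <- residual_to_ordinal(residual)
  comp <- if (is.null(complications) || (length(complications) > 0L && all(is.na(complications)))) {
    av_missing()
  } else {
    av_present(sort(unique(as.character(complications))))
  }
  new_event("surgery", list(
    procedure_codes = as.character(procedure_codes),
    surgery_group = classify_surgery_group(procedure_codes),
    residual = as_av_ordinal(res, 3L, "residual status"),
    complications = comp
  ), date)
}

#' Aggregate the radiations of a radiotherapy event
#'
#' The application types of the individual radiations are pooled into a set
#' (empty radiation list: missing). The target regions collapse to a single
#' value: `Breast` if only the breast is irradiated, `Thorax` if the thorax
#' (possibly with the breast) is irradiated, and unrelated as soon as any
#' region other than breast or thorax occurs.
#'
#' @param radiations list of `list(application_type =, target_region =)`
#' @return `list(application_types = tc_attr set, target_region = tc_attr)`
#' @export
aggregate_radiotherapy <- function(radiations) {
  if (is.null(radiations) || length(radiations) == 0L) {
    return(list(application_types = av_missing(), target_region = av_missing()))
  }
  types <- unlist(lapply(radiations, `[[`, "application_type"))
  regions <- tolower(unlist(lapply(radiations, `[[`, "target_region")))
  types <- types[!is.na(types)]
  app <- if (length(types) == 0L) {
    av_missing()
  } else if (all(types %in% APPLICATION_TYPES)) {
    av_present(sort(unique(types)))
  } else {
    av_unrelated()
  }
  regions <- regions[!is.na(regions)]
  region <- if (length(regions) == 0L) {
    av_missing()
  } else if (any(!regions %in% c("breast", "thorax"))) {
    av_unrelated()
  } else if (any(regions == "thorax")) {
    av_present("Thorax")
  } else {
    av_present("Breast")
  }
  list(application_types = app, target_region = region)
}

#' @rdname events
#' @param radiations list of individual radiations, each a
#'   `list(application_type =, target_region =)`; application types are one
#'   of `APPLICATION_TYPES`, target regions free strings
#' @param temporal temporal relation to the primary surgery: `"A"`djuvant,
#'   `"N"`eoadjuvant, `"I"`ntraoperative, `"O"` without relation
#' @export
radiotherapy_event <- function(radiations = list(), temporal = NULL, date = NA) {
  agg <- aggregate_radiotherapy(radiations)
  new_event("radiotherapy", list(
    radiations = radiations,
    application_types = agg$application_types,
    target_region = agg$target_region,
    temporal = as_av(temporal, TEMPORAL_RELATIONS)
  ), date)
}

#' @rdname events
#' @param therapy_type one of the 13 systemic therapy codes in
#'   `THERAPY_TYPES`; an absent type is treated as the matrix code MI
#' @export
systemic_event <- function(therapy_type = NULL, temporal = NULL, date = NA) {
  tt <- as_av(therapy_type, THERAPY_TYPES)
  # the matrix reserves MI for a missing type; an out-of-domain code is
  # equally incomparable, so both collapse to missing
  if (av_state(tt) == "unrelated") tt <- av_missing(raw = tt$raw)
  new_event("systemic", list(
    therapy_type = tt,
    temporal = as_av(temporal, TEMPORAL_RELATIONS)
  ), date)
}

#' Order events chronologically
#'
#' Stable sort by date; events on the same day are ordered diagnosis <
#' surgery < radiotherapy < systemic, and remaining ties keep input order.
#' Events without a date sort after all dated events.
#'
#' @param events list of `tc_event`
#' @return the sorted list
#' @export
order_events <- function(events) {
  if (length(events) == 0L) return(events)
  dates <- vapply(events, function(e) as.numeric(e$date), numeric(1))
  dates[is.na(dates)] <- Inf
  rank <- vapply(events, function(e) EVENT_TYPES[[e$type]], integer(1))
  events[order(dates, rank)]
}

#' Treatment courses and patient records
#'
#' A treatment course is the ordered event sequence of one patient, holding
#' at most one diagnosis event. A patient record wraps a course together
#' with the survival fields and the Cox covariates.
#'
#' @param patient_id unique patient identifier
#' @param events list of `tc_event` (any order; sorted on construction)
#' @return `tc_course` / `tc_patient`
#' @export
treatment_course <- function(patient_id, events = list()) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (!all(vapply(events, inherits, logical(1), "tc_event"))) {
    stop("all course elements must be treatment events", call. = FALSE)
  }
  ndiag <- sum(vapply(events, function(e) e$type == "diagnosis", logical(1)))
  if (ndiag > 1L) {
    stop(sprintf("course %s has %d diagnosis events (at most 1 allowed)",
                 patient_id, ndiag), call. = FALSE)
  }
  structure(list(patient_id = patient_id, events = order_events(events)),
            class = "tc_course")
}

#' @export
print.tc_course <- function(x, ...) {
  cat(sprintf("<course %s, %d events> %s\n", x$patient_id, length(x$events),
              paste(course_tokens(x), collapse = " -> ")))
  invisible(x)
}

#' @export
length.tc_course <- function(x) length(x$events)

#' @rdname treatment_course
#' @param course a `tc_course`
#' @param diagnosis_date date of diagnosis
#' @param death_date date of death or `NULL`/`NA` if alive at linkage
#' @param covariates list with `age` (years), `grading` (`"G1"`..`"G3"` or
#'   NA), `uicc` (main stage `"0"`,`"I"`..`"IV"` or NA), `uicc_substage`
#'   (e.g. `"IIA"`), `lobular` (logical)
#' @export
patient_record <- function(course, diagnosis_date, death_date = NULL,
                           covariates = list()) {
  stopifnot(inherits(course, "tc_course"))
  diagnosis_date <- as.Date(diagnosis_date)
  death_date <- if (is.null(death_date) || all(is.na(death_date))) {
    as.Date(NA)
  } else {
    as.Date(death_date)
  }
  if (!is.na(death_date) && death_date < diagnosis_date) {
    stop(sprintf("patient %s: death date precedes diagnosis date",
                 course$patient_id), call. = FALSE)
  }
  defaults <- list(age = NA_real_, grading = NA_character_,
                   uicc = NA_character_, uicc_substage = NA_character_,
                   histology_code = NA_character_, lobular = NA)
  covariates <- utils::modifyList(defaults, covariates[!vapply(covariates, is.null, logical(1))])
  if (is.na(covariates$lobular) && !is.na(covariates$histology_code)) {
    covariates$lobular <- covariates$histology_code == "8520/3"
  }
  structure(list(patient_id = course$patient_id, course = course,
                 diagnosis_date = diagnosis_date, death_date = death_date,
                 covariates = covariates),
            class = "tc_patient")
}

#' @export
print.tc_patient <- function(x, ...) {
  cat(sprintf("<patient %s> diagnosed %s, %s\n", x$patient_id,
              format(x$diagnosis_date),
              if (is.na(x$death_date)) "alive at linkage" else paste("died", format(x$death_date))))
  print(x$course)
  invisible(x)
}
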