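#' Subcohort filter specification
#'
#' The intercluster survival workflow restricts the cohort to patients aged
#' 50 to 69 at diagnosis who survived the landmark period (56 days after
#' diagnosis) and have a documented tumor grading, split into a
#' prognostically favorable subgroup (`"pf"`, UICC stage I or II) and an
#' unfavorable one (`"pu"`, stage III or IV).
#'
#' @param subgroup `"pf"` or `"pu"`
#' @param age_range inclusive age band at diagnosis
#' @param min_survival_days minimum survival after diagnosis (landmark)
#' @param require_grading drop patients with missing grading covariate
#' @return `tc_filter_spec`
#' @export
cohort_filter_spec <- function(subgroup = c("pf", "pu"),
                               age_range = c(50, 69),
                               min_survival_days = 56L,
                               require_grading = TRUE) {
  subgroup <- match.arg(subgroup)
  structure(list(subgroup = subgroup, age_range = age_range,
                 min_survival_days = as.integer(min_survival_days),
                 require_grading = require_grading,
                 uicc_stages = if (subgroup == "pf") c("I", "II") else c("III", "IV")),
            class = "tc_filter_spec")
}

#' Build a survival subcohort with an attrition table
#'
#' Applies the filters of a [cohort_filter_spec()] in a fixed order (age
#' band, landmark survival, grading documented, UICC subgroup) and reports
#' how many patients each rule removed.
#'
#' @param records list of `tc_patient`
#' @param spec a [cohort_filter_spec()]
#' @param censor_date date of last mortality linkage; patients alive are
#'   censored here, and landmark survival is assessed against death dates
#'   only
#' @return list with `records` (the retained patients) and `attrition`
#'   (data.frame of rule, removed, remaining)
#' @export
build_subcohort <- function(records, spec = cohort_filter_spec("pf"),
                            censor_date = as.Date("2023-06-30")) {
  stopifnot(inherits(spec, "tc_filter_spec"))
  steps <- list(
    age_band = function(p) {
      a <- p$covariates$age
      !is.na(a) && a >= spec$age_range[1] && a <= spec$age_range[2]
    },
    landmark_survival = function(p) {
      is.na(p$death_date) ||
        as.numeric(p$death_date - p$diagnosis_date) >= spec$min_survival_days
    },
    grading_documented = function(p) {
      !spec$require_grading || !is.na(p$covariates$grading)
    },
    uicc_subgroup = function(p) {
      u <- p$covariates$uicc
      !is.na(u) && u %in% spec$uicc_stages
    }
  )
  attr_rows <- list()
  for (rule in names(steps)) {
    keep <- vapply(records, steps[[rule]], logical(1))
    attr_rows[[rule]] <- data.frame(rule = rule, removed = sum(!keep),
                                    remaining = sum(keep))
    records <- records[keep]
  }
  list(records = records, attrition = do.call(rbind, c(attr_rows, make.row.names = FALSE)))
}

#' Landmark survival records
#'
#' Converts patients plus cluster labels into the analysis table: time in
#' days from the landmark origin (diagnosis + `landmark_days`) to death or
#' right censoring at `censor_date`, with the Cox covariates.
#'
#' @param records list of `tc_patient` (already filtered to survive the
#'   landmark period)
#' @param labels named integer vector of cluster labels (names = patient
#'   ids); the DBSCAN outlier label -1 participates as its own cluster
#' @param landmark_days landmark period after diagnosis (default 56)
#' @param censor_date right-censoring date (last mortality linkage)
#' @return data.frame: patient_id, time, event, cluster (factor), age,
#'   grading, uicc_substage, lobular
#' @export
survival_records <- function(records, labels,
                             landmark_days = 56L,
                             censor_date = as.Date("2023-06-30")) {
  censor_date <- as.Date(censor_date)
  rows <- lapply(records, function(p) {
    lab <- labels[[p$patient_id]]
    if (is.null(lab)) return(NULL)
    origin <- p$diagnosis_date + landmark_days
    end <- if (is.na(p$death_date)) censor_date else min(p$death_date, censor_date)
    event <- !is.na(p$death_date) && p$death_date <= censor_date
    time <- as.numeric(end - origin)
    if (time <= 0) {
      stop(sprintf("patient %s: non-positive landmark time; filter the cohort with build_subcohort() first",
                   p$patient_id), call. = FALSE)
    }
    cv <- p$covariates
    data.frame(patient_id = p$patient_id, time = time, event = as.integer(event),
               cluster = lab, age = cv$age, grading = cv$grading,
               uicc_substage = cv$uicc_substage, lobular = isTRUE(cv$lobular),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$cluster <- factor(out$cluster)
  out
}

#' Landmark Kaplan-Meier per cluster
#'
#' Product-limit estimator with right censoring for each cluster, with
#' complementary log-log (Greenwood) confidence intervals, read out at the
#' survival horizon (4 years = 1460 days from the landmark origin by
#' default). Clusters without any death are flagged as excluded - their
#' KM curve is uninformative for intercluster comparison and they cannot
#' enter the Cox model - but they are listed, not silently dropped.
#'
#' @param srec survival records from [survival_records()]
#' @param horizon_days readout time in days from the landmark origin
#' @param conf_level confidence level for the Greenwood interval
#' @return `tc_km`: list with `table` (cluster, n, deaths, survival at the
#'   horizon, CI bounds, excluded flag) and `fits` (a `survfit` per cluster)
#' @export
landmark_km <- function(srec, horizon_days = 1460L, conf_level = 0.95) {
  stopifnot(nrow(srec) > 0)
  out <- list()
  fits <- list()
  for (cl in levels(srec$cluster)) {
    sub <- srec[srec$cluster == cl, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty cluster ", cl, call. = FALSE)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub,
                             conf.type = "log-log", conf.int = conf_level)
    fits[[cl]] <- fit
    sm <- summary(fit, times = horizon_days, extend = TRUE)
    out[[cl]] <- data.frame(cluster = cl, n = nrow(sub),
                            deaths = sum(sub$event),
                            survival = sm$surv, lower = sm$lower,
                            upper = sm$upper,
                            excluded = sum(sub$event) == 0L,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(out, make.row.names = FALSE))
  structure(list(table = tab, fits = fits, horizon_days = horizon_days),
            class = "tc_km")
}

#' @export
print.tc_km <- function(x, ...) {
  cat(sprintf("<landmark Kaplan-Meier, %d clusters, horizon %d days>\n",
              nrow(x$table), x$horizon_days))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Reference cluster for the Cox model
#'
#' The cluster with the highest observed horizon survival among non-excluded
#' clusters; ties go to the larger cluster, then the smaller label.
#'
#' @param km a `tc_km` from [landmark_km()]
#' @return the reference cluster label (character)
#' @export
select_reference_cluster <- function(km) {
  stopifnot(inherits(km, "tc_km"))
  tab <- km$table[!km$table$excluded, , drop = FALSE]
  if (nrow(tab) == 0L) stop("all clusters are excluded (no deaths anywhere)", call. = FALSE)
  ord <- order(-tab$survival, -tab$n, tab$cluster)
  tab$cluster[ord[1L]]
}

#' Cox proportional hazards model across clusters
#'
#' Fits `Surv(time, event) ~ cluster + lobular + uicc_substage + grading +
#' age` with the supplied reference cluster, reference substage and
#' reference grading G1. Zero-death clusters must have been excluded
#' upstream (they cause separation). Returns the hazard-ratio table in the
#' usual layout: cluster rows first with the reference marked (HR 1, no
#' CI), then covariate rows.
#'
#' @param srec survival records from [survival_records()]
#' @param reference reference cluster label, see
#'   [select_reference_cluster()]
#' @param reference_substage reference level for the UICC substage factor
#'   (default: first level present, e.g. `"IA"` in the favorable subgroup,
#'   `"IIIA"` in the unfavorable one)
#' @param exclude_clusters labels to drop before fitting (e.g. the
#'   zero-death clusters flagged by [landmark_km()])
#' @param extra_terms names of additional covariate columns in `srec` to
#'   adjust for (e.g. a gender column, off by default)
#' @param conf_level confidence level for the hazard-ratio intervals
#' @return `tc_coxfit`: list with `fit` (the `coxph` object), `table`
#'   (term, hazard_ratio, se, lower, upper, reference flag), `reference`,
#'   `data` (the model data), `convergence` diagnostics
#' @export
cox_fit <- function(srec, reference, reference_substage = NULL,
                    exclude_clusters = character(0),
                    extra_terms = character(0), conf_level = 0.95) {
  srec <- srec[!(as.character(srec$cluster) %in% as.character(exclude_clusters)), , drop = FALSE]
  srec$cluster <- stats::relevel(factor(as.character(srec$cluster)),
                                 ref = as.character(reference))
  if (nlevels(srec$cluster) < 2L) {
    stop("fewer than 2 clusters remain after exclusions; ",
         "no intercluster comparison possible", call. = FALSE)
  }
  dead_by_cl <- tapply(srec$event, srec$cluster, sum)
  if (any(dead_by_cl == 0)) {
    stop("cluster(s) without deaths in the Cox data: ",
         paste(names(dead_by_cl)[dead_by_cl == 0], collapse = ", "),
         "; exclude them upstream (see landmark_km)", call. = FALSE)
  }
  terms <- "cluster"
  if (length(unique(srec$lobular[!is.na(srec$lobular)])) > 1L) terms <- c(terms, "lobular")
  if (length(unique(srec$uicc_substage[!is.na(srec$uicc_substage)])) > 1L) {
    subs <- sort(unique(srec$uicc_substage))
    ref_sub <- if (is.null(reference_substage)) subs[1L] else reference_substage
    srec$uicc_substage <- stats::relevel(factor(srec$uicc_substage, levels = subs),
                                         ref = ref_sub)
    terms <- c(terms, "uicc_substage")
  }
  if (length(unique(srec$grading[!is.na(srec$grading)])) > 1L) {
    srec$grading <- factor(srec$grading, levels = sort(unique(srec$grading)))
    terms <- c(terms, "grading")
  }
  if (length(unique(srec$age[!is.na(srec$age)])) > 1L) terms <- c(terms, "age")
  if (length(extra_terms) > 0L) {
    missing_cols <- setdiff(extra_terms, names(srec))
    if (length(missing_cols) > 0L) {
      stop("extra_terms not found in the survival records: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    terms <- c(terms, extra_terms)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = srec, model = TRUE)
  iter_max <- if (is.null(fit$control$iter.max)) 20L else fit$control$iter.max
  conv <- list(converged = is.finite(fit$loglik[2]) && fit$iter < iter_max,
               iterations = fit$iter,
               warn = if (anyNA(stats::coef(fit)))
                 "inestimable coefficient(s): collinear covariates"
               else if (any(abs(stats::coef(fit)) > 15))
                 "very large coefficient: possible separation" else NULL)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(term = names(co), hazard_ratio = exp(co), se = se,
                    lower = exp(co - z * se), upper = exp(co + z * se),
                    reference = FALSE, stringsAsFactors = FALSE)
  # insert reference rows (HR 1, no CI) before their factor's rows
  ref_rows <- data.frame(
    term = c(paste0("cluster", levels(srec$cluster)[1L], " (reference)"),
             if ("uicc_substage" %in% terms)
               paste0("uicc_substage", levels(srec$uicc_substage)[1L], " (reference)"),
             if ("grading" %in% terms)
               paste0("grading", levels(srec$grading)[1L], " (reference)")),
    hazard_ratio = 1, se = NA_real_, lower = NA_real_, upper = NA_real_,
    reference = TRUE, stringsAsFactors = FALSE)
  tab <- rbind(tab, ref_rows)
  # stable display order: clusters, lobular, substage, grading, age
  key <- function(tm) {
    if (startsWith(tm, "cluster")) 1
    else if (startsWith(tm, "lobular")) 2
    else if (startsWith(tm, "uicc_substage")) 3
    else if (startsWith(tm, "grading")) 4
    else 5
  }
  tab <- tab[order(vapply(tab$term, key, numeric(1)), tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(fit = fit, table = tab, reference = as.character(reference),
                 data = srec, terms = terms, conf_level = conf_level,
                 convergence = conv),
            class = "tc_coxfit")
}

#' @export
print.tc_coxfit <- function(x, ...) {
  cat(sprintf("<Cox PH fit: %d patients, %d deaths, reference cluster %s%s>\n",
              nrow(x$data), sum(x$data$event), x$reference,
              if (!x$convergence$converged) ", NOT CONVERGED" else ""))
  if (!is.null(x$convergence$warn)) cat("  warning:", x$convergence$warn, "\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Confounder-adjusted survival curves by G-computation
#'
#' For every cluster c, each patient's cluster is counterfactually set to c,
#' the fitted Cox model predicts that patient's survival curve, and the
#' curves are averaged over the cohort; this yields one covariate-adjusted
#' curve per cluster on a common time grid. Predictions use the model's
#' estimated baseline hazard (`stype = 2`, the Breslow-type exponential of
#' the cumulative hazard, by default; `stype = 1` requests the
#' product-limit form, under which a strata-only model reproduces the
#' stratified Kaplan-Meier exactly).
#'
#' @param coxfit a `tc_coxfit` (or a plain `coxph` fit with `model = TRUE`)
#' @param srec survival records to standardize over (defaults to the model
#'   data)
#' @param times time grid in days; defaults to the event times observed in
#'   the data; times beyond the last observed time are truncated
#' @param stype survival estimate type passed to `survfit`
#' @return `tc_adjusted`: list with `times` and `curves`, a matrix with one
#'   column per cluster, rows on the time grid; curves start at 1 and are
#'   non-increasing
#' @export
g_computation_curves <- function(coxfit, srec = NULL, times = NULL, stype = 2) {
  fit <- if (inherits(coxfit, "tc_coxfit")) coxfit$fit else coxfit
  if (is.null(srec)) {
    srec <- if (inherits(coxfit, "tc_coxfit")) coxfit$data
            else stop("srec required when passing a bare coxph fit", call. = FALSE)
  }
  cl_levels <- levels(factor(srec$cluster))
  tmax <- max(srec$time)
  if (is.null(times)) {
    times <- sort(unique(srec$time[srec$event == 1]))
  }
  times <- times[times <= tmax]  # truncate at the observed follow-up
  times <- sort(unique(c(0, times)))
  curves <- base::matrix(NA_real_, length(times), length(cl_levels),
                         dimnames = list(NULL, cl_levels))
  if (length(stats::coef(fit)) == 0L) {
    # coefficient-less (e.g. strata-only) model: the counterfactual curve of
    # every patient under cluster c is the stratum-c baseline itself
    sf <- survival::survfit(fit, se.fit = FALSE, stype = stype)
    sm <- summary(sf, times = times, extend = TRUE)
    strat <- sub("^.*=", "", as.character(sm$strata))
    for (cl in cl_levels) {
      curves[, cl] <- sm$surv[strat == cl]
    }
  } else {
    for (cl in cl_levels) {
      nd <- srec
      nd$cluster <- factor(cl, levels = levels(srec$cluster))
      sf <- survival::survfit(fit, newdata = nd, se.fit = FALSE, stype = stype)
      sm <- summary(sf, times = times, extend = TRUE)
      surv <- sm$surv
      if (is.null(dim(surv))) surv <- base::matrix(surv, ncol = nrow(nd))
      curves[, cl] <- rowMeans(surv)
    }
  }
  structure(list(times = times, curves = curves), class = "tc_adjusted")
}

#' @export
print.tc_adjusted <- function(x, ...) {
  cat(sprintf("<G-computation adjusted curves: %d clusters on %d time points>\n",
              ncol(x$curves), length(x$times)))
  invisible(x)
}

#' Write survival outputs as CSV
#'
#' @param km a `tc_km`
#' @param path file path
#' @export
write_km_csv <- function(km, path) {
  rows <- lapply(names(km$fits), function(cl) {
    f <- km$fits[[cl]]
    data.frame(cluster = cl, time = f$time, survival = f$surv,
               lower = f$lower, upper = f$upper)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_km_csv
#' @param coxfit a `tc_coxfit`
#' @export
write_hr_csv <- function(coxfit, path) {
  utils::write.csv(coxfit$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_km_csv
#' @param adjusted a `tc_adjusted`
#' @export
write_adjusted_csv <- function(adjusted, path) {
  df <- data.frame(time = adjusted$times, adjusted$curves, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
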