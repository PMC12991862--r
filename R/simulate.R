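#' Archetype specification for the cohort generator
#'
#' A course archetype is a template event sequence with per-attribute value
#' distributions (probabilities may include a missing mass), an age band,
#' a planted log hazard ratio, and perturbation rates: each attribute is
#' independently resampled from its distribution with probability
#' `resample`, each non-diagnosis event is dropped with probability `drop`,
#' and with probability `insert` one extra event is duplicated into the
#' course. Mixture weights over archetypes must sum to 1.
#'
#' Attribute distributions are `list(values =, probs =)`; an `NA` value
#' means the attribute is not documented. Template events are lists with a
#' `type`, a `gap` (meanlog/sdlog of the lognormal day gap to the previous
#' event), an optional `present_prob`, and type-specific attribute
#' distributions.
#'
#' @param name archetype name
#' @param weight mixture weight
#' @param age_band one of `AGE_GROUPS`
#' @param events list of template events (first is normally the diagnosis)
#' @param loghr planted log hazard ratio relative to the baseline hazard
#' @param resample,drop,insert perturbation probabilities in [0,1]
#' @return `tc_archetype`
#' @export
archetype_spec <- function(name, weight, age_band, events, loghr = 0,
                           resample = 0.05, drop = 0.02, insert = 0.01) {
  stopifnot(weight >= 0, age_band %in% AGE_GROUPS,
            resample >= 0, resample <= 1, drop >= 0, drop <= 1,
            insert >= 0, insert <= 1)
  structure(list(name = name, weight = weight, age_band = age_band,
                 events = events, loghr = loghr, resample = resample,
                 drop = drop, insert = insert),
            class = "tc_archetype")
}

#' Survival model specification for the generator
#'
#' Death times follow a proportional-hazards model: an exponential (or
#' Weibull) baseline multiplied by the archetype's planted hazard ratio and
#' the covariate effects. Patients are enrolled uniformly over the
#' diagnosis year and right-censored administratively at the censor date.
#'
#' @param baseline `"exponential"` or `"weibull"`
#' @param rate baseline rate per day
#' @param shape Weibull shape (ignored for exponential)
#' @param age_effect log-HR per year of age (centered at age 60)
#' @param grading_effect named log-HRs for G2 and G3 (reference G1)
#' @param stage_effect named log-HRs per main UICC stage (reference I)
#' @param lobular_effect log-HR for lobular histology
#' @param censor_date administrative censoring date
#' @param enrollment_year diagnosis year (dates drawn uniformly within)
#' @return `tc_survival_spec`
#' @export
survival_spec <- function(baseline = c("exponential", "weibull"),
                          rate = 2e-5, shape = 1,
                          age_effect = 0.05,
                          grading_effect = c(G2 = 0.2, G3 = 0.7),
                          stage_effect = c("0" = -0.2, "I" = 0, "II" = 0.5,
                                           "III" = 1.0, "IV" = 1.8),
                          lobular_effect = 0.2,
                          censor_date = as.Date("2023-06-30"),
                          enrollment_year = 2019L) {
  baseline <- match.arg(baseline)
  stopifnot(rate > 0, shape > 0)
  enroll_end <- as.Date(sprintf("%d-12-31", enrollment_year))
  if (censor_date <= enroll_end) {
    stop("censor date must lie after the enrollment window", call. = FALSE)
  }
  structure(list(baseline = baseline, rate = rate, shape = shape,
                 age_effect = age_effect, grading_effect = grading_effect,
                 stage_effect = stage_effect, lobular_effect = lobular_effect,
                 censor_date = censor_date,
                 enrollment_year = as.integer(enrollment_year)),
            class = "tc_survival_spec")
}

# sample one value from a list(values, probs) distribution
draw1 <- function(dist) {
  i <- sample.int(length(dist$probs), 1L, prob = dist$probs)
  dist$values[[i]]
}

dist_spec <- function(values, probs) list(values = values, probs = probs)

# substage conditional on main stage
draw_substage <- function(stage) {
  switch(stage,
         "0" = "0",
         "I" = sample(c("IA", "IB"), 1L, prob = c(0.95, 0.05)),
         "II" = sample(c("IIA", "IIB"), 1L, prob = c(0.74, 0.26)),
         "III" = sample(c("IIIA", "IIIB", "IIIC"), 1L, prob = c(0.41, 0.28, 0.31)),
         "IV" = "IV",
         NA_character_)
}

STAGE_ORDINAL <- c("0" = 0L, "I" = 1L, "II" = 2L, "III" = 3L, "IV" = 4L)
GRADING_SCALE <- c(G1 = 2L, G2 = 4L, G3 = 6L)

# shared attribute distributions. ECOG is rarely documented in registry
# extracts; keeping its missing mass high (and archetype-independent) makes
# its contribution to the course distance near-constant rather than noisy.
.ecog_dist <- dist_spec(list(0L, 1L, NA), c(0.07, 0.03, 0.90))
.hist_dist <- dist_spec(list("8500/3", "8520/3", "8140/3", "8480/3"),
                        c(0.85, 0.08, 0.05, 0.02))

diag_template <- function(uicc, grading, ecog = .ecog_dist, hist = .hist_dist) {
  list(type = "diagnosis", gap = NULL, uicc = uicc, grading = grading,
       ecog = ecog, histology = hist)
}

surgery_template <- function(codes, gap = c(log(30), 0.5),
                             residual = dist_spec(list(0L, 2L, NA), c(0.92, 0.03, 0.05)),
                             complications = dist_spec(
                               list(character(0), "bleeding", "infection", NA),
                               c(0.85, 0.03, 0.02, 0.10)),
                             present_prob = 1) {
  list(type = "surgery", gap = gap, codes = codes, residual = residual,
       complications = complications, present_prob = present_prob)
}

radio_template <- function(gap = c(log(45), 0.4),
                           region = dist_spec(list("breast"), 1),
                           temporal = dist_spec(list("A", NA), c(0.95, 0.05)),
                           present_prob = 1) {
  list(type = "radiotherapy", gap = gap, region = region, temporal = temporal,
       present_prob = present_prob)
}

systemic_template <- function(type, gap = c(log(40), 0.5),
                              temporal = dist_spec(list("A", NA), c(0.95, 0.05)),
                              present_prob = 1) {
  list(type = "systemic", gap = gap, therapy_type = type, temporal = temporal,
       present_prob = present_prob)
}

#' Default breast-cancer archetype set
#'
#' Nine archetypes emulating the course shapes a registry extract shows:
#' diagnosis-only cases in each of the three age bands, single-surgery
#' cases (breast-conserving or mastectomy), BCS with adjuvant radiotherapy,
#' BCS followed by hormone therapy (a minority with additional
#' radiotherapy), a multimodal neoadjuvant-chemotherapy course, and a small
#' "implausible" archetype whose radiotherapy is dated before its BCS, for
#' data-quality workflows. Mixture weights are chosen so the generated age
#' bands and treatment-modality marginals land near the registry cohort's
#' published frequencies; the joint structure is archetype-driven.
#'
#' @param implausible_weight mixture weight of the implausible archetype
#'   (default 0.02; set to 0 to disable, other weights are rescaled)
#' @return list of [archetype_spec()]
#' @export
default_archetypes <- function(implausible_weight = 0.02) {
  a <- list(
    archetype_spec("dx_only_under50", 0.112, "Under50",
                   list(diag_template(
                     uicc = dist_spec(list(NA, "II", "I"), c(0.35, 0.45, 0.20)),
                     grading = dist_spec(list("G3", "G2", NA), c(0.60, 0.30, 0.10)))),
                   loghr = 1.3),
    archetype_spec("dx_only_50to69", 0.016, "From50to69",
                   list(diag_template(
                     uicc = dist_spec(list(NA, "I", "II"), c(0.35, 0.45, 0.20)),
                     grading = dist_spec(list("G1", "G2", NA), c(0.45, 0.45, 0.10)))),
                   loghr = 1.1),
    archetype_spec("dx_only_over69", 0.252, "Over69",
                   list(diag_template(
                     uicc = dist_spec(list(NA, "IV", "III"), c(0.35, 0.40, 0.25)),
                     grading = dist_spec(list("G2", "G3", NA), c(0.60, 0.30, 0.10)))),
                   loghr = 1.3),
    archetype_spec("surgery_only_bcs", 0.056, "Over69",
                   list(diag_template(
                     uicc = dist_spec(list("I", "II", NA), c(0.60, 0.25, 0.15)),
                     grading = dist_spec(list("G1", "G2", NA), c(0.50, 0.40, 0.10))),
                     surgery_template(c("5-870.0", "5-870.1"))),
                   loghr = 0.3),
    archetype_spec("surgery_only_mastectomy", 0.061, "Over69",
                   list(diag_template(
                     uicc = dist_spec(list("II", "III", NA), c(0.55, 0.30, 0.15)),
                     grading = dist_spec(list("G2", "G3", NA), c(0.55, 0.35, 0.10))),
                     surgery_template(c("5-872.0"))),
                   loghr = 0.5),
    archetype_spec("bcs_radiotherapy", 0.138, "From50to69",
                   list(diag_template(
                     uicc = dist_spec(list("I", "0", NA), c(0.65, 0.20, 0.15)),
                     grading = dist_spec(list("G1", "G2", NA), c(0.45, 0.45, 0.10))),
                     surgery_template(c("5-870.1")),
                     radio_template()),
                   loghr = -0.3),
    archetype_spec("bcs_hormone_therapy", 0.225, "Under50",
                   list(diag_template(
                     uicc = dist_spec(list("I", "II", NA), c(0.55, 0.30, 0.15)),
                     grading = dist_spec(list("G2", "G1", NA), c(0.65, 0.25, 0.10))),
                     surgery_template(c("5-870.2")),
                     systemic_template(dist_spec(list("HO", "IT"), c(0.95, 0.05))),
                     radio_template(present_prob = 0.10)),
                   loghr = 0),
    archetype_spec("chemo_multimodal", 0.120, "Under50",
                   list(diag_template(
                     uicc = dist_spec(list("III", "II", "IV", NA), c(0.45, 0.30, 0.10, 0.15)),
                     grading = dist_spec(list("G3", "G2", NA), c(0.60, 0.30, 0.10))),
                     systemic_template(dist_spec(list("CH", "CT", "CI"), c(0.85, 0.10, 0.05)),
                                       gap = c(log(20), 0.4),
                                       temporal = dist_spec(list("N", NA), c(0.95, 0.05))),
                     surgery_template(c("5-872.1"), gap = c(log(120), 0.3)),
                     radio_template(region = dist_spec(list("breast", "thorax"), c(0.8, 0.2))),
                     systemic_template(dist_spec(list("HO"), 1), gap = c(log(30), 0.4))),
                   loghr = 0.8),
    archetype_spec("implausible_rt_before_bcs", 0.020, "Under50",
                   list(diag_template(
                     uicc = dist_spec(list("I", "II", NA), c(0.55, 0.25, 0.20)),
                     grading = dist_spec(list("G2", "G1", NA), c(0.55, 0.35, 0.10))),
                     radio_template(gap = c(log(20), 0.3)),
                     surgery_template(c("5-870.1"), gap = c(log(40), 0.3))),
                   loghr = 0.6)
  )
  w <- vapply(a, `[[`, numeric(1), "weight")
  imp <- length(a)
  w_other <- w[-imp] / sum(w[-imp]) * (1 - implausible_weight)
  for (i in seq_len(imp - 1L)) a[[i]]$weight <- w_other[i]
  a[[imp]]$weight <- implausible_weight
  if (implausible_weight == 0) a <- a[-imp]
  a
}

sample_age <- function(band) {
  switch(band,
         Under50 = sample(32:49, 1L),
         From50to69 = sample(50:69, 1L),
         Over69 = sample(70:90, 1L))
}

# resample-with-probability wrapper
perturb_draw <- function(value, dist, p) {
  if (stats::runif(1) < p) draw1(dist) else value
}

build_patient <- function(pid, arch, spec) {
  diag_date <- as.Date(sprintf("%d-01-01", spec$enrollment_year)) +
    sample.int(365L, 1L) - 1L
  age <- sample_age(arch$age_band)
  # age band perturbation: with prob resample the patient falls in a
  # neighbouring band (registry ages are not perfectly archetypal)
  if (stats::runif(1) < arch$resample) {
    age <- sample_age(sample(AGE_GROUPS, 1L))
  }
  events <- list()
  truth_cov <- list(stage = NA_character_, grading = NA_character_,
                    histology = NA_character_)
  cur_date <- diag_date
  for (tpl in arch$events) {
    if (!is.null(tpl$present_prob) && stats::runif(1) >= tpl$present_prob) next
    if (!is.null(tpl$gap)) {
      cur_date <- cur_date + max(1, round(stats::rlnorm(1, tpl$gap[1], tpl$gap[2])))
    }
    r <- arch$resample
    if (tpl$type == "diagnosis") {
      stage <- draw1(tpl$uicc)
      grading <- draw1(tpl$grading)
      hist_code <- draw1(tpl$histology)
      ecog <- draw1(tpl$ecog)
      truth_cov$stage <- if (is.na(stage)) NA_character_ else stage
      truth_cov$grading <- if (is.na(grading)) NA_character_ else grading
      truth_cov$histology <- hist_code
      events[[length(events) + 1L]] <- diagnosis_event(
        uicc = if (is.na(stage)) NULL else STAGE_ORDINAL[[stage]],
        ecog = if (is.na(ecog)) NULL else ecog,
        age = age,
        histology = hist_code,
        grading = if (is.na(grading)) NULL else GRADING_SCALE[[grading]],
        date = cur_date)
    } else if (tpl$type == "surgery") {
      if (stats::runif(1) < arch$drop) next
      res <- perturb_draw(draw1(tpl$residual), tpl$residual, r)
      comp <- perturb_draw(draw1(tpl$complications), tpl$complications, r)
      events[[length(events) + 1L]] <- surgery_event(
        procedure_codes = tpl$codes,
        residual = if (length(res) == 1L && is.na(res)) NULL else res,
        complications = if (length(comp) == 1L && is.na(comp)) NULL else comp,
        date = cur_date)
    } else if (tpl$type == "radiotherapy") {
      if (stats::runif(1) < arch$drop) next
      region <- perturb_draw(draw1(tpl$region), tpl$region, r)
      temporal <- perturb_draw(draw1(tpl$temporal), tpl$temporal, r)
      events[[length(events) + 1L]] <- radiotherapy_event(
        radiations = list(list(application_type = "Percutaneous",
                               target_region = region)),
        temporal = if (is.na(temporal)) NULL else temporal,
        date = cur_date)
    } else if (tpl$type == "systemic") {
      if (stats::runif(1) < arch$drop) next
      ty <- perturb_draw(draw1(tpl$therapy_type), tpl$therapy_type, r)
      temporal <- perturb_draw(draw1(tpl$temporal), tpl$temporal, r)
      events[[length(events) + 1L]] <- systemic_event(
        therapy_type = if (is.na(ty)) NULL else ty,
        temporal = if (is.na(temporal)) NULL else temporal,
        date = cur_date)
    }
  }
  # occasional duplicated event (e.g. a re-excision or a second therapy block)
  dup_ok <- which(vapply(events, function(e) e$type != "diagnosis", logical(1)))
  if (length(dup_ok) > 0L && stats::runif(1) < arch$insert) {
    e <- events[[dup_ok[sample.int(length(dup_ok), 1L)]]]
    e$date <- cur_date + max(1, round(stats::rlnorm(1, log(30), 0.4)))
    events[[length(events) + 1L]] <- e
  }

  # survival: proportional-hazards draw on the planted archetype hazard
  lp <- arch$loghr + spec$age_effect * (age - 60)
  if (!is.na(truth_cov$grading) && truth_cov$grading %in% names(spec$grading_effect)) {
    lp <- lp + spec$grading_effect[[truth_cov$grading]]
  }
  if (!is.na(truth_cov$stage) && truth_cov$stage %in% names(spec$stage_effect)) {
    lp <- lp + spec$stage_effect[[truth_cov$stage]]
  }
  lobular <- identical(truth_cov$histology, "8520/3")
  if (lobular) lp <- lp + spec$lobular_effect
  t_days <- if (spec$baseline == "exponential") {
    stats::rexp(1, rate = spec$rate * exp(lp))
  } else {
    # Weibull PH: S(t) = exp(-(rate*t)^shape * exp(lp))
    (stats::rexp(1, rate = exp(lp)))^(1 / spec$shape) / spec$rate
  }
  t_days <- max(1, round(t_days))
  death <- diag_date + t_days
  censored <- death > spec$censor_date

  rec <- patient_record(
    treatment_course(pid, events),
    diagnosis_date = diag_date,
    death_date = if (censored) NULL else death,
    covariates = list(age = age, grading = truth_cov$grading,
                      uicc = truth_cov$stage,
                      uicc_substage = if (is.na(truth_cov$stage)) NULL
                                      else draw_substage(truth_cov$stage),
                      histology_code = truth_cov$histology))
  list(record = rec,
       truth = data.frame(patient_id = pid, archetype = arch$name,
                          loghr = arch$loghr, lp = lp,
                          event_time = t_days, stringsAsFactors = FALSE))
}

#' Generate a synthetic registry cohort
#'
#' Draws `n` patients from the archetype mixture, applies the archetypes'
#' perturbations and missingness, dates events consistently with their
#' temporal relations (neoadjuvant therapy before the surgery date,
#' adjuvant after), and draws death times from the proportional-hazards
#' model. The truth table records each patient's archetype, planted
#' log-HR, linear predictor and uncensored event time. Deterministic for a
#' fixed seed.
#'
#' @param archetypes list of [archetype_spec()] with weights summing to 1
#' @param spec a [survival_spec()]
#' @param n cohort size (n = 0 gives an empty cohort)
#' @param seed integer seed
#' @return list with `records` (list of `tc_patient`) and `truth`
#'   (data.frame)
#' @export
generate_cohort <- function(archetypes, spec = survival_spec(), n, seed = 1L) {
  stopifnot(inherits(spec, "tc_survival_spec"), n >= 0)
  if (!all(vapply(archetypes, inherits, logical(1), "tc_archetype"))) {
    stop("archetypes must be archetype_spec() objects", call. = FALSE)
  }
  w <- vapply(archetypes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("archetype weights must sum to 1", call. = FALSE)
  }
  if (n == 0L) {
    return(list(records = list(),
                truth = data.frame(patient_id = character(0),
                                   archetype = character(0), loghr = numeric(0),
                                   lp = numeric(0), event_time = numeric(0))))
  }
  set.seed(seed)
  arch_ix <- sample.int(length(archetypes), n, replace = TRUE, prob = w)
  out <- vector("list", n)
  width <- max(5L, nchar(as.character(n)))
  for (i in seq_len(n)) {
    pid <- sprintf(paste0("P%0", width, "d"), i)
    out[[i]] <- build_patient(pid, archetypes[[arch_ix[i]]], spec)
  }
  list(records = lapply(out, `[[`, "record"),
       truth = do.call(rbind, c(lapply(out, `[[`, "truth"),
                                make.row.names = FALSE)))
}

#' Default synthetic breast-cancer cohort
#'
#' [generate_cohort()] with [default_archetypes()] and the default
#' [survival_spec()].
#'
#' @inheritParams generate_cohort
#' @inheritParams default_archetypes
#' @return list with `records` and `truth`
#' @export
default_breast_cohort <- function(n, seed = 1L, implausible_weight = 0.02) {
  generate_cohort(default_archetypes(implausible_weight), survival_spec(),
                  n = n, seed = seed)
}

#' Simulate a minimal clustered survival cohort
#'
#' A stripped-down proportional-hazards simulator for calibration studies:
#' patients are split evenly across `k` clusters with planted log hazard
#' ratios, event times are exponential, and censoring times are uniform on
#' (0, c) with c calibrated so the expected censoring fraction matches
#' `censor_frac`.
#'
#' @param n patients
#' @param log_hrs planted log-HRs, one per cluster (first is reference 0 by
#'   convention)
#' @param baseline_rate exponential baseline rate
#' @param censor_frac target expected fraction censored
#' @param seed integer seed
#' @return data.frame with time, event, cluster (factor)
#' @export
simulate_survival_cohort <- function(n, log_hrs = c(0, 0.7, 1.4),
                                     baseline_rate = 0.1, censor_frac = 0.2,
                                     seed = 1L) {
  set.seed(seed)
  k <- length(log_hrs)
  cl <- rep_len(seq_len(k), n)
  theta <- baseline_rate * exp(log_hrs[cl])
  tt <- stats::rexp(n, rate = theta)
  cmax <- calibrate_uniform_censoring(baseline_rate * exp(log_hrs), censor_frac)
  cens <- stats::runif(n, 0, cmax)
  data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens),
             cluster = factor(cl - 1L))
}

# expected censoring fraction under C ~ U(0, c), T ~ Exp(theta_k), equal
# cluster shares: mean_k (1 - exp(-theta_k c)) / (theta_k c)
calibrate_uniform_censoring <- function(thetas, target) {
  stopifnot(target > 0, target < 1)
  f <- function(cc) mean((1 - exp(-thetas * cc)) / (thetas * cc)) - target
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}
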