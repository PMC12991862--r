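mk_patient <- function(id, age, diag, death = NULL, grading = "G2",
                       uicc = "I", substage = "IA", hist = "8500/3") {
  patient_record(
    treatment_course(id, list(diagnosis_event(
      uicc = if (is.na(uicc)) NULL else unname(c("0" = 0, I = 1, II = 2, III = 3, IV = 4)[uicc]),
      age = age, histology = hist, date = diag))),
    diagnosis_date = diag, death_date = death,
    covariates = list(age = age, grading = grading, uicc = uicc,
                      uicc_substage = substage, histology_code = hist))
}

test_that("subcohort filters apply in order with exact attrition accounting", {
  recs <- list(
    mk_patient("young", 45, "2019-01-01"),
    mk_patient("early_death", 60, "2019-01-01", death = "2019-01-31"),
    mk_patient("no_grading", 60, "2019-01-01", grading = NA),
    mk_patient("wrong_stage", 60, "2019-01-01", uicc = "III", substage = "IIIA"),
    mk_patient("kept", 60, "2019-01-01"),
    mk_patient("kept2", 69, "2019-06-01", death = "2021-06-01")
  )
  out <- build_subcohort(recs, cohort_filter_spec("pf"))
  expect_equal(vapply(out$records, `[[`, character(1), "patient_id"),
               c("kept", "kept2"))
  expect_equal(out$attrition$rule,
               c("age_band", "landmark_survival", "grading_documented",
                 "uicc_subgroup"))
  expect_equal(out$attrition$removed, c(1L, 1L, 1L, 1L))
  expect_equal(sum(out$attrition$removed), length(recs) - length(out$records))
  # the unfavorable subgroup keeps stage III/IV instead
  pu <- build_subcohort(recs, cohort_filter_spec("pu"))
  expect_equal(vapply(pu$records, `[[`, character(1), "patient_id"), "wrong_stage")
})

test_that("survival records measure days from the landmark origin", {
  recs <- list(mk_patient("a", 60, "2019-01-01", death = "2019-12-31"),
               mk_patient("b", 60, "2019-01-01"))
  sr <- survival_records(recs, c(a = 0L, b = 0L),
                         censor_date = as.Date("2023-06-30"))
  # origin 2019-02-26; death 2019-12-31 -> 308 days, event
  expect_equal(sr$time[sr$patient_id == "a"], 308)
  expect_equal(sr$event[sr$patient_id == "a"], 1L)
  expect_equal(sr$time[sr$patient_id == "b"],
               as.numeric(as.Date("2023-06-30") - as.Date("2019-02-26")))
  expect_equal(sr$event[sr$patient_id == "b"], 0L)
  # a death after the censor date is censored there
  recs2 <- list(mk_patient("c", 60, "2019-01-01", death = "2024-01-01"))
  sr2 <- survival_records(recs2, c(c = 0L))
  expect_equal(sr2$event, 0L)
  # landmark violations are a hard error, not silent nonsense
  recs3 <- list(mk_patient("d", 60, "2019-01-01", death = "2019-01-20"))
  expect_error(survival_records(recs3, c(d = 0L)), "non-positive landmark")
})

test_that("landmark KM reproduces the hand product-limit on the worked example", {
  sr <- data.frame(patient_id = letters[1:4],
                   time = c(100, 300, 500, 1500),
                   event = c(1L, 1L, 0L, 0L),
                   cluster = factor(rep(0, 4)),
                   age = 60, grading = "G2", uicc_substage = "IA",
                   lobular = FALSE)
  km <- landmark_km(sr)
  expect_equal(km$table$survival, (3 / 4) * (2 / 3))
  expect_false(km$table$excluded)
  # all die on day 1
  sr1 <- transform(sr, time = 1, event = 1L)
  expect_equal(landmark_km(sr1)$table$survival, 0)
  # no deaths: flagged excluded, not dropped
  sr0 <- transform(sr, event = 0L)
  km0 <- landmark_km(sr0)
  expect_true(km0$table$excluded)
  expect_equal(nrow(km0$table), 1L)
})

test_that("KM matches the product-limit oracle on an exhaustive small-case suite", {
  for (n in 1:6) {
    events <- expand.grid(rep(list(0:1), n))
    for (r in seq_len(nrow(events))) {
      ev <- as.integer(events[r, ])
      time <- seq_len(n) * 100
      sr <- data.frame(patient_id = as.character(seq_len(n)), time = time,
                       event = ev, cluster = factor(rep(0, n)),
                       age = 60, grading = "G2", uicc_substage = "IA",
                       lobular = FALSE)
      km <- landmark_km(sr, horizon_days = 550L)
      expect_equal(km$table$survival, km_oracle(time, ev, 550),
                   tolerance = 1e-12)
    }
  }
  # tied death and censor times
  sr <- data.frame(patient_id = as.character(1:6),
                   time = c(100, 100, 100, 200, 200, 300),
                   event = c(1L, 1L, 0L, 1L, 0L, 0L),
                   cluster = factor(rep(0, 6)),
                   age = 60, grading = "G2", uicc_substage = "IA",
                   lobular = FALSE)
  expect_equal(landmark_km(sr, horizon_days = 250L)$table$survival,
               km_oracle(sr$time, sr$event, 250), tolerance = 1e-12)
})

test_that("the reference cluster is the highest horizon survival with stated ties", {
  mk_km <- function(cluster, survival, n, excluded = FALSE) {
    structure(list(table = data.frame(cluster = cluster, n = n,
                                      deaths = ifelse(excluded, 0L, 1L),
                                      survival = survival, lower = NA,
                                      upper = NA, excluded = excluded),
                   fits = list(), horizon_days = 1460L), class = "tc_km")
  }
  expect_equal(select_reference_cluster(mk_km(c("c1", "c2"), c(0.9, 0.95), c(10, 10))),
               "c2")
  expect_equal(select_reference_cluster(mk_km(c("c1", "c2"), c(0.9, 0.9), c(10, 50))),
               "c2")
  expect_equal(select_reference_cluster(mk_km("c9", 0.5, 3)), "c9")
  # excluded clusters cannot become the reference
  expect_equal(select_reference_cluster(
    mk_km(c("c1", "c2"), c(0.9, 1.0), c(10, 10), excluded = c(FALSE, TRUE))), "c1")
  expect_error(select_reference_cluster(mk_km("c1", 1, 5, excluded = TRUE)),
               "all clusters are excluded")
})

test_that("the Cox fit recovers a planted hazard ratio of 2", {
  d <- simulate_survival_cohort(2000, log_hrs = c(0, log(2)), seed = 601)
  sr <- data.frame(patient_id = as.character(seq_len(nrow(d))), time = d$time,
                   event = d$event, cluster = d$cluster,
                   age = 60, grading = "G2", uicc_substage = "IA",
                   lobular = FALSE)
  fit <- cox_fit(sr, reference = "0")
  hr <- fit$table$hazard_ratio[fit$table$term == "cluster1"]
  expect_gt(hr, 1.7)
  expect_lt(hr, 2.3)
  # reference row is printed with HR 1 and no interval
  ref_row <- fit$table[fit$table$reference & startsWith(fit$table$term, "cluster"), ]
  expect_equal(ref_row$term, "cluster0 (reference)")
  expect_equal(ref_row$hazard_ratio, 1)
  expect_true(is.na(ref_row$lower) && is.na(ref_row$upper))
})

test_that("with no planted effect every hazard ratio is near 1", {
  d <- simulate_survival_cohort(3000, log_hrs = c(0, 0, 0), seed = 602)
  sr <- data.frame(patient_id = as.character(seq_len(nrow(d))), time = d$time,
                   event = d$event, cluster = d$cluster,
                   age = 60, grading = "G2", uicc_substage = "IA",
                   lobular = FALSE)
  fit <- cox_fit(sr, reference = "0")
  hrs <- fit$table$hazard_ratio[!fit$table$reference]
  expect_true(all(hrs > 0.8 & hrs < 1.25))
})

test_that("zero-death clusters must be excluded before the Cox fit", {
  set.seed(608)
  sr <- data.frame(patient_id = as.character(1:60),
                   time = rep(100:119, 3),
                   event = c(rbinom(40, 1, 0.6), rep(0L, 20)),
                   cluster = factor(rep(c(0, 1, 2), each = 20)),
                   age = 60, grading = "G2", uicc_substage = "IA",
                   lobular = FALSE)
  expect_error(cox_fit(sr, reference = "0"), "without deaths")
  fit <- cox_fit(sr, reference = "0", exclude_clusters = "2")
  expect_false(any(grepl("cluster2", fit$table$term)))
  # excluding everything but one cluster leaves nothing to compare
  expect_error(cox_fit(sr, reference = "0", exclude_clusters = c("1", "2")),
               "fewer than 2 clusters")
})

test_that("confidence intervals cover planted hazard ratios at the nominal rate", {
  true_hr <- c(exp(0.7), exp(1.4))
  cover <- 0L; total <- 0L
  for (s in 1:40) {
    d <- simulate_survival_cohort(600, log_hrs = c(0, 0.7, 1.4), seed = 603 + s)
    f <- survival::coxph(survival::Surv(time, event) ~ cluster, data = d)
    ci <- exp(stats::confint(f))
    for (j in 1:2) {
      total <- total + 1L
      if (ci[j, 1] <= true_hr[j] && true_hr[j] <= ci[j, 2]) cover <- cover + 1L
    }
  }
  expect_gte(cover / total, 0.85)
  expect_lte(cover / total, 1.0)
})

test_that("uniform censoring is calibrated to its target fraction", {
  d <- simulate_survival_cohort(8000, seed = 604)
  expect_lt(abs(mean(d$event == 0) - 0.2), 0.02)
})

test_that("G-computation with zero cluster coefficients gives identical curves", {
  # duplicating every patient into both clusters makes the partial-likelihood
  # score vanish at beta = 0, so the fitted cluster effect is exactly zero
  set.seed(605)
  base <- data.frame(time = round(rexp(60, 0.01)) + 1,
                     event = rbinom(60, 1, 0.7))
  sr <- rbind(transform(base, cluster = factor(0)),
              transform(base, cluster = factor(1)))
  sr$patient_id <- as.character(seq_len(nrow(sr)))
  sr$age <- 60; sr$grading <- "G2"; sr$uicc_substage <- "IA"; sr$lobular <- FALSE
  fit <- cox_fit(sr, reference = "0")
  expect_lt(abs(fit$table$hazard_ratio[fit$table$term == "cluster1"] - 1), 1e-8)
  adj <- g_computation_curves(fit)
  expect_lt(max(abs(adj$curves[, 1] - adj$curves[, 2])), 1e-9)
  # and the common curve is the population-average baseline
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = sr)
  pop <- summary(sf, times = adj$times, extend = TRUE)$surv
  expect_lt(max(abs(adj$curves[, 1] - pop)), 0.02)
})

test_that("adjusted curves are survival functions ordered by the planted hazard", {
  d <- simulate_survival_cohort(1500, log_hrs = c(0, log(3)), censor_frac = 0.2,
                                seed = 606)
  sr <- data.frame(patient_id = as.character(seq_len(nrow(d))), time = d$time,
                   event = d$event, cluster = d$cluster,
                   age = rnorm(nrow(d), 60, 5), grading = "G2",
                   uicc_substage = "IA", lobular = FALSE)
  fit <- cox_fit(sr, reference = "0")
  adj <- g_computation_curves(fit)
  expect_equal(unname(adj$curves[1, ]), c(1, 1))
  for (j in 1:2) expect_true(all(diff(adj$curves[, j]) <= 1e-12))
  # the high-hazard cluster's adjusted curve lies below everywhere
  expect_true(all(adj$curves[-1, "1"] <= adj$curves[-1, "0"] + 1e-12))
  # curves never extend beyond the observed follow-up
  expect_lte(max(adj$times), max(sr$time))
})

test_that("a saturated stratified model reproduces the stratified KM exactly", {
  set.seed(607)
  sr <- data.frame(time = round(rexp(80, 0.01)) + 1,
                   event = rbinom(80, 1, 0.8),
                   cluster = factor(rep(0:1, each = 40)))
  fit <- survival::coxph(survival::Surv(time, event) ~ survival::strata(cluster),
                         data = sr, model = TRUE)
  adj <- g_computation_curves(fit, srec = sr, stype = 1)
  for (cl in levels(sr$cluster)) {
    sub <- sr[sr$cluster == cl, ]
    expected <- vapply(adj$times, function(t) km_oracle(sub$time, sub$event, t),
                       numeric(1))
    expect_equal(unname(adj$curves[, cl]), expected, tolerance = 1e-6)
  }
})
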