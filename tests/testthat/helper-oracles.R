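# Independent oracles and random-instance generators shared across tests.
# Everything here deliberately avoids the package's own computational paths:
# the edit-distance oracle enumerates edit scripts recursively, the
# silhouette oracle is a plain double loop, and the Kaplan-Meier oracle is a
# hand-written product-limit.

# minimum edit cost by exhaustive recursion over all edit scripts (no DP
# table; exponential, only for tiny sequences)
edit_script_min_cost <- function(a, b, subst_cost) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- Inf
    if (i > 0L) best <- min(best, rec(i - 1L, j) + 1)
    if (j > 0L) best <- min(best, rec(i, j - 1L) + 1)
    if (i > 0L && j > 0L) best <- min(best, rec(i - 1L, j - 1L) + subst_cost(a[[i]], b[[j]]))
    best
  }
  rec(length(a), length(b))
}

course_distance_oracle <- function(ca, cb) {
  na <- length(ca$events); nb <- length(cb$events)
  if (na == 0L && nb == 0L) return(0)
  edit_script_min_cost(ca$events, cb$events, event_distance) / max(na, nb)
}

# naive O(n^2) mean silhouette width; labels without -1 entries, singleton
# clusters contribute width 0 (matching the convention of the pipeline)
naive_silhouette <- function(D, labels) {
  n <- nrow(D)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { widths[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == cl]))
    }
    widths[i] <- (b - a) / max(a, b)
  }
  mean(widths)
}

# hand product-limit estimator: survival at time t with right censoring
km_oracle <- function(time, event, t) {
  s <- 1
  for (tt in sort(unique(time[event == 1 & time <= t]))) {
    d <- sum(time == tt & event == 1)
    r <- sum(time >= tt)
    s <- s * (1 - d / r)
  }
  s
}

# --- random instances under a caller-controlled seed -------------------

rand_av <- function(domain_sampler, p_present = 0.7, p_missing = 0.2) {
  u <- runif(1)
  if (u < p_present) av_present(domain_sampler())
  else if (u < p_present + p_missing) av_missing()
  else av_unrelated()
}

random_event <- function(types = c("diagnosis", "surgery", "radiotherapy",
                                   "systemic")) {
  type <- types[sample.int(length(types), 1L)]
  switch(type,
    diagnosis = diagnosis_event(
      uicc = if (runif(1) < 0.7) sample(0:4, 1) else NULL,
      ecog = if (runif(1) < 0.7) sample(0:4, 1) else NULL,
      age_group = if (runif(1) < 0.8) sample(AGE_GROUPS, 1) else NULL,
      histology = sample(c(HISTOLOGY_CODES, "8140/3", NA), 1),
      grading = if (runif(1) < 0.7) sample(0:8, 1) else NULL,
      date = as.Date("2019-01-01") + sample(0:300, 1)),
    surgery = surgery_event(
      procedure_codes = sample(c("5-870.1", "5-872.0", "5-874.2", "5-879.0",
                                 "1-502", "5-401.1"),
                               sample(0:2, 1), replace = TRUE),
      residual = if (runif(1) < 0.7) sample(c("R0", "R1", "R1(is)", "R2"), 1) else NULL,
      complications = if (runif(1) < 0.5) {
        sample(c("bleeding", "infection", "seroma"), sample(0:2, 1))
      } else NULL,
      date = as.Date("2019-01-01") + sample(0:300, 1)),
    radiotherapy = radiotherapy_event(
      radiations = lapply(seq_len(sample(0:2, 1)), function(i) {
        list(application_type = sample(APPLICATION_TYPES, 1),
             target_region = sample(c("breast", "thorax", "axilla"), 1))
      }),
      temporal = if (runif(1) < 0.8) sample(TEMPORAL_RELATIONS, 1) else NULL,
      date = as.Date("2019-01-01") + sample(0:300, 1)),
    systemic = systemic_event(
      therapy_type = if (runif(1) < 0.8) sample(THERAPY_TYPES, 1) else NULL,
      temporal = if (runif(1) < 0.8) sample(TEMPORAL_RELATIONS, 1) else NULL,
      date = as.Date("2019-01-01") + sample(0:300, 1)))
}

random_course <- function(id, max_events = 4L) {
  n <- sample(0:max_events, 1L)
  events <- list()
  for (i in seq_len(n)) {
    # a course holds at most one diagnosis event
    allowed <- c(if (i == 1L) "diagnosis", "surgery", "radiotherapy", "systemic")
    events[[i]] <- random_event(allowed)
  }
  treatment_course(id, events)
}

# fully specified events (self-distance zero) for monotonicity checks
full_surgery <- function(date = "2019-03-01") {
  surgery_event("5-870.1", residual = "R0", complications = character(0),
                date = date)
}

full_diagnosis <- function(date = "2019-01-01") {
  diagnosis_event(uicc = 1, ecog = 0, age = 55, histology = "8500/3",
                  grading = 4, date = date)
}

full_radio <- function(date = "2019-05-01", region = "breast", temporal = "A") {
  radiotherapy_event(list(list(application_type = "Percutaneous",
                               target_region = region)),
                     temporal = temporal, date = date)
}

full_systemic <- function(type = "CH", temporal = "A", date = "2019-04-01") {
  systemic_event(type, temporal, date = date)
}

# small hand-built distance matrix
manual_distmat <- function(ids, lower) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- lower
  m <- m + t(m)
  structure(list(ids = ids, cells = m), class = c("tc_distmat"))
}
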