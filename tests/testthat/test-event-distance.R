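test_that("ordinal distance is the range-normalized absolute difference", {
  expect_equal(ordinal_distance(av_present(1L), av_present(3L), 4L), 0.5)
  expect_equal(ordinal_distance(av_present(2L), av_present(2L), 4L), 0)
  expect_equal(ordinal_distance(av_present(0L), av_present(8L), 8L), 1)
  # missing/unrelated take the maximum distance, also from themselves
  expect_equal(ordinal_distance(av_missing(), av_missing(), 4L), 1)
  expect_equal(ordinal_distance(av_present(2L), av_unrelated(), 4L), 1)
  expect_error(ordinal_distance(av_present(9L), av_present(1L), 4L), "outside")
})

test_that("categorical and Jaccard distances honour the missing-value rule", {
  expect_equal(categorical_distance(av_present("8500/3"), av_present("8500/3")), 0)
  expect_equal(categorical_distance(av_present("8500/3"), av_present("8211/3")), 1)
  expect_equal(categorical_distance(av_present("8500/3"), av_unrelated()), 1)
  expect_equal(categorical_distance(av_missing(), av_missing()), 1)

  expect_equal(jaccard_distance(av_present("x"), av_present("x")), 0)
  expect_equal(jaccard_distance(av_present("Percutaneous"),
                                av_present(c("Percutaneous", "Contact"))), 0.5)
  expect_equal(jaccard_distance(av_missing(), av_present("x")), 1)
  # two documented-empty sets are an informative agreement
  expect_equal(jaccard_distance(av_present(character(0)), av_present(character(0))), 0)
})

test_that("the therapy-type matrix matches its published cells and invariants", {
  m <- therapy_type_matrix()
  expect_equal(dim(m), c(14L, 14L))
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)[colnames(m) != "MI"]), rep(0, 13))
  expect_equal(unname(m["MI", ]), rep(1, 14))
  expect_equal(unname(m[, "MI"]), rep(1, 14))
  # spot cells
  expect_equal(m["CH", "HO"], 0.8)
  expect_equal(m["CH", "CI"], 0.4)
  expect_equal(m["CI", "CIT"], 0.1)
  expect_equal(m["CH", "SC"], 0.5)
  expect_equal(m["AS", "WW"], 0.4)
  expect_equal(m["HO", "IT"], 0.2)
  expect_equal(m["OT", "CH"], 1)
})

test_that("user matrices are validated and decimal commas tolerated", {
  m <- therapy_type_matrix()
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(code = rownames(m),
                   matrix(sub(".", ",", format(m), fixed = TRUE), nrow(m)))
  colnames(df) <- c("code", colnames(m))
  write.csv(df, f, row.names = FALSE)
  expect_equal(unname(therapy_type_matrix(f)), unname(m))

  bad <- m; bad["CH", "HO"] <- 0.3   # breaks symmetry
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(code = rownames(bad), bad, check.names = FALSE), f2,
            row.names = FALSE)
  expect_error(therapy_type_matrix(f2), "symmetric")
})

test_that("attribute weights must sum to one", {
  w <- attribute_weights()
  for (nm in names(w)) expect_equal(sum(w[[nm]]), 1)
  expect_error(attribute_weights(systemic = c(type = 0.8, temporal = 0.3)),
               "sum to 1")
})

test_that("diagnosis distance is the equally weighted attribute mean", {
  a <- full_diagnosis()
  expect_equal(diagnosis_distance(a, a), 0)
  b <- diagnosis_event(uicc = 3, ecog = 0, age = 55, histology = "8500/3",
                       grading = 4)
  expect_equal(diagnosis_distance(a, b), 0.2 * 0.5)  # |1-3|/4 at weight 0.2
  b <- diagnosis_event(uicc = NULL, ecog = 0, age = 55, histology = "8500/3",
                       grading = 4)
  expect_equal(diagnosis_distance(a, b), 0.2)
})

test_that("systemic distance weights type 0.7 and temporal 0.3", {
  expect_equal(systemic_distance(full_systemic("CH", "A"), full_systemic("CH", "A")), 0)
  expect_equal(systemic_distance(full_systemic("CH", "A"), full_systemic("HO", "A")), 0.56)
  expect_equal(systemic_distance(full_systemic("CH", "A"), full_systemic("CH", "N")), 0.3)
  # a missing type compares through the MI row: distance 1 to everything
  expect_equal(systemic_distance(full_systemic("OT", "A"), systemic_event(NULL, "A")), 0.7)
  expect_equal(systemic_distance(systemic_event(NULL, "A"), systemic_event(NULL, "A")), 0.7)
})

test_that("surgery distance weights group 0.5 and residual/complications 0.25", {
  bcs <- full_surgery()
  expect_equal(surgery_distance(bcs, bcs), 0)
  mast <- surgery_event("5-872.0", residual = "R0", complications = character(0))
  expect_equal(surgery_distance(bcs, mast), 0.5)
  r2 <- surgery_event("5-870.1", residual = "R2", complications = character(0))
  expect_equal(surgery_distance(bcs, r2), 0.25)  # |0-3|/3 at weight 0.25
})

test_that("residual status maps R0/R1(is)/R1(cy+)/R1/R2 to 0/1/1/2/3", {
  vals <- vapply(c("R0", "R1(is)", "R1(cy+)", "R1", "R2"), function(r) {
    av_value(surgery_event("5-870.1", residual = r)$residual)
  }, integer(1))
  expect_equal(unname(vals), c(0L, 1L, 1L, 2L, 3L))
})

test_that("radiotherapy distance uses the breast/thorax half-distance", {
  a <- full_radio()
  expect_equal(radiotherapy_distance(a, a), 0)
  th <- full_radio(region = "thorax")
  expect_equal(radiotherapy_distance(a, th), 0.25)  # 0.5 weight x 0.5 region
  neo <- full_radio(temporal = "N")
  expect_equal(radiotherapy_distance(a, neo), 0.25)  # 0.25 weight x 1
})

test_that("events of different types are incomparable at distance 1", {
  expect_equal(event_distance(full_surgery(), full_radio()), 1)
  expect_equal(event_distance(full_diagnosis(), full_diagnosis()), 0)
  expect_equal(event_distance(full_systemic("CH", "A"), full_systemic("CI", "A")),
               0.7 * 0.4)
})

test_that("self-distance is zero iff every attribute is present and related", {
  expect_equal(event_distance(full_surgery(), full_surgery()), 0)
  # a missing attribute contributes exactly its weight to the self-distance
  s <- surgery_event("5-870.1", residual = NULL, complications = character(0))
  expect_equal(surgery_distance(s, s), 0.25)
  d <- diagnosis_event(uicc = 1, ecog = NULL, age = 55, histology = "8500/3",
                       grading = 4)
  expect_equal(diagnosis_distance(d, d), 0.2)
  amb <- surgery_event(c("5-870.1", "5-872.0"), residual = "R0",
                       complications = character(0))
  expect_equal(surgery_distance(amb, amb), 0.5)
})

test_that("random event pairs are symmetric, bounded and convex combinations", {
  set.seed(401)
  for (rep in seq_len(2000)) {
    a <- random_event(); b <- random_event()
    d1 <- event_distance(a, b)
    expect_true(d1 >= 0 && d1 <= 1)
    expect_identical(d1, event_distance(b, a))
    if (a$type == b$type) {
      parts <- switch(a$type,
        diagnosis = c(ordinal_distance(a$uicc, b$uicc, 4),
                      ordinal_distance(a$ecog, b$ecog, 4),
                      categorical_distance(a$age_group, b$age_group),
                      categorical_distance(a$histology, b$histology),
                      ordinal_distance(a$grading, b$grading, 8)),
        surgery = c(categorical_distance(a$surgery_group, b$surgery_group),
                    ordinal_distance(a$residual, b$residual, 3),
                    jaccard_distance(a$complications, b$complications)),
        radiotherapy = c(treatclust:::region_distance(a$target_region, b$target_region),
                         jaccard_distance(a$application_types, b$application_types),
                         categorical_distance(a$temporal, b$temporal)),
        systemic = c(therapy_type_matrix()[
                       if (is_present(a$therapy_type)) av_value(a$therapy_type) else "MI",
                       if (is_present(b$therapy_type)) av_value(b$therapy_type) else "MI"],
                     categorical_distance(a$temporal, b$temporal)))
      expect_gte(d1, min(parts) - 1e-12)
      expect_lte(d1, max(parts) + 1e-12)
    }
  }
})
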