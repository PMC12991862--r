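# deterministic planted two-blob coordinates
two_blobs <- function(n_per = 40, sep = 10, sd = 0.3, seed = 501) {
  set.seed(seed)
  pts <- rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
               cbind(rnorm(n_per, sep, sd), rnorm(n_per, 0, sd)))
  rownames(pts) <- sprintf("p%03d", seq_len(2 * n_per))
  list(pts = pts, labels = rep(0:1, each = n_per))
}

test_that("embedding validates its input matrix", {
  bad <- matrix(c(0, 0.2, 0.4, 0), 2, 2)
  expect_error(embed_courses(bad), "symmetric")
  bad2 <- matrix(c(0.1, 0.2, 0.2, 0.1), 2, 2)
  expect_error(embed_courses(bad2), "diagonal")
  bad3 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_error(embed_courses(bad3), "\\[0,1\\]")
})

test_that("embedding separates a planted two-group distance matrix", {
  ids <- sprintf("x%02d", 1:12)
  cells <- matrix(0.9, 12, 12, dimnames = list(ids, ids))
  cells[1:6, 1:6] <- 0.05
  cells[7:12, 7:12] <- 0.05
  diag(cells) <- 0
  dm <- structure(list(ids = ids, cells = cells), class = "tc_distmat")
  for (m in c("cmdscale", "nmds")) {
    emb <- embed_courses(dm, embedding_config(method = m))
    D <- as.matrix(dist(emb$points))
    within <- c(D[1:6, 1:6][upper.tri(D[1:6, 1:6])],
                D[7:12, 7:12][upper.tri(D[7:12, 7:12])])
    between <- D[1:6, 7:12]
    expect_lt(max(within), min(between) / 5)
  }
})

test_that("embedding is deterministic and round-trips its configuration", {
  coh <- default_breast_cohort(60, seed = 5)
  dm <- pairwise_matrix(coh$records)
  e1 <- embed_courses(dm)
  e2 <- embed_courses(dm)
  expect_identical(e1$points, e2$points)
  f <- withr::local_tempfile(fileext = ".csv")
  write_embedding_csv(e1, f)
  back <- read_embedding_csv(f)
  expect_equal(back$config, e1$config)
  expect_equal(back$points, e1$points, tolerance = 1e-12)
})

test_that("pipeline silhouette matches the naive oracle", {
  set.seed(502)
  pts <- matrix(rnorm(400), ncol = 2)
  D <- as.matrix(dist(pts))
  for (k in c(2, 3, 7)) {
    labels <- sample(0:(k - 1), nrow(pts), replace = TRUE)
    expect_equal(silhouette_score(pts, labels), naive_silhouette(D, labels),
                 tolerance = 1e-9)
  }
  # outliers are excluded before scoring
  labels <- sample(0:1, nrow(pts), replace = TRUE)
  out <- sample(nrow(pts), 20)
  labels_out <- labels; labels_out[out] <- -1L
  expect_equal(silhouette_score(pts, labels_out),
               naive_silhouette(D[-out, -out], labels[-out]),
               tolerance = 1e-9)
  # fewer than two clusters: undefined
  expect_true(is.na(silhouette_score(pts, rep(0L, nrow(pts)))))
})

test_that("dbscan finds planted blobs and marks far points as noise", {
  tb <- two_blobs()
  pts <- rbind(tb$pts, far = c(100, 100))
  D <- as.matrix(dist(pts))
  labels <- dbscan_labels(D, eps = 1.5, min_samples = 5)
  expect_equal(length(unique(labels[labels != -1])), 2L)
  expect_equal(labels[length(labels)], -1L)
  expect_equal(labels[1:80], tb$labels)
})

test_that("hdbscan recovers planted blobs with noise under the cap", {
  tb <- two_blobs(n_per = 60, sep = 8, sd = 0.5, seed = 503)
  D <- as.matrix(dist(tb$pts))
  labels <- hdbscan_labels(D, min_samples = 5, min_cluster_size = 10)
  expect_equal(length(unique(labels[labels != -1])), 2L)
  keep <- labels != -1
  expect_gt(mean(keep), 0.95)
  expect_equal(mclust::adjustedRandIndex(labels[keep], tb$labels[keep]), 1)
  # too few points for the requested cluster size: everything is noise
  expect_equal(hdbscan_labels(D[1:15, 1:15], 5, 10), rep(-1L, 15))
})

test_that("hierarchical labels cut the complete-linkage tree at a height", {
  tb <- two_blobs()
  hc <- hclust(dist(tb$pts), method = "complete")
  labels <- hierarchical_labels(hc, 5)
  expect_equal(length(unique(labels)), 2L)
  expect_equal(labels, tb$labels)
})

test_that("granularity bands are disjoint, ordered and validated", {
  b <- granularity_band("coarse")
  expect_equal(c(b$min_clusters, b$max_clusters), c(1L, 50L))
  m <- granularity_band("medium")
  f <- granularity_band("fine")
  expect_equal(c(m$min_clusters, m$max_clusters), c(51L, 100L))
  expect_equal(c(f$min_clusters, f$max_clusters), c(101L, 200L))
  expect_lt(b$max_clusters, m$min_clusters)
  expect_lt(m$max_clusters, f$min_clusters)
  custom <- granularity_band("custom", 15, 30)
  expect_equal(c(custom$min_clusters, custom$max_clusters), c(15L, 30L))
  expect_error(granularity_band("custom", 10, 5), "invalid band")
})

test_that("grid search selects a high-silhouette two-cluster solution on planted blobs", {
  tb <- two_blobs(n_per = 50, sep = 12, sd = 0.4, seed = 504)
  gs <- cluster_grid_search(tb$pts, granularity_band("coarse"))
  expect_false(gs$unsatisfiable)
  expect_equal(gs$best$n_clusters, 2L)
  expect_gt(gs$best$silhouette, 0.8)
  # leaderboard is sorted by silhouette (NA rows at the tail) and headed by
  # the best entry
  sil <- gs$leaderboard$silhouette
  ok <- !is.na(sil)
  expect_true(all(diff(sil[ok]) <= 1e-12))
  expect_true(all(which(!ok) > max(which(ok))))
  adm <- gs$leaderboard[gs$leaderboard$admissible, ]
  expect_equal(adm$silhouette[1], gs$best$silhouette)
  expect_equal(adm$algorithm[1], gs$best$algorithm)
  # every admissible result respects the band and the 5% outlier cap
  expect_true(all(adm$n_clusters >= 1 & adm$n_clusters <= 50))
  expect_true(all(adm$outlier_fraction <= 0.05))
})

test_that("a band larger than the cohort is reported unsatisfiable", {
  tb <- two_blobs(n_per = 25, seed = 505)  # 50 points
  gs <- cluster_grid_search(tb$pts, granularity_band("fine"))
  expect_true(gs$unsatisfiable)
  expect_null(gs$best)
})

test_that("cluster_courses assembles labels, sizes and medoids consistently", {
  coh <- default_breast_cohort(150, seed = 9, implausible_weight = 0)
  dm <- pairwise_matrix(coh$records)
  res <- cluster_courses(dm, granularity_band("coarse"))
  expect_false(res$unsatisfiable)
  expect_equal(length(res$labels), 150L)
  expect_equal(sum(res$sizes), sum(res$labels != -1L))
  expect_equal(res$n_clusters, length(res$sizes))
  for (cl in names(res$medoids)) {
    members <- names(res$labels)[res$labels == as.integer(cl)]
    expect_equal(res$medoids[[cl]], medoid(members, dm))
  }
  f <- withr::local_tempfile(fileext = ".csv")
  write_labels_csv(res, f)
  df <- read.csv(f, colClasses = c("character", "integer"))
  expect_equal(setNames(df$label, df$id), res$labels)
})

test_that("cluster reports carry medoid tokens, neighbours and frequencies", {
  mk <- function(id, uicc) treatment_course(id, list(
    diagnosis_event(uicc = uicc, ecog = 0, age = 55, histology = "8500/3",
                    grading = 4, date = "2019-01-01"),
    full_surgery("2019-02-01"), full_radio("2019-04-01")))
  courses <- list(mk("a", 1), mk("b", 1), mk("c", 1), mk("d", 3))
  dm <- pairwise_matrix(courses)
  emb <- embed_courses(dm)
  res <- structure(list(labels = setNames(c(0L, 0L, 0L, 0L), dm$ids),
                        embedding = emb, unsatisfiable = FALSE,
                        n_clusters = 1L),
                   class = "tc_clustering")
  rep1 <- summarize_cluster(res, 0L, courses, dm)
  expect_equal(rep1$size, 4L)
  expect_equal(rep1$medoid_tokens, c("I", "BCS", "Breast"))
  expect_true(rep1$medoid_id %in% c("a", "b", "c"))
  expect_equal(sort(c(rep1$nearest, rep1$medoid_id)), c("a", "b", "c", "d"))
  expect_equal(rep1$farthest[1], "d")
  # frequency tables match manual tallies
  expect_equal(unname(rep1$frequencies$diagnosis$uicc[c("1", "3")]),
               c(3L, 1L), ignore_attr = TRUE)
  expect_equal(unname(rep1$frequencies$surgery$surgery_group[["BCS"]]), 4L)
  expect_error(summarize_cluster(res, 7L, courses, dm), "does not exist")
})

test_that("a singleton cluster reports empty neighbour lists", {
  courses <- list(treatment_course("a", list(full_surgery())),
                  treatment_course("b", list(full_radio())))
  dm <- pairwise_matrix(courses)
  res <- structure(list(labels = setNames(c(0L, 1L), dm$ids),
                        embedding = embed_courses(dm), unsatisfiable = FALSE),
                   class = "tc_clustering")
  rep1 <- summarize_cluster(res, 0L, courses, dm)
  expect_equal(rep1$size, 1L)
  expect_length(rep1$nearest, 0L)
  expect_length(rep1$farthest, 0L)
})

test_that("SVG exports are structurally sound and byte-deterministic", {
  coh <- default_breast_cohort(60, seed = 13)
  dm <- pairwise_matrix(coh$records)
  res <- cluster_courses(dm, granularity_band("coarse"))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- export_views(res, coh$records, dir1)
  p2 <- export_views(res, coh$records, dir2)
  expect_true(file.exists(file.path(dir1, "scatter.svg")))
  expect_equal(length(p1), res$n_clusters + 1L)
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
  # one row of cells per course in a cluster diagram
  cl0 <- names(res$labels)[res$labels == 0L]
  courses <- as_course_list(coh$records)
  names(courses) <- vapply(courses, `[[`, character(1), "patient_id")
  n_cells <- sum(vapply(courses[cl0], length, integer(1)))
  svg <- readLines(file.path(dir1, "cluster-000.svg"))
  expect_gt(length(grep("circle", readLines(file.path(dir1, "scatter.svg")))), 50)
  expect_equal(sum(grepl('height="18"', svg)), n_cells)
})
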