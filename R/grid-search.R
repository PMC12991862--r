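#' Default hyperparameter grids
#'
#' The grid searched per algorithm: complete-linkage hierarchical
#' clustering over a log-spaced distance threshold, DBSCAN over an
#' eps x min_samples grid, and the hierarchical density method over
#' min_cluster_size x min_samples.
#'
#' @return named list of parameter grids
#' @export
default_grids <- function() {
  list(
    hierarchical = list(distance_threshold = exp(seq(log(0.1), log(30), length.out = 25))),
    dbscan = list(eps = seq(0.05, 2.0, length.out = 20),
                  min_samples = c(5L, 7L, 10L, 15L, 25L)),
    hdbscan = list(min_cluster_size = c(10L, 25L, 50L, 100L, 200L),
                   min_samples = c(5L, 10L, 25L))
  )
}

#' Silhouette-selected clustering within a granularity band
#'
#' Evaluates every configuration in `grids` on the 2D embedding, keeps the
#' results whose cluster count lies in the band and whose outlier fraction
#' is at most `outlier_cap` (5% by default), and returns the admissible
#' configuration with the highest mean silhouette width, together with the
#' full leaderboard. Ties are broken lexicographically by (algorithm name,
#' parameter string). If no configuration is admissible the band is
#' reported unsatisfiable rather than raising an error.
#'
#' @param embedding a `tc_embedding` (or plain n x 2 matrix)
#' @param band a [granularity_band()]
#' @param grids parameter grids, see [default_grids()]
#' @param outlier_cap maximum admissible outlier fraction
#' @param silhouette_on `"embedding"` (default; Euclidean silhouette in the
#'   clustered space) or `"course"` (silhouette on the original course
#'   distances, requires `dmat`)
#' @param dmat optional `tc_distmat` when `silhouette_on = "course"`
#' @return `tc_gridsearch`: list with `best` (or NULL), `leaderboard`,
#'   `band`, `unsatisfiable`
#' @export
cluster_grid_search <- function(embedding, band = granularity_band("coarse"),
                                grids = default_grids(), outlier_cap = 0.05,
                                silhouette_on = c("embedding", "course"),
                                dmat = NULL) {
  silhouette_on <- match.arg(silhouette_on)
  pts <- if (inherits(embedding, "tc_embedding")) embedding$points else as.matrix(embedding)
  if (nrow(pts) < 2L) stop("need at least 2 embedded points", call. = FALSE)
  if (silhouette_on == "course" && is.null(dmat)) {
    stop("silhouette_on = 'course' requires dmat", call. = FALSE)
  }
  sil_space <- if (silhouette_on == "course") dmat else pts
  D <- as.matrix(stats::dist(pts))
  hc <- stats::hclust(stats::as.dist(D), method = "complete")

  configs <- list()
  add <- function(algorithm, params, labels) {
    configs[[length(configs) + 1L]] <<- list(algorithm = algorithm,
                                             params = params, labels = labels)
  }
  for (th in grids$hierarchical$distance_threshold) {
    add("hierarchical", c(distance_threshold = th), hierarchical_labels(hc, th))
  }
  for (ms in grids$dbscan$min_samples) {
    for (eps in grids$dbscan$eps) {
      add("dbscan", c(eps = eps, min_samples = ms), dbscan_labels(D, eps, ms))
    }
  }
  for (ms in grids$hdbscan$min_samples) {
    for (mcs in grids$hdbscan$min_cluster_size) {
      add("hdbscan", c(min_cluster_size = mcs, min_samples = ms),
          hdbscan_labels(D, ms, mcs))
    }
  }

  rows <- lapply(configs, function(cf) {
    labels <- cf$labels
    k <- length(unique(labels[labels != -1L]))
    outfrac <- mean(labels == -1L)
    admissible <- k >= band$min_clusters && k <= band$max_clusters &&
      outfrac <= outlier_cap
    sil <- if (admissible && k >= 2L) silhouette_score(sil_space, labels) else NA_real_
    data.frame(algorithm = cf$algorithm,
               params = paste(names(cf$params), signif(cf$params, 6),
                              sep = "=", collapse = ","),
               n_clusters = k, outlier_fraction = outfrac,
               silhouette = sil,
               admissible = admissible && !is.na(sil),
               stringsAsFactors = FALSE)
  })
  leaderboard <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(leaderboard$silhouette), -Inf, leaderboard$silhouette),
               leaderboard$algorithm, leaderboard$params)
  leaderboard <- leaderboard[ord, , drop = FALSE]
  rownames(leaderboard) <- NULL
  configs <- configs[ord]

  best_i <- which(leaderboard$admissible)
  if (length(best_i) == 0L) {
    return(structure(list(best = NULL, leaderboard = leaderboard, band = band,
                          unsatisfiable = TRUE), class = "tc_gridsearch"))
  }
  best_i <- best_i[1L]
  cf <- configs[[best_i]]
  labels <- cf$labels
  best <- list(algorithm = cf$algorithm,
               params = leaderboard$params[best_i],
               param_values = cf$params, labels = labels,
               n_clusters = leaderboard$n_clusters[best_i],
               silhouette = leaderboard$silhouette[best_i],
               outlier_fraction = leaderboard$outlier_fraction[best_i])
  structure(list(best = best, leaderboard = leaderboard, band = band,
                 unsatisfiable = FALSE), class = "tc_gridsearch")
}

#' @export
print.tc_gridsearch <- function(x, ...) {
  if (x$unsatisfiable) {
    cat(sprintf("<grid search: band %s (%d-%d clusters) unsatisfiable>\n",
                x$band$name, x$band$min_clusters, x$band$max_clusters))
  } else {
    cat(sprintf("<grid search: best %s (%s), %d clusters, silhouette %.3f, %.1f%% outliers>\n",
                x$best$algorithm, x$best$params, x$best$n_clusters,
                x$best$silhouette, 100 * x$best$outlier_fraction))
  }
  invisible(x)
}

#' End-to-end clustering of a course cohort
#'
#' Embeds the distance matrix, runs the silhouette grid search inside the
#' band, and assembles the full clustering result: labels per course,
#' per-cluster sizes and medoids, the embedding and the leaderboard.
#'
#' @param dmat a `tc_distmat` from [pairwise_matrix()]
#' @param band a [granularity_band()]
#' @param config an [embedding_config()]
#' @inheritParams cluster_grid_search
#' @return `tc_clustering` with fields `algorithm`, `params`, `labels`
#'   (named integer vector, -1 = outlier), `n_clusters`, `silhouette`,
#'   `outlier_fraction`, `sizes`, `medoids`, `embedding`, `leaderboard`,
#'   `band`, `unsatisfiable`
#' @export
cluster_courses <- function(dmat, band = granularity_band("coarse"),
                            config = embedding_config(),
                            grids = default_grids(), outlier_cap = 0.05,
                            silhouette_on = c("embedding", "course")) {
  stopifnot(inherits(dmat, "tc_distmat"))
  embedding <- embed_courses(dmat, config)
  gs <- cluster_grid_search(embedding, band, grids, outlier_cap,
                            silhouette_on, dmat = dmat)
  if (gs$unsatisfiable) {
    return(structure(list(labels = NULL, embedding = embedding,
                          leaderboard = gs$leaderboard, band = band,
                          unsatisfiable = TRUE), class = "tc_clustering"))
  }
  labels <- stats::setNames(gs$best$labels, dmat$ids)
  cl_ids <- sort(unique(labels[labels != -1L]))
  sizes <- vapply(cl_ids, function(cl) sum(labels == cl), integer(1))
  medoids <- vapply(cl_ids, function(cl) medoid(names(labels)[labels == cl], dmat),
                    character(1))
  structure(list(algorithm = gs$best$algorithm, params = gs$best$params,
                 labels = labels, n_clusters = gs$best$n_clusters,
                 silhouette = gs$best$silhouette,
                 outlier_fraction = gs$best$outlier_fraction,
                 sizes = stats::setNames(sizes, cl_ids),
                 medoids = stats::setNames(medoids, cl_ids),
                 embedding = embedding, leaderboard = gs$leaderboard,
                 band = band, unsatisfiable = FALSE),
            class = "tc_clustering")
}

#' @export
print.tc_clustering <- function(x, ...) {
  if (x$unsatisfiable) {
    cat(sprintf("<clustering: band %s unsatisfiable>\n", x$band$name))
    return(invisible(x))
  }
  cat(sprintf("<clustering: %s (%s), %d clusters, silhouette %.3f, %.1f%% outliers>\n",
              x$algorithm, x$params, x$n_clusters, x$silhouette,
              100 * x$outlier_fraction))
  invisible(x)
}

#' Export cluster labels as CSV
#'
#' @param result a `tc_clustering`
#' @param path file path
#' @export
write_labels_csv <- function(result, path) {
  stopifnot(inherits(result, "tc_clustering"), !result$unsatisfiable)
  utils::write.csv(data.frame(id = names(result$labels),
                              label = unname(result$labels)),
                   path, row.names = FALSE)
  invisible(path)
}
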