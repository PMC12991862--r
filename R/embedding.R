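#' Embedding configuration
#'
#' Courses are embedded in the plane before clustering, both to improve
#' separability and to support scatter visualization. The default method is
#' classical (metric) multidimensional scaling of the course-distance
#' matrix, which is fully linear-algebraic and deterministic; it preserves
#' the large-scale separation between course families well, which is what
#' the silhouette-based model selection downstream relies on. Non-metric
#' MDS (vegan's monoMDS, initialized from the classical solution) is
#' available as `"nmds"` when only the rank order of the distances should
#' be trusted. Both are deterministic for a fixed input; the seed is still
#' set and recorded with every output for provenance.
#'
#' @param method `"cmdscale"` (default) or `"nmds"`
#' @param n_dim embedding dimension; fixed to 2 in this workflow
#' @param seed integer seed recorded in outputs and set before embedding
#' @param maxit maximum NMDS iterations
#' @return `tc_embed_config`
#' @export
embedding_config <- function(method = c("cmdscale", "nmds"), n_dim = 2L,
                             seed = 42L, maxit = 200L) {
  method <- match.arg(method)
  stopifnot(n_dim == 2L, maxit >= 1L)
  structure(list(method = method, n_dim = 2L, seed = as.integer(seed),
                 maxit = as.integer(maxit)),
            class = "tc_embed_config")
}

#' Embed a course-distance matrix in 2D
#'
#' @param dmat a `tc_distmat` (symmetric, zero diagonal, cells in [0,1]) or
#'   a plain symmetric matrix
#' @param config an [embedding_config()]
#' @return `tc_embedding`: list with `points` (n x 2, rownames = ids) and
#'   the `config` used
#' @export
embed_courses <- function(dmat, config = embedding_config()) {
  cells <- if (inherits(dmat, "tc_distmat")) dmat$cells else as.matrix(dmat)
  validate_distmat(cells)
  n <- nrow(cells)
  set.seed(config$seed)
  d <- stats::as.dist(cells)
  pts <- if (all(cells == 0)) {
    base::matrix(0, n, 2L)
  } else {
    init <- stats::cmdscale(d, k = min(2L, n - 1L))
    if (ncol(init) < 2L) {
      init <- cbind(init, base::matrix(0, n, 2L - ncol(init)))
    }
    if (config$method == "nmds") {
      fit <- vegan::monoMDS(d, y = init, k = 2L, model = "global",
                            maxit = config$maxit)
      unname(fit$points)
    } else {
      unname(init)
    }
  }
  rownames(pts) <- rownames(cells)
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, config = config), class = "tc_embedding")
}

#' @export
print.tc_embedding <- function(x, ...) {
  cat(sprintf("<2D embedding of %d courses, method %s, seed %d>\n",
              nrow(x$points), x$config$method, x$config$seed))
  invisible(x)
}

#' Write an embedding (with its configuration) to CSV
#'
#' The configuration round-trips through comment lines at the top of the
#' file, so an exported embedding is self-describing.
#'
#' @param embedding a `tc_embedding`
#' @param path file path
#' @export
write_embedding_csv <- function(embedding, path) {
  stopifnot(inherits(embedding, "tc_embedding"))
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- embedding$config
  writeLines(sprintf("# method=%s n_dim=%d seed=%d maxit=%d",
                     cfg$method, cfg$n_dim, cfg$seed, cfg$maxit), con)
  utils::write.csv(data.frame(id = rownames(embedding$points),
                              x = embedding$points[, 1],
                              y = embedding$points[, 2]),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_csv
#' @export
read_embedding_csv <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- strsplit(sub("^# ", "", header), " ")[[1]]
  cfg <- stats::setNames(lapply(strsplit(kv, "="), `[[`, 2),
                         vapply(strsplit(kv, "="), `[[`, character(1), 1))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  pts <- as.matrix(df[, c("x", "y")])
  rownames(pts) <- df$id
  structure(list(points = pts,
                 config = embedding_config(method = cfg$method,
                                           seed = as.integer(cfg$seed),
                                           maxit = as.integer(cfg$maxit))),
            class = "tc_embedding")
}
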