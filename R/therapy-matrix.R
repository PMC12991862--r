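#' Systemic-therapy type distance matrix
#'
#' Loads the expert-derived 14x14 distance matrix over the systemic therapy
#' type codes CH, HO, IM, TS, CI, CT, CIT, IT, SC, AS, WS, WW, OT plus the
#' pseudo-code MI for a missing type. The matrix ships with the package as a
#' CSV data file and can be overridden by a user-supplied file with the same
#' layout (header row and first column holding the 14 codes).
#'
#' The matrix must be symmetric with values in [0,1]; every code other than
#' MI has diagonal 0, while MI keeps the maximum distance of 1 from every
#' code including itself, so that two therapies with undocumented types are
#' never counted as similar.
#'
#' @param path optional path to a replacement CSV; default is the shipped
#'   matrix
#' @return a named 14x14 numeric matrix
#' @export
therapy_type_matrix <- local({
  cache <- NULL
  function(path = NULL) {
    if (is.null(path)) {
      if (!is.null(cache)) return(cache)
      path <- system.file("extdata", "therapy_type_distance.csv",
                          package = "treatclust", mustWork = TRUE)
      m <- read_therapy_matrix(path)
      cache <<- m
      return(m)
    }
    read_therapy_matrix(path)
  }
})

MATRIX_CODES <- c(THERAPY_TYPES, "MI")

read_therapy_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  # tolerate German decimal commas in user-supplied matrices
  cells <- as.matrix(raw[, -1, drop = FALSE])
  if (is.character(cells)) {
    cells <- matrix(as.numeric(sub(",", ".", cells, fixed = TRUE)),
                    nrow = nrow(cells))
  }
  rownames(cells) <- raw[[1]]
  colnames(cells) <- colnames(raw)[-1]
  validate_therapy_matrix(cells)
  cells[MATRIX_CODES, MATRIX_CODES]
}

validate_therapy_matrix <- function(m) {
  if (!setequal(rownames(m), MATRIX_CODES) || !setequal(colnames(m), MATRIX_CODES)) {
    stop("therapy matrix must be labelled with the 14 codes ",
         paste(MATRIX_CODES, collapse = ", "), call. = FALSE)
  }
  m <- m[MATRIX_CODES, MATRIX_CODES]
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stop("therapy matrix cells must be numeric in [0,1]", call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m)))) {
    stop("therapy matrix must be symmetric", call. = FALSE)
  }
  d <- diag(m)
  if (any(d[MATRIX_CODES != "MI"] != 0) || d[["MI"]] != 1) {
    stop("therapy matrix diagonal must be 0 for all codes and 1 for MI",
         call. = FALSE)
  }
  if (any(m["MI", ] != 1)) {
    stop("MI row of the therapy matrix must be all 1", call. = FALSE)
  }
  invisible(m)
}
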