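#' Distance between two treatment courses
#'
#' A modified, length-normalized Levenshtein distance over the ordered event
#' sequences of two patients. Insertion and deletion cost 1; substituting
#' one event for another costs their [event_distance()], so that swapping
#' similar events is cheap and swapping incomparable events (different
#' types) costs as much as a delete-plus-insert. The dynamic-program total
#' is divided by the longer sequence length, keeping courses of different
#' lengths comparable; two empty courses have distance 0.
#'
#' This reference implementation is pure R; [pairwise_matrix()] computes the
#' same quantity for all pairs in compiled code.
#'
#' @param a,b `tc_course` objects (events are ordered at construction)
#' @param weights attribute weights, see [attribute_weights()]
#' @param matrix therapy-type matrix, see [therapy_type_matrix()]
#' @return numeric distance in [0,1]
#' @export
course_distance <- function(a, b, weights = attribute_weights(),
                            matrix = therapy_type_matrix()) {
  stopifnot(inherits(a, "tc_course"), inherits(b, "tc_course"))
  ea <- a$events; eb <- b$events
  na_ <- length(ea); nb_ <- length(eb)
  if (na_ == 0L && nb_ == 0L) return(0)
  D <- base::matrix(0, na_ + 1L, nb_ + 1L)
  D[, 1L] <- 0:na_
  D[1L, ] <- 0:nb_
  for (i in seq_len(na_)) {
    for (j in seq_len(nb_)) {
      sub <- D[i, j] + event_distance(ea[[i]], eb[[j]], weights, matrix)
      D[i + 1L, j + 1L] <- min(sub, D[i, j + 1L] + 1, D[i + 1L, j] + 1)
    }
  }
  D[na_ + 1L, nb_ + 1L] / max(na_, nb_)
}

# --- event encoding for the compiled kernel ----------------------------

# code a tc_attr payload as a 0-based index into a domain, -1 if not present
av_index <- function(x, domain) {
  if (!is_present(x)) return(-1)
  match(x$value, domain) - 1L
}

av_ord <- function(x) if (is_present(x)) x$value else -1

# set -> bitmask over a vocabulary (first 31 codes supported)
av_mask <- function(x, vocab) {
  if (!is_present(x)) return(-1)
  if (length(x$value) == 0L) return(0)
  sum(2^(match(x$value, vocab) - 1L))
}

# Collect the cohort-wide complication vocabulary; the bitmask encoding
# supports at most 31 distinct codes.
complication_vocab <- function(courses) {
  vocab <- unique(unlist(lapply(courses, function(cr) {
    unlist(lapply(cr$events, function(e) {
      if (e$type == "surgery" && is_present(e$complications)) e$complications$value
    }))
  })))
  vocab <- sort(vocab)
  if (length(vocab) > 31L) {
    stop("more than 31 distinct complication codes in the cohort; ",
         "the pairwise kernel encodes complication sets as 31-bit masks",
         call. = FALSE)
  }
  vocab
}

encode_course <- function(course, comp_vocab) {
  ev <- course$events
  m <- base::matrix(0, nrow = length(ev), ncol = 6L)
  for (i in seq_along(ev)) {
    e <- ev[[i]]
    m[i, ] <- switch(e$type,
      diagnosis = c(1, av_ord(e$uicc), av_ord(e$ecog),
                    av_index(e$age_group, AGE_GROUPS),
                    av_index(e$histology, HISTOLOGY_CODES),
                    av_ord(e$grading)),
      surgery = c(2, av_index(e$surgery_group, SURGERY_GROUPS),
                  av_ord(e$residual), av_mask(e$complications, comp_vocab),
                  0, 0),
      radiotherapy = c(3, av_mask(e$application_types, APPLICATION_TYPES),
                       av_index(e$target_region, c("Breast", "Thorax")),
                       av_index(e$temporal, TEMPORAL_RELATIONS), 0, 0),
      systemic = c(4, av_index(e$therapy_type, THERAPY_TYPES),
                   av_index(e$temporal, TEMPORAL_RELATIONS), 0, 0, 0))
  }
  m
}

#' Pairwise course-distance matrix
#'
#' Computes the symmetric matrix of [course_distance()] values over a
#' cohort in compiled code. The diagonal is forced to 0 even though a
#' course with missing attributes has a positive semantic self-distance
#' (available via `course_distance(x, x)`), because the downstream
#' embedding requires a genuine zero diagonal.
#'
#' @param courses list of `tc_course` (or of `tc_patient`, whose courses
#'   are taken), length >= 2
#' @inheritParams course_distance
#' @return a `tc_distmat`: list with `ids` and the n x n numeric `cells`
#' @export
pairwise_matrix <- function(courses, weights = attribute_weights(),
                            matrix = therapy_type_matrix()) {
  courses <- as_course_list(courses)
  if (length(courses) < 2L) stop("need at least 2 courses", call. = FALSE)
  ids <- vapply(courses, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort", call. = FALSE)
  vocab <- complication_vocab(courses)
  enc <- lapply(courses, encode_course, comp_vocab = vocab)
  cells <- cpp_pairwise_course_distance(enc, matrix, weights)
  dimnames(cells) <- list(ids, ids)
  structure(list(ids = ids, cells = cells), class = "tc_distmat")
}

#' @export
print.tc_distmat <- function(x, ...) {
  cat(sprintf("<course distance matrix, %d courses, mean off-diagonal %.3f>\n",
              length(x$ids), mean(x$cells[upper.tri(x$cells)])))
  invisible(x)
}

#' Coerce patients or courses to a plain course list
#'
#' @param x list of `tc_course` or `tc_patient`
#' @return list of `tc_course`
#' @export
as_course_list <- function(x) {
  lapply(x, function(el) {
    if (inherits(el, "tc_patient")) el$course
    else if (inherits(el, "tc_course")) el
    else stop("expected tc_course or tc_patient elements", call. = FALSE)
  })
}

#' Write / read a distance matrix as CSV
#'
#' Plain-text interchange: a header row of patient ids, then one row per
#' course (id in the first column).
#'
#' @param dmat a `tc_distmat`
#' @param path file path
#' @export
write_distmat_csv <- function(dmat, path) {
  stopifnot(inherits(dmat, "tc_distmat"))
  df <- data.frame(id = dmat$ids, dmat$cells, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distmat_csv
#' @export
read_distmat_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  cells <- as.matrix(df[, -1, drop = FALSE])
  dimnames(cells) <- list(ids, ids)
  validate_distmat(cells)
  structure(list(ids = ids, cells = cells), class = "tc_distmat")
}

validate_distmat <- function(cells) {
  if (!isTRUE(all.equal(cells, t(cells), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(cells) != 0)) stop("distance matrix diagonal must be 0", call. = FALSE)
  if (any(cells < 0) || any(cells > 1)) {
    stop("distance matrix cells must lie in [0,1]", call. = FALSE)
  }
  invisible(cells)
}

#' Medoid of a cluster
#'
#' The member minimizing the sum of distances to all other members; ties
#' are broken by the smallest id (lexicographic).
#'
#' @param member_ids character vector of member ids (nonempty, all in
#'   `dmat$ids`)
#' @param dmat a `tc_distmat`
#' @return the medoid id
#' @export
medoid <- function(member_ids, dmat) {
  stopifnot(inherits(dmat, "tc_distmat"))
  if (length(member_ids) == 0L) stop("empty cluster has no medoid", call. = FALSE)
  if (!all(member_ids %in% dmat$ids)) {
    stop("member ids not all present in the distance matrix", call. = FALSE)
  }
  sub <- dmat$cells[member_ids, member_ids, drop = FALSE]
  sums <- rowSums(sub)
  ord <- order(sums, member_ids)
  member_ids[ord[1L]]
}

#' Nearest and farthest cluster members from the medoid
#'
#' @param medoid_id the medoid id
#' @param member_ids cluster member ids (including the medoid)
#' @param dmat a `tc_distmat`
#' @param k how many courses to list on each side (default 5)
#' @return `list(nearest =, farthest =)`, each a character vector sorted by
#'   distance to the medoid (ascending / descending), medoid excluded and
#'   truncated for small clusters
#' @export
nearest_and_farthest <- function(medoid_id, member_ids, dmat, k = 5L) {
  stopifnot(inherits(dmat, "tc_distmat"), k >= 1L)
  others <- setdiff(member_ids, medoid_id)
  if (length(others) == 0L) return(list(nearest = character(0), farthest = character(0)))
  d <- dmat$cells[medoid_id, others]
  asc <- others[order(d, others)]
  desc <- others[order(-d, others)]
  list(nearest = utils::head(asc, k), farthest = utils::head(desc, k))
}
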