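#' Attribute weights for event distances
#'
#' Each event type combines its attribute distances as a weighted average.
#' The defaults follow the expert weighting: systemic therapy weights the
#' type at 0.7 and the temporal relation at 0.3; surgery weights the
#' procedure group at 0.5 and residual status and complications at 0.25
#' each; radiotherapy weights the target region at 0.5 and application
#' types and temporal relation at 0.25 each; the five diagnosis attributes
#' are weighted equally at 0.2.
#'
#' @param systemic,surgery,radiotherapy,diagnosis named numeric weight
#'   vectors; each must sum to 1
#' @return a validated list of weight vectors, class `tc_weights`
#' @export
attribute_weights <- function(
    systemic = c(type = 0.7, temporal = 0.3),
    surgery = c(procedure = 0.5, residual = 0.25, complications = 0.25),
    radiotherapy = c(target = 0.5, application = 0.25, temporal = 0.25),
    diagnosis = c(uicc = 0.2, ecog = 0.2, age_group = 0.2,
                  histology = 0.2, grading = 0.2)) {
  w <- list(systemic = systemic, surgery = surgery,
            radiotherapy = radiotherapy, diagnosis = diagnosis)
  for (nm in names(w)) {
    v <- w[[nm]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-8) {
      stop(sprintf("%s weights must be nonnegative and sum to 1", nm),
           call. = FALSE)
    }
  }
  structure(w, class = "tc_weights")
}

#' Attribute-level distances
#'
#' The three primitive distances underlying every event comparison. All are
#' in [0,1], and any missing or unrelated operand yields the maximum
#' distance of 1 - including against another missing/unrelated value.
#'
#' @param a,b [attribute values][attr_value]
#' @param scale_max upper end of the ordinal scale (lower end is 0), so the
#'   normalized 1-D Euclidean distance is `|a - b| / scale_max`
#' @name attribute_distance
NULL

#' @rdname attribute_distance
#' @export
ordinal_distance <- function(a, b, scale_max) {
  stopifnot(is_av(a), is_av(b), scale_max >= 1)
  if (!is_present(a) || !is_present(b)) return(1)
  va <- a$value; vb <- b$value
  if (va < 0 || va > scale_max || vb < 0 || vb > scale_max) {
    stop("ordinal payload outside [0, scale_max]", call. = FALSE)
  }
  abs(va - vb) / scale_max
}

#' @rdname attribute_distance
#' @export
categorical_distance <- function(a, b) {
  stopifnot(is_av(a), is_av(b))
  if (!is_present(a) || !is_present(b)) return(1)
  if (identical(a$value, b$value)) 0 else 1
}

#' @rdname attribute_distance
#' @export
jaccard_distance <- function(a, b) {
  stopifnot(is_av(a), is_av(b))
  if (!is_present(a) || !is_present(b)) return(1)
  A <- unique(a$value); B <- unique(b$value)
  u <- length(union(A, B))
  if (u == 0L) return(0)  # two documented-empty sets agree
  1 - length(intersect(A, B)) / u
}

#' Event-level distances
#'
#' Weighted-average distances between two events of the same type, each in
#' [0,1]. `event_distance()` dispatches on the event types and assigns the
#' maximum distance of 1 to events of different types, which are inherently
#' incomparable.
#'
#' Note that an event with missing or unrelated attributes has a positive
#' distance from itself (each such attribute contributes its full weight);
#' this is deliberate and keeps incomplete documentation from inflating
#' similarity.
#'
#' @param a,b events of the matching type
#' @param weights `tc_weights`, see [attribute_weights()]
#' @param matrix therapy-type distance matrix, see [therapy_type_matrix()]
#' @return numeric distance in [0,1]
#' @name event_distances
NULL

#' @rdname event_distances
#' @export
diagnosis_distance <- function(a, b, weights = attribute_weights()) {
  stopifnot(inherits(a, "tc_diagnosis"), inherits(b, "tc_diagnosis"))
  w <- weights$diagnosis
  unname(
    w[["uicc"]] * ordinal_distance(a$uicc, b$uicc, 4L) +
    w[["ecog"]] * ordinal_distance(a$ecog, b$ecog, 4L) +
    w[["age_group"]] * categorical_distance(a$age_group, b$age_group) +
    w[["histology"]] * categorical_distance(a$histology, b$histology) +
    w[["grading"]] * ordinal_distance(a$grading, b$grading, 8L)
  )
}

#' @rdname event_distances
#' @export
systemic_distance <- function(a, b, weights = attribute_weights(),
                              matrix = therapy_type_matrix()) {
  stopifnot(inherits(a, "tc_systemic"), inherits(b, "tc_systemic"))
  code <- function(e) if (is_present(e$therapy_type)) e$therapy_type$value else "MI"
  ca <- code(a); cb <- code(b)
  if (!ca %in% rownames(matrix) || !cb %in% rownames(matrix)) {
    stop(sprintf("therapy type '%s' not in the distance matrix",
                 setdiff(c(ca, cb), rownames(matrix))[1]), call. = FALSE)
  }
  w <- weights$systemic
  unname(w[["type"]] * matrix[ca, cb] +
         w[["temporal"]] * categorical_distance(a$temporal, b$temporal))
}

#' @rdname event_distances
#' @export
surgery_distance <- function(a, b, weights = attribute_weights()) {
  stopifnot(inherits(a, "tc_surgery"), inherits(b, "tc_surgery"))
  w <- weights$surgery
  unname(
    w[["procedure"]] * categorical_distance(a$surgery_group, b$surgery_group) +
    w[["residual"]] * ordinal_distance(a$residual, b$residual, 3L) +
    w[["complications"]] * jaccard_distance(a$complications, b$complications)
  )
}

# breast/thorax get the intermediate distance 0.5; anything else the rules
# for categorical values apply
region_distance <- function(a, b) {
  if (!is_present(a) || !is_present(b)) return(1)
  if (identical(a$value, b$value)) return(0)
  0.5
}

#' @rdname event_distances
#' @export
radiotherapy_distance <- function(a, b, weights = attribute_weights()) {
  stopifnot(inherits(a, "tc_radiotherapy"), inherits(b, "tc_radiotherapy"))
  w <- weights$radiotherapy
  unname(
    w[["target"]] * region_distance(a$target_region, b$target_region) +
    w[["application"]] * jaccard_distance(a$application_types, b$application_types) +
    w[["temporal"]] * categorical_distance(a$temporal, b$temporal)
  )
}

#' @rdname event_distances
#' @export
event_distance <- function(a, b, weights = attribute_weights(),
                           matrix = therapy_type_matrix()) {
  stopifnot(inherits(a, "tc_event"), inherits(b, "tc_event"))
  if (a$type != b$type) return(1)
  switch(a$type,
         diagnosis = diagnosis_distance(a, b, weights),
         surgery = surgery_distance(a, b, weights),
         radiotherapy = radiotherapy_distance(a, b, weights),
         systemic = systemic_distance(a, b, weights, matrix),
         stop("unknown event type ", a$type))
}
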