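#' Tri-state attribute values
#'
#' Every event attribute used in distance computation is one of three states:
#' `present` (carries a payload), `missing` (not documented / coded unknown),
#' or `unrelated` (documented, but outside the value set considered
#' meaningful for breast-cancer comparison, e.g. a histology code other than
#' the six comparable ones). Missing and unrelated values are never dropped;
#' they take the maximum distance of 1 from every value including
#' themselves, so that undocumented attributes cannot artificially increase
#' course similarity.
#'
#' @param value payload of a present value; any R object, typically a
#'   scalar or a character vector (for set-valued attributes).
#' @name attr_value
NULL

#' @rdname attr_value
#' @return an object of class `tc_attr`
#' @export
av_present <- function(value) {
  if (missing(value)) stop("av_present() requires a payload", call. = FALSE)
  structure(list(state = "present", value = value, raw = NULL), class = "tc_attr")
}

#' @rdname attr_value
#' @param raw optional raw source value kept for serialization only; it is
#'   never used in distance computation (missing and unrelated values carry
#'   no comparable payload)
#' @export
av_missing <- function(raw = NULL) {
  structure(list(state = "missing", value = NULL, raw = raw), class = "tc_attr")
}

#' @rdname attr_value
#' @export
av_unrelated <- function(raw = NULL) {
  structure(list(state = "unrelated", value = NULL, raw = raw), class = "tc_attr")
}

#' @rdname attr_value
#' @param x object to test or inspect
#' @export
is_av <- function(x) inherits(x, "tc_attr")

#' @rdname attr_value
#' @export
av_state <- function(x) {
  stopifnot(is_av(x))
  x$state
}

#' @rdname attr_value
#' @export
is_present <- function(x) is_av(x) && x$state == "present"

#' @rdname attr_value
#' @export
av_value <- function(x) {
  stopifnot(is_av(x))
  x$value
}

#' @export
print.tc_attr <- function(x, ...) {
  if (is_present(x)) {
    cat("<present> ", paste(format(x$value), collapse = ", "), "\n", sep = "")
  } else {
    cat("<", x$state, ">\n", sep = "")
  }
  invisible(x)
}

#' @export
format.tc_attr <- function(x, ...) {
  if (is_present(x)) paste(format(x$value), collapse = "+") else paste0("<", x$state, ">")
}

# Coerce a raw field into a tc_attr against a declared domain.
# NULL / NA -> missing; value in domain -> present; otherwise unrelated.
as_av <- function(x, domain = NULL) {
  if (is_av(x)) {
    if (is_present(x) && !is.null(domain) && !all(x$value %in% domain)) {
      return(av_unrelated(raw = x$value))
    }
    return(x)
  }
  if (is.null(x) || length(x) == 0L || all(is.na(x))) return(av_missing())
  if (!is.null(domain) && !all(x %in% domain)) return(av_unrelated(raw = x))
  av_present(x)
}

# Ordinal variant: payload must be integer-like within [0, scale_max].
as_av_ordinal <- function(x, scale_max, what = "ordinal attribute") {
  a <- as_av(x)
  if (!is_present(a)) return(a)
  v <- a$value
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v) ||
      v < 0 || v > scale_max) {
    stop(sprintf("%s payload must be an integer in [0, %d], got %s",
                 what, scale_max, paste(format(v), collapse = ",")),
         call. = FALSE)
  }
  av_present(as.integer(v))
}
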