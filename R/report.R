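#' Headline attribute token of an event
#'
#' Every event is summarized by its most heavily weighted attribute:
#' diagnoses by UICC stage (roman numeral), surgeries by procedure group,
#' radiotherapies by target region and systemic therapies by therapy type.
#' Missing or unrelated headline attributes render as `"?"`.
#'
#' @param e a `tc_event`
#' @return a single character token
#' @export
headline_token <- function(e) {
  stopifnot(inherits(e, "tc_event"))
  pick <- function(x, fmt = identity) if (is_present(x)) fmt(x$value) else "?"
  switch(e$type,
         diagnosis = pick(e$uicc, function(v) c("0", "I", "II", "III", "IV")[v + 1L]),
         surgery = pick(e$surgery_group),
         radiotherapy = pick(e$target_region),
         systemic = pick(e$therapy_type))
}

#' @rdname headline_token
#' @param course a `tc_course`
#' @export
course_tokens <- function(course) {
  vapply(course$events, headline_token, character(1))
}

#' Characterize one cluster
#'
#' Builds the review report for a cluster: its size, the medoid course
#' rendered as its headline token sequence, the five most similar and most
#' dissimilar courses to the medoid, and per-attribute frequency tables
#' over the cluster members.
#'
#' @param result a `tc_clustering`
#' @param cluster_id a cluster label occurring in `result$labels`
#' @param courses the cohort (list of `tc_course` / `tc_patient`) the
#'   clustering was computed on
#' @param dmat the `tc_distmat` used for the clustering
#' @param k how many nearest/farthest neighbours to list
#' @return `tc_cluster_report`
#' @export
summarize_cluster <- function(result, cluster_id, courses, dmat, k = 5L) {
  stopifnot(inherits(result, "tc_clustering"), inherits(dmat, "tc_distmat"))
  if (!cluster_id %in% result$labels) {
    stop(sprintf("cluster %s does not exist in this result", cluster_id),
         call. = FALSE)
  }
  courses <- as_course_list(courses)
  names(courses) <- vapply(courses, `[[`, character(1), "patient_id")
  member_ids <- names(result$labels)[result$labels == cluster_id]
  med <- medoid(member_ids, dmat)
  nf <- nearest_and_farthest(med, member_ids, dmat, k)
  freq <- attribute_frequencies(courses[member_ids])
  structure(list(cluster_id = cluster_id, size = length(member_ids),
                 medoid_id = med, medoid_tokens = course_tokens(courses[[med]]),
                 nearest = nf$nearest, farthest = nf$farthest,
                 frequencies = freq),
            class = "tc_cluster_report")
}

#' @export
print.tc_cluster_report <- function(x, ...) {
  cat(sprintf("<cluster %s: %d courses>\n", x$cluster_id, x$size))
  cat("  medoid ", x$medoid_id, ": ", paste(x$medoid_tokens, collapse = ", "),
      "\n", sep = "")
  if (length(x$nearest)) cat("  most similar:   ", paste(x$nearest, collapse = ", "), "\n")
  if (length(x$farthest)) cat("  most dissimilar:", paste(x$farthest, collapse = ", "), "\n")
  invisible(x)
}

# tally attribute values (by display format, missing/unrelated as states)
# per event type over a set of courses
attribute_frequencies <- function(courses) {
  events <- unlist(lapply(courses, `[[`, "events"), recursive = FALSE)
  out <- list()
  for (type in names(EVENT_TYPES)) {
    evs <- Filter(function(e) e$type == type, events)
    if (length(evs) == 0L) next
    attrs <- switch(type,
                    diagnosis = c("uicc", "ecog", "age_group", "histology", "grading"),
                    surgery = c("surgery_group", "residual", "complications"),
                    radiotherapy = c("application_types", "target_region", "temporal"),
                    systemic = c("therapy_type", "temporal"))
    out[[type]] <- lapply(stats::setNames(attrs, attrs), function(a) {
      vals <- vapply(evs, function(e) format(e[[a]]), character(1))
      table(vals)
    })
  }
  out
}

# --- deterministic SVG rendering --------------------------------------

# The exports are written as hand-assembled SVG so that rerendering the
# same inputs is byte-identical across platforms.

svg_header <- function(width, height) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect width="%d" height="%d" fill="white"/>', width, height))
}

# fixed qualitative palette (12 distinguishable hues), recycled
TC_PALETTE <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
                "#aec7e8", "#ffbb78")

palette_for <- function(keys) {
  stats::setNames(TC_PALETTE[(seq_along(keys) - 1L) %% length(TC_PALETTE) + 1L], keys)
}

fmt_num <- function(x) formatC(x, format = "f", digits = 2)

#' Export cluster views as SVG
#'
#' Writes a scatter plot of the embedding colored by cluster (legend:
#' each cluster's most frequent headline-token sequence) and one sequence
#' diagram per cluster (one row per course, one cell per event, colored by
#' headline token). Output is deterministic: identical inputs produce
#' byte-identical files.
#'
#' @param result a `tc_clustering`
#' @param courses the cohort the clustering was computed on
#' @param dir output directory (created if needed)
#' @param max_rows cap on rows per sequence diagram (largest clusters are
#'   truncated to keep files reviewable)
#' @return invisibly, the paths written
#' @export
export_views <- function(result, courses, dir, max_rows = 200L) {
  stopifnot(inherits(result, "tc_clustering"), !result$unsatisfiable)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  courses <- as_course_list(courses)
  names(courses) <- vapply(courses, `[[`, character(1), "patient_id")
  paths <- character(0)

  scatter <- file.path(dir, "scatter.svg")
  write_scatter_svg(result, courses, scatter)
  paths <- c(paths, scatter)

  for (cl in sort(unique(result$labels[result$labels != -1L]))) {
    ids <- names(result$labels)[result$labels == cl]
    p <- file.path(dir, sprintf("cluster-%03d.svg", cl))
    write_sequence_svg(courses[utils::head(ids, max_rows)],
                       sprintf("cluster %d (n=%d)", cl, length(ids)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

write_scatter_svg <- function(result, courses, path, width = 760L, height = 560L) {
  pts <- result$embedding$points
  labels <- result$labels
  cl_ids <- sort(unique(labels[labels != -1L]))
  pal <- palette_for(as.character(cl_ids))
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  pad <- 30
  sx <- function(x) pad + (x - rx[1]) / max(rx[2] - rx[1], 1e-12) * (520 - 2 * pad)
  sy <- function(y) height - pad - (y - ry[1]) / max(ry[2] - ry[1], 1e-12) * (height - 2 * pad)
  lines <- svg_header(width, height)
  ord <- order(rownames(pts))
  for (i in ord) {
    col <- if (labels[i] == -1L) "#cccccc" else pal[[as.character(labels[i])]]
    lines <- c(lines, sprintf('<circle cx="%s" cy="%s" r="2.2" fill="%s" fill-opacity="0.8"/>',
                              fmt_num(sx(pts[i, 1])), fmt_num(sy(pts[i, 2])), col))
  }
  # legend: most frequent token sequence per cluster
  y <- 20
  for (cl in cl_ids) {
    ids <- names(labels)[labels == cl]
    seqs <- vapply(courses[ids], function(cr) paste(course_tokens(cr), collapse = ", "),
                   character(1))
    tt <- sort(table(seqs), decreasing = TRUE)
    lab <- sprintf("%d (n=%d): %s", cl, length(ids), names(tt)[1])
    lines <- c(lines,
               sprintf('<rect x="530" y="%d" width="10" height="10" fill="%s"/>', y - 9, pal[[as.character(cl)]]),
               sprintf('<text x="545" y="%d" font-family="sans-serif" font-size="10">%s</text>',
                       y, xml_escape(substr(lab, 1, 40))))
    y <- y + 14
    if (y > height - 10) break
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

write_sequence_svg <- function(courses, title, path, cell = 18L) {
  nrows <- length(courses)
  ncols <- max(c(1L, vapply(courses, length, integer(1))))
  tokens <- sort(unique(unlist(lapply(courses, course_tokens))))
  pal <- palette_for(tokens)
  width <- as.integer(40 + ncols * (cell + 2) + 180)
  height <- as.integer(40 + max(nrows, length(pal)) * (cell + 2))
  lines <- c(svg_header(width, height),
             sprintf('<text x="10" y="20" font-family="sans-serif" font-size="12">%s</text>',
                     xml_escape(title)))
  for (r in seq_len(nrows)) {
    toks <- course_tokens(courses[[r]])
    y <- 30 + (r - 1L) * (cell + 2)
    for (cix in seq_along(toks)) {
      x <- 40 + (cix - 1L) * (cell + 2)
      lines <- c(lines, sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
                                x, y, cell, cell, pal[[toks[cix]]]))
    }
  }
  # legend
  for (i in seq_along(pal)) {
    y <- 30 + (i - 1L) * (cell + 2)
    x <- as.integer(40 + ncols * (cell + 2) + 20)
    lines <- c(lines,
               sprintf('<rect x="%d" y="%d" width="10" height="10" fill="%s"/>', x, y, pal[[i]]),
               sprintf('<text x="%d" y="%d" font-family="sans-serif" font-size="10">%s</text>',
                       x + 15L, y + 9L, xml_escape(names(pal)[i])))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
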