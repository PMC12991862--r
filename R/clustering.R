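#' Granularity bands for cluster-count selection
#'
#' Model selection is constrained to a band of admissible cluster counts:
#' coarse (1-50), medium (51-100) and fine (101-200) for content review,
#' plus a custom band (the survival workflow uses 15-30). Bands are
#' disjoint and ordered.
#'
#' @param name `"coarse"`, `"medium"`, `"fine"` or `"custom"`
#' @param min_clusters,max_clusters band limits for a custom band
#' @return `tc_band`
#' @export
granularity_band <- function(name = c("coarse", "medium", "fine", "custom"),
                             min_clusters = NULL, max_clusters = NULL) {
  name <- match.arg(name)
  lim <- switch(name,
                coarse = c(1L, 50L), medium = c(51L, 100L),
                fine = c(101L, 200L),
                custom = c(as.integer(min_clusters), as.integer(max_clusters)))
  if (anyNA(lim) || lim[1] < 1L || lim[2] < lim[1]) {
    stop("invalid band limits", call. = FALSE)
  }
  structure(list(name = name, min_clusters = lim[1], max_clusters = lim[2]),
            class = "tc_band")
}

# relabel raw cluster labels to 0..k-1 in order of first occurrence,
# keeping -1 for outliers
relabel_clusters <- function(labels) {
  out <- rep(-1L, length(labels))
  seen <- unique(labels[labels != -1L])
  for (i in seq_along(seen)) out[labels == seen[i]] <- i - 1L
  out
}

#' Mean silhouette width of a labelling
#'
#' Computed on the 2D embedding with Euclidean distance (the space the
#' clustering operates in); pass a precomputed `tc_distmat` as `coords` to
#' score on the original course distances instead. Outliers (label -1) are
#' excluded; singleton clusters contribute width 0.
#'
#' @param coords n x 2 coordinate matrix, `tc_embedding`, or `tc_distmat`
#' @param labels integer labels, -1 = outlier
#' @return mean silhouette width in [-1, 1], or `NA` if fewer than 2
#'   clusters remain after excluding outliers
#' @export
silhouette_score <- function(coords, labels) {
  if (inherits(coords, "tc_embedding")) coords <- coords$points
  keep <- labels != -1L
  lab <- labels[keep]
  if (length(unique(lab)) < 2L) return(NA_real_)
  d <- if (inherits(coords, "tc_distmat")) {
    stats::as.dist(coords$cells[keep, keep, drop = FALSE])
  } else {
    stats::dist(coords[keep, , drop = FALSE])
  }
  sil <- cluster::silhouette(as.integer(factor(lab)), d)
  mean(sil[, "sil_width"])
}

#' DBSCAN on a precomputed distance matrix
#'
#' Classic density-based clustering: points with at least `min_samples`
#' neighbours (self included) within `eps` are core points; clusters are
#' the connected components of the core-point neighbourhood graph, plus
#' border points attached to their smallest-index core neighbour's
#' cluster. Everything else is noise (-1). Deterministic: components are
#' seeded in index order.
#'
#' @param D symmetric distance matrix
#' @param eps neighbourhood radius
#' @param min_samples minimum neighbourhood size for a core point
#' @return integer labels, 0-based, -1 for noise
#' @export
dbscan_labels <- function(D, eps, min_samples) {
  n <- nrow(D)
  within <- D <= eps
  core <- rowSums(within) >= min_samples
  labels <- rep(-1L, n)
  cl <- -1L
  visited <- !core  # only core points drive expansion
  for (i in seq_len(n)) {
    if (visited[i]) next
    cl <- cl + 1L
    frontier <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(frontier) > 0L) {
      reach <- if (length(frontier) == 1L) within[frontier, ] else colSums(within[frontier, , drop = FALSE]) > 0
      nxt <- which(reach & core & !visited)
      visited[nxt] <- TRUE
      labels[nxt] <- cl
      frontier <- nxt
    }
  }
  # border points: non-core within eps of a core point join that core's
  # cluster (smallest index wins for determinism)
  if (cl >= 0L) {
    border <- which(!core)
    core_ix <- which(core)
    for (b in border) {
      hits <- core_ix[within[core_ix, b]]
      if (length(hits) > 0L) labels[b] <- labels[hits[1L]]
    }
  }
  relabel_clusters(labels)
}

#' HDBSCAN-style density clustering on a precomputed distance matrix
#'
#' Hierarchical density-based clustering: distances are inflated to mutual
#' reachability (the maximum of the pairwise distance and both points' core
#' distances, the distance to the `min_samples`-th nearest neighbour), a
#' single-linkage hierarchy is built on them, condensed by discarding
#' components smaller than `min_cluster_size`, and flat clusters are
#' extracted by excess-of-mass stability. Points not falling inside any
#' selected cluster are noise (-1).
#'
#' @param D symmetric distance matrix
#' @param min_samples neighbourhood size defining the core distance
#' @param min_cluster_size smallest cluster retained in the condensed tree
#'   (at least 2)
#' @return integer labels, 0-based, -1 for noise
#' @export
hdbscan_labels <- function(D, min_samples, min_cluster_size) {
  n <- nrow(D)
  stopifnot(min_cluster_size >= 2L)
  if (n < 2L * min_cluster_size) return(rep(-1L, n))
  # core distance: k-th nearest neighbour excluding self
  core <- vapply(seq_len(n), function(i) {
    sort(D[i, -i], partial = min_samples)[min_samples]
  }, numeric(1))
  mr <- pmax(D, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  condensed <- condense_tree(hc, n, min_cluster_size)
  selected <- eom_select(condensed)
  labels <- rep(-1L, n)
  if (length(selected) > 0L) {
    # a point belongs to the selected ancestor of the condensed cluster it
    # fell out of
    sel_of <- integer(length(condensed$parent))
    for (cid in seq_along(condensed$parent)) {
      a <- cid
      hit <- 0L
      while (a != 0L) {
        if (a %in% selected) { hit <- a; break }
        a <- condensed$parent[a]
      }
      sel_of[cid] <- hit
    }
    for (p in seq_len(n)) {
      fc <- condensed$fall_cluster[p]
      if (fc > 0L && sel_of[fc] > 0L) labels[p] <- sel_of[fc]
    }
  }
  relabel_clusters(labels)
}

# Build the condensed cluster tree from a single-linkage hclust object.
# Returns parent pointers, stabilities, and for each point the condensed
# cluster it fell out of.
condense_tree <- function(hc, n, mcs) {
  m <- nrow(hc$merge)
  # members of each internal node
  members <- vector("list", m)
  for (k in seq_len(m)) {
    ch <- hc$merge[k, ]
    members[[k]] <- c(if (ch[1] < 0) -ch[1] else members[[ch[1]]],
                      if (ch[2] < 0) -ch[2] else members[[ch[2]]])
  }
  node_size <- function(v) if (v < 0) 1L else length(members[[v]])
  lam <- function(h) if (h <= 0) 1e12 else min(1 / h, 1e12)

  parent <- integer(0)     # condensed-tree parent (0 = none)
  birth <- numeric(0)      # birth lambda
  stability <- numeric(0)
  fall_cluster <- integer(n)  # condensed cluster each point fell out of

  new_cluster <- function(par, lam_birth) {
    parent[length(parent) + 1L] <<- par
    birth[length(birth) + 1L] <<- lam_birth
    stability[length(stability) + 1L] <<- 0
    length(parent)
  }
  root_id <- new_cluster(0L, lam(hc$height[m]))
  # stack entries: dendrogram node, condensed cluster id
  stack <- list(list(node = m, cid = root_id))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top$node; cid <- top$cid
    if (v < 0) {  # singleton continuing a cluster (only when mcs = 1)
      fall_cluster[-v] <- cid
      next
    }
    ch <- hc$merge[v, ]
    l <- lam(hc$height[v])
    s1 <- node_size(ch[1]); s2 <- node_size(ch[2])
    big1 <- s1 >= mcs; big2 <- s2 >= mcs
    drop_points <- function(node, at_lam) {
      pts <- if (node < 0) -node else members[[node]]
      stability[cid] <<- stability[cid] + length(pts) * (at_lam - birth[cid])
      fall_cluster[pts] <<- cid
    }
    if (big1 && big2) {
      # true split: close this cluster, spawn two condensed children
      stability[cid] <- stability[cid] + (s1 + s2) * (l - birth[cid])
      for (node in ch) {
        stack[[length(stack) + 1L]] <- list(node = node,
                                            cid = new_cluster(cid, l))
      }
    } else if (big1 || big2) {
      keep <- if (big1) ch[1] else ch[2]
      drop_points(if (big1) ch[2] else ch[1], l)
      stack[[length(stack) + 1L]] <- list(node = keep, cid = cid)
    } else {
      drop_points(ch[1], l)
      drop_points(ch[2], l)
    }
  }
  list(parent = parent, birth = birth, stability = stability,
       fall_cluster = fall_cluster, root = root_id)
}

# Excess-of-mass cluster selection over the condensed tree; the root is
# never selected (no single all-points cluster).
eom_select <- function(condensed) {
  np <- length(condensed$parent)
  children <- lapply(seq_len(np), function(i) which(condensed$parent == i))
  subtree_value <- numeric(np)
  selected_sets <- vector("list", np)
  # process deepest-first: children always have larger ids than parents
  child_sets <- function(ch) {
    v <- unlist(selected_sets[ch])
    if (is.null(v)) integer(0) else v
  }
  for (i in rev(seq_len(np))) {
    ch <- children[[i]]
    child_val <- sum(subtree_value[ch])
    if (i == condensed$root) {
      subtree_value[i] <- child_val
      selected_sets[[i]] <- child_sets(ch)
    } else if (length(ch) == 0L || condensed$stability[i] >= child_val) {
      subtree_value[i] <- condensed$stability[i]
      selected_sets[[i]] <- i
    } else {
      subtree_value[i] <- child_val
      selected_sets[[i]] <- child_sets(ch)
    }
  }
  selected_sets[[condensed$root]]
}

#' Agglomerative complete-linkage labels at a distance threshold
#'
#' @param hc a complete-linkage `hclust` over the embedding
#' @param threshold cut height: clusters are merged while their complete
#'   linkage stays below the threshold
#' @return integer labels, 0-based (no outliers)
#' @export
hierarchical_labels <- function(hc, threshold) {
  relabel_clusters(unname(stats::cutree(hc, h = threshold)))
}
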