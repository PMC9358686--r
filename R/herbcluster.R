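#' Binary herb-by-case incidence matrix
#'
#' Builds the 0/1 matrix whose rows are herbs and columns are cases, with a
#' 1 where the herb was prescribed in the case. Only herbs prescribed in
#' strictly more than `min_count` cases are included (the study enrolled
#' herbs with cumulative occurrences higher than 50 into its cluster
#' analysis). Rows are ordered alphabetically, columns in case order.
#'
#' @param cases Clean case tibble.
#' @param min_count Strict lower bound on herb occurrence count.
#' @return An integer matrix with herb rownames and case-id colnames.
#' @export
build_incidence <- function(cases, min_count = 50) {
  if (nrow(cases) == 0) abort("no cases")
  counts <- table(unlist(lapply(cases$herbs, unique)))
  keep <- sort(names(counts)[counts > min_count])
  if (length(keep) == 0) {
    abort(paste0("no herb occurs in more than ", min_count, " cases"))
  }
  mat <- matrix(0L, length(keep), nrow(cases),
                dimnames = list(keep, cases$case_id))
  for (j in seq_len(nrow(cases))) {
    mat[intersect(cases$herbs[[j]], keep), j] <- 1L
  }
  mat
}

#' Agglomerative hierarchical clustering of herbs
#'
#' Clusters the rows of the incidence matrix bottom-up: starting from
#' singletons, the pair of clusters at minimal inter-cluster distance is
#' merged repeatedly. Complete linkage (default) uses the maximum pairwise
#' row distance between clusters, average the mean, single the minimum.
#' Distance ties are broken deterministically by the lexicographically
#' smallest pair of cluster representatives (each cluster represented by
#' its smallest leaf name), so permuting input rows cannot change the
#' dendrogram.
#'
#' @param incidence Matrix from [build_incidence()] (>= 2 rows), or any
#'   numeric matrix with row names.
#' @param metric `"euclidean"` or `"jaccard"` (asymmetric binary) row
#'   distance.
#' @param method `"complete"`, `"average"` or `"single"` linkage.
#' @return A `herb_dendrogram`: list with `leaves` (alphabetical), `merge`
#'   (merge matrix in `stats::hclust` convention), `height`, `metric`,
#'   `method`.
#' @export
herb_linkage <- function(incidence, metric = c("euclidean", "jaccard"),
                         method = c("complete", "average", "single")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (is.null(rownames(incidence)) || nrow(incidence) < 2) {
    abort("incidence must have >= 2 named rows")
  }
  ord <- order(rownames(incidence))
  incidence <- incidence[ord, , drop = FALSE]
  leaves <- rownames(incidence)
  n <- length(leaves)
  d <- as.matrix(dist(incidence,
                      method = if (metric == "jaccard") "binary" else "euclidean"))

  # active clusters: leaf index sets, representative = smallest leaf name
  members <- as.list(seq_len(n))
  node_of <- -seq_len(n)          # hclust convention: negatives are leaves
  reps <- leaves
  active <- seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  cluster_dist <- function(a, b) {
    block <- d[members[[a]], members[[b]], drop = FALSE]
    switch(method,
           complete = max(block),
           average = mean(block),
           single = min(block))
  }

  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        a <- active[i]; b <- active[j]
        dd <- cluster_dist(a, b)
        key <- sort(c(reps[a], reps[b]))
        better <- dd < best_d ||
          (dd == best_d && (key[1] < best_key[1] ||
                              (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) { best <- c(a, b); best_d <- dd; best_key <- key }
      }
    }
    a <- best[1]; b <- best[2]
    # order merge columns by representative for determinism
    pair <- if (reps[a] <= reps[b]) c(a, b) else c(b, a)
    merge[step, ] <- c(node_of[pair[1]], node_of[pair[2]])
    height[step] <- best_d
    members[[a]] <- c(members[[a]], members[[b]])
    reps[a] <- min(reps[a], reps[b])
    node_of[a] <- step
    active <- setdiff(active, b)
  }

  structure(list(leaves = leaves, merge = merge, height = height,
                 metric = metric, method = method),
            class = "herb_dendrogram")
}

#' @export
print.herb_dendrogram <- function(x, ...) {
  cat("<herb_dendrogram>", length(x$leaves), "leaves,", x$method,
      "linkage on", x$metric, "distance; max height",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

#' Convert to a `stats::hclust` object
#'
#' @param x A `herb_dendrogram`.
#' @param ... Ignored.
#' @return An object of class `hclust`.
#' @export
as.hclust.herb_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = leaf_order(x),
         labels = x$leaves, method = x$method, dist.method = x$metric,
         call = match.call()),
    class = "hclust"
  )
}

# left-to-right leaf ordering by recursive traversal of the merge matrix
leaf_order <- function(dend) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(dend$merge[node, 1]), walk(dend$merge[node, 2]))
  }
  walk(nrow(dend$merge))
}

#' Cut a dendrogram into k groups
#'
#' Removes the `k - 1` last (highest) merges; the connected components that
#' remain are the groups. Group ids are assigned in first-leaf order: the
#' group containing the alphabetically first leaf is 1, and so on.
#'
#' @param dend A `herb_dendrogram`.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return A tibble with columns `herb` and `group`.
#' @export
cut_groups <- function(dend, k) {
  n <- length(dend$leaves)
  if (k < 1 || k > n) abort("k must lie between 1 and the number of leaves")
  group <- seq_len(n)               # union-find by relabelling
  leaf_of <- function(node) {       # any leaf under an internal node
    while (node > 0) node <- dend$merge[node, 1]
    -node
  }
  for (step in seq_len(n - k)) {
    l <- group[leaf_of(dend$merge[step, 1])]
    r <- group[leaf_of(dend$merge[step, 2])]
    group[group == r] <- l
  }
  ids <- unique(group)              # leaves are alphabetical already
  tibble(herb = dend$leaves, group = match(group, ids))
}

#' Export a dendrogram as a Newick tree
#'
#' Writes an ultrametric tree: a node at merge height `h` places each child
#' at depth `h / 2` below the root of that subtree, so every leaf sits at
#' path length `h_root / 2` from the root and the cophenetic distance
#' between two leaves equals the height of their lowest common ancestor.
#'
#' @param dend A `herb_dendrogram`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(dend, digits = 15) {
  node_height <- function(node) {
    if (node < 0) 0 else dend$height[node]
  }
  build <- function(node, parent_h) {
    bl <- format(parent_h / 2 - node_height(node) / 2, digits = digits,
                 scientific = FALSE, trim = TRUE)
    if (node < 0) return(paste0(dend$leaves[-node], ":", bl))
    paste0("(", build(dend$merge[node, 1], node_height(node)), ",",
           build(dend$merge[node, 2], node_height(node)), "):", bl)
  }
  root <- nrow(dend$merge)
  h <- dend$height[root]
  paste0("(", build(dend$merge[root, 1], h), ",",
         build(dend$merge[root, 2], h), ");")
}

#' Cophenetic (merge-height) distances between leaves
#'
#' @param dend A `herb_dendrogram`.
#' @return A symmetric matrix: the height of the lowest common ancestor of
#'   each leaf pair.
#' @export
cophenetic_heights <- function(dend) {
  n <- length(dend$leaves)
  out <- matrix(0, n, n, dimnames = list(dend$leaves, dend$leaves))
  below <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    side <- function(node) if (node < 0) -node else below[[node]]
    l <- side(dend$merge[step, 1]); r <- side(dend$merge[step, 2])
    out[l, r] <- dend$height[step]
    out[r, l] <- dend$height[step]
    below[[step]] <- c(l, r)
  }
  out
}
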