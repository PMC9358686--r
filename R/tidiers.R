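#' Tidy an association rule set
#'
#' @param x A `herb_rules` tibble.
#' @param ... Ignored.
#' @return A plain tibble with one row per rule (`lhs`, `rhs`, `support`,
#'   `confidence`, `lift`, `co_count`).
#' @export
tidy.herb_rules <- function(x, ...) {
  tibble(lhs = x$lhs_label, rhs = x$rhs, support = x$support,
         confidence = x$confidence, lift = x$lift, co_count = x$co_count)
}

#' @rdname tidy.herb_rules
#' @return `glance()` returns a one-row summary: rule count, transaction
#'   count and the thresholds used.
#' @export
glance.herb_rules <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    n_rules = nrow(x),
    n_transactions = attr(x, "n_transactions") %||% NA_integer_,
    order = attr(x, "order") %||% NA_real_,
    min_support = th$min_support, min_confidence = th$min_confidence,
    min_lift = th$min_lift, min_count = th$min_count
  )
}

#' Tidy a herb dendrogram
#'
#' @param x A `herb_dendrogram`.
#' @param ... Ignored.
#' @return One row per merge: the merged node ids (`stats::hclust`
#'   convention, negatives are leaves), their labels where leaves, and the
#'   merge height.
#' @export
tidy.herb_dendrogram <- function(x, ...) {
  lab <- function(nodes) {
    vapply(nodes, function(node) {
      if (node < 0) x$leaves[-node] else paste0("node", node)
    }, character(1))
  }
  tibble(
    step = seq_len(nrow(x$merge)),
    left = x$merge[, 1], right = x$merge[, 2],
    left_label = lab(x$merge[, 1]), right_label = lab(x$merge[, 2]),
    height = x$height
  )
}

#' @rdname tidy.herb_dendrogram
#' @export
glance.herb_dendrogram <- function(x, ...) {
  tibble(n_leaves = length(x$leaves), n_merges = nrow(x$merge),
         max_height = max(x$height), metric = x$metric, method = x$method)
}
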