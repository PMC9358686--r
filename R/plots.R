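#' Frequency histogram of items
#'
#' Bar chart of item counts in descending order, annotated with the rate;
#' the plotting-ready analogue of the symptom/herb frequency histograms.
#'
#' @param table A frequency tibble from [frequency_table()].
#' @param top_n Show at most this many items.
#' @return A ggplot object.
#' @export
plot_frequency <- function(table, top_n = Inf) {
  df <- head(table, top_n)
  df$item <- factor(df$item, levels = rev(df$item))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$rate)),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Cases") +
    ggplot2::theme_minimal()
}

#' Pain/other proportion chart
#'
#' @param share Output of [pain_share()].
#' @return A ggplot object.
#' @export
plot_pain_share <- function(share) {
  ggplot2::ggplot(share,
                  ggplot2::aes(x = "", y = .data$fraction, fill = .data$term)) +
    ggplot2::geom_col(width = 1, color = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' Bubble diagram of association rules
#'
#' Confidence on the x axis, LHS on the y axis faceted by RHS, bubble size
#' proportional to support and color to lift.
#'
#' @param object A `herb_rules` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.herb_rules <- function(object, ...) {
  df <- bubble_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence, y = .data$lhs,
                                   size = .data$support, color = .data$lift)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~rhs) +
    ggplot2::scale_color_gradient(low = "navy", high = "red") +
    ggplot2::labs(x = "Confidence (%)", y = "LHS",
                  size = "Support (%)", color = "Lift") +
    ggplot2::theme_bw()
}

#' Dendrogram plot
#'
#' Draws the merge tree as segments, leaves at height 0 in dendrogram
#' order.
#'
#' @param object A `herb_dendrogram`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.herb_dendrogram <- function(object, ...) {
  ord <- leaf_order(object)
  xpos <- numeric(length(object$leaves))
  xpos[ord] <- seq_along(ord)
  segs <- list()
  node_x <- numeric(nrow(object$merge))
  pos <- function(node) if (node < 0) xpos[-node] else node_x[node]
  hgt <- function(node) if (node < 0) 0 else object$height[node]
  for (i in seq_len(nrow(object$merge))) {
    l <- object$merge[i, 1]; r <- object$merge[i, 2]
    h <- object$height[i]
    node_x[i] <- (pos(l) + pos(r)) / 2
    segs[[length(segs) + 1]] <- tibble(
      x = c(pos(l), pos(l), pos(r)),
      xend = c(pos(l), pos(r), pos(r)),
      y = c(hgt(l), h, hgt(r)),
      yend = c(h, h, h)
    )
  }
  segs <- bind_rows(segs)
  labels <- tibble(x = seq_along(ord), label = object$leaves[ord])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.05, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "Merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
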