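#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-position alignment coverage profile
#'
#' @param object a `promcons_coverage` tibble ([coverage_profile()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.promcons_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "position relative to TSS (nt)",
                  y = "promoters with alignment coverage") +
    ggplot2::theme_minimal()
}

#' Plot a TSS-relative site position profile
#'
#' @param object a `promcons_site_profile` tibble ([site_position_profile()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.promcons_site_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$count))
  if ("level" %in% names(object)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = factor(.data$level)), width = 1) +
      ggplot2::labs(fill = "conservation level")
  } else {
    p <- p + ggplot2::geom_col(width = 1)
  }
  p + ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "site start relative to TSS (nt)", y = "conserved sites") +
    ggplot2::theme_minimal()
}

#' Plot the binned similarity-vs-identity regression
#'
#' Bin proportions sized by gene count with the weighted least-squares line.
#'
#' @param object a `promcons_regression` ([binned_weighted_regression()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.promcons_regression <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin, y = .data$proportion_similar)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "protein percent identity (bin)",
                  y = "proportion with similar promoters", size = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot a TF-family co-occurrence network
#'
#' Families on a circle, edges weighted by the number of shared promoters.
#'
#' @param object a `promcons_network` ([cooccurrence_network()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.promcons_network <- function(object, ...) {
  nodes <- object$nodes
  k <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  layout <- dplyr::mutate(nodes, x = cos(theta), y = sin(theta))
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(layout, "tf_family", xa = "x", ya = "y"),
                     by = c(family_a = "tf_family")) |>
    dplyr::left_join(dplyr::select(layout, "tf_family", xb = "x", yb = "y"),
                     by = c(family_b = "tf_family"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       linewidth = .data$weight),
                          colour = "grey60", alpha = 0.7) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$n_genes), colour = "steelblue") +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$tf_family), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "shared promoters", size = "promoters")
}
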