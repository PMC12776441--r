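# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-position profile test
#'
#' Z-scores by motif-relative position, colored by strand, with
#' significant cells marked by direction.
#'
#' @param object A `uvf_profile_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uvf_profile_test
#' @export
autoplot.uvf_profile_test <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$z), , drop = FALSE]
  if (!"strand" %in% names(d)) d$strand <- "aggregate"
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$z,
                                       colour = .data$strand)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(data = d[d$significant, , drop = FALSE],
                        ggplot2::aes(shape = .data$direction), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(enriched = 24,
                                           depleted = 25)) +
    ggplot2::labs(x = "position relative to motif center",
                  y = "z-score", colour = "strand",
                  shape = "direction") +
    ggplot2::theme_minimal()
  p
}

#' Plot an observed-vs-expected damage profile
#'
#' @param profile Profile tibble with `observed` and `expected` (and
#'   optionally `expected_scaled`) columns.
#' @return A ggplot.
#' @export
plot_profile <- function(profile) {
  d <- tidyr::pivot_longer(tibble::as_tibble(profile),
                           dplyr::any_of(c("observed", "expected",
                                           "expected_scaled")),
                           names_to = "series", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$count,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::labs(x = "position relative to motif center",
                  y = "damage count") +
    ggplot2::theme_minimal()
}

#' Plot projected versus actual mutation concordance
#'
#' Scatter of per-position projected vs actual counts with the OLS fit;
#' discordant positions highlighted.
#'
#' @param object A `uvf_concordance`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uvf_concordance
#' @export
autoplot.uvf_concordance <- function(object, ...) {
  d <- object$positions
  ggplot2::ggplot(d, ggplot2::aes(x = .data$projected,
                                  y = .data$actual)) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$discordant)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "projected C>T (from damage)",
                  y = "observed C>T",
                  subtitle = paste0("r = ", format(object$r,
                                                   digits = 3))) +
    ggplot2::theme_minimal()
}

#' Heatmap of signed max-|z| per cluster and position
#'
#' @param zmat Tibble from [signed_z_matrix()].
#' @return A ggplot.
#' @export
plot_z_heatmap <- function(zmat) {
  ggplot2::ggplot(zmat, ggplot2::aes(x = .data$position,
                                     y = .data$cluster,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "position relative to motif center", y = NULL,
                  fill = "z") +
    ggplot2::theme_minimal()
}
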