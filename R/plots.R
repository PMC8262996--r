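process_palette <- c(
  homogeneous_selection = "#1b9e77", variable_selection = "#d95f02",
  homogeneous_dispersal = "#7570b3", dispersal_limitation = "#e7298a",
  undominated = "#666666", unclassified = "#cccccc"
)

#' Plot methods for assembly-process results
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' the (betaNTI, RC) plane for a pair table, per-group process fractions
#' with bootstrap CIs for a summary, and the bootstrap slope distribution
#' for a regression.
#'
#' @param object A `pair_process`, `process_summary`, or
#'   `regression_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-assemblyproc
NULL

#' @rdname autoplot-assemblyproc
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pair_process <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rc, y = .data$bnti,
                                       colour = .data$process)) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-0.95, 0.95), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = process_palette, drop = FALSE) +
    ggplot2::labs(x = "Raup-Crick index", y = expression(beta * "NTI"),
                  colour = "process") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-assemblyproc
#' @export
autoplot.process_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group,
                                       y = .data$fraction,
                                       fill = .data$process)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::scale_fill_manual(values = process_palette, drop = FALSE) +
    ggplot2::labs(x = NULL, y = "relative importance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.regression_result <- function(object, ...) {
  df <- tibble::tibble(slope = object$boot_slopes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$slope, colour = "#d95f02") +
    ggplot2::geom_vline(xintercept = object$ci95, linetype = "dashed") +
    ggplot2::labs(x = paste0("bootstrap slope (", object$ylab, " ~ ",
                             object$xlab, ")"),
                  y = "count") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a distance-decay relationship
#'
#' @param sim Similarity matrix.
#' @param geo Distance matrix (km).
#' @param fit Optional `regression_result` from [distance_decay()] whose
#'   line is overlaid.
#' @return A ggplot object.
#' @export
plot_distance_decay <- function(sim, geo, fit = NULL) {
  df <- dist_to_pairs(geo, "distance_km")
  df$similarity <- dist_to_pairs(sim, "v")$v
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_km,
                                        y = .data$similarity)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "geographic distance (km)",
                  y = "community similarity (1 - BC)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(intercept = fit$intercept,
                                  slope = fit$slope, colour = "#d95f02")
  }
  p
}
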