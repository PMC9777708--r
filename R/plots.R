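#' Saturation plot
#'
#' Boxplots of a prediction metric against the fold reduction of sequencing
#' depth (or against the training fraction): flat stretches of the curve
#' mark depth (or cohort size) that can be sacrificed without losing
#' predictive power.
#'
#' @param grid a `saturation_grid` data.frame.
#' @param metric `"cindex"` or `"ibs"`.
#' @param x `"delta"` or `"train_fraction"`.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the plotted data subset.
#' @export
plot_saturation <- function(grid, metric = c("cindex", "ibs"),
                            x = c("delta", "train_fraction"), ...) {
  metric <- match.arg(metric)
  x <- match.arg(x)
  g <- grid[grid$metric == metric, , drop = FALSE]
  fac <- factor(g[[x]], levels = sort(unique(g[[x]])))
  ylab <- if (metric == "cindex") "C-index" else "Integrated Brier score"
  xlab <- if (x == "delta") expression(paste("Fold reduction ", delta)) else
    "Training fraction"
  graphics::boxplot(g$value ~ fac, xlab = xlab, ylab = ylab, ...)
  if (metric == "cindex") graphics::abline(h = 0.5, lty = 3)
  invisible(g)
}
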