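#' Plot a p-value cloud with its fitted curve and decision markers
#'
#' Scatter of the MCCV p-values against subsample size, the per-size means,
#' the fitted exponential curve, the significance level `alpha`, and (when
#' defined) vertical markers at `n_alpha` and `n_gamma`.
#'
#' @param x A [run_mccv()] result.
#' @param model Optional [fit_exponential()] result to overlay.
#' @param config Optional [decision_config()] for the `alpha` line and
#'   markers.
#' @param log_x Plot sizes on a log axis (default TRUE).
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.pvalue_cloud <- function(x, model = NULL, config = NULL,
                              log_x = TRUE, ...) {
  pts <- x$points
  graphics::plot(pts$n, pts$p, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.25),
                 log = if (log_x) "x" else "",
                 xlab = "subsample size n", ylab = "p-value",
                 main = sprintf("%s vs %s", x$labels[1], x$labels[2]), ...)
  s <- x$summaries
  graphics::points(s$n, s$p_mean, pch = 18, col = "firebrick")
  if (!is.null(model)) {
    nn <- exp(seq(log(min(pts$n)), log(max(pts$n)), length.out = 200))
    graphics::lines(nn, evaluate_model(model, nn), lwd = 2, col = "navy")
  }
  if (!is.null(config)) {
    graphics::abline(h = config$alpha, lty = 2, col = "grey40")
    if (!is.null(model)) {
      na <- n_alpha(model, config$alpha)
      if (is.finite(na$real) && na$real > 0)
        graphics::abline(v = na$real, lty = 3, col = "darkgreen")
      ng <- n_gamma(model, config$gamma)
      if (!is.na(ng) && ng > 0)
        graphics::abline(v = ng, lty = 3, col = "purple")
    }
  }
  invisible(x)
}
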