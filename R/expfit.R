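#' Fit the exponential p-value model p(n) = a exp(-c n)
#'
#' Estimates the amplitude `a` and decay rate `c` from all points of a
#' p-value cloud (not the per-size means), under the constraints
#' `0 < a <= 1` and `c >= 0`.
#'
#' Two loss spaces are available:
#' \describe{
#'   \item{`"log"`}{ordinary least squares of `log p` on `n`.  Every decade
#'     of p-value counts equally, so this space emphasises the tail of the
#'     decay; it is exact when the noise is multiplicative.}
#'   \item{`"linear"`}{least squares on the raw p-values, the loss under
#'     which the simulation-study results are calibrated.  Solved by
#'     profiling: for fixed `c` the optimal amplitude has the closed form
#'     `a(c) = sum(w p) / sum(w^2)` with `w = exp(-c n)` (clamped to
#'     `(0, 1]`), and the resulting one-dimensional objective in `c` is
#'     minimised by a deterministic log-spaced scan refined with Brent
#'     search.  This avoids the local minima that general-purpose nonlinear
#'     least-squares starts are prone to on clouds spanning hundreds of
#'     orders of magnitude.}
#' }
#' When a constraint binds in log space (amplitude above 1, or positive
#' slope), the bound is imposed and the other parameter re-solved
#' conditionally.
#'
#' @param cloud A [run_mccv()] result, or any data frame with columns `n`
#'   and `p`.
#' @param fit_space `"log"` (default) or `"linear"`.
#' @return An object of class `exp_model`: list with `a`, `c`, `fit_space`,
#'   `n_points`, `residual_norm` (root-sum-of-squares in the chosen space).
#' @examples
#' cl <- data.frame(n = 1:100, p = 0.5 * exp(-0.02 * (1:100)))
#' fit_exponential(cl)
#' @export
fit_exponential <- function(cloud, fit_space = c("log", "linear")) {
  fit_space <- match.arg(fit_space)
  pts <- cloud_points(cloud)
  if (length(unique(pts$n)) < 2L)
    stop("underdetermined fit: need at least 2 distinct sizes")
  if (nrow(pts) < 3L)
    stop("underdetermined fit: need at least 3 points")
  fit <- if (fit_space == "log") fit_log(pts) else fit_linear(pts)
  structure(list(a = unname(fit[["a"]]), c = unname(fit[["c"]]),
                 fit_space = fit_space, n_points = nrow(pts),
                 residual_norm = unname(fit[["rss"]])),
            class = "exp_model")
}

cloud_points <- function(cloud) {
  pts <- if (inherits(cloud, "pvalue_cloud")) cloud$points else
    as.data.frame(cloud)
  if (!all(c("n", "p") %in% names(pts)))
    stop("cloud must have columns 'n' and 'p'")
  pts
}

fit_log <- function(pts) {
  n <- pts$n
  lp <- log(pmax(pts$p, .Machine$double.xmin))
  co <- coef(lm(lp ~ n))
  a <- exp(co[[1]])
  cc <- -co[[2]]
  if (a > 1) {            # amplitude bound binds: re-solve slope with a = 1
    a <- 1
    cc <- -sum(n * lp) / sum(n^2)
  }
  if (cc < 0) {           # no decay: flat model at the geometric mean
    cc <- 0
    a <- min(exp(mean(lp)), 1)
  }
  r <- lp - (log(a) - cc * n)
  c(a = a, c = cc, rss = sqrt(sum(r^2)))
}

fit_linear <- function(pts, c_max = 10) {
  n <- pts$n
  p <- pts$p
  a_of_c <- function(cc) {
    w <- exp(-cc * n)
    min(max(sum(w * p) / sum(w * w), .Machine$double.xmin), 1)
  }
  sse <- function(cc) {
    a <- a_of_c(cc)
    sum((p - a * exp(-cc * n))^2)
  }
  cgrid <- c(0, exp(seq(log(1e-7), log(c_max), length.out = 100)))
  vals <- vapply(cgrid, sse, numeric(1))
  i <- which.min(vals)
  lo <- cgrid[max(1L, i - 1L)]
  hi <- cgrid[min(length(cgrid), i + 1L)]
  opt <- optimize(sse, c(lo, hi), tol = 1e-12)
  cc <- if (opt$objective < vals[i]) opt$minimum else cgrid[i]
  c(a = a_of_c(cc), c = cc, rss = sqrt(sse(cc)))
}

#' Evaluate a fitted exponential model
#'
#' @param model An [fit_exponential()] result (or any list with `a` and
#'   `c`).
#' @param n Sample size(s), `>= 0`; vectorised.
#' @return `a * exp(-c * n)`.
#' @export
evaluate_model <- function(model, n) {
  stopifnot(all(n >= 0))
  model$a * exp(-model$c * n)
}

#' @export
print.exp_model <- function(x, ...) {
  cat(sprintf(
    "exponential p-value model: a = %.4g, c = %.4g  (%s-space fit, %d points, rss %.3g)\n",
    x$a, x$c, x$fit_space, x$n_points, x$residual_norm))
  invisible(x)
}

#' LOWESS curve through the per-size mean p-values
#'
#' Diagnostic companion to the exponential fit: a locally weighted linear
#' regression through the per-size mean p-values, evaluated at the grid
#' sizes.  If the decay is genuinely exponential the smoothed curve tracks
#' the fitted model closely, and the ratio of its derivative to its value
#' (see [derivative_ratio()]) is constant.  The smoother can undershoot
#' slightly below zero near a flat tail; such values are retained (the curve
#' is a diagnostic, never an input to the decision calculus).
#'
#' @param cloud A [run_mccv()] result (needs at least 4 distinct sizes).
#' @param bandwidth Smoother span as a fraction of the size range, in
#'   `(0, 1]`.
#' @return An object of class `smoothed_curve`: data frame with columns `n`
#'   and `value`, plus a `bandwidth` attribute.
#' @export
lowess_mean_curve <- function(cloud, bandwidth = 0.5) {
  stopifnot(bandwidth > 0, bandwidth <= 1)
  s <- if (inherits(cloud, "pvalue_cloud")) cloud$summaries else
    summarise_cloud(cloud_points(cloud))
  if (nrow(s) < 4L)
    stop("underdetermined: LOWESS needs at least 4 distinct sizes")
  sm <- lowess(s$n, s$p_mean, f = bandwidth)
  structure(data.frame(n = sm$x, value = sm$y),
            bandwidth = bandwidth,
            class = c("smoothed_curve", "data.frame"))
}

#' Derivative-to-value ratio of a smoothed p-value curve
#'
#' Finite-difference estimate of `p'(n) / p(n)` along a smoothed curve:
#' central differences at interior grid points, one-sided differences at the
#' ends.  For an exponential curve the ratio is the constant `-c`, so a flat
#' ratio profile is empirical evidence for the exponential model.  Points
#' where the curve value is numerically zero (|value| < 1e-12) are skipped;
#' a message reports how many.
#'
#' @param curve A [lowess_mean_curve()] result, or a data frame with
#'   columns `n` and `value`.
#' @return Data frame with columns `n` and `ratio`.
#' @export
derivative_ratio <- function(curve) {
  n <- curve$n
  v <- curve$value
  k <- length(n)
  if (k < 3L) stop("need at least 3 curve points")
  d <- numeric(k)
  d[1] <- (v[2] - v[1]) / (n[2] - n[1])
  d[k] <- (v[k] - v[k - 1]) / (n[k] - n[k - 1])
  i <- 2:(k - 1)
  d[i] <- (v[i + 1] - v[i - 1]) / (n[i + 1] - n[i - 1])
  ok <- abs(v) >= 1e-12
  if (any(!ok))
    message("derivative_ratio: skipped ", sum(!ok),
            " point(s) with near-zero curve value")
  data.frame(n = n[ok], ratio = d[ok] / v[ok])
}
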