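#' Decision configuration: significance level and convergence threshold
#'
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param gamma Convergence threshold for the slope of `p(n)`, in
#'   `(0, 0.1]`; default `5e-6`, the value at which the decision index is
#'   empirically stable.  `gamma` must satisfy `gamma / c < alpha` for the
#'   convergence point of a fitted curve to be meaningful; fits violating
#'   that constraint are routed to the no-decay rule (see [theta_index()]).
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(alpha = 0.05, gamma = 5e-6) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("invalid config: alpha must be in (0, 1)")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma > 0.1)
    stop("invalid config: gamma must be in (0, 0.1]")
  structure(list(alpha = alpha, gamma = gamma), class = "decision_config")
}

#' Convergence point of the fitted p-value curve
#'
#' The smallest `n` at which the slope magnitude of `p(n) = a exp(-c n)`
#' falls below `gamma`:
#' `n_gamma = max(0, log(a c / gamma) / c)`.  When `c = 0` the curve never
#' decays and the convergence point is undefined (`NA`, the "no decay"
#' case, handled by the degenerate rules of [theta_index()]).
#'
#' @param model An [fit_exponential()] result or list with `a`, `c`.
#' @param gamma Slope threshold > 0.
#' @return The convergence point (>= 0), or `NA_real_` when `c = 0`.
#' @export
n_gamma <- function(model, gamma = 5e-6) {
  stopifnot(gamma > 0)
  if (model$c <= 0) return(NA_real_)
  max(0, log(model$a * model$c / gamma) / model$c)
}

#' Area distance between the significance level and the p-value curve
#'
#' The signed area between the constant `alpha` and `p(n)` over
#' `[0, n_gamma]`:
#' `delta = alpha * n_gamma - (a / c) * (1 - exp(-c * n_gamma))`.
#' Positive values mean the curve spends most of that range below `alpha`.
#'
#' @param model An [fit_exponential()] result.
#' @param config A [decision_config()].
#' @return The area distance, or `NA_real_` when the model has no decay
#'   (`c = 0`).
#' @export
delta_area <- function(model, config = decision_config()) {
  ng <- n_gamma(model, config$gamma)
  if (is.na(ng)) return(NA_real_)
  config$alpha * ng - (model$a / model$c) * (1 - exp(-model$c * ng))
}

#' Is gamma valid for this fitted curve?
#'
#' The convergence threshold is usable only if `gamma <= 0.1`, the curve
#' decays (`c > 0`), and `gamma / c < alpha` — otherwise the "converged"
#' value of `p(n)` at `n_gamma` would exceed the significance level itself
#' and convergence to zero cannot be claimed.
#'
#' @inheritParams delta_area
#' @return Logical.
#' @export
gamma_validity <- function(model, config = decision_config()) {
  config$gamma <= 0.1 && model$c > 0 && config$gamma / model$c < config$alpha
}

#' Binary decision index
#'
#' Classifies a fitted p-value curve as showing practically meaningful
#' differences (`theta = 1`) or not (`theta = 0`).  Rules, in order:
#' \enumerate{
#'   \item `a < alpha`: the curve starts below the significance level, so
#'     `theta = 1` for any `gamma` (path `"a_below_alpha"`).
#'   \item no resolvable convergence — `c` below `gamma / alpha` (including
#'     `c = 0`) or `gamma` invalid for this fit: `theta = 0`
#'     (path `"no_decay"`); this covers the null case of a flat curve with
#'     `a >= alpha`.
#'   \item otherwise `theta = 1` iff `delta_area >= 0` (path `"regular"`).
#' }
#'
#' @inheritParams delta_area
#' @return List with elements `theta` (0 or 1) and `decision_path`.
#' @export
theta_index <- function(model, config = decision_config()) {
  if (model$a < config$alpha)
    return(list(theta = 1L, decision_path = "a_below_alpha"))
  if (model$c < config$gamma / config$alpha || !gamma_validity(model, config))
    return(list(theta = 0L, decision_path = "no_decay"))
  d <- delta_area(model, config)
  list(theta = as.integer(d >= 0), decision_path = "regular")
}

#' Minimum sample size for statistical significance (fitted)
#'
#' Solves `alpha = a exp(-c n_alpha)`.  If `a <= alpha` the curve is
#' significant at any size and `n_alpha = 0`.  If `c = 0` with `a > alpha`
#' the curve never reaches `alpha` and `n_alpha` is infinite.  The integer
#' report uses the floor of the real solution.
#'
#' @param model An [fit_exponential()] result.
#' @param alpha Significance level.
#' @return List with `real` and `int` (both `Inf` when unreachable).
#' @export
n_alpha <- function(model, alpha = 0.05) {
  if (model$a <= alpha) return(list(real = 0, int = 0))
  if (model$c <= 0) return(list(real = Inf, int = Inf))
  nr <- log(model$a / alpha) / model$c
  list(real = nr, int = floor(nr))
}

#' Minimum sample size for statistical significance (empirical)
#'
#' The empirical counterpart of [n_alpha()]: the smallest grid size whose
#' mean p-value minus its standard error falls below `alpha`,
#' `n_alpha_hat = argmin_{n_i} { (p_mean_i - p_sem_i) < alpha }`.
#' Because the SEM correction makes the condition stricter where the mean
#' is estimated precisely, `n_alpha_hat` typically lands slightly above the
#' fitted `n_alpha`.  Returns `Inf` when no grid size qualifies (the data
#' are too small to exhibit significance).
#'
#' @param cloud A [run_mccv()] result (or data frame with columns `n`,
#'   `p`).
#' @param alpha Significance level.
#' @return Smallest qualifying grid size, or `Inf`.
#' @export
n_alpha_hat <- function(cloud, alpha = 0.05) {
  s <- if (inherits(cloud, "pvalue_cloud")) cloud$summaries else
    summarise_cloud(cloud_points(cloud))
  hit <- which(s$p_mean - s$p_sem < alpha)
  if (length(hit) == 0L) Inf else s$n[hit[1]]
}

#' Shannon information of a p-value (S-value)
#'
#' `s = -log2(p)`: the information, in bits, carried by a p-value against
#' the null hypothesis.  A p-value of 0.05 carries about 4.32 bits.
#'
#' @param p p-value(s) in (0, 1]; vectorised.
#' @return Non-negative S-value(s).
#' @export
s_value <- function(p) {
  if (any(p <= 0 | p > 1)) stop("invalid input: p must be in (0, 1]")
  -log2(p)
}

#' Full decision report for one fitted comparison
#'
#' Assembles every decision quantity for one pairwise comparison into a
#' single record: convergence point, area distance, decision index and its
#' path, gamma validity, and the fitted and empirical minimum sizes.
#'
#' @param model An [fit_exponential()] result.
#' @param cloud Optional [run_mccv()] result used for the empirical
#'   minimum size; when omitted `n_alpha_hat` is `NA`.
#' @param config A [decision_config()].
#' @return An object of class `decision_report`: one-row data frame with
#'   columns `a`, `c`, `n_gamma`, `delta`, `theta`, `gamma_valid`,
#'   `n_alpha_real`, `n_alpha_int`, `n_alpha_hat`, `decision_path`.
#' @export
decide <- function(model, cloud = NULL, config = decision_config()) {
  th <- theta_index(model, config)
  na <- n_alpha(model, config$alpha)
  rep <- data.frame(
    a = model$a, c = model$c,
    n_gamma = n_gamma(model, config$gamma),
    delta = delta_area(model, config),
    theta = th$theta,
    gamma_valid = gamma_validity(model, config),
    n_alpha_real = na$real,
    n_alpha_int = na$int,
    n_alpha_hat = if (is.null(cloud)) NA_real_ else
      n_alpha_hat(cloud, config$alpha),
    decision_path = th$decision_path,
    stringsAsFactors = FALSE)
  attr(rep, "config") <- config
  class(rep) <- c("decision_report", "data.frame")
  rep
}

#' @export
print.decision_report <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("decision report (alpha = %g, gamma = %g)\n",
              cfg$alpha, cfg$gamma))
  cat(sprintf("  fit: a = %.4g, c = %.4g\n", x$a, x$c))
  cat(sprintf("  theta = %d (%s), delta = %s, n_gamma = %s\n",
              x$theta, x$decision_path,
              format(x$delta, digits = 4), format(x$n_gamma, digits = 5)))
  cat(sprintf("  n_alpha = %s (fit), n_alpha_hat = %s (empirical)\n",
              format(x$n_alpha_int), format(x$n_alpha_hat)))
  invisible(x)
}
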