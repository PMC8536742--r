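#' Two-sample test p-value
#'
#' Computes the p-value of a two-sample comparison, the elementary operation
#' repeated thousands of times inside the MCCV loop.  The default test is the
#' Mann-Whitney U test, chosen because it is distribution-free and tolerates
#' heteroscedastic groups.
#'
#' For `test = "mann_whitney"` the null distribution of the U statistic is
#' enumerated exactly (via [stats::pwilcox()]) when both samples have at most
#' 8 observations and there are no ties; otherwise the tie-corrected normal
#' approximation is used.  The approximation is applied *without* a
#' continuity correction: under the null the folded one-sided p-value is then
#' uniform on (0, 1/2] in the large-sample limit, with mean 1/4, which is the
#' convention under which the amplitude of a fitted null p-value curve is
#' interpretable (see the package vignette).  `exact = FALSE` forces the
#' asymptotic statistic at every size, the convention used by the
#' simulation-study profile.
#'
#' `tail_mode` selects between the usual two-sided p-value and the *folded*
#' one-sided p-value, i.e. the smaller of the two one-tailed p-values.  The
#' folded convention does not require a prior direction of effect; under the
#' null its expectation is 1/4 instead of 1/2.
#'
#' For `test = "t_test"` Welch's t statistic is used, with the same two
#' tail conventions.  For `test = "chi2"`, `x` and `y` are interpreted as
#' *category labels* (count-category data): the test is Pearson's chi-squared
#' test on the 2 x k contingency table of group by category, and `tail_mode`
#' is ignored because the statistic is inherently one-sided in its upper
#' tail.
#'
#' The returned p-value is clamped to the interval
#' `(.Machine$double.xmin, 1]` so that log-space fitting is always defined.
#'
#' @param x,y Numeric vectors of observations (category labels for
#'   `test = "chi2"`).  Each needs at least 1 finite value (2 for the
#'   t test).
#' @param test One of `"mann_whitney"`, `"t_test"`, `"chi2"`.
#' @param tail_mode `"two_sided"` or `"folded_one_sided"`.
#' @param exact For the Mann-Whitney test: `NULL` (default) applies the
#'   small-sample rule above, `TRUE` forces exact enumeration (falling back
#'   to the approximation when ties are present), `FALSE` forces the
#'   asymptotic statistic.
#' @return A single p-value in `(0, 1]`.
#' @examples
#' two_sample_p(c(1, 2), c(3, 4))                       # exact: 1/3
#' two_sample_p(c(1, 2), c(3, 4), tail_mode = "folded_one_sided")  # 1/6
#' @export
two_sample_p <- function(x, y,
                         test = c("mann_whitney", "t_test", "chi2"),
                         tail_mode = c("two_sided", "folded_one_sided"),
                         exact = NULL) {
  test <- match.arg(test)
  tail_mode <- match.arg(tail_mode)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 1L || length(y) < 1L)
    stop("invalid input: both samples need at least one finite value")
  p <- switch(test,
    mann_whitney = mw_p(x, y, tail_mode, exact),
    t_test = t_p(x, y, tail_mode),
    chi2 = chi2_p(x, y))
  min(max(p, .Machine$double.xmin), 1)
}

# Mann-Whitney U p-value from one joint ranking; both tails in one pass.
# U is the statistic for x (number of (x, y) pairs with x > y, ties = 1/2).
mw_p <- function(x, y, tail_mode, exact = NULL) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  tie_tab <- tabulate(match(r, unique(r)))
  has_ties <- any(tie_tab > 1L)
  if (is.null(exact)) exact <- nx <= 8L && ny <= 8L && !has_ties
  if (exact && !has_ties) {
    p_less <- pwilcox(U, nx, ny)
    p_greater <- pwilcox(U - 1, nx, ny, lower.tail = FALSE)
  } else {
    N <- nx + ny
    sigma2 <- (nx * ny / 12) *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)  # complete ties: no evidence either way
    z <- (U - nx * ny / 2) / sqrt(sigma2)
    p_less <- pnorm(z)
    p_greater <- pnorm(z, lower.tail = FALSE)
  }
  fold_tails(p_less, p_greater, tail_mode)
}

t_p <- function(x, y, tail_mode) {
  if (length(x) < 2L || length(y) < 2L)
    stop("invalid input: t test needs at least two values per group")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0)
    stop("degenerate variance: all values identical in both groups")
  se2 <- vx / length(x) + vy / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                 vy^2 / (length(y)^2 * (length(y) - 1)))
  fold_tails(pt(tstat, df), pt(tstat, df, lower.tail = FALSE), tail_mode)
}

chi2_p <- function(x, y) {
  lev <- sort(unique(c(x, y)))
  tab <- rbind(tabulate(match(x, lev), length(lev)),
               tabulate(match(y, lev), length(lev)))
  if (ncol(tab) < 2L) return(1)  # a single shared category carries no signal
  suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
}

fold_tails <- function(p_less, p_greater, tail_mode) {
  if (tail_mode == "folded_one_sided") min(p_less, p_greater)
  else min(1, 2 * min(p_less, p_greater))
}
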