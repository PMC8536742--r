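#' Specification of a simulated normal population
#'
#' @param mu Mean.
#' @param sigma Standard deviation, > 0.
#' @param size Number of observations to generate, >= 2.
#' @return An object of class `normal_spec`.
#' @export
normal_spec <- function(mu = 0, sigma = 1, size = 50000L) {
  stopifnot(is.finite(mu), sigma > 0, size >= 2)
  structure(list(mu = mu, sigma = sigma, size = as.integer(size)),
            class = "normal_spec")
}

#' Draw a seeded pair of normal observation groups
#'
#' @param spec_a,spec_b [normal_spec()] objects.
#' @param seed Integer seed; the same seed always reproduces the same pair.
#' @return List of two [observation_group()]s labelled
#'   `"N(mu,sigma)"`.
#' @export
simulate_pair <- function(spec_a, spec_b, seed = 1L) {
  lab <- function(s) sprintf("N(%g,%g)", s$mu, s$sigma)
  with_seed(seed, {
    a <- observation_group(lab(spec_a),
                           rnorm(spec_a$size, spec_a$mu, spec_a$sigma))
    b <- observation_group(lab(spec_b),
                           rnorm(spec_b$size, spec_b$mu, spec_b$sigma))
    list(a = a, b = b)
  })
}

#' Simulation study: N(0,1) against shifted normal distributions
#'
#' Replicates the validation design of the method: for each `mu` the
#' standard normal `N(0,1)` is compared with `N(mu,1)` through the full
#' pipeline — MCCV subsampling, exponential fit, decision calculus — and
#' one summary row is produced per comparison.
#'
#' The study profile deliberately mirrors the conditions under which the
#' decision calculus is calibrated: folded one-sided Mann-Whitney p-values
#' computed with the asymptotic (tie-corrected, uncorrected-for-continuity)
#' statistic at every size, a log-spaced grid of ~30 sizes on
#' `[2, min(2500, n_per_group)]` with repetitions decreasing from 500 to
#' 20, and a linear-space exponential fit on all cloud points.
#'
#' @param mus Numeric vector of mean shifts (one comparison per value).
#' @param n_per_group Observations generated per group (default 50,000).
#' @param config A [decision_config()].
#' @param grid Optional [sample_grid()]; defaults to
#'   [default_grid()] capped at `n_per_group`.
#' @param tail_mode,test,exact,fit_space Pipeline options; defaults are the
#'   study profile above.
#' @param seed Master seed; per-comparison seeds are derived from it, so
#'   single rows can be reproduced in isolation.
#' @return An object of class `study_result`: data frame with one row per
#'   `mu` (ordered by `mu`) carrying the comparison label, fitted `a` and
#'   `c`, decision quantities, and the per-row seed.
#' @examples
#' \donttest{
#' run_study(c(0, 1), n_per_group = 2000, seed = 7)
#' }
#' @export
run_study <- function(mus, n_per_group = 50000L,
                      config = decision_config(),
                      grid = NULL,
                      tail_mode = "folded_one_sided",
                      test = "mann_whitney",
                      exact = FALSE,
                      fit_space = "linear",
                      seed = 1L) {
  mus <- sort(mus)
  if (is.null(grid)) grid <- default_grid(n_per_group)
  if (max(grid$size) > n_per_group)
    stop("invalid grid: largest size exceeds n_per_group")
  seeds <- derive_seeds(seed, length(mus))
  rows <- lapply(seq_along(mus), function(i) {
    rep_i <- study_row(mus[i], n_per_group, config, grid, tail_mode, test,
                       exact, fit_space, seeds[i])
    rep_i
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "grid") <- grid
  class(out) <- c("study_result", "data.frame")
  out
}

study_row <- function(mu, n_per_group, config, grid, tail_mode, test,
                      exact, fit_space, seed) {
  pair <- simulate_pair(normal_spec(0, 1, n_per_group),
                        normal_spec(mu, 1, n_per_group), seed)
  cloud <- run_mccv(pair$a, pair$b, grid, test = test,
                    tail_mode = tail_mode, seed = seed, exact = exact)
  model <- fit_exponential(cloud, fit_space)
  rep <- decide(model, cloud, config)
  cbind(data.frame(comparison = sprintf("N(0,1) vs N(%g,1)", mu), mu = mu),
        as.data.frame(rep), data.frame(seed = seed))
}

#' Reliability protocol: robustness rate of the decision index
#'
#' Repeats the simulation study with fresh random samples (and optionally
#' reduced MCCV budgets) and reports, per comparison and budget, the
#' percentage of repeats whose decision index agrees with the full-budget
#' reference run.  100% means the decision is fully reproducible under
#' resampling at that budget.
#'
#' @param mus Mean shifts to test.
#' @param repeats Number of repeated runs per budget (>= 2).
#' @param budgets Named list of [sample_grid()]s; the first is used only
#'   for comparison runs, the reference decision always comes from a run
#'   with `full_grid`.
#' @param full_grid Grid of the reference run (default [default_grid()]
#'   capped at `n_per_group`).
#' @param n_per_group,config,tail_mode,test,exact,fit_space As in
#'   [run_study()].
#' @param seed Master seed; the reference uses it directly, repeats use
#'   derived fresh seeds.
#' @return An object of class `robustness_report`: data frame with one row
#'   per (mu, budget): reference theta, repeats, `agreement_rate` in
#'   percent, and a budget descriptor.
#' @export
robustness_rate <- function(mus, repeats = 10L,
                            budgets = NULL,
                            full_grid = NULL,
                            n_per_group = 50000L,
                            config = decision_config(),
                            tail_mode = "folded_one_sided",
                            test = "mann_whitney",
                            exact = FALSE,
                            fit_space = "linear",
                            seed = 1L) {
  stopifnot(repeats >= 2)
  if (is.null(full_grid)) full_grid <- default_grid(n_per_group)
  if (is.null(budgets)) budgets <- list(full = full_grid)
  if (is.null(names(budgets)) || any(!nzchar(names(budgets))))
    names(budgets) <- paste0("budget", seq_along(budgets))
  ref <- run_study(mus, n_per_group, config, full_grid, tail_mode, test,
                   exact, fit_space, seed)
  rep_seeds <- derive_seeds(seed + 1L, repeats)
  rows <- list()
  for (b in names(budgets)) {
    theta_mat <- vapply(rep_seeds, function(s) {
      run_study(mus, n_per_group, config, budgets[[b]], tail_mode, test,
                exact, fit_space, s)$theta
    }, numeric(length(mus)))
    theta_mat <- matrix(theta_mat, nrow = length(mus))
    for (i in seq_along(ref$mu)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mu = ref$mu[i],
        budget = b,
        budget_sizes = nrow(budgets[[b]]),
        budget_draws = sum(budgets[[b]]$reps),
        theta_ref = ref$theta[i],
        repeats = repeats,
        agreement_rate = 100 * mean(theta_mat[i, ] == ref$theta[i]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_report", "data.frame")
  out
}
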