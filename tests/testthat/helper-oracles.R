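# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Brute-force Mann-Whitney: enumerate every assignment of the pooled ranks
# to group x, giving the exact null distribution of U, then read off both
# one-sided tail probabilities of the observed U.
enumerate_mw <- function(x, y, tail_mode = "two_sided") {
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  p_less <- mean(u_all <= u_obs)
  p_greater <- mean(u_all >= u_obs)
  if (tail_mode == "folded_one_sided") min(p_less, p_greater)
  else min(1, 2 * min(p_less, p_greater))
}

# Quadrature oracle for the area distance: integrate alpha - a exp(-c n)
# over [0, n_gamma] numerically.
quadrature_delta <- function(a, cc, alpha, gamma) {
  ng <- max(0, log(a * cc / gamma) / cc)
  stats::integrate(function(n) alpha - a * exp(-cc * n), 0, ng,
                   rel.tol = 1e-12)$value
}

# Brute scan oracle for the convergence point: first n (step 0.01) at which
# the slope magnitude of a exp(-c n) falls below gamma.
scan_n_gamma <- function(a, cc, gamma, step = 0.01, n_max = 1e5) {
  n <- seq(0, n_max, by = step)
  slope <- a * cc * exp(-cc * n)
  hit <- which(slope < gamma)
  if (length(hit) == 0L) NA_real_ else n[hit[1]]
}

# Bisection oracle for the size at which a exp(-c n) crosses alpha.
bisect_n_alpha <- function(a, cc, alpha, hi = 1e7) {
  f <- function(n) a * exp(-cc * n) - alpha
  stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}

# Cloud generated exactly from the model (optionally with multiplicative
# log-normal noise), several points per size.
model_cloud <- function(a, cc, sizes, reps = 3, log_sd = 0) {
  n <- rep(sizes, each = reps)
  noise <- if (log_sd > 0) exp(rnorm(length(n), 0, log_sd)) else 1
  data.frame(n = n, p = pmin(a * exp(-cc * n) * noise, 1))
}
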