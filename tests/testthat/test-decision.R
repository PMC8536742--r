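test_that("convergence point matches its closed form and brute-force scan", {
  m <- list(a = 0.286, c = 0.042)
  ng <- n_gamma(m, 5e-6)
  expect_equal(ng, 185.34, tolerance = 1e-4)
  expect_lt(abs(ng - scan_n_gamma(0.286, 0.042, 5e-6)), 0.011)
  # already converged at n = 0 when the initial slope is below gamma
  expect_equal(n_gamma(list(a = 0.5, c = 0.5), 0.5), 0)
  # a flat curve has no convergence point
  expect_true(is.na(n_gamma(list(a = 0.5, c = 0), 0.01)))
  # scan agreement across a parameter sweep
  for (a in c(0.1, 0.3, 0.9)) for (cc in c(0.005, 0.05, 0.5)) {
    expect_lt(abs(n_gamma(list(a = a, c = cc), 1e-5) -
                  scan_n_gamma(a, cc, 1e-5)), 0.011)
  }
})

test_that("area distance agrees with numerical quadrature", {
  cfg <- decision_config(0.05, 5e-6)
  d <- delta_area(list(a = 0.286, c = 0.042), cfg)
  expect_equal(d, 2.46, tolerance = 1e-2)
  expect_equal(d, quadrature_delta(0.286, 0.042, 0.05, 5e-6),
               tolerance = 1e-10)
  # the published borderline case, recomputed from its printed parameters
  d2 <- delta_area(list(a = 0.263, c = 0.010), decision_config(0.05, 5e-5))
  expect_equal(d2, quadrature_delta(0.263, 0.010, 0.05, 5e-5),
               tolerance = 1e-10)
  expect_equal(d2, -5.99, tolerance = 1e-2)
  # near the c -> 0 limit with a = alpha the distance vanishes
  expect_equal(delta_area(list(a = 0.05, c = 1e-9), cfg), 0,
               tolerance = 1e-4)
})

test_that("gamma validity implements the slope constraint", {
  expect_true(gamma_validity(list(a = .3, c = 0.042),
                             decision_config(0.05, 5e-6)))
  expect_false(gamma_validity(list(a = .3, c = 0.0001),
                              decision_config(0.05, 0.1)))
  expect_false(gamma_validity(list(a = .3, c = 0), decision_config()))
})

test_that("decision index follows the rule precedence", {
  cfg <- decision_config(0.05, 5e-6)
  # amplitude already below alpha: meaningful for any gamma
  th <- theta_index(list(a = 0.03, c = 0), cfg)
  expect_equal(th$theta, 1L)
  expect_equal(th$decision_path, "a_below_alpha")
  # flat curve at a >= alpha: the null route
  th0 <- theta_index(list(a = 0.256, c = 0), cfg)
  expect_equal(th0$theta, 0L)
  expect_equal(th0$decision_path, "no_decay")
  # published borderline comparison: positive area distance
  th1 <- theta_index(list(a = 0.263, c = 0.010), cfg)
  expect_equal(th1$theta, 1L)
  expect_equal(th1$decision_path, "regular")
  # regular path follows the sign of delta
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1, 0.06, 1)
    cc <- runif(1, 2 * cfg$gamma / cfg$alpha, 0.5)
    m <- list(a = a, c = cc)
    th <- theta_index(m, cfg)
    expect_equal(th$decision_path, "regular")
    expect_equal(th$theta, as.integer(delta_area(m, cfg) >= 0))
  }
})

test_that("delta and theta are monotone in the decay rate near the boundary", {
  # delta(c) is monotone below its peak, the regime containing the sign
  # change that theta responds to; past the peak it decays towards 0+
  cfg <- decision_config(0.05, 5e-6)
  cs <- seq(0.002, 0.016, length.out = 30)
  ds <- sapply(cs, function(cc) delta_area(list(a = 0.3, c = cc), cfg))
  ths <- sapply(cs, function(cc) theta_index(list(a = 0.3, c = cc), cfg)$theta)
  expect_true(all(diff(ds) > -1e-9))
  expect_true(all(diff(ths) >= 0))
})

test_that("fitted minimum size solves p(n) = alpha, floor convention", {
  na <- n_alpha(list(a = 0.313, c = 0.152), 0.05)
  expect_equal(na$real, 12.07, tolerance = 1e-3)
  expect_equal(na$int, 12)
  expect_equal(n_alpha(list(a = 0.04, c = 0.1))$real, 0)
  expect_equal(n_alpha(list(a = 0.04, c = 0.1))$int, 0)
  expect_equal(n_alpha(list(a = 0.5, c = 0.1))$real, log(10) / 0.1,
               tolerance = 1e-10)
  expect_equal(n_alpha(list(a = 0.5, c = 0.1))$real,
               bisect_n_alpha(0.5, 0.1, 0.05), tolerance = 1e-6)
  expect_true(is.infinite(n_alpha(list(a = 0.3, c = 0))$real))
  # self-consistency: the curve evaluated at n_alpha gives exactly alpha
  set.seed(42)
  for (i in 1:20) {
    m <- list(a = runif(1, 0.06, 1), c = runif(1, 1e-4, 1))
    nr <- n_alpha(m, 0.05)$real
    expect_equal(evaluate_model(m, nr), 0.05, tolerance = 1e-10)
  }
  # strictly decreasing in c for fixed a > alpha
  nas <- sapply(seq(0.01, 1, length.out = 25),
                function(cc) n_alpha(list(a = 0.4, c = cc))$real)
  expect_true(all(diff(nas) < 0))
})

test_that("empirical minimum size applies the mean-minus-SEM rule", {
  # construct a cloud whose per-size summaries are known exactly:
  # n=10: mean .30 sem .05 | n=20: mean .10 sem .05 | n=30: mean .06 sem .03
  mk <- function(mean, sem) mean + c(-1, 1) * sem  # two values; sd/sqrt(2) = sem
  cl <- data.frame(n = rep(c(10, 20, 30), each = 2),
                   p = c(mk(0.30, 0.05), mk(0.10, 0.05), mk(0.06, 0.03)))
  expect_equal(n_alpha_hat(cl, 0.05), 30)
  # 20 is excluded because 0.10 - 0.05 is not strictly below alpha
  expect_equal(n_alpha_hat(cl, 0.051), 20)
  # nothing qualifies
  flat <- data.frame(n = rep(c(5, 10), each = 3), p = 0.4)
  expect_true(is.infinite(n_alpha_hat(flat, 0.05)))
})

test_that("S-values convert p-values to bits of information", {
  expect_equal(s_value(1), 0)
  expect_equal(s_value(0.25), 2)
  expect_equal(s_value(0.05), 4.3219, tolerance = 1e-4)
  expect_error(s_value(0), "invalid input")
  expect_error(s_value(1.2), "invalid input")
  p <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(s_value(p)) < 0))
})

test_that("decide() assembles a coherent report", {
  cl <- model_cloud(0.3, 0.05, seq(5, 400, by = 5), reps = 3)
  m <- fit_exponential(cl, "linear")
  rep <- decide(m, cl)
  expect_s3_class(rep, "decision_report")
  expect_equal(rep$theta, 1L)
  expect_equal(rep$decision_path, "regular")
  expect_true(rep$gamma_valid)
  expect_equal(rep$n_alpha_int, floor(rep$n_alpha_real))
  expect_gte(rep$n_alpha_hat, rep$n_alpha_int)
  # no-decay route for a flat cloud
  flat <- data.frame(n = rep(c(10, 100, 1000), each = 3), p = 0.3)
  mf <- fit_exponential(flat, "linear")
  rf <- decide(mf, flat)
  expect_equal(rf$theta, 0L)
  expect_equal(rf$decision_path, "no_decay")
  expect_true(is.na(rf$delta))
})
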