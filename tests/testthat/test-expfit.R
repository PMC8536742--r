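test_that("noiseless model clouds are recovered exactly in both spaces", {
  cl <- model_cloud(0.5, 0.01, 1:500)
  for (space in c("log", "linear")) {
    m <- fit_exponential(cl, space)
    expect_equal(m$a, 0.5, tolerance = 1e-6)
    expect_equal(m$c, 0.01, tolerance = 1e-6)
    expect_equal(m$n_points, nrow(cl))
  }
  # the two spaces agree on clean data
  ml <- fit_exponential(cl, "log")
  mn <- fit_exponential(cl, "linear")
  expect_equal(ml$a, mn$a, tolerance = 1e-6)
  expect_equal(ml$c, mn$c, tolerance = 1e-6)
})

test_that("constant clouds give a flat model", {
  cl <- data.frame(n = rep(c(10, 50, 100), each = 4), p = 0.3)
  for (space in c("log", "linear")) {
    m <- fit_exponential(cl, space)
    expect_equal(m$a, 0.3, tolerance = 1e-9)
    expect_equal(m$c, 0, tolerance = 1e-9)
  }
})

test_that("parameter bounds hold under pathological inputs", {
  # increasing p-values: the decay bound c >= 0 must bind
  up <- data.frame(n = 1:50, p = pmin(1, 0.2 * exp(0.02 * (1:50))))
  # p-values hugging 1: amplitude bound a <= 1 must bind
  hi <- data.frame(n = rep(1:20, 2), p = rep(c(1, 0.999), each = 20))
  for (space in c("log", "linear")) {
    for (cl in list(up, hi)) {
      m <- fit_exponential(cl, space)
      expect_gt(m$a, 0)
      expect_lte(m$a, 1)
      expect_gte(m$c, 0)
    }
  }
})

test_that("log-space fit bias vanishes as multiplicative noise shrinks", {
  set.seed(31)
  err <- sapply(c(0.2, 0.02), function(sdlog) {
    reps <- replicate(20, {
      cl <- model_cloud(0.4, 0.02, seq(5, 400, by = 5), reps = 2,
                        log_sd = sdlog)
      m <- fit_exponential(cl, "log")
      c(m$a - 0.4, m$c - 0.02)
    })
    rowMeans(abs(reps))
  })
  expect_lt(err[1, 2], err[1, 1])  # amplitude bias shrinks with noise
  expect_lt(err[2, 2], err[2, 1])  # decay bias shrinks with noise
})

test_that("linear-space fit agrees with independent nonlinear least squares", {
  skip_if_not_installed("minpack.lm")
  set.seed(32)
  cl <- model_cloud(0.35, 0.015, seq(2, 300, by = 6), reps = 4, log_sd = 0.3)
  m <- fit_exponential(cl, "linear")
  ref <- minpack.lm::nlsLM(p ~ a * exp(-cc * n), data = cl,
                           start = list(a = 0.35, cc = 0.015),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  expect_equal(m$a, coef(ref)[["a"]], tolerance = 1e-4)
  expect_equal(m$c, coef(ref)[["cc"]], tolerance = 1e-3)
})

test_that("underdetermined clouds are rejected", {
  expect_error(fit_exponential(data.frame(n = c(5, 5, 5), p = c(.1, .2, .3))),
               "underdetermined")
  expect_error(fit_exponential(data.frame(n = c(5, 6), p = c(.1, .2))),
               "underdetermined")
})

test_that("evaluate_model reproduces the closed form", {
  m <- list(a = 0.5, c = 0.1)
  expect_equal(evaluate_model(m, 0), 0.5)
  expect_equal(evaluate_model(m, 23.0259), 0.05, tolerance = 1e-4)
  expect_equal(evaluate_model(list(a = 1, c = 0), c(0, 10, 1e6)), rep(1, 3))
})

test_that("LOWESS mean curve tracks constant and decaying signals", {
  flat <- data.frame(n = rep(seq(10, 100, by = 10), each = 3), p = 0.4)
  sc <- lowess_mean_curve(flat)
  expect_equal(sc$value, rep(0.4, 10), tolerance = 1e-9)

  set.seed(33)
  sizes <- seq(10, 500, by = 10)
  noisy <- data.frame(
    n = rep(sizes, each = 5),
    p = pmin(1, 0.5 * exp(-0.01 * rep(sizes, each = 5)) *
               exp(rnorm(5 * length(sizes), 0, 0.05))))
  sc2 <- lowess_mean_curve(noisy, bandwidth = 0.3)
  interior <- sc2$n > 50 & sc2$n < 450
  expect_lt(max(abs(sc2$value - 0.5 * exp(-0.01 * sc2$n))[interior]), 0.02)
  # smoothing preserves monotone decay away from the ends
  expect_true(all(diff(sc2$value[interior]) <= 1e-6))

  expect_error(lowess_mean_curve(data.frame(n = rep(1:3, 2), p = 0.1)),
               "4 distinct")
})

test_that("derivative ratio is the constant -c for an exponential curve", {
  sizes <- seq(10, 500, by = 10)
  curve <- structure(data.frame(n = sizes, value = 0.5 * exp(-0.01 * sizes)),
                     class = c("smoothed_curve", "data.frame"))
  dr <- derivative_ratio(curve)
  expect_equal(nrow(dr), length(sizes))
  expect_lt(max(abs(dr$ratio + 0.01)), 1e-3)

  const <- data.frame(n = sizes, value = rep(0.4, length(sizes)))
  expect_equal(derivative_ratio(const)$ratio, rep(0, length(sizes)))

  withzero <- data.frame(n = 1:5, value = c(0.5, 0.4, 0, 0.2, 0.1))
  expect_message(dr2 <- derivative_ratio(withzero), "skipped 1")
  expect_equal(nrow(dr2), 4)
})
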