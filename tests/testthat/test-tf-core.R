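test_that("kernel evaluation matches an independent log-gamma oracle", {
  p <- standard_tf()
  # oracle: gamma density from first principles via lgamma
  gamma_pdf <- function(t, shape, rate) {
    exp(shape * log(rate) + (shape - 1) * log(t) - rate * t - lgamma(shape))
  }
  t <- 0.87
  expect_equal(evaluate_tf(p, t),
               p$p4 * gamma_pdf(t - p$p3, p$p1, p$p2),
               tolerance = 1e-10)
  # zero at and before the time shift
  expect_equal(evaluate_tf(p, c(0, 0.1, p$p3)), c(0, 0, 0))
})

test_that("the standard kernel peaks at 0.9 s on a 1 ms grid", {
  grid <- seq(0, 10, by = 0.001)
  vals <- evaluate_tf(standard_tf(), grid)
  expect_equal(round(grid[which.max(vals)], 1), 0.9)
})

test_that("closed-form peak time agrees with grid argmax for random kernels", {
  set.seed(11)
  for (i in 1:100) {
    p <- tf_params(runif(1, 1.05, 6), runif(1, 0.2, 5), runif(1, 0, 2),
                   runif(1, 0.01, 2))
    pk <- tf_peak_time(p)
    grid <- seq(max(0, pk - 2), pk + 2, by = 0.001)
    expect_lt(abs(grid[which.max(evaluate_tf(p, grid))] - pk), 0.0011)
  }
  expect_equal(tf_peak_time(tf_params(2, 1, 0, 1)), 1)
  # the time shift translates the peak
  expect_equal(tf_peak_time(tf_params(1.3, 0.5, 0.27, 1)) -
                 tf_peak_time(tf_params(1.3, 0.5, 0.001, 1)), 0.269)
  expect_error(tf_peak_time(tf_params(0.9, 1, 0, 1)), "undefined")
})

test_that("kernel integral equals the amplitude parameter", {
  set.seed(12)
  for (i in 1:20) {
    p <- tf_params(runif(1, 1.05, 6), runif(1, 0.2, 5), runif(1, 0, 2),
                   runif(1, 0.01, 2))
    q <- stats::integrate(function(t) evaluate_tf(p, t),
                          p$p3, p$p3 + 40 / p$p2, rel.tol = 1e-10)
    expect_equal(q$value, p$p4, tolerance = 1e-6)
  }
})

test_that("parameter validation rejects invalid kernels", {
  expect_error(tf_params(-1, 1, 0, 1), "positive")
  expect_error(tf_params(1, -1, 0, 1), "positive")
  expect_error(tf_params(1, 1, -0.1, 1), ">= 0")
  expect_true(check_validity(standard_tf()))
  expect_false(check_validity(tf_params(0.9, 1, 0.1, 1)))  # diverges at onset
  expect_false(check_validity(tf_params(1.0, 1, 0.1, 1)))  # jumps to p2*p4
})

test_that("a discrete impulse reproduces the kernel", {
  p <- standard_tf()
  dt <- 0.01
  imp <- uniform_series(rep(0, 1000), 0, dt)
  imp$value[201] <- 1 / dt  # impulse at t = 2 s
  pred <- convolve_predict(imp, p)
  # each output sample is the kernel's average over one bin, i.e. the
  # midpoint value up to O(dt^2)
  expected <- evaluate_tf(p, pred$time - 2 - dt / 2)
  expect_lt(max(abs(pred$value - expected)), 0.03 * max(expected))
})

test_that("zero input predicts zero; empty input errors", {
  z <- uniform_series(rep(0, 100), 0, 0.05)
  expect_true(all(convolve_predict(z, standard_tf())$value == 0))
  expect_error(convolve_predict(tibble::tibble(time = numeric(), value = numeric()),
                                standard_tf()))
})

test_that("unit-step response matches the incomplete-gamma closed form", {
  p <- standard_tf()
  dt <- 0.05
  s0 <- 5
  step <- uniform_series(rep(0, 601), 0, dt)
  step$value[step$time >= s0 - 1e-9] <- 1
  pred <- convolve_predict(step, p)
  closed <- ifelse(pred$time > s0 + p$p3,
                   p$p4 * stats::pgamma(pred$time - s0 - p$p3, p$p1, rate = p$p2),
                   0)
  expect_lt(max(abs(pred$value - closed)), 0.01 * max(abs(closed)))
})

test_that("convolution is linear and causal", {
  set.seed(13)
  p <- standard_tf()
  x <- uniform_series(rnorm(200), 0, 0.05)
  y <- uniform_series(rnorm(200), 0, 0.05)
  combo <- x; combo$value <- 2 * x$value - 3 * y$value
  lhs <- convolve_predict(combo, p)$value
  rhs <- 2 * convolve_predict(x, p)$value - 3 * convolve_predict(y, p)$value
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # perturbing a late sample leaves earlier outputs unchanged
  xp <- x; xp$value[150] <- xp$value[150] + 100
  before <- convolve_predict(x, p)$value[1:149]
  after <- convolve_predict(xp, p)$value[1:149]
  expect_equal(before, after, tolerance = 1e-12)
})

test_that("prediction can be resampled onto a coarser To grid", {
  tr <- noiseless_trial(seed = 5)
  to_grid <- seq(5, 27, by = 0.2)
  pred <- convolve_predict(tr$from, standard_tf(), to_grid)
  expect_equal(pred$time, to_grid)
  full <- convolve_predict(tr$from, standard_tf())
  idx <- round((to_grid - full$time[1]) / 0.05) + 1
  expect_equal(pred$value, full$value[idx], tolerance = 1e-9)
})

test_that("amplitude rescale matches the closed-form least-squares factor", {
  tr <- noiseless_trial(seed = 6)
  pred <- convolve_predict(tr$from, standard_tf(), tr$to)
  obs <- pred
  obs$value <- 2 * obs$value
  out <- rescale_amplitude(pred, obs, stimulus_onset = 10)
  expect_equal(attr(out, "scale"), 2, tolerance = 1e-6)
  # oracle: k = sum(p*o)/sum(p^2) on the window
  w <- pred$time >= 12 & pred$time <= 18
  k_closed <- sum(pred$value[w] * obs$value[w]) / sum(pred$value[w]^2)
  expect_equal(attr(out, "scale"), k_closed, tolerance = 1e-6)
  # identity case
  expect_equal(attr(rescale_amplitude(pred, pred, 10), "scale"), 1,
               tolerance = 1e-6)
  zero <- pred; zero$value <- 0
  expect_error(rescale_amplitude(zero, obs, 10), "identically zero")
})

test_that("rescaling leaves the Pearson coefficient untouched", {
  set.seed(14)
  tr <- noiseless_trial(seed = 7)
  pred <- convolve_predict(tr$from, standard_tf(), tr$to)
  obs <- tr$to
  obs$value <- obs$value + rnorm(nrow(obs), sd = 0.02 * max(obs$value))
  r_before <- pearson(pred, obs)
  scaled <- rescale_amplitude(pred, obs, 10)
  expect_gt(attr(scaled, "scale"), 0)
  expect_equal(pearson(scaled, obs), r_before, tolerance = 1e-12)
})

test_that("pearson follows the product-moment definition", {
  a <- uniform_series(c(1, 2, 3, 4), 0, 1)
  b <- uniform_series(c(1, 3, 2, 4), 0, 1)
  expect_equal(pearson(a, b), 0.8)
  expect_equal(pearson(a, a), 1)
  neg <- a; neg$value <- -a$value
  expect_equal(pearson(a, neg), -1)
  # invariance under positive affine maps
  shifted <- a; shifted$value <- 3 * a$value + 7
  expect_equal(pearson(shifted, b), pearson(a, b), tolerance = 1e-12)
  const <- uniform_series(rep(1, 4), 0, 1)
  expect_error(pearson(a, const), "zero-variance")
})

test_that("sum of squared residuals matches a brute-force loop", {
  set.seed(15)
  a <- uniform_series(rnorm(30), 0, 0.1)
  b <- uniform_series(rnorm(30), 0, 0.1)
  brute <- 0
  for (i in 1:30) brute <- brute + (a$value[i] - b$value[i])^2
  expect_equal(sum_squared_residuals(a, b), brute, tolerance = 1e-12)
  expect_equal(sum_squared_residuals(a, a), 0)
  c2 <- a; c2$value <- a$value + 0.5
  expect_equal(sum_squared_residuals(a, c2), 30 * 0.25, tolerance = 1e-12)
  mism <- uniform_series(rnorm(30), 1, 0.1)
  expect_error(sum_squared_residuals(a, mism), "grids")
})
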