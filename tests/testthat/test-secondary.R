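test_that("the residual vanishes when the standard kernel explains everything", {
  tr <- noiseless_trial(seed = 1)
  res <- residual_component(tr$to, tr$from, standard_tf(), stimulus_onset = 10)
  expect_lt(max(abs(res$value)), 1e-6 * max(abs(tr$to$value)))
})

test_that("the residual isolates a delayed bump at its true position", {
  tr <- noiseless_trial(seed = 2, acquisition_len = 60)
  bumped <- tr$to
  bump <- 0.05 * exp(-(bumped$time - 27)^2 / 8)
  bumped$value <- bumped$value + bump
  res <- residual_component(bumped, tr$from, standard_tf(), stimulus_onset = 10)
  late <- res$time > 20
  expect_lt(abs(res$time[late][which.max(res$value[late])] - 27), 1)
  # the optional early mask zeroes the onset-mismatch band
  masked <- residual_component(bumped, tr$from, standard_tf(), 10,
                               mask_early = c(5, 15))
  expect_true(all(masked$value[masked$time >= 5 & masked$time <= 15] == 0))
})

test_that("the residual of pure noise is centred on zero", {
  tr <- noiseless_trial(seed = 3)
  set.seed(33)
  means <- replicate(20, {
    noisy <- tr$to
    noisy$value <- noisy$value + rnorm(nrow(noisy), sd = 0.1 * max(noisy$value))
    mean(residual_component(noisy, tr$from, standard_tf(), 10)$value)
  })
  expect_lt(abs(mean(means)), 0.01 * max(tr$to$value))
})

test_that("a known delayed secondary kernel is recovered from the residual", {
  cfg <- sim_config(acquisition_len = 60, noise_sd_from = 0, noise_sd_to = 0,
                    secondary_tf = delayed_tf(), secondary_ratio = 0.4)
  tr <- simulate_trial(cfg, seed = 4)
  fw <- cut_fit_window(tr$from, 60)
  tw <- cut_fit_window(tr$to, 60)
  res <- residual_component(tw, fw, standard_tf(), 10)
  fit2 <- fit_secondary(fw, res,
                        fit_config(upper = c(20, 20, 20, 20),
                                   runs_per_iteration = 10,
                                   max_iterations = 2, n_moves = 400,
                                   seed = 11))
  expect_lt(abs(tf_peak_time(fit2$params) - tf_peak_time(delayed_tf())), 2)
  expect_gt(fit2$pearson, 0.99)
})

test_that("fitting a near-zero residual collapses the secondary amplitude", {
  tr <- noiseless_trial(seed = 5)
  res <- residual_component(tr$to, tr$from, standard_tf(), 10)
  fit2 <- fit_secondary(tr$from, res,
                        fit_config(upper = c(20, 20, 20, 20),
                                   runs_per_iteration = 3,
                                   max_iterations = 1, n_moves = 200,
                                   seed = 12))
  pred <- convolve_predict(tr$from, fit2$params, res)
  expect_lt(max(abs(pred$value)), 0.01 * max(abs(tr$to$value)))
})

test_that("combined prediction recovers the generating amplitudes", {
  cfg <- sim_config(acquisition_len = 60, noise_sd_from = 0, noise_sd_to = 0,
                    secondary_tf = delayed_tf(), secondary_ratio = 0.4)
  tr <- simulate_trial(cfg, seed = 6)
  fw <- cut_fit_window(tr$from, 60)
  tw <- cut_fit_window(tr$to, 60)
  two <- two_component_tf(standard_tf(), delayed_tf())
  comb <- combined_predict(fw, two, tw, observed = tw)
  a <- attr(comb, "amplitudes")
  expect_equal(a[1], 1, tolerance = 0.1)
  expect_equal(a[2], 0.4, tolerance = 0.1 * 0.4 + 0.02)
  expect_gt(pearson(comb, tw), 0.99)
})

test_that("combined prediction is linear and symmetric in its components", {
  tr <- noiseless_trial(seed = 7)
  two <- two_component_tf(standard_tf(), delayed_tf(), amplitudes = c(1.2, 0.3))
  swapped <- two_component_tf(delayed_tf(), standard_tf(), amplitudes = c(0.3, 1.2))
  c1 <- combined_predict(tr$from, two, tr$to)
  c2 <- combined_predict(tr$from, swapped, tr$to)
  expect_equal(c1$value, c2$value, tolerance = 1e-12)
  # a2 = 0 reduces to the primary prediction
  only1 <- two_component_tf(standard_tf(), delayed_tf(), amplitudes = c(1, 0))
  expect_equal(combined_predict(tr$from, only1, tr$to)$value,
               convolve_predict(tr$from, standard_tf(), tr$to)$value,
               tolerance = 1e-12)
  # linearity in the amplitudes
  double <- two_component_tf(standard_tf(), delayed_tf(), amplitudes = c(2.4, 0.6))
  expect_equal(combined_predict(tr$from, double, tr$to)$value, 2 * c1$value,
               tolerance = 1e-12)
})

test_that("two-component prediction beats the single kernel on bimodal data", {
  cfg <- sim_config(acquisition_len = 60, noise_sd_from = 0, noise_sd_to = 0.02,
                    secondary_tf = delayed_tf(), secondary_ratio = 0.3)
  tr <- simulate_trial(cfg, seed = 8)
  fw <- cut_fit_window(tr$from, 60)
  tw <- cut_fit_window(tr$to, 60)
  single <- rescale_amplitude(convolve_predict(fw, standard_tf(), tw), tw, 10)
  two <- two_component_tf(standard_tf(), delayed_tf())
  comb <- combined_predict(fw, two, tw, observed = tw)
  expect_gt(pearson(comb, tw), pearson(single, tw))
  # no systematic late structure left in the combined residual
  late <- tw$time >= 15
  resid_late <- tw$value[late] - comb$value[late]
  expect_lt(abs(mean(resid_late)), 3 * 0.02 * max(tw$value))
})

test_that("nonnegativity is enforced on the combined amplitudes", {
  tr <- noiseless_trial(seed = 9)
  two <- two_component_tf(standard_tf(), delayed_tf())
  p1 <- convolve_predict(tr$from, standard_tf(), tr$to)
  p2 <- convolve_predict(tr$from, delayed_tf(), tr$to)
  anti <- tr$to
  anti$value <- p1$value - 0.2 * p2$value  # negative true weight on TF2
  comb <- combined_predict(tr$from, two, tr$to, observed = anti)
  a <- attr(comb, "amplitudes")
  expect_equal(a[2], 0)
  expect_gt(a[1], 0)
  # a fully anti-correlated observation leaves no nonnegative combination
  flipped <- tr$to
  flipped$value <- -p1$value
  expect_error(combined_predict(tr$from, two, tr$to, observed = flipped),
               "degenerate")
  expect_error(two_component_tf(standard_tf(), delayed_tf(), c(-1, 1)),
               "nonnegative")
})
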