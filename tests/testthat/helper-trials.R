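# Shared fixtures for the test suite: the standard calcium-to-RBC-velocity
# kernel and small, fast fit configurations. All data are generated in code.

standard_tf <- function() tf_params(1.3, 0.5, 0.27, 0.19)

# delayed kernel peaking at (3 - 1)/0.15 + 12 = 25.33 s
delayed_tf <- function() tf_params(3, 0.15, 12, 0.19)

# a fast fit protocol for unit tests (not the full 50-run acceptance one)
quick_config <- function(seed, runs = 6, iters = 2, moves = 300, ...) {
  fit_config(runs_per_iteration = runs, max_iterations = iters,
             n_moves = moves, seed = seed, ...)
}

# noiseless single-trial fixture, window-cut
noiseless_trial <- function(seed = 1, acquisition_len = 30, ...) {
  cfg <- sim_config(noise_sd_from = 0, noise_sd_to = 0,
                    acquisition_len = acquisition_len, seed = seed, ...)
  tr <- simulate_trial(cfg, seed = seed)
  list(from = cut_fit_window(tr$from, acquisition_len),
       to = cut_fit_window(tr$to, acquisition_len),
       full = tr, config = cfg)
}

expect_series_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$time, b$time, tolerance = tol)
  expect_equal(a$value, b$value, tolerance = tol)
}
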