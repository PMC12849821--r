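test_that("stimulus sequences are uniform draws on [low, high)", {
  set.seed(1)
  x <- make_stimulus_sequence(1000, 0, 180)
  expect_true(all(x >= 0 & x < 180))
  set.seed(2); a <- make_stimulus_sequence(100, 0, 180)
  set.seed(2); b <- make_stimulus_sequence(100, 0, 180)
  expect_identical(a, b)
  set.seed(3)
  big <- make_stimulus_sequence(1e5, 0, 180)
  expect_lt(abs(mean(big) - 90), 3 * (180 / sqrt(12)) / sqrt(1e5))
  expect_error(make_stimulus_sequence(0), ">= 1")
})

test_that("generator configs are validated", {
  expect_error(generator_config("delta_rs", dog_params(1, 0.05)),
               "params_2back")
  expect_error(generator_config("delta_s", dog_params(1, 0.05),
                                params_2back = dog_params(1, 0.05)),
               "delta_rs")
  expect_error(generator_config("delta_s", dog_params(1, 0.05),
                                n_trials = 1), ">= 2")
  expect_error(generator_config("delta_s", dog_params(1, 0.05),
                                noise_sd = -1), ">= 0")
})

test_that("simulated series honour the recursion and the seed", {
  cfg <- generator_config("delta_r", dog_params(0, 0.05), n_trials = 200,
                          noise_sd = 0, seed = 4)
  s <- simulate_series(cfg)
  expect_equal(s$response, s$stimulus)   # zero amplitude: pass-through
  expect_equal(s$error, rep(0, 200))

  cfg2 <- generator_config("delta_rs", dog_params(5, 0.04),
                           params_2back = dog_params(5, 0.04),
                           n_trials = 300, seed = 9)
  s1 <- simulate_series(cfg2)
  s2 <- simulate_series(cfg2)
  expect_identical(s1$response, s2$response)
  expect_equal(s1$error, s1$response - s1$stimulus)
})

test_that("with no feedback the errors keep the noise distribution", {
  cfg <- generator_config("delta_s", dog_params(0, 0.05),
                          n_trials = 1e5, noise_sd = 1, seed = 6)
  s <- simulate_series(cfg)
  expect_lt(abs(sd(s$error) - 1), 0.03)
  expect_lt(abs(mean(s$error)), 0.02)
})

test_that("impulse responses reproduce the reported values", {
  p <- dog_params(4.8, 0.03)
  expect_equal(round(impulse_response("delta_s", p, 4), 2),
               c(0.66, 0.34, 0.00, 0.00))
  expect_equal(round(impulse_response("delta_r", p, 4), 2),
               c(0.66, 0.22, 0.07, 0.03))
  expect_equal(impulse_response("delta_s", dog_params(0, 0.05), 4),
               c(1, 0, 0, 0))
  expect_error(impulse_response("delta_rs", p, 4), "delta_s and delta_r")
})

test_that("stimulus feedback dies after one step; response feedback decays slowly", {
  for (a in c(0.25, 1, 5)) for (w in c(0.01, 0.05, 0.1)) {
    ys <- impulse_response("delta_s", dog_params(a, w), 8)
    expect_equal(ys[3:8], rep(0, 6))
  }
  ## the response-feedback tail is positive and strictly decreasing
  ## wherever the feedback slope a*w*c stays below 1 (no overshoot)
  for (a in c(0.25, 1, 5)) for (w in c(0.01, 0.03)) {
    yr <- impulse_response("delta_r", dog_params(a, w), 8)
    expect_true(all(yr[-1] > 0))
    expect_true(all(diff(yr[-1]) < 0))
  }
  ## at fixed step the response-feedback tail grows with a
  tails <- sapply(c(1, 2, 5), function(a)
    impulse_response("delta_r", dog_params(a, 0.03), 4)[3])
  expect_true(all(diff(tails) > 0))
})

test_that("response feedback induces slowly decaying error autocorrelation", {
  cfg <- generator_config("delta_r", dog_params(5, 0.01),
                          n_trials = 1e5, noise_sd = 1, seed = 8)
  e <- simulate_series(cfg)$error
  ac <- acf(e, lag.max = 5, plot = FALSE)$acf[-1]
  ## the 1-back response feedback leaves strong serial structure whose
  ## magnitude decays with lag but persists beyond one trial
  expect_gt(abs(ac[1]), 10 / sqrt(1e5))
  expect_gt(abs(ac[1]), abs(ac[3]))
  expect_gt(abs(ac[2]), abs(ac[5]))
  ## a stimulus-feedback generator leaves none beyond lag 1
  cfg_s <- generator_config("delta_s", dog_params(5, 0.01),
                            n_trials = 1e5, noise_sd = 1, seed = 8)
  ac_s <- acf(simulate_series(cfg_s)$error, lag.max = 3,
              plot = FALSE)$acf[-1]
  expect_lt(abs(ac_s[3]), 4 / sqrt(1e5))
})

test_that("series CSV round-trips with its configuration", {
  cfg <- generator_config("delta_r", dog_params(2, 0.05), n_trials = 50,
                          seed = 10)
  s <- simulate_series(cfg)
  path <- file.path(tempdir(), "series.csv")
  write_series_csv(s, path)
  s2 <- read_series_csv(path)
  for (col in c("stimulus", "response", "error"))
    expect_equal(s2[[col]], s[[col]], tolerance = 1e-10)
  cfg2 <- attr(s2, "config")
  expect_equal(cfg2$seed, 10L)
  expect_equal(simulate_series(cfg2)$response, s$response,
               tolerance = 1e-12)
  file.remove(path, paste0(path, ".json"))
})
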