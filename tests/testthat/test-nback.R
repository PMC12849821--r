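test_that("n-back designs pair lagged predictors with current errors", {
  s <- noiseless_series(n = 5)
  d <- nback_design(s, 1, "stimulus")
  expect_equal(sum(d$valid), 4)
  expect_equal(d$delta[-1], s$stimulus[1:4] - s$stimulus[2:5])

  toy <- structure(data.frame(trial = 1:2, stimulus = c(10, 30),
                              response = c(10, 30), error = c(0, 0)),
                   class = c("trial_series", "data.frame"))
  expect_equal(nback_design(toy, 1, "stimulus")$delta[2], -20)

  toy2 <- structure(data.frame(trial = 1:2, stimulus = c(170, 10),
                               response = c(170, 10), error = c(0, 0)),
                    class = c("trial_series", "data.frame"))
  expect_equal(nback_design(toy2, 1, "stimulus", wrap = TRUE)$delta[2],
               -20)                      # 160 wrapped into (-90, 90]

  expect_error(nback_design(s, 5, "stimulus"), "smaller than")
  expect_error(nback_design(s, 2, "response"), "lag 1 only")
})

test_that("at fixed w the fitted amplitude is the closed-form least-squares slope", {
  set.seed(20)
  delta <- runif(500, -180, 180)
  y <- dog(delta, dog_params(3, 0.03)) + rnorm(500)
  f <- fit_dog(list(delta = delta, outcome = y),
               w_bounds = c(0.03, 0.03))
  z <- dog_norm_const() * 0.03 * delta * exp(-(0.03 * delta)^2)
  expect_equal(f$a_hat, sum(z * y) / sum(z * z), tolerance = 1e-8)
  expect_equal(f$a_hat, unname(coef(lm(y ~ z - 1))), tolerance = 1e-8)
  expect_equal(f$w_hat, 0.03)
})

test_that("noiseless generative parameters are recovered exactly", {
  for (pars in list(c(4.8, 0.03), c(2, 0.05), c(0.5, 0.08))) {
    s <- simulate_series(generator_config(
      "delta_s", dog_params(pars[1], pars[2]), n_trials = 800,
      noise_sd = 0, seed = 21))
    f <- fit_dog(nback_design(s, 1, "stimulus"))
    expect_equal(f$a_hat, pars[1], tolerance = 1e-3)
    expect_equal(f$w_hat, pars[2], tolerance = 1e-3)
    expect_lt(max(abs(f$residuals)), 1e-4)
    expect_true(f$converged)
    expect_true(f$ci_a[1] <= f$a_hat && f$a_hat <= f$ci_a[2])
    expect_true(f$ci_w[1] <= f$w_hat && f$w_hat <= f$ci_w[2])
  }
})

test_that("fit agrees with an independent bounded Levenberg-Marquardt fit", {
  skip_if_not_installed("minpack.lm")
  s <- simulate_series(generator_config(
    "delta_s", dog_params(4.8, 0.03), n_trials = 1000, noise_sd = 0.5,
    seed = 22))
  d <- nback_design(s, 1, "stimulus")
  f <- fit_dog(d)
  keep <- d$valid
  delta <- d$delta[keep]; y <- d$outcome[keep]; c0 <- dog_norm_const()
  g <- minpack.lm::nlsLM(y ~ a * c0 * w * delta * exp(-(w * delta)^2),
                         start = list(a = 1, w = 0.05),
                         lower = c(-Inf, 0), upper = c(Inf, 1))
  expect_equal(f$a_hat, unname(coef(g)[["a"]]), tolerance = 1e-5)
  expect_equal(f$w_hat, unname(coef(g)[["w"]]), tolerance = 1e-5)
  expect_equal(f$se_a, summary(g)$coefficients["a", "Std. Error"],
               tolerance = 1e-4)
})

test_that("degenerate and invalid designs raise errors", {
  expect_error(fit_dog(list(delta = rep(1, 50), outcome = rnorm(50))),
               "degenerate")
  expect_error(fit_dog(list(delta = 1:5, outcome = rnorm(5))),
               "at least 10")
})

test_that("significance follows the attraction rule by default", {
  f <- structure(list(ci_a = c(0.2, 1.5)), class = "dog_fit")
  expect_true(is_significant(f))
  f$ci_a <- c(-1.5, -0.2)
  expect_false(is_significant(f))
  expect_true(is_significant(f, sign = "two_sided"))
  f$ci_a <- c(-0.2, 0.9)
  expect_false(is_significant(f, sign = "two_sided"))
  f$ci_a <- c(-Inf, Inf)                 # non-converged fit
  expect_false(is_significant(f))
})

test_that("the two-stage correction residualizes the 1-back response effect", {
  s <- simulate_series(generator_config(
    "delta_r", dog_params(5, 0.01), n_trials = 1000, seed = 23))
  cf <- corrected_fit(s, 2)
  expect_equal(cf$stage1$a_hat, 5, tolerance = 0.2)
  ## stage 1 must explain variance: residual variance below raw variance
  expect_lt(var(cf$stage1$residuals), var(s$error[-1]))
  expect_equal(cf$stage2$n_used, 998)

  ## an error-free series yields zero residuals and a zero stage-2 amplitude
  s0 <- simulate_series(generator_config(
    "delta_s", dog_params(0, 0.05), n_trials = 100, noise_sd = 0,
    seed = 24))
  cf0 <- corrected_fit(s0, 2)
  expect_equal(max(abs(cf0$stage1$residuals)), 0)
  expect_equal(cf0$stage2$a_hat, 0)
})

test_that("fit serializes to JSON", {
  s <- noiseless_series(n = 100)
  f <- fit_dog(nback_design(s, 1, "stimulus"))
  path <- file.path(tempdir(), "fit.json")
  write_fit_json(f, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$a, f$a_hat)
  expect_equal(j$ci_a, f$ci_a)
  file.remove(path)
})
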