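test_that("angle differences wrap into (-90, 90]", {
  expect_equal(wrap_deg(160), -20)
  expect_equal(wrap_deg(-90), 90)
  expect_equal(wrap_deg(45), 45)
  set.seed(1)
  x <- runif(1000, -1000, 1000)
  w <- wrap_deg(x)
  expect_true(all(w > -90 & w <= 90))
  expect_equal(sin(pi * x / 90), sin(pi * w / 90), tolerance = 1e-9)
})

test_that("trial tables validate their inputs row by row", {
  df <- data.frame(subject = "S1", block = 1, trial = 1:3,
                   stimulus = c(10, 20, 30), response = c(12, 18, 33))
  tab <- as_trial_table(df)
  expect_s3_class(tab, "trial_table")
  expect_equal(tab$error, c(2, -2, 3))
  expect_true(all(tab$usable))
  expect_error(as_trial_table(df[, -4]), "missing column")
  df2 <- df; df2$stimulus[2] <- 200
  expect_error(as_trial_table(df2), "row 2")
  df3 <- df; df3$response <- c("a", "b", "c")
  expect_error(as_trial_table(df3), "response")
})

test_that("polynomial debiasing removes stimulus-dependent bias", {
  ## cubic bias is inside the degree-9 space: residuals vanish
  tab <- toy_table(n = 200, err_fn = function(x)
    1e-4 * (x - 90)^3 / 50 + 0.5)
  de <- debias_errors(tab)
  expect_lt(max(abs(de$error)), 1e-8)

  ## constant offset: residual mean zero
  tab2 <- toy_table(n = 100, err_fn = function(x) rep(3.7, length(x)))
  expect_lt(abs(mean(debias_errors(tab2)$error)), 1e-10)

  ## planted degree-9 polynomial + noise: residual sd matches the noise
  set.seed(31)
  coefs <- rnorm(10)
  tab3 <- toy_table(n = 4000, seed = 32, err_fn = function(x) {
    s <- (x - 90) / 90
    drop(outer(s, 0:9, `^`) %*% coefs) + rnorm(length(x), 0, 2)
  })
  expect_equal(sd(debias_errors(tab3)$error), 2, tolerance = 0.05)

  expect_error(debias_errors(toy_table(n = 8)), "degree-9")
})

test_that("outliers and their followers are flagged, blockwise", {
  tab <- toy_table(n = 50, err_fn = function(x) rnorm(length(x)))
  tab$error[10] <- 40                    # single outlier
  out <- flag_outliers(tab)
  expect_equal(which(!out$usable), c(10, 11))
  expect_equal(which(!out$pred_ok), c(10, 11))

  ## outlier at the last trial of a block: no follower to remove
  tab2 <- toy_table(n = 50, blocks = 2, err_fn = function(x)
    rnorm(length(x)))
  tab2$error[50] <- -40
  out2 <- flag_outliers(tab2)
  expect_equal(which(!out2$usable), 50)

  ## two planted outliers in different blocks: exactly four removals
  tab3 <- toy_table(n = 50, blocks = 2, err_fn = function(x)
    rnorm(length(x)))
  tab3$error[c(5, 70)] <- c(35, -35)
  out3 <- flag_outliers(tab3)
  expect_equal(which(!out3$usable), c(5, 6, 70, 71))

  ## flagging is idempotent
  expect_identical(flag_outliers(out3)$usable, out3$usable)
})

test_that("the 3-sd rule removes about 0.54% of clean Gaussian trials", {
  tab <- toy_table(n = 2000, blocks = 10, seed = 33,
                   err_fn = function(x) rnorm(length(x)))
  out <- flag_outliers(tab)
  rate <- mean(!out$usable)
  expected <- 2 * 2 * pnorm(-3)          # outliers + followers
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(rate - expected), 4 * se + 1e-4)
})

test_that("block starts are trimmed as outcomes only", {
  tab <- toy_table(n = 100, blocks = 3, err_fn = function(x)
    rnorm(length(x)))
  tr <- trim_block_starts(tab, 2)
  expect_equal(sum(!tr$usable), 6)
  expect_true(all(tr$pred_ok))           # still usable as predictors
  expect_equal(which(!tr$usable), c(1, 2, 101, 102, 201, 202))
  tr1 <- trim_block_starts(toy_table(n = 30), 1)
  expect_equal(which(!tr1$usable), 1)
  expect_error(trim_block_starts(toy_table(n = 5), 5), "shortest block")

  ## masks from different rules union
  both <- trim_block_starts(flag_outliers(tab), 2)
  expect_true(all(!both$usable[c(1, 2)]))
})

test_that("the preprocessing pipeline is idempotent on the usable mask", {
  tab <- generate_cohort(cohort_config(n_subjects = 2, n_blocks = 4,
                                       trials_per_block = 100,
                                       outlier_rate = 0.01, seed = 34))
  once <- preprocess(tab)
  twice <- trim_block_starts(flag_outliers(debias_errors(once)))
  expect_identical(once$usable, twice$usable)
  expect_equal(nrow(once), nrow(tab))
  rep <- attr(once, "report")
  expect_equal(sum(rep$usable) + sum(rep$outlier_and_follower) +
                 sum(rep$block_start), nrow(tab))
  path <- file.path(tempdir(), "report.json")
  write_preprocess_report(once, path)
  expect_true(file.exists(path))
  file.remove(path)
})
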