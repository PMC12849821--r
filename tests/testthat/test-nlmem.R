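test_that("the modelling frame honours masks and block boundaries", {
  tab <- generate_cohort(cohort_config(n_subjects = 2, n_blocks = 2,
                                       trials_per_block = 50, seed = 41))
  fr1 <- serialdep:::build_nlmem_frame(tab, "response_1back")
  ## one trial lost per block (no 1-back predecessor)
  expect_equal(nrow(fr1), 2 * 2 * 49)
  fr2 <- serialdep:::build_nlmem_frame(tab, "stimulus_nback", lag = 2)
  expect_equal(nrow(fr2), 2 * 2 * 48)
  expect_true(all(abs(fr2$delta) <= 90))  # wrapped by default

  ## a trial flagged as outlier cannot serve as lagged predictor
  tab$pred_ok[5] <- FALSE
  fr3 <- serialdep:::build_nlmem_frame(tab, "response_1back")
  expect_false(6 %in% fr3$row)
  expect_true(5 %in% fr3$row)            # trial 5 itself is still usable
})

test_that("a single-subject model reduces to intercept-augmented NLS", {
  tab <- generate_cohort(cohort_config(n_subjects = 1, sigma_nu = 0,
                                       sigma_psi = 0, n_blocks = 4,
                                       trials_per_block = 200,
                                       sigma_eps = 3, seed = 42))
  f <- fit_dog_nlmem(tab, "response_1back")
  expect_equal(f$n_subjects, 1L)
  expect_equal(f$sigma_nu, 0)
  fr <- serialdep:::build_nlmem_frame(tab, "response_1back")
  g <- fit_dog(list(delta = fr$delta, outcome = fr$y), intercept = TRUE)
  expect_equal(f$a0, g$a_hat, tolerance = 1e-3)
  expect_equal(f$w, g$w_hat, tolerance = 1e-3)
  expect_equal(f$b0, g$b_hat, tolerance = 1e-3)
})

test_that("the mixed model recovers cohort-level parameters", {
  tab <- generate_cohort(cohort_config(seed = 43))
  f <- fit_dog_nlmem(tab, "response_1back")
  expect_true(f$converged)
  expect_equal(f$n_subjects, 4L)
  expect_lt(abs(f$a0 - 2), 0.75)
  expect_lt(abs(f$w - 0.05), 0.03)
  expect_lt(abs(f$sigma_eps - 5), 0.5)
  expect_equal(nrow(f$subject_effects), 4)
  expect_equal(length(f$residuals), f$n_obs)
  ## per-subject amplitudes scatter around the group value
  expect_lt(max(abs(f$subject_effects$a_i - f$a0)), 3)
})

test_that("an error-free table yields zero amplitudes throughout", {
  tab <- generate_cohort(cohort_config(a0 = 0, b0 = 0, sigma_nu = 0,
                                       sigma_psi = 0, sigma_eps = 0,
                                       n_blocks = 2,
                                       trials_per_block = 60,
                                       seed = 44))
  expect_equal(max(abs(tab$error)), 0)
  ts <- two_stage_nlmem(tab, lag = 2)
  expect_equal(ts$stage1$a0, 0)
  expect_equal(ts$stage2$a0, 0)
  expect_equal(ts$reference$a0, 0)
})

test_that("two-stage residualization reduces variance and aligns outcomes", {
  tab <- preprocess(generate_cohort(cohort_config(seed = 45)))
  ts <- two_stage_nlmem(tab, lag = 2)
  fr <- serialdep:::build_nlmem_frame(tab, "response_1back")
  expect_lt(var(ts$stage1$residuals), var(fr$y))
  ## stage 2 outcomes are stage-1 residuals on the shared rows
  expect_true(all(ts$stage2$rows %in% ts$stage1$rows))
})

test_that("permutation p-values follow the strict-exceedance rule", {
  nulls <- c(-0.5, 0.1, 0.4, 0.9, 1.4)
  expect_equal(perm_pvalue(2, nulls), 0)       # larger than every null
  expect_equal(perm_pvalue(-1, nulls), 1)      # smaller than every null
  expect_equal(perm_pvalue(0.4, nulls), 2 / 5) # strict inequality
  expect_equal(perm_pvalue(0.4, nulls, plus_one = TRUE), 3 / 6)
})

test_that("shuffling errors within subject destroys the 1-back structure", {
  tab <- generate_cohort(cohort_config(a0 = 3, n_blocks = 6,
                                       trials_per_block = 100,
                                       seed = 46))
  set.seed(47)
  for (rows in split(seq_len(nrow(tab)), tab$subject))
    tab$error[rows] <- sample(tab$error[rows])
  tab$response <- tab$stimulus + tab$error
  f <- fit_dog_nlmem(tab, "response_1back")
  expect_true(f$ci_a0[1] <= 0 && 0 <= f$ci_a0[2])
})

test_that("the permutation test runs end to end on a small cohort", {
  tab <- preprocess(generate_cohort(cohort_config(
    n_subjects = 2, n_blocks = 3, trials_per_block = 80, seed = 48)))
  pr <- permutation_test(tab, lag = 2, B = 4, seed = 49)
  expect_lte(pr$B, 4)
  expect_true(pr$p_value >= 0 && pr$p_value <= 1)
  expect_equal(pr$observed_diff,
               pr$observed_fit$reference$a0 - pr$observed_fit$stage2$a0)
  pr2 <- permutation_test(tab, lag = 2, B = 4, seed = 49)
  expect_equal(pr$null_diffs, pr2$null_diffs)
})
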