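## Build the per-trial modelling frame for the mixed-effects fits:
## outcome, predictor difference and subject, honouring the usable /
## pred_ok masks and block boundaries.
build_nlmem_frame <- function(table, predictor = c("response_1back",
                                                   "stimulus_nback"),
                              lag = 2L, outcome = NULL, wrap = TRUE) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(table, "trial_table"))
  if (is.null(outcome)) outcome <- table$error
  if (length(outcome) != nrow(table))
    stop("'outcome' must have one value per table row", call. = FALSE)
  pred_ok <- if (is.null(table$pred_ok)) rep(TRUE, nrow(table))
             else table$pred_ok
  lag <- if (predictor == "response_1back") 1L else as.integer(lag)
  if (lag < 1) stop("'lag' must be >= 1", call. = FALSE)

  delta <- rep(NA_real_, nrow(table))
  blocks <- split(seq_len(nrow(table)), list(table$subject, table$block),
                  drop = TRUE)
  for (rows in blocks) {
    if (length(rows) <= lag) next
    cur <- rows[(lag + 1L):length(rows)]
    prev <- rows[seq_len(length(rows) - lag)]
    src <- if (predictor == "response_1back") table$response[prev]
           else table$stimulus[prev]
    d <- src - table$stimulus[cur]
    d[!pred_ok[prev]] <- NA_real_
    delta[cur] <- d
  }
  if (wrap) delta <- wrap_deg(delta)
  ok <- table$usable & !is.na(delta) & is.finite(outcome)
  data.frame(row = which(ok),
             subject = factor(table$subject[ok]),
             delta = delta[ok], y = outcome[ok])
}

.nlmem_from_nls <- function(frame, spec_out, start, alpha) {
  ## single-subject degenerate path: fixed-effects NLS with intercept
  f <- fit_dog(list(delta = frame$delta, outcome = frame$y),
               start = c(a = start[["a0"]], w = start[["w"]]),
               alpha = alpha, intercept = TRUE)
  structure(c(list(a0 = f$a_hat, b0 = f$b_hat, w = f$w_hat,
                   ci_a0 = f$ci_a, se_a0 = f$se_a,
                   sigma_nu = 0, sigma_psi = 0, sigma_eps = f$sigma,
                   subject_effects = data.frame(
                     subject = levels(frame$subject)[1],
                     a_i = f$a_hat, b_i = f$b_hat),
                   residuals = f$residuals, rows = frame$row[f$keep],
                   converged = f$converged, boundary = f$boundary,
                   n_obs = f$n_used, n_subjects = 1L, alpha = alpha),
              spec_out),
            class = "dog_nlmem")
}

#' Fit a DoG nonlinear mixed-effects model
#'
#' Fits `y_ij = b_i + dog(delta_ij; a_i, w) + eps_ij` with per-subject
#' Gaussian random deviations on the amplitude (`a_i = a0 + nu_i`) and
#' the intercept (`b_i = b0 + psi_i`), uncorrelated, and a single inverse
#' width `w` shared across subjects and constrained to `(0, 1)` through a
#' logistic reparameterization. Estimation delegates to [nlme::nlme()]
#' (Lindstrom-Bates first-order conditional estimation; restricted
#' maximum likelihood by default). With one subject the model reduces to
#' fixed-effects nonlinear least squares with an intercept.
#'
#' @param table A `"trial_table"` (preprocessed for empirical data).
#' @param predictor `"response_1back"` (`y[n-1] - x[n]`) or
#'   `"stimulus_nback"` (`x[n-lag] - x[n]`).
#' @param lag Lag of the stimulus predictor (ignored for
#'   `"response_1back"`). Default 2.
#' @param outcome Optional per-row outcome vector replacing the error
#'   column (e.g., stage-1 residuals); rows with `NA` are excluded.
#' @param start Named starting values `c(a0 = 2, w = 0.05)`.
#' @param max_iter Maximum optimizer iterations. Default 200.
#' @param tol Convergence tolerance. Default 1e-4.
#' @param method `"REML"` or `"ML"`.
#' @param wrap Wrap predictor differences into `(-90, 90]`? Default
#'   `TRUE` (orientation is circular).
#' @param alpha CI level is `1 - alpha`.
#' @return An object of class `"dog_nlmem"` with elements `a0`, `b0`,
#'   `w`, `ci_a0`, `se_a0`, `sigma_nu`, `sigma_psi`, `sigma_eps`,
#'   `subject_effects`, `residuals` (conditional, aligned with `rows`),
#'   `converged`, `boundary` and bookkeeping fields.
#' @export
fit_dog_nlmem <- function(table,
                          predictor = c("response_1back",
                                        "stimulus_nback"),
                          lag = 2L, outcome = NULL,
                          start = c(a0 = 2, w = 0.05),
                          max_iter = 200L, tol = 1e-4,
                          method = c("REML", "ML"), wrap = TRUE,
                          alpha = 0.05) {
  predictor <- match.arg(predictor)
  method <- match.arg(method)
  frame <- build_nlmem_frame(table, predictor, lag, outcome, wrap)
  if (nrow(frame) < 10L)
    stop("fewer than 10 valid trials for the mixed-effects fit",
         call. = FALSE)
  spec_out <- list(predictor = predictor, lag = lag, method = method)

  if (stats::var(frame$y) == 0) {        # degenerate: constant outcome
    b <- frame$y[1L]
    return(structure(c(list(
      a0 = 0, b0 = b, w = start[["w"]], ci_a0 = c(0, 0), se_a0 = 0,
      sigma_nu = 0, sigma_psi = 0, sigma_eps = 0,
      subject_effects = data.frame(subject = levels(frame$subject),
                                   a_i = 0, b_i = b),
      residuals = rep(0, nrow(frame)), rows = frame$row,
      converged = TRUE, boundary = TRUE, n_obs = nrow(frame),
      n_subjects = nlevels(frame$subject), alpha = alpha,
      df_a0 = max(nlevels(frame$subject) - 1L, 1L)), spec_out),
      class = "dog_nlmem"))
  }

  if (nlevels(frame$subject) < 2L)
    return(.nlmem_from_nls(frame, spec_out, start, alpha))

  ## The normalization constant is inlined (nlme resolves every formula
  ## symbol against the data), and w = plogis(tw) keeps w in (0, 1).
  model <- stats::as.formula(sprintf(
    "y ~ b + a * %.17g * delta * (1/(1+exp(-tw))) * exp(-((1/(1+exp(-tw))) * delta)^2)",
    dog_norm_const()))
  ctrl <- nlme::nlmeControl(maxIter = max_iter, tolerance = tol,
                            msMaxIter = max(max_iter, 100L),
                            pnlsMaxIter = 25L, returnObject = FALSE)
  tw0 <- stats::qlogis(min(max(start[["w"]], 1e-4), 0.999))
  try_nlme <- function(st, method, ctrl) {
    clean <- TRUE
    fit <- tryCatch(
      withCallingHandlers(
        nlme::nlme(model, fixed = a + b + tw ~ 1,
                   random = nlme::pdDiag(a + b ~ 1), groups = ~subject,
                   data = frame, start = st, method = method,
                   control = ctrl),
        warning = function(w) {
          if (grepl("without convergence", conditionMessage(w)))
            clean <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) NULL else list(fit = fit, clean = clean)
  }
  starts <- list(c(a = start[["a0"]], b = 0, tw = tw0),
                 c(a = 0.5, b = 0, tw = tw0),
                 c(a = start[["a0"]], b = 0, tw = stats::qlogis(0.02)),
                 c(a = start[["a0"]], b = 0, tw = stats::qlogis(0.1)))
  res <- NULL
  for (st in starts) {
    res <- try_nlme(st, method, ctrl)
    if (!is.null(res)) break
  }
  if (is.null(res))                      # objective fallback
    res <- try_nlme(starts[[1L]],
                    if (method == "REML") "ML" else "REML", ctrl)
  if (is.null(res)) {
    ctrl$returnObject <- TRUE
    res <- try_nlme(starts[[1L]], method, ctrl)
    if (!is.null(res)) res$clean <- FALSE
  }
  if (is.null(res)) {
    ## last resort: pooled fixed-effects fit, flagged as non-converged
    out <- .nlmem_from_nls(frame, spec_out, start, alpha)
    out$converged <- FALSE
    out$n_subjects <- nlevels(frame$subject)
    return(out)
  }
  fit <- res$fit
  converged <- res$clean

  fe <- nlme::fixef(fit)
  w_hat <- stats::plogis(fe[["tw"]])
  se_a0 <- sqrt(fit$varFix["a", "a"])
  ## Between-subject df for the amplitude: its subject-level loadings
  ## vary (random slope), so the effective sample size for a0 is the
  ## number of subjects. The large residual df of the naive Wald
  ## interval is anticonservative for cohorts of a few subjects, where
  ## the amplitude variance component is often pinned at zero.
  df_a0 <- nlevels(frame$subject) - 1L
  ci <- fe[["a"]] + c(-1, 1) * stats::qt(1 - alpha / 2, df_a0) * se_a0
  vc <- suppressWarnings(nlme::VarCorr(fit))
  sigma_nu <- suppressWarnings(as.numeric(vc["a", "StdDev"]))
  sigma_psi <- suppressWarnings(as.numeric(vc["b", "StdDev"]))
  ce <- stats::coef(fit)
  res <- as.numeric(stats::resid(fit))

  structure(c(list(a0 = unname(fe[["a"]]), b0 = unname(fe[["b"]]),
                   w = unname(w_hat), ci_a0 = ci, se_a0 = unname(se_a0),
                   sigma_nu = sigma_nu, sigma_psi = sigma_psi,
                   sigma_eps = fit$sigma,
                   subject_effects = data.frame(
                     subject = rownames(ce), a_i = ce$a, b_i = ce$b),
                   residuals = res, rows = frame$row,
                   converged = converged,
                   boundary = sigma_nu < 1e-8 || sigma_psi < 1e-8,
                   n_obs = nrow(frame),
                   n_subjects = nlevels(frame$subject), alpha = alpha,
                   df_a0 = df_a0, fit = fit),
              spec_out),
            class = "dog_nlmem")
}

#' @export
print.dog_nlmem <- function(x, ...) {
  cat("DoG nonlinear mixed-effects fit\n")
  cat(sprintf("  predictor: %s%s, %d trials, %d subject(s)\n",
              x$predictor,
              if (x$predictor == "stimulus_nback")
                sprintf(" (lag %d)", x$lag) else "",
              x$n_obs, x$n_subjects))
  cat(sprintf("  a0 = %.4f  [%.4f, %.4f]  (%.0f%% CI)\n",
              x$a0, x$ci_a0[1], x$ci_a0[2], 100 * (1 - x$alpha)))
  cat(sprintf("  b0 = %.4f, w = %.4f\n", x$b0, x$w))
  cat(sprintf("  sd(amplitude RE) = %.4f, sd(intercept RE) = %.4f, residual sd = %.4f\n",
              x$sigma_nu, x$sigma_psi, x$sigma_eps))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
coef.dog_nlmem <- function(object, ...)
  c(a0 = object$a0, b0 = object$b0, w = object$w)

#' @export
confint.dog_nlmem <- function(object, parm = "a0", level = NULL, ...) {
  m <- rbind(a0 = object$ci_a0)
  colnames(m) <- c("lower", "upper")
  m
}

#' @export
residuals.dog_nlmem <- function(object, ...) object$residuals

#' @export
predict.dog_nlmem <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) stop("'newdata' with a 'delta' element required",
                                  call. = FALSE)
       else if (is.list(newdata)) newdata$delta else newdata
  object$b0 + dog(d, dog_params(object$a0, object$w))
}

#' @export
summary.dog_nlmem <- function(object, ...) {
  print(object)
  if (!is.null(object$subject_effects)) {
    cat("  per-subject effects:\n")
    print(object$subject_effects, row.names = FALSE)
  }
  invisible(object)
}

#' Two-stage corrected mixed-effects analysis of an n-back effect
#'
#' The containment analysis for empirical cohorts: stage 1 fits the
#' 1-back relative response onto the errors; stage 2 fits the lag-`N`
#' relative stimulus onto stage 1's conditional residuals. A reference
#' model fits the lag-`N` stimulus directly onto the raw errors. The
#' amplitude `a0` of each model indexes the association strength; the
#' n-back effect is called significant when `a0`'s CI excludes zero.
#'
#' @inheritParams fit_dog_nlmem
#' @param ... Passed on to [fit_dog_nlmem()] for all three fits.
#' @return An object of class `"two_stage_nlmem"`: list with `stage1`,
#'   `stage2` and `reference` (`"dog_nlmem"` each).
#' @export
two_stage_nlmem <- function(table, lag = 2L, wrap = TRUE, ...) {
  stage1 <- fit_dog_nlmem(table, "response_1back", wrap = wrap, ...)
  r_full <- rep(NA_real_, nrow(table))
  r_full[stage1$rows] <- stage1$residuals
  stage2 <- fit_dog_nlmem(table, "stimulus_nback", lag = lag,
                          outcome = r_full, wrap = wrap, ...)
  reference <- fit_dog_nlmem(table, "stimulus_nback", lag = lag,
                             wrap = wrap, ...)
  structure(list(stage1 = stage1, stage2 = stage2,
                 reference = reference, lag = lag),
            class = "two_stage_nlmem")
}

#' @export
print.two_stage_nlmem <- function(x, ...) {
  cat(sprintf("Two-stage corrected %d-back mixed-effects analysis\n",
              x$lag))
  cat(sprintf("  reference  (raw %d-back):       a0 = %.4f [%.4f, %.4f]\n",
              x$lag, x$reference$a0, x$reference$ci_a0[1],
              x$reference$ci_a0[2]))
  cat(sprintf("  corrected  (residualized):      a0 = %.4f [%.4f, %.4f]\n",
              x$stage2$a0, x$stage2$ci_a0[1], x$stage2$ci_a0[2]))
  cat(sprintf("  stage 1    (1-back response):   a0 = %.4f [%.4f, %.4f]\n",
              x$stage1$a0, x$stage1$ci_a0[1], x$stage1$ci_a0[2]))
  invisible(x)
}

#' Permutation p-value helper
#'
#' Proportion of null differences strictly larger than the observed one;
#' with `plus_one`, the add-one variant `(k + 1) / (B + 1)`.
#'
#' @param observed Observed statistic.
#' @param nulls Vector of null statistics.
#' @param plus_one Use the add-one estimator?
#' @return The p-value.
#' @export
perm_pvalue <- function(observed, nulls, plus_one = FALSE) {
  k <- sum(nulls > observed)
  if (plus_one) (k + 1) / (length(nulls) + 1) else k / length(nulls)
}

#' Within-subject permutation test of the containment effect
#'
#' Tests whether the raw n-back amplitude exceeds the corrected one
#' (`a0_ref - a0_corrected > 0`) against a null distribution built by
#' shuffling each subject's errors (sampling without replacement,
#' balanced per subject), reconstructing the responses as
#' `stimulus + shuffled error` so that response-derived predictors stay
#' consistent, and rerunning the full two-stage analysis. Permutations
#' whose fits fail are dropped and counted.
#'
#' @inheritParams two_stage_nlmem
#' @param B Number of permutations. Default 1000.
#' @param seed Integer seed for the permutation stream.
#' @param plus_one Use the `(k+1)/(B+1)` p-value variant?
#' @param ... Passed on to [fit_dog_nlmem()].
#' @return An object of class `"permutation_result"`: `observed_diff`,
#'   `null_diffs`, `p_value`, `B` (effective), `B_requested`,
#'   `n_failed`, `seed`, plus the observed `"two_stage_nlmem"` in
#'   `$observed_fit`.
#' @export
permutation_test <- function(table, lag = 2L, B = 1000L, seed = 1L,
                             plus_one = FALSE, wrap = TRUE, ...) {
  obs_fit <- two_stage_nlmem(table, lag = lag, wrap = wrap, ...)
  observed <- obs_fit$reference$a0 - obs_fit$stage2$a0
  subj_rows <- .split_subject(table)
  nulls <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    set.seed(.derive_seed(seed, b))
    perm <- table
    for (rows in subj_rows)
      perm$error[rows] <- sample(perm$error[rows])
    perm$response <- perm$stimulus + perm$error
    nulls[b] <- tryCatch({
      f <- two_stage_nlmem(perm, lag = lag, wrap = wrap, ...)
      f$reference$a0 - f$stage2$a0
    }, error = function(e) NA_real_)
  }
  ok <- is.finite(nulls)
  structure(list(observed_diff = observed, null_diffs = nulls[ok],
                 p_value = perm_pvalue(observed, nulls[ok], plus_one),
                 B = sum(ok), B_requested = B, n_failed = sum(!ok),
                 seed = seed, plus_one = plus_one,
                 observed_fit = obs_fit),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test of the containment effect\n")
  cat(sprintf("  observed a0(raw) - a0(corrected) = %.4f\n",
              x$observed_diff))
  cat(sprintf("  p = %.4f  (%d permutations%s)\n", x$p_value, x$B,
              if (x$n_failed > 0)
                sprintf(", %d failed and dropped", x$n_failed) else ""))
  invisible(x)
}

#' Full reanalysis of an orientation-reproduction trial table
#'
#' Convenience pipeline: preprocess (debias, outlier removal with
#' followers, block-start trimming), run the two-stage corrected
#' mixed-effects analysis and the permutation test, and return a compact
#' report.
#'
#' @param table A `"trial_table"` (raw).
#' @param lag Stimulus lag under test. Default 2.
#' @param B Number of permutations (0 skips the permutation test).
#' @param seed Permutation seed.
#' @param degree,k,n_trim Preprocessing parameters, see [preprocess()].
#' @param ... Passed on to [fit_dog_nlmem()].
#' @return List with `table` (preprocessed), `analysis`
#'   (`"two_stage_nlmem"`) and `permutation` (`"permutation_result"` or
#'   `NULL`).
#' @export
reanalyze <- function(table, lag = 2L, B = 1000L, seed = 1L,
                      degree = 9L, k = 3, n_trim = 2L, ...) {
  table <- preprocess(table, degree = degree, k = k, n_trim = n_trim)
  if (B > 0) {
    perm <- permutation_test(table, lag = lag, B = B, seed = seed, ...)
    analysis <- perm$observed_fit
  } else {
    perm <- NULL
    analysis <- two_stage_nlmem(table, lag = lag, ...)
  }
  list(table = table, analysis = analysis, permutation = perm)
}
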