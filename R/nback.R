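#' Build an n-back regression design from a trial series
#'
#' The n-back analysis fits the current error against the difference
#' between a past stimulus (or the immediately preceding response) and the
#' current stimulus. This builds the predictor/outcome pairs and marks the
#' leading trials whose lagged terms do not exist.
#'
#' @param series A `"trial_series"` object (or any data frame with
#'   `stimulus`, `response`, `error` columns).
#' @param lag Positive integer lag `N`. For `source = "response"` only
#'   `lag = 1` is supported (the analyses pair the 1-back response with
#'   n-back stimuli).
#' @param source `"stimulus"`: predictor `x[n-lag] - x[n]`; `"response"`:
#'   predictor `y[n-1] - x[n]`.
#' @param wrap If `TRUE`, predictors are wrapped into `(-90, 90]`.
#' @return An object of class `"nback_design"`: list with `delta`,
#'   `outcome`, `valid`, `lag`, `source`, `wrap`.
#' @export
nback_design <- function(series, lag = 1L,
                         source = c("stimulus", "response"),
                         wrap = FALSE) {
  source <- match.arg(source)
  if (!all(c("stimulus", "response", "error") %in% names(series)))
    stop("'series' must have stimulus, response and error columns",
         call. = FALSE)
  n <- nrow(series)
  if (!is.numeric(lag) || length(lag) != 1L || lag < 1)
    stop("'lag' must be a positive integer", call. = FALSE)
  lag <- as.integer(lag)
  if (lag >= n)
    stop(sprintf("lag (%d) must be smaller than the series length (%d)",
                 lag, n), call. = FALSE)
  if (source == "response" && lag != 1L)
    stop("response-source designs are supported at lag 1 only",
         call. = FALSE)

  x <- series$stimulus
  delta <- rep(NA_real_, n)
  valid <- rep(TRUE, n)
  if (source == "stimulus") {
    idx <- (lag + 1L):n
    delta[idx] <- x[idx - lag] - x[idx]
    valid[seq_len(lag)] <- FALSE
  } else {
    idx <- 2:n
    delta[idx] <- series$response[idx - 1L] - x[idx]
    valid[1L] <- FALSE
  }
  if (wrap) delta <- wrap_deg(delta)
  structure(list(delta = delta, outcome = series$error, valid = valid,
                 lag = lag, source = source, wrap = wrap),
            class = "nback_design")
}

## DoG regression basis: dog(delta; a, w) = a * .dog_basis(delta, w).
.dog_basis <- function(delta, w, c0) c0 * w * delta * exp(-(w * delta)^2)

## Linear least squares at fixed w (used for bound projection and the
## fixed-w fitting path; the model is linear in a given w).
.fixed_w_ls <- function(delta, y, w, c0, intercept) {
  z <- .dog_basis(delta, w, c0)
  if (intercept) {
    X <- cbind(1, z)
    cf <- qr.coef(qr(X), y)
    cf[is.na(cf)] <- 0
    list(a = cf[2L], b = cf[1L], fitted = drop(X %*% cf))
  } else {
    zz <- sum(z * z)
    a <- if (zz > 0) sum(z * y) / zz else 0
    list(a = a, b = NULL, fitted = a * z)
  }
}

#' Fit a DoG curve to an n-back design by nonlinear least squares
#'
#' Minimizes the residual sum of squares of `outcome - dog(delta; a, w)`
#' with the amplitude free and the inverse width constrained to
#' `w_bounds` (default `[0, 1]`). The optimizer is the damped
#' Gauss-Newton method of [stats::nls()] started at `start` — a local
#' fit by design: the sum-of-squares surface is multimodal in `w` under
#' noise, and a global search over widths would act as an implicit
#' multiple comparison, distorting the operating characteristics of the
#' significance rule the Monte-Carlo audits rely on. Fits that fail to
#' converge (singular gradient, step-size collapse, iteration limit)
#' are returned with `converged = FALSE` and the start-value estimates;
#' the Monte-Carlo harness counts them as non-significant. A fitted `w`
#' beyond the upper bound is projected onto the bound (fixed-`w` linear
#' refit) and flagged as a boundary solution; a negative fitted `w` is
#' sign-canonicalized (the curve is identical under
#' `(a, w) -> (-a, -w)`). Confidence intervals are Wald-type t
#' intervals from the Jacobian at the optimum with residual variance
#' `SSE / (n - p)`.
#'
#' @param design An [nback_design()], or a list with numeric `delta` and
#'   `outcome` (and optionally `valid`).
#' @param w_bounds Length-2 interval constraining `w`. Default `c(0, 1)`.
#'   A zero-width interval requests a fixed-`w` fit (linear in `a`).
#' @param start Named start values; default `c(a = 1, w = 0.05)`.
#' @param alpha Two-sided interval level is `1 - alpha`. Default 0.05.
#' @param intercept If `TRUE`, an additive intercept is estimated jointly.
#' @param multistart If `TRUE`, non-convergence triggers retries from
#'   `w0 in {0.01, 0.05, 0.2}` before giving up. Default `FALSE`.
#' @param c0 Normalization constant of the curve.
#' @return An object of class `"dog_fit"`: estimates `a_hat`, `w_hat`
#'   (and `b_hat` if requested), `ci_a`, `ci_w`, `covariance`,
#'   `residuals`, `fitted`, `converged`, `boundary`, `n_used`, `sigma`,
#'   `df`, `alpha`.
#' @export
#' @examples
#' cfg <- generator_config("delta_s", dog_params(4.8, 0.03),
#'                         noise_sd = 0, seed = 7)
#' f <- fit_dog(nback_design(simulate_series(cfg), 1, "stimulus"))
#' coef(f)
fit_dog <- function(design, w_bounds = c(0, 1),
                    start = c(a = 1, w = 0.05),
                    alpha = 0.05, intercept = FALSE, multistart = FALSE,
                    c0 = dog_norm_const()) {
  if (!is.list(design) || is.null(design$delta) || is.null(design$outcome))
    stop("'design' must contain 'delta' and 'outcome'", call. = FALSE)
  valid <- if (is.null(design$valid)) rep(TRUE, length(design$delta))
           else design$valid
  keep <- valid & is.finite(design$delta) & is.finite(design$outcome)
  delta <- design$delta[keep]
  y <- design$outcome[keep]
  n <- length(y)
  if (n < 10L)
    stop("need at least 10 valid (delta, outcome) pairs", call. = FALSE)
  if (length(unique(delta)) == 1L)
    stop("degenerate design: all predictor values are equal", call. = FALSE)
  if (!is.numeric(w_bounds) || length(w_bounds) != 2L ||
      any(!is.finite(w_bounds)) || w_bounds[1] < 0 ||
      w_bounds[2] < w_bounds[1])
    stop("'w_bounds' must be an interval within [0, Inf)", call. = FALSE)

  a0 <- if (!is.null(start[["a"]])) start[["a"]] else 1
  w0 <- if (!is.null(start[["w"]])) start[["w"]] else 0.05
  converged <- TRUE
  boundary <- FALSE

  if (w_bounds[2] <= w_bounds[1]) {      # fixed-w fit (linear in a)
    w_hat <- w_bounds[2]
    fixed_w <- TRUE
    ls <- .fixed_w_ls(delta, y, max(w_hat, 1e-12), c0, intercept)
    a_hat <- ls$a; b_hat <- ls$b; fitted <- ls$fitted
  } else {
    fixed_w <- FALSE
    df_fit <- data.frame(delta = delta, y = y)
    form <- if (intercept)
      y ~ b + a * c0 * w * delta * exp(-(w * delta)^2)
    else
      y ~ a * c0 * w * delta * exp(-(w * delta)^2)
    environment(form) <- environment()
    starts <- list(c(a = a0, w = w0))
    if (multistart)
      starts <- c(starts, lapply(c(0.01, 0.05, 0.2),
                                 function(w1) c(a = a0, w = w1)))
    fit <- NULL
    for (st in starts) {
      st_list <- if (intercept) list(a = st[["a"]], b = 0, w = st[["w"]])
                 else list(a = st[["a"]], w = st[["w"]])
      fit <- tryCatch(
        suppressWarnings(stats::nls(form, data = df_fit,
                                    start = st_list,
                                    control = stats::nls.control(
                                      scaleOffset = 1))),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {                  # non-convergence: keep starts
      converged <- FALSE
      w_hat <- w0
      ls <- .fixed_w_ls(delta, y, w_hat, c0, intercept)
      a_hat <- ls$a; b_hat <- ls$b; fitted <- ls$fitted
    } else {
      cf <- stats::coef(fit)
      a_hat <- cf[["a"]]; w_hat <- cf[["w"]]
      b_hat <- if (intercept) cf[["b"]] else NULL
      if (w_hat < 0) {                   # sign canonicalization
        w_hat <- -w_hat; a_hat <- -a_hat
      }
      if (w_hat < w_bounds[1] || w_hat > w_bounds[2]) {
        w_hat <- min(max(w_hat, w_bounds[1]), w_bounds[2])
        boundary <- TRUE
        ls <- .fixed_w_ls(delta, y, max(w_hat, 1e-12), c0, intercept)
        a_hat <- ls$a; b_hat <- ls$b; fitted <- ls$fitted
      } else {
        fitted <- y - as.numeric(stats::resid(fit))
      }
    }
  }

  res <- y - fitted
  sse <- sum(res^2)
  p <- 2L + as.integer(intercept)
  df <- n - p
  sigma2 <- sse / df
  ## Jacobian at the solution: d/da = z; d/dw = a * dz/dw
  z <- .dog_basis(delta, w_hat, c0)
  dzdw <- c0 * delta * exp(-(w_hat * delta)^2) *
    (1 - 2 * (w_hat * delta)^2)
  J <- if (intercept) cbind(b = 1, a = z, w = a_hat * dzdw)
       else cbind(a = z, w = a_hat * dzdw)
  if (fixed_w || boundary || !converged)
    J <- J[, setdiff(colnames(J), "w"), drop = FALSE]
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(JtJ), error = function(e) NULL)
  if (is.null(cov)) {                    # singular (e.g., a_hat == 0)
    cov <- matrix(NA_real_, ncol(J), ncol(J),
                  dimnames = list(colnames(J), colnames(J)))
    zz <- sum(z * z)
    if (zz > 0) cov["a", "a"] <- sigma2 / zz
  }
  tq <- stats::qt(1 - alpha / 2, df)
  se_a <- sqrt(cov["a", "a"])
  ci_a <- if (converged) a_hat + c(-1, 1) * tq * se_a
          else c(-Inf, Inf)              # undetermined: never significant
  ci_w <- if (!fixed_w && !boundary && converged &&
              "w" %in% colnames(cov) && is.finite(cov["w", "w"]))
    w_hat + c(-1, 1) * tq * sqrt(cov["w", "w"])
  else c(w_hat, w_hat)

  structure(list(a_hat = unname(a_hat), w_hat = unname(w_hat),
                 b_hat = if (is.null(b_hat)) NULL else unname(b_hat),
                 ci_a = ci_a, ci_w = ci_w, se_a = unname(se_a),
                 covariance = cov, residuals = res, fitted = fitted,
                 delta = delta, outcome = y, keep = keep,
                 converged = converged, boundary = boundary,
                 n_used = n, sigma = sqrt(sigma2), df = df, alpha = alpha,
                 c0 = c0, lag = design$lag, source = design$source),
            class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  cat("DoG nonlinear least-squares fit\n")
  if (!is.null(x$lag))
    cat(sprintf("  design: lag-%d %s predictor, %d trials\n",
                x$lag, x$source, x$n_used))
  cat(sprintf("  a = %.4f  [%.4f, %.4f]  (%.0f%% CI)\n",
              x$a_hat, x$ci_a[1], x$ci_a[2], 100 * (1 - x$alpha)))
  cat(sprintf("  w = %.4f  [%.4f, %.4f]%s\n", x$w_hat, x$ci_w[1], x$ci_w[2],
              if (x$boundary) "  (at bound)" else ""))
  if (!is.null(x$b_hat)) cat(sprintf("  intercept = %.4f\n", x$b_hat))
  cat(sprintf("  residual sd = %.4f on %d df\n", x$sigma, x$df))
  invisible(x)
}

#' @export
coef.dog_fit <- function(object, ...) {
  cf <- c(a = object$a_hat, w = object$w_hat)
  if (!is.null(object$b_hat)) cf <- c(b = object$b_hat, cf)
  cf
}

#' @export
confint.dog_fit <- function(object, parm = c("a", "w"), level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  m <- rbind(a = object$ci_a, w = object$ci_w)
  colnames(m) <- c("lower", "upper")
  m[parm, , drop = FALSE]
}

#' @export
residuals.dog_fit <- function(object, ...) object$residuals

#' @export
predict.dog_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$delta
       else if (is.list(newdata)) newdata$delta else newdata
  out <- object$a_hat * .dog_basis(d, object$w_hat, object$c0)
  if (!is.null(object$b_hat)) out <- out + object$b_hat
  out
}

#' @export
summary.dog_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.dog_fit <- function(x, ...) {
  graphics::plot(x$delta, x$outcome, pch = 16, cex = 0.4,
                 col = "grey60", xlab = "predictor difference (deg)",
                 ylab = "outcome (deg)", ...)
  o <- order(x$delta)
  graphics::lines(x$delta[o], x$fitted[o], col = "red3", lwd = 2)
  invisible(x)
}

#' Is the fitted amplitude significant?
#'
#' The significance rule of the Monte-Carlo audits. With
#' `sign = "positive"` (the default) a fit counts as significant when
#' the amplitude's confidence interval lies entirely above zero — a
#' significant attractive effect, the direction serial dependence takes
#' with this package's sign convention. `sign = "two_sided"` counts any
#' CI excluding zero. Non-converged fits (infinite CI) are never
#' significant.
#'
#' @param fit A `"dog_fit"` (or `"dog_nlmem"`) object.
#' @param sign `"positive"` or `"two_sided"`.
#' @return Logical scalar.
#' @export
is_significant <- function(fit, sign = c("positive", "two_sided")) {
  sign <- match.arg(sign)
  ci <- if (inherits(fit, "dog_nlmem")) fit$ci_a0 else fit$ci_a
  if (!all(is.finite(ci))) return(FALSE)
  if (sign == "positive") ci[1] > 0 else (ci[1] > 0 || ci[2] < 0)
}

#' Two-stage residualization ("containment") fit
#'
#' Removes the 1-back response effect before testing an n-back stimulus
#' effect: stage 1 fits the 1-back relative response onto the current
#' error; stage 2 fits the lag-`N` relative stimulus onto stage 1's
#' residuals. Trials invalid in either design are excluded from stage 2.
#' The stage-2 amplitude CI is the corrected test of the n-back effect.
#'
#' @inheritParams nback_design
#' @param ... Passed on to [fit_dog()] for both stages.
#' @return An object of class `"corrected_dog_fit"`: list with elements
#'   `stage1` and `stage2`, both `"dog_fit"`.
#' @export
corrected_fit <- function(series, lag = 2L, wrap = FALSE, ...) {
  if (lag < 2)
    stop("'lag' must be >= 2 for the corrected fit", call. = FALSE)
  d1 <- nback_design(series, 1L, "response", wrap = wrap)
  stage1 <- fit_dog(d1, ...)
  r_full <- rep(NA_real_, length(d1$delta))
  r_full[stage1$keep] <- stage1$residuals
  d2 <- nback_design(series, lag, "stimulus", wrap = wrap)
  d2$outcome <- r_full
  d2$valid <- d2$valid & !is.na(r_full)
  stage2 <- fit_dog(d2, ...)
  structure(list(stage1 = stage1, stage2 = stage2, lag = lag),
            class = "corrected_dog_fit")
}

#' @export
print.corrected_dog_fit <- function(x, ...) {
  cat(sprintf("Corrected (residualized) %d-back fit\n", x$lag))
  cat("-- stage 1: 1-back response on error --\n"); print(x$stage1)
  cat(sprintf("-- stage 2: %d-back stimulus on stage-1 residuals --\n",
              x$lag))
  print(x$stage2)
  invisible(x)
}

#' Serialize a DoG fit to JSON
#'
#' @param fit A `"dog_fit"`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(a = fit$a_hat, w = fit$w_hat, b = fit$b_hat,
         ci_a = fit$ci_a, ci_w = fit$ci_w, se_a = fit$se_a,
         sigma = fit$sigma, n_used = fit$n_used,
         converged = fit$converged, boundary = fit$boundary,
         alpha = fit$alpha),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
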