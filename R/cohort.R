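#' Configuration of a synthetic multi-subject cohort
#'
#' Describes a cohort with the statistical structure the empirical
#' reanalysis assumes: a few subjects, many trials in blocks, DoG-shaped
#' 1-back response feedback with per-subject amplitude and intercept
#' variation, Gaussian trial noise, an optional genuine 2-back stimulus
#' term, an optional planted polynomial orientation bias, and optional
#' injected outliers. The defaults mirror a small
#' orientation-reproduction study: 4 subjects, 10 blocks of 80 trials
#' (800 per subject).
#'
#' @param n_subjects Number of subjects. Default 4.
#' @param n_blocks Blocks per subject. Default 10.
#' @param trials_per_block Trials per block. Default 80.
#' @param a0 Group-level DoG amplitude (degrees). Default 2.
#' @param b0 Group-level intercept (degrees). Default 0.
#' @param w Shared inverse width (1/degrees). Default 0.05.
#' @param sigma_nu Between-subject sd of the amplitude. Default 0.5.
#' @param sigma_psi Between-subject sd of the intercept. Default 0.3.
#' @param sigma_eps Trial noise sd (degrees). Default 5.
#' @param true_2back Optional [dog_params()] for a genuine 2-back
#'   stimulus term.
#' @param bias_poly_coeffs Coefficients (ascending powers, constant
#'   first) of a planted polynomial orientation bias evaluated on the
#'   scaled stimulus `(stimulus - 90) / 90` in `[-1, 1)`. Up to degree 9.
#' @param outlier_rate Proportion of trials receiving an additive
#'   contamination of magnitude 5-8 `sigma_eps` with random sign, in
#'   `[0, 0.1]`. Default 0.
#' @param seed Optional integer seed.
#' @param wrap_differences Wrap feedback differences into `(-90, 90]`?
#'   Default `TRUE` (orientation is circular in the empirical pipeline).
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 4L, n_blocks = 10L,
                          trials_per_block = 80L, a0 = 2, b0 = 0,
                          w = 0.05, sigma_nu = 0.5, sigma_psi = 0.3,
                          sigma_eps = 5, true_2back = NULL,
                          bias_poly_coeffs = numeric(0),
                          outlier_rate = 0, seed = NULL,
                          wrap_differences = TRUE) {
  if (n_subjects < 1 || n_blocks < 1 || trials_per_block < 1)
    stop("all sizes must be >= 1", call. = FALSE)
  if (sigma_nu < 0 || sigma_psi < 0 || sigma_eps < 0)
    stop("variance components must be >= 0", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate > 0.1)
    stop("'outlier_rate' must be in [0, 0.1]", call. = FALSE)
  if (length(bias_poly_coeffs) > 10L)
    stop("'bias_poly_coeffs' supports up to degree 9", call. = FALSE)
  if (!is.null(true_2back)) true_2back <- as_dog_params(true_2back)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 a0 = a0, b0 = b0, w = w, sigma_nu = sigma_nu,
                 sigma_psi = sigma_psi, sigma_eps = sigma_eps,
                 true_2back = true_2back,
                 bias_poly_coeffs = bias_poly_coeffs,
                 outlier_rate = outlier_rate,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 wrap_differences = isTRUE(wrap_differences)),
            class = "cohort_config")
}

.poly_bias <- function(stimulus, coeffs) {
  if (!length(coeffs)) return(numeric(length(stimulus)))
  s <- (stimulus - 90) / 90
  drop(outer(s, seq_along(coeffs) - 1L, `^`) %*% coeffs)
}

#' Generate a synthetic multi-subject cohort
#'
#' Per subject, the amplitude and intercept are drawn as
#' `a_i ~ N(a0, sigma_nu^2)`, `b_i ~ N(b0, sigma_psi^2)`. Each block is
#' an independent response-feedback (optionally + 2-back stimulus)
#' recursion on stimuli uniform in `[0, 180)` with trial noise
#' `sigma_eps`; the feedback resets at block boundaries (the first trial
#' of a block has no serial term). The planted polynomial bias of the
#' stimulus and injected outliers are added to the responses, and the
#' error column is the wrapped response minus stimulus.
#'
#' @param config A [cohort_config()].
#' @return A `"trial_table"` with the configuration in
#'   `attr(, "config")` and the injected-outlier row indices in
#'   `attr(, "planted_outliers")`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be a cohort_config", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  wrapfun <- if (config$wrap_differences) wrap_deg else identity
  k1_of <- function(a) a * config$w * dog_norm_const()
  p2 <- config$true_2back
  if (!is.null(p2)) { k2 <- p2$a * p2$w * p2$c; w2 <- p2$w }

  rows <- vector("list", config$n_subjects * config$n_blocks)
  idx <- 0L
  for (s in seq_len(config$n_subjects)) {
    a_i <- stats::rnorm(1, config$a0, config$sigma_nu)
    b_i <- stats::rnorm(1, config$b0, config$sigma_psi)
    k1 <- k1_of(a_i); w1 <- config$w
    for (blk in seq_len(config$n_blocks)) {
      n <- config$trials_per_block
      x <- make_stimulus_sequence(n, 0, 180)
      eps <- stats::rnorm(n, 0, config$sigma_eps)
      bias <- .poly_bias(x, config$bias_poly_coeffs)
      y <- numeric(n)
      for (i in seq_len(n)) {
        fb <- 0
        if (i > 1L) {
          d1 <- wrapfun(y[i - 1L] - x[i])
          fb <- d1 * k1 * exp(-(w1 * d1)^2)
        }
        if (!is.null(p2) && i > 2L) {
          d2 <- wrapfun(x[i - 2L] - x[i])
          fb <- fb + d2 * k2 * exp(-(w2 * d2)^2)
        }
        y[i] <- x[i] + b_i + fb + bias[i] + eps[i]
      }
      idx <- idx + 1L
      rows[[idx]] <- data.frame(subject = sprintf("S%02d", s),
                                block = blk, trial = seq_len(n),
                                stimulus = x, response = y)
    }
  }
  df <- do.call(rbind, rows)

  planted <- integer(0)
  if (config$outlier_rate > 0) {
    hit <- which(stats::runif(nrow(df)) < config$outlier_rate)
    if (length(hit)) {
      shift <- sample(c(-1, 1), length(hit), replace = TRUE) *
        stats::runif(length(hit), 5, 8) * config$sigma_eps
      df$response[hit] <- df$response[hit] + shift
      planted <- hit
    }
  }

  out <- as_trial_table(df)
  attr(out, "config") <- config
  attr(out, "planted_outliers") <- planted
  out
}

#' Write / read a cohort fixture
#'
#' Serializes a trial table to the standard trial CSV (`subject, block,
#' trial, stimulus, response`) with a JSON sidecar carrying the cohort
#' configuration (including the seed, so the cohort can be regenerated).
#'
#' @param table A `"trial_table"`.
#' @param path Output CSV path.
#' @return `read_fixture` returns the reconstructed `"trial_table"` (with
#'   the configuration attribute when the sidecar is present).
#' @export
write_fixture <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write fixture: directory does not exist: ", dir,
         call. = FALSE)
  write_trials_csv(table, path)
  cfg <- attr(table, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(
      list(n_subjects = cfg$n_subjects, n_blocks = cfg$n_blocks,
           trials_per_block = cfg$trials_per_block, a0 = cfg$a0,
           b0 = cfg$b0, w = cfg$w, sigma_nu = cfg$sigma_nu,
           sigma_psi = cfg$sigma_psi, sigma_eps = cfg$sigma_eps,
           true_2back = if (is.null(cfg$true_2back)) NULL
                        else unclass(cfg$true_2back),
           bias_poly_coeffs = cfg$bias_poly_coeffs,
           outlier_rate = cfg$outlier_rate, seed = cfg$seed,
           wrap_differences = cfg$wrap_differences),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  table <- read_trials_csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(table, "config") <- cohort_config(
      n_subjects = j$n_subjects, n_blocks = j$n_blocks,
      trials_per_block = j$trials_per_block, a0 = j$a0, b0 = j$b0,
      w = j$w, sigma_nu = j$sigma_nu, sigma_psi = j$sigma_psi,
      sigma_eps = j$sigma_eps,
      true_2back = if (is.null(j$true_2back)) NULL
                   else dog_params(j$true_2back$a, j$true_2back$w,
                                   j$true_2back$c),
      bias_poly_coeffs = if (is.null(j$bias_poly_coeffs)) numeric(0)
                         else as.numeric(j$bias_poly_coeffs),
      outlier_rate = j$outlier_rate, seed = j$seed,
      wrap_differences = j$wrap_differences)
  }
  table
}
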