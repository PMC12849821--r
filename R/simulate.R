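#' Draw a uniform stimulus sequence
#'
#' Orientation stimuli are drawn independently and uniformly from
#' `[low, high)`, the sampling scheme of the simulated reproduction runs.
#'
#' @param n Number of trials, `>= 1`.
#' @param low,high Range endpoints in degrees, `low < high`. Defaults 0 and
#'   180 (orientation space).
#' @return Numeric vector of length `n`.
#' @export
make_stimulus_sequence <- function(n, low = 0, high = 180) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single integer >= 1", call. = FALSE)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("need finite 'low' < 'high'", call. = FALSE)
  stats::runif(as.integer(n), low, high)
}

#' Configuration of a generative serial-dependence system
#'
#' Describes one simulated reproduction run. Three generative recursions
#' are supported, all built on the DoG tuning curve:
#' \describe{
#'   \item{`"delta_s"`}{stimulus feedback: `y[n] = dog(x[n-1] - x[n]) + x[n] + eps`}
#'   \item{`"delta_r"`}{response feedback: `y[n] = dog(y[n-1] - x[n]) + x[n] + eps`}
#'   \item{`"delta_rs"`}{response feedback plus a genuine 2-back stimulus
#'     term: `y[n] = dog1(y[n-1] - x[n]) + dog2(x[n-2] - x[n]) + x[n] + eps`}
#' }
#' Trials where a lagged term is undefined (the first trial for 1-back
#' terms, the first two for the 2-back term) receive a zero contribution
#' from that term.
#'
#' @param model One of `"delta_s"`, `"delta_r"`, `"delta_rs"`.
#' @param params_1back [dog_params()] of the 1-back feedback term.
#' @param params_2back [dog_params()] of the 2-back stimulus term; required
#'   exactly when `model = "delta_rs"`.
#' @param n_trials Number of trials, `>= 2`. Default 1000.
#' @param noise_sd Standard deviation of the Gaussian trial noise, degrees,
#'   `>= 0`. Default 1.
#' @param stim_low,stim_high Stimulus range in degrees. Defaults 0, 180.
#' @param seed Optional integer seed; if given, [simulate_series()] is
#'   reproducible.
#' @param wrap_differences If `TRUE`, every difference fed to the DoG is
#'   wrapped into `(-90, 90]` first. Default `FALSE`: the simulation
#'   recursions use raw arithmetic differences; wrapping is the convention
#'   of the empirical pipeline where orientation is genuinely circular.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(model = c("delta_s", "delta_r", "delta_rs"),
                             params_1back,
                             params_2back = NULL,
                             n_trials = 1000L,
                             noise_sd = 1,
                             stim_low = 0, stim_high = 180,
                             seed = NULL,
                             wrap_differences = FALSE) {
  model <- match.arg(model)
  params_1back <- as_dog_params(params_1back)
  if (model == "delta_rs") {
    if (is.null(params_2back))
      stop("'params_2back' is required for the delta_rs model", call. = FALSE)
    params_2back <- as_dog_params(params_2back)
  } else if (!is.null(params_2back)) {
    stop("'params_2back' is only meaningful for the delta_rs model",
         call. = FALSE)
  }
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 2)
    stop("'n_trials' must be >= 2", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L ||
      !is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be a finite number >= 0", call. = FALSE)
  if (!is.finite(stim_low) || !is.finite(stim_high) || stim_low >= stim_high)
    stop("need finite 'stim_low' < 'stim_high'", call. = FALSE)
  structure(list(model = model, params_1back = params_1back,
                 params_2back = params_2back,
                 n_trials = as.integer(n_trials), noise_sd = noise_sd,
                 stim_low = stim_low, stim_high = stim_high,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 wrap_differences = isTRUE(wrap_differences)),
            class = "generator_config")
}

#' Simulate one trial series from a serial-dependence generator
#'
#' Runs the recursion described by the configuration and returns stimuli,
#' responses and errors (`error = response - stimulus`).
#'
#' @param config A [generator_config()].
#' @return A `data.frame` of class `"trial_series"` with columns `trial`,
#'   `stimulus`, `response`, `error` and the configuration in
#'   `attr(, "config")`.
#' @export
#' @examples
#' cfg <- generator_config("delta_r", dog_params(5, 0.01), seed = 1)
#' s <- simulate_series(cfg)
#' head(s)
simulate_series <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("'config' must be a generator_config object", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_trials
  x <- make_stimulus_sequence(n, config$stim_low, config$stim_high)
  eps <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd)
         else numeric(n)

  p1 <- config$params_1back
  k1 <- p1$a * p1$w * p1$c; w1 <- p1$w
  wrap <- config$wrap_differences
  y <- numeric(n)

  if (config$model == "delta_s") {
    d <- c(0, x[-n] - x[-1L])            # x[n-1] - x[n], zero for trial 1
    if (wrap) d <- wrap_deg(d)
    fb <- d * k1 * exp(-(w1 * d)^2)
    fb[1L] <- 0
    y <- fb + x + eps
  } else if (config$model == "delta_r") {
    y[1L] <- x[1L] + eps[1L]
    for (i in 2:n) {
      d <- y[i - 1L] - x[i]
      if (wrap) d <- wrap_deg(d)
      y[i] <- d * k1 * exp(-(w1 * d)^2) + x[i] + eps[i]
    }
  } else {                               # delta_rs
    p2 <- config$params_2back
    k2 <- p2$a * p2$w * p2$c; w2 <- p2$w
    y[1L] <- x[1L] + eps[1L]
    for (i in 2:n) {
      d1 <- y[i - 1L] - x[i]
      if (wrap) d1 <- wrap_deg(d1)
      fb <- d1 * k1 * exp(-(w1 * d1)^2)
      if (i > 2L) {
        d2 <- x[i - 2L] - x[i]
        if (wrap) d2 <- wrap_deg(d2)
        fb <- fb + d2 * k2 * exp(-(w2 * d2)^2)
      }
      y[i] <- fb + x[i] + eps[i]
    }
  }

  out <- data.frame(trial = seq_len(n), stimulus = x, response = y,
                    error = y - x)
  attr(out, "config") <- config
  class(out) <- c("trial_series", "data.frame")
  out
}

#' Impulse response of the stimulus- or response-feedback system
#'
#' Drives the noise-free recursion with a one-sample unit input
#' (`x[0] = 1`, `x[n] = 0` otherwise) and zero pre-history
#' (`x[-1] = 0`, and `y[-1] = 0` for the response-feedback system),
#' revealing how a perturbation propagates across trials. The
#' stimulus-feedback system returns to zero after one step; the
#' response-feedback system decays slowly, the mechanism by which 1-back
#' response effects masquerade as n-back stimulus effects.
#'
#' @param model `"delta_s"` or `"delta_r"`. The combined `"delta_rs"`
#'   system is not supported here.
#' @param params [dog_params()] of the feedback term.
#' @param n_steps Number of output samples, `>= 1`.
#' @return Numeric vector `y[0..n_steps-1]`.
#' @export
#' @examples
#' round(impulse_response("delta_s", dog_params(4.8, 0.03), 4), 2)
#' round(impulse_response("delta_r", dog_params(4.8, 0.03), 4), 2)
impulse_response <- function(model = c("delta_s", "delta_r"), params,
                             n_steps = 10L) {
  model <- tryCatch(match.arg(model),
                    error = function(e) stop(
                      "impulse_response() supports only the delta_s and delta_r systems",
                      call. = FALSE))
  params <- as_dog_params(params)
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("'n_steps' must be >= 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  x <- c(1, numeric(max(0L, n_steps - 1L)))
  y <- numeric(n_steps)
  if (model == "delta_s") {
    for (i in seq_len(n_steps)) {
      xm1 <- if (i == 1L) 0 else x[i - 1L]
      y[i] <- dog(xm1 - x[i], params) + x[i]
    }
  } else {
    for (i in seq_len(n_steps)) {
      ym1 <- if (i == 1L) 0 else y[i - 1L]
      y[i] <- dog(ym1 - x[i], params) + x[i]
    }
  }
  y
}

#' @export
print.trial_series <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Trial series: %d trials, %s generator (a=%g, w=%g), noise sd %g\n",
              nrow(x), cfg$model, cfg$params_1back$a, cfg$params_1back$w,
              cfg$noise_sd))
  NextMethod()
}

#' Write / read a trial series as CSV
#'
#' The CSV has columns `trial`, `stimulus`, `response`, `error`; the
#' generator configuration travels in a JSON sidecar (`<path>.json`) so a
#' round trip is lossless.
#'
#' @param series A `"trial_series"` object.
#' @param path Output CSV path.
#' @return `read_series_csv` returns the reconstructed series.
#' @export
write_series_csv <- function(series, path) {
  if (!inherits(series, "trial_series"))
    stop("'series' must be a trial_series", call. = FALSE)
  utils::write.csv(as.data.frame(series)[, c("trial", "stimulus",
                                             "response", "error")],
                   path, row.names = FALSE)
  cfg <- attr(series, "config")
  jsonlite::write_json(
    list(model = cfg$model,
         params_1back = unclass(cfg$params_1back),
         params_2back = if (is.null(cfg$params_2back)) NULL
                        else unclass(cfg$params_2back),
         n_trials = cfg$n_trials, noise_sd = cfg$noise_sd,
         stim_low = cfg$stim_low, stim_high = cfg$stim_high,
         seed = cfg$seed, wrap_differences = cfg$wrap_differences),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "stimulus", "response", "error")
  if (!all(need %in% names(df)))
    stop("series CSV must have columns trial, stimulus, response, error",
         call. = FALSE)
  side <- paste0(path, ".json")
  cfg <- NULL
  if (file.exists(side)) {
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    cfg <- generator_config(
      model = j$model,
      params_1back = dog_params(j$params_1back$a, j$params_1back$w,
                                j$params_1back$c),
      params_2back = if (is.null(j$params_2back)) NULL
                     else dog_params(j$params_2back$a, j$params_2back$w,
                                     j$params_2back$c),
      n_trials = j$n_trials, noise_sd = j$noise_sd,
      stim_low = j$stim_low, stim_high = j$stim_high,
      seed = j$seed, wrap_differences = j$wrap_differences)
  }
  out <- df[, need]
  attr(out, "config") <- cfg
  class(out) <- c("trial_series", "data.frame")
  out
}
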