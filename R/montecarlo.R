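## Deterministic seed streams: each cell gets a seed derived from the
## master seed and its grid coordinates, each iteration from the cell
## seed, so results are identical under any execution order.
.derive_seed <- function(master, i, j = 0L) {
  s <- (as.double(master) %% 2147483647) + 7919 * as.double(i) +
    104729 * as.double(j)
  as.integer(s %% 2147483629 + 1)
}

#' Monte-Carlo audit configuration
#'
#' Holds the study conditions for the spurious-association and recovery
#' audits: 1000 iterations of 1000-trial series with unit Gaussian noise,
#' stimuli uniform on `[0, 180)`, significance from the 95% amplitude CI.
#' The parameter grid spans amplitudes 0.25–5.00 (step 0.25) and inverse
#' widths 0.01–0.10 (step 0.01).
#'
#' @param n_iter Monte-Carlo iterations per cell. Default 1000.
#' @param n_trials Trials per simulated series. Default 1000.
#' @param lag n-back lag under test, 2–5. Default 2.
#' @param a_grid,w_grid Parameter grids for [run_grid()].
#' @param alpha CI level for the significance rule. Default 0.05.
#' @param master_seed Integer master seed.
#' @param corrected Apply the residualization correction before the
#'   n-back fit?
#' @param generator `"delta_s"`, `"delta_r"` or `"delta_rs"`.
#' @param true_2back [dog_params()] of a genuine 2-back stimulus term
#'   (recovery experiments; the reference truth is its amplitude).
#' @param noise_sd Trial noise sd. Default 1.
#' @param wrap_differences Wrap differences fed to the DoG? Default FALSE.
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(n_iter = 1000L, n_trials = 1000L, lag = 2L,
                      a_grid = seq(0.25, 5, by = 0.25),
                      w_grid = seq(0.01, 0.10, by = 0.01),
                      alpha = 0.05, master_seed = 1L, corrected = FALSE,
                      generator = c("delta_r", "delta_s", "delta_rs"),
                      true_2back = NULL, noise_sd = 1,
                      wrap_differences = FALSE) {
  generator <- match.arg(generator)
  if (n_iter < 1) stop("'n_iter' must be >= 1", call. = FALSE)
  if (lag < 2 || lag > 5) stop("'lag' must be in 2..5", call. = FALSE)
  if (!length(a_grid) || !length(w_grid))
    stop("parameter grids must be nonempty", call. = FALSE)
  if (generator == "delta_rs" && is.null(true_2back))
    stop("'true_2back' is required for the delta_rs generator",
         call. = FALSE)
  if (!is.null(true_2back)) true_2back <- as_dog_params(true_2back)
  structure(list(n_iter = as.integer(n_iter),
                 n_trials = as.integer(n_trials), lag = as.integer(lag),
                 a_grid = a_grid, w_grid = w_grid, alpha = alpha,
                 master_seed = as.integer(master_seed),
                 corrected = isTRUE(corrected), generator = generator,
                 true_2back = true_2back, noise_sd = noise_sd,
                 wrap_differences = isTRUE(wrap_differences)),
            class = "mc_config")
}

.cell_iterate <- function(config, gen_cfg_fn, decide_fn, seed) {
  k <- 0L; n_failed <- 0L
  for (it in seq_len(config$n_iter)) {
    cfg <- gen_cfg_fn(.derive_seed(seed, it))
    series <- simulate_series(cfg)
    hit <- tryCatch(decide_fn(series),
                    error = function(e) NA)
    if (is.na(hit)) n_failed <- n_failed + 1L   # counted non-significant
    else if (hit) k <- k + 1L
  }
  list(k = k, n_failed = n_failed)
}

#' Probability of a spurious n-back association
#'
#' Simulates series from a generator containing only a 1-back feedback
#' term, fits the lag-`N` stimulus DoG to each (raw, or after the
#' residualization correction), and returns the fraction of iterations
#' whose amplitude CI excludes zero — the spurious-significance
#' probability of the n-back analysis at these generator parameters.
#'
#' @param generator `"delta_s"` or `"delta_r"`.
#' @param params [dog_params()] of the 1-back feedback term.
#' @param lag n-back lag under test.
#' @param config An [mc_config()]; its `n_iter`, `n_trials`, `alpha`,
#'   `noise_sd`, `wrap_differences` and `corrected` fields are used.
#' @param seed Cell seed; defaults to the config's master seed.
#' @return An object of class `"cell_estimate"`: list with `a`, `w`, `p`,
#'   `k`, `n_iter`, `n_failed`.
#' @export
spurious_cell <- function(generator = c("delta_r", "delta_s"), params,
                          lag = 2L, config = mc_config(),
                          seed = config$master_seed) {
  generator <- match.arg(generator)
  params <- as_dog_params(params)
  corrected <- config$corrected
  wrap <- config$wrap_differences
  alpha <- config$alpha
  gen_fn <- function(s) generator_config(
    generator, params, n_trials = config$n_trials,
    noise_sd = config$noise_sd, seed = s,
    wrap_differences = wrap)
  decide <- if (corrected) {
    function(series) {
      cf <- corrected_fit(series, lag, wrap = wrap, alpha = alpha)
      if (!cf$stage1$converged || !cf$stage2$converged) return(NA)
      is_significant(cf$stage2)
    }
  } else {
    function(series) {
      f <- fit_dog(nback_design(series, lag, "stimulus", wrap = wrap),
                   alpha = alpha)
      if (!f$converged) return(NA)
      is_significant(f)
    }
  }
  r <- .cell_iterate(config, gen_fn, decide, seed)
  structure(list(a = params$a, w = params$w, p = r$k / config$n_iter,
                 k = r$k, n_iter = config$n_iter, n_failed = r$n_failed,
                 corrected = corrected, generator = generator, lag = lag),
            class = "cell_estimate")
}

#' Coverage of a true 2-back amplitude under response feedback
#'
#' Simulates the combined system (1-back response feedback plus a genuine
#' 2-back stimulus term), fits the 2-back stimulus DoG (raw or corrected),
#' and returns the fraction of iterations whose amplitude CI covers the
#' true 2-back amplitude. Uncorrected fits lose coverage because the slow
#' decay of the response feedback inflates the 2-back estimate.
#'
#' @param params_1back [dog_params()] of the 1-back response term.
#' @param true_2back [dog_params()] of the genuine 2-back stimulus term;
#'   its amplitude is the coverage target.
#' @param config An [mc_config()].
#' @param corrected Apply the residualization correction first?
#' @param seed Cell seed.
#' @return A `"cell_estimate"` (with `p` the coverage probability).
#' @export
recovery_cell <- function(params_1back, true_2back,
                          config = mc_config(), corrected = FALSE,
                          seed = config$master_seed) {
  params_1back <- as_dog_params(params_1back)
  true_2back <- as_dog_params(true_2back)
  target <- true_2back$a
  wrap <- config$wrap_differences
  alpha <- config$alpha
  gen_fn <- function(s) generator_config(
    "delta_rs", params_1back, params_2back = true_2back,
    n_trials = config$n_trials, noise_sd = config$noise_sd, seed = s,
    wrap_differences = wrap)
  decide <- if (corrected) {
    function(series) {
      cf <- corrected_fit(series, 2L, wrap = wrap, alpha = alpha)
      if (!cf$stage1$converged || !cf$stage2$converged) return(NA)
      ci <- cf$stage2$ci_a
      ci[1] <= target && target <= ci[2]
    }
  } else {
    function(series) {
      f <- fit_dog(nback_design(series, 2L, "stimulus", wrap = wrap),
                   alpha = alpha)
      if (!f$converged) return(NA)
      ci <- f$ci_a
      ci[1] <= target && target <= ci[2]
    }
  }
  r <- .cell_iterate(config, gen_fn, decide, seed)
  structure(list(a = params_1back$a, w = params_1back$w,
                 p = r$k / config$n_iter, k = r$k, n_iter = config$n_iter,
                 n_failed = r$n_failed, corrected = corrected,
                 generator = "delta_rs", lag = 2L, target = target),
            class = "cell_estimate")
}

#' @export
print.cell_estimate <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo cell (%s%s, lag %d): a = %g, w = %g -> p = %.3f (%d/%d%s)\n",
    x$generator, if (x$corrected) ", corrected" else "", x$lag, x$a, x$w,
    x$p, x$k, x$n_iter,
    if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

#' Odds and odds ratios of Monte-Carlo probabilities
#'
#' `odds(p) = p / (1 - p)`; `odds_ratio(p1, p2) = odds(p1) / odds(p2)`.
#' Degenerate probabilities 0 or 1 yield 0 or `Inf` with a warning.
#'
#' @param p,p1,p2 Proportions in `[0, 1]`.
#' @return Numeric scalar.
#' @export
#' @examples
#' odds_ratio(0.653, 0.249)
odds <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("'p' must be a proportion in [0, 1]", call. = FALSE)
  if (p == 0 || p == 1) {
    warning("degenerate proportion: odds are ", if (p == 0) "0" else "Inf",
            call. = FALSE)
    return(if (p == 0) 0 else Inf)
  }
  p / (1 - p)
}

#' @rdname odds
#' @export
odds_ratio <- function(p1, p2) odds(p1) / odds(p2)

#' Run a Monte-Carlo audit over an (a, w) grid
#'
#' Evaluates [spurious_cell()] (or [recovery_cell()] for the `"delta_rs"`
#' generator) at every grid point. Cell seeds are derived from the master
#' seed and the grid coordinates, so cells are independent and any
#' execution order yields identical results.
#'
#' @param config An [mc_config()].
#' @param progress Print one line per cell?
#' @return An object of class `"grid_result"`: data frame with columns
#'   `a`, `w`, `p`, `k`, `n_iter`, `n_failed` and the configuration in
#'   `attr(, "config")`.
#' @export
run_grid <- function(config = mc_config(), progress = FALSE) {
  stopifnot(inherits(config, "mc_config"))
  cells <- vector("list", length(config$a_grid) * length(config$w_grid))
  idx <- 0L
  for (i in seq_along(config$a_grid)) {
    for (j in seq_along(config$w_grid)) {
      idx <- idx + 1L
      seed <- .derive_seed(config$master_seed, i, j)
      cell <- if (config$generator == "delta_rs") {
        recovery_cell(dog_params(config$a_grid[i], config$w_grid[j]),
                      config$true_2back, config,
                      corrected = config$corrected, seed = seed)
      } else {
        spurious_cell(config$generator,
                      dog_params(config$a_grid[i], config$w_grid[j]),
                      config$lag, config, seed = seed)
      }
      if (progress) print(cell)
      cells[[idx]] <- data.frame(a = cell$a, w = cell$w, p = cell$p,
                                 k = cell$k, n_iter = cell$n_iter,
                                 n_failed = cell$n_failed)
    }
  }
  out <- do.call(rbind, cells)
  attr(out, "config") <- config
  class(out) <- c("grid_result", "data.frame")
  out
}

#' @export
print.grid_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Monte-Carlo grid (%s%s, lag %d): %d cells, %d iterations each\n",
    cfg$generator, if (cfg$corrected) ", corrected" else "", cfg$lag,
    nrow(x), cfg$n_iter))
  cat(sprintf("  max p = %.3f at a = %g, w = %g\n",
              max(x$p), x$a[which.max(x$p)], x$w[which.max(x$p)]))
  cat(sprintf("  min p = %.3f at a = %g, w = %g\n",
              min(x$p), x$a[which.min(x$p)], x$w[which.min(x$p)]))
  invisible(x)
}

#' Write a grid result as CSV
#'
#' Long format (`a, w, p, k, n_iter, n_failed`), plus an optional
#' wide-matrix CSV (rows = a, columns = w) for heatmapping, plus a JSON
#' echo of the configuration.
#'
#' @param grid A `"grid_result"`.
#' @param path Output CSV path.
#' @param matrix_path Optional path for the wide-format CSV.
#' @export
write_grid_csv <- function(grid, path, matrix_path = NULL) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  cfg <- attr(grid, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(
      list(n_iter = cfg$n_iter, n_trials = cfg$n_trials, lag = cfg$lag,
           a_grid = cfg$a_grid, w_grid = cfg$w_grid, alpha = cfg$alpha,
           master_seed = cfg$master_seed, corrected = cfg$corrected,
           generator = cfg$generator,
           true_2back = if (is.null(cfg$true_2back)) NULL
                        else unclass(cfg$true_2back)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  if (!is.null(matrix_path)) {
    m <- stats::xtabs(p ~ a + w, data = as.data.frame(grid))
    utils::write.csv(as.data.frame.matrix(m), matrix_path)
  }
  invisible(path)
}
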