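#' Read / write the standard trial CSV
#'
#' The trial CSV is comma-separated UTF-8 with a header and columns
#' `subject, block, trial, stimulus, response` (degrees, stimulus in
#' `[0, 180)`). Reading computes the wrapped error and the usable flag;
#' writing emits exactly the five input columns, so the pair round-trips.
#'
#' @param path CSV path.
#' @param table A `"trial_table"`.
#' @return `read_trials_csv` returns a `"trial_table"`.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  as_trial_table(df)
}

#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(table, path) {
  need <- c("subject", "block", "trial", "stimulus", "response")
  if (!all(need %in% names(table)))
    stop("table lacks the standard columns", call. = FALSE)
  utils::write.csv(as.data.frame(table)[, need], path, row.names = FALSE)
  invisible(path)
}

.cli_usage <- function() {
  cat("usage: serialdep <subcommand> [--flag value ...]\n",
      "subcommands:\n",
      "  impulse    --model dS|dR --a A --w W [--steps N]\n",
      "  simulate   --model dS|dR|dRS --a A --w W [--a2 A2 --w2 W2]\n",
      "             [--n-trials N --noise-sd SD --seed S] --out FILE.csv\n",
      "  audit      [--generator dS|dR --lag L --corrected --a-grid a1,a2,..\n",
      "             --w-grid w1,w2,.. --n-iter I --n-trials N --seed S] --out FILE.csv\n",
      "  recovery   [--a A --w W --a2 A2 --w2 W2 --corrected --n-iter I --seed S]\n",
      "             --out FILE.json\n",
      "  reanalyze  --data trials.csv [--lag L --permutations B --seed S] --out FILE.json\n",
      "  genfixture [--subjects K --blocks B --trials-per-block T --a0 A\n",
      "             --w W --seed S] --out FILE.csv\n", sep = "")
}

.parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE                # bare flag
      i <- i + 1L
    }
  }
  out
}

.flag_num <- function(flags, key, default = NULL) {
  v <- flags[[key]]
  if (is.null(v)) {
    if (is.null(default)) stop("missing required flag --",
                               gsub("_", "-", key), call. = FALSE)
    return(default)
  }
  as.numeric(v)
}

.flag_model <- function(flags, allow_rs = TRUE) {
  m <- flags[["model"]]
  if (is.null(m)) stop("missing required flag --model", call. = FALSE)
  full <- switch(m, dS = "delta_s", dR = "delta_r", dRS = "delta_rs",
                 stop("unknown model: ", m, " (use dS, dR or dRS)",
                      call. = FALSE))
  if (!allow_rs && full == "delta_rs")
    stop("model dRS is not supported by this subcommand", call. = FALSE)
  full
}

.flag_grid <- function(flags, key, default) {
  v <- flags[[key]]
  if (is.null(v)) return(default)
  as.numeric(strsplit(v, ",")[[1]])
}

#' Command-line entry point
#'
#' A thin dispatcher over the package's functions, also installed as the
#' `serialdep` script under `inst/cli/`. Subcommands: `impulse`
#' (noise-free impulse response), `simulate` (one generator run to CSV),
#' `audit` (spurious-association Monte-Carlo grid to CSV), `recovery`
#' (coverage of a true 2-back amplitude to JSON), `reanalyze`
#' (preprocess + two-stage mixed-effects + permutation test of a trial
#' CSV to JSON), and `genfixture` (synthetic cohort to CSV). Every
#' output is accompanied by the resolved configuration, and identical
#' arguments and seed reproduce identical files.
#'
#' @param args Character vector of command-line arguments (e.g.,
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 on success, 1 on usage or
#'   runtime error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) { .cli_usage(); return(invisible(1L)) }
    sub <- args[1L]
    flags <- .parse_flags(args[-1L])
    switch(sub,
      impulse = .cli_impulse(flags),
      simulate = .cli_simulate(flags),
      audit = .cli_audit(flags),
      recovery = .cli_recovery(flags),
      reanalyze = .cli_reanalyze(flags),
      genfixture = .cli_genfixture(flags),
      { message("unknown subcommand: ", sub); .cli_usage(); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(as.integer(status))
}

.cli_impulse <- function(flags) {
  model <- .flag_model(flags, allow_rs = FALSE)
  y <- impulse_response(model,
                        dog_params(.flag_num(flags, "a"),
                                   .flag_num(flags, "w")),
                        n_steps = .flag_num(flags, "steps", 4))
  cat(sprintf("%.2f", y), sep = "\n")
  0L
}

.cli_simulate <- function(flags) {
  model <- .flag_model(flags)
  p2 <- if (model == "delta_rs")
    dog_params(.flag_num(flags, "a2"), .flag_num(flags, "w2"))
  cfg <- generator_config(
    model, dog_params(.flag_num(flags, "a"), .flag_num(flags, "w")),
    params_2back = p2,
    n_trials = .flag_num(flags, "n_trials", 1000),
    noise_sd = .flag_num(flags, "noise_sd", 1),
    seed = .flag_num(flags, "seed", 1))
  out <- flags[["out"]]
  if (is.null(out)) stop("missing required flag --out", call. = FALSE)
  write_series_csv(simulate_series(cfg), out)
  message("wrote ", out, " (+ .json sidecar)")
  0L
}

.cli_audit <- function(flags) {
  gen <- if (is.null(flags[["generator"]])) "delta_r"
         else switch(flags[["generator"]], dS = "delta_s",
                     dR = "delta_r",
                     stop("audit supports generators dS and dR",
                          call. = FALSE))
  cfg <- mc_config(
    n_iter = .flag_num(flags, "n_iter", 1000),
    n_trials = .flag_num(flags, "n_trials", 1000),
    lag = .flag_num(flags, "lag", 2),
    a_grid = .flag_grid(flags, "a_grid", seq(0.25, 5, by = 0.25)),
    w_grid = .flag_grid(flags, "w_grid", seq(0.01, 0.1, by = 0.01)),
    master_seed = .flag_num(flags, "seed", 1),
    corrected = isTRUE(flags[["corrected"]]), generator = gen)
  out <- flags[["out"]]
  if (is.null(out)) stop("missing required flag --out", call. = FALSE)
  write_grid_csv(run_grid(cfg), out)
  message("wrote ", out, " (+ .json config echo)")
  0L
}

.cli_recovery <- function(flags) {
  cfg <- mc_config(
    n_iter = .flag_num(flags, "n_iter", 1000),
    n_trials = .flag_num(flags, "n_trials", 1000),
    master_seed = .flag_num(flags, "seed", 1),
    generator = "delta_rs",
    true_2back = dog_params(.flag_num(flags, "a2", 5),
                            .flag_num(flags, "w2", 0.04)))
  cell <- recovery_cell(
    dog_params(.flag_num(flags, "a", 5), .flag_num(flags, "w", 0.04)),
    cfg$true_2back, cfg, corrected = isTRUE(flags[["corrected"]]))
  out <- flags[["out"]]
  if (is.null(out)) stop("missing required flag --out", call. = FALSE)
  jsonlite::write_json(unclass(cell), out, auto_unbox = TRUE,
                       digits = NA)
  print(cell)
  0L
}

.cli_reanalyze <- function(flags) {
  data <- flags[["data"]]
  if (is.null(data)) stop("missing required flag --data", call. = FALSE)
  res <- reanalyze(read_trials_csv(data),
                   lag = .flag_num(flags, "lag", 2),
                   B = .flag_num(flags, "permutations", 1000),
                   seed = .flag_num(flags, "seed", 1))
  out <- flags[["out"]]
  if (is.null(out)) stop("missing required flag --out", call. = FALSE)
  a <- res$analysis
  jsonlite::write_json(
    list(a0_stage1 = a$stage1$a0, ci_stage1 = a$stage1$ci_a0,
         a0_corrected = a$stage2$a0, ci_corrected = a$stage2$ci_a0,
         a0_reference = a$reference$a0, ci_reference = a$reference$ci_a0,
         permutation_p = if (is.null(res$permutation)) NULL
                         else res$permutation$p_value,
         permutations = if (is.null(res$permutation)) NULL
                        else res$permutation$B,
         preprocessing = attr(res$table, "report")),
    out, auto_unbox = TRUE, digits = NA, null = "null",
    dataframe = "rows")
  print(a)
  0L
}

.cli_genfixture <- function(flags) {
  cfg <- cohort_config(
    n_subjects = .flag_num(flags, "subjects", 4),
    n_blocks = .flag_num(flags, "blocks", 10),
    trials_per_block = .flag_num(flags, "trials_per_block", 80),
    a0 = .flag_num(flags, "a0", 2), w = .flag_num(flags, "w", 0.05),
    seed = .flag_num(flags, "seed", 1))
  out <- flags[["out"]]
  if (is.null(out)) stop("missing required flag --out", call. = FALSE)
  write_fixture(generate_cohort(cfg), out)
  message("wrote ", out, " (+ .json sidecar)")
  0L
}
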