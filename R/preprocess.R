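#' Wrap an angle difference into a half-open interval
#'
#' Orientation lives on a 180-degree circle, so differences are wrapped
#' into `(-half_period, half_period]` (default `(-90, 90]`).
#'
#' @param x Numeric vector of differences (degrees). NAs pass through.
#' @param half_period Half of the period; default 90.
#' @return Wrapped values in `(-half_period, half_period]`.
#' @export
#' @examples
#' wrap_deg(c(160, -90, 45))   # -20, 90, 45
wrap_deg <- function(x, half_period = 90) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  m <- x %% (2 * half_period)
  m[!is.na(m) & m > half_period] <- m[!is.na(m) & m > half_period] -
    2 * half_period
  m
}

#' Construct a subject trial table
#'
#' The standard container for empirical (or synthetic) orientation
#' reproduction data: one row per trial with subject and block
#' identifiers, the within-block trial index, stimulus and response
#' orientations in degrees, the wrapped error `wrap_deg(response -
#' stimulus)`, and a `usable` flag manipulated by the preprocessing steps.
#'
#' @param df Data frame with columns `subject`, `block`, `trial`,
#'   `stimulus`, `response` (degrees; stimulus in `[0, 180)`).
#' @return A `data.frame` of class `"trial_table"` with added `error` and
#'   `usable` columns, ordered by subject, block, trial.
#' @export
as_trial_table <- function(df) {
  need <- c("subject", "block", "trial", "stimulus", "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("trial", "stimulus", "response")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d", col,
                   bad[1]), call. = FALSE)
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(df$stimulus < 0 | df$stimulus >= 180)
  if (length(bad))
    stop(sprintf("stimulus out of [0, 180) at row %d (value %g)", bad[1],
                 df$stimulus[bad[1]]), call. = FALSE)
  out <- df[order(df$subject, df$block, df$trial),
            c("subject", "block", "trial", "stimulus", "response")]
  dup <- duplicated(out[, c("subject", "block", "trial")])
  if (any(dup))
    stop("trial indices must be unique within subject and block",
         call. = FALSE)
  out$error <- wrap_deg(out$response - out$stimulus)
  out$usable <- TRUE
  out$pred_ok <- TRUE
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

#' @export
print.trial_table <- function(x, n = 6L, ...) {
  cat(sprintf("Trial table: %d trials, %d subject(s), %d usable\n",
              nrow(x), length(unique(x$subject)), sum(x$usable)))
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

.split_subject <- function(table) split(seq_len(nrow(table)), table$subject)

#' Remove systematic orientation biases from the errors
#'
#' Observers carry idiosyncratic, stimulus-dependent biases (e.g., around
#' the cardinal orientations). Per subject, a polynomial of the stated
#' degree is fit by least squares to the usable errors as a function of
#' stimulus orientation, and the errors are replaced by the residuals of
#' that fit.
#'
#' @param table A `"trial_table"`.
#' @param degree Polynomial degree; default 9.
#' @return The table with the `error` column debiased.
#' @export
debias_errors <- function(table, degree = 9L) {
  stopifnot(inherits(table, "trial_table"))
  for (sub in names(idx <- .split_subject(table))) {
    rows <- idx[[sub]]
    use <- rows[table$usable[rows]]
    if (length(use) <= degree + 1L)
      stop(sprintf(
        "subject '%s' has %d usable trials; need more than %d for a degree-%d fit",
        sub, length(use), degree + 1L, degree), call. = FALSE)
    basis <- stats::poly(table$stimulus[use], degree)
    fit <- stats::lm.fit(cbind(1, basis), table$error[use])
    pred_all <- drop(cbind(1, stats::predict(basis,
                                             table$stimulus[rows])) %*%
                       fit$coefficients)
    table$error[rows] <- table$error[rows] - pred_all
  }
  table
}

#' Flag outlier trials and their followers
#'
#' Per subject, trials whose (debiased) error lies further than `k`
#' standard deviations from the subject mean are marked unusable, along
#' with the immediately following trial in the same block (whose 1-back
#' predictor is contaminated). Statistics are computed over all of the
#' subject's errors, so the operation is idempotent. Flagged trials are
#' also barred from serving as lagged predictors (`pred_ok = FALSE`);
#' block-start trimming, by contrast, removes trials as outcomes only.
#'
#' @param table A `"trial_table"` (errors debiased first, by convention).
#' @param k Threshold in standard deviations; default 3.
#' @return The table with outliers and followers marked `usable = FALSE`.
#' @export
flag_outliers <- function(table, k = 3) {
  stopifnot(inherits(table, "trial_table"))
  for (rows in .split_subject(table)) {
    e <- table$error[rows]
    m <- mean(e); s <- stats::sd(e)
    if (!is.finite(s) || s == 0) next
    out <- which(abs(e - m) > k * s)
    for (o in out) {
      table$usable[rows[o]] <- FALSE
      table$pred_ok[rows[o]] <- FALSE
      nxt <- o + 1L
      if (nxt <= length(rows) &&
          table$block[rows[nxt]] == table$block[rows[o]]) {
        table$usable[rows[nxt]] <- FALSE
        table$pred_ok[rows[nxt]] <- FALSE
      }
    }
  }
  table
}

#' Drop the first trials of every block
#'
#' Trials at the start of a block have undefined (or contaminated) lagged
#' predictors; the first `n_trim` trials of every block are marked
#' unusable as outcomes. They may still serve as lagged predictors for
#' later trials.
#'
#' @param table A `"trial_table"`.
#' @param n_trim Number of leading trials to drop per block; default 2
#'   (the maximum lag analyzed).
#' @return The table with block-start trials marked `usable = FALSE`.
#' @export
trim_block_starts <- function(table, n_trim = 2L) {
  stopifnot(inherits(table, "trial_table"))
  if (n_trim < 1) stop("'n_trim' must be >= 1", call. = FALSE)
  blocks <- split(seq_len(nrow(table)), list(table$subject, table$block),
                  drop = TRUE)
  if (n_trim >= min(lengths(blocks)))
    stop("'n_trim' must be smaller than the shortest block",
         call. = FALSE)
  for (rows in blocks)
    table$usable[rows[seq_len(min(n_trim, length(rows)))]] <- FALSE
  table
}

#' Full preprocessing pipeline
#'
#' Applies, in order: polynomial debiasing of the errors, outlier
#' flagging with followers, and block-start trimming. A per-subject
#' report of removed-trial counts is attached as `attr(, "report")`.
#'
#' @param table A `"trial_table"`.
#' @param degree Debiasing polynomial degree. Default 9.
#' @param k Outlier threshold in sd units. Default 3.
#' @param n_trim Block-start trials to drop. Default 2.
#' @return The preprocessed table.
#' @export
preprocess <- function(table, degree = 9L, k = 3, n_trim = 2L) {
  table <- debias_errors(table, degree)
  before <- table$usable
  table <- flag_outliers(table, k)
  out_removed <- tapply(before & !table$usable, table$subject, sum)
  before <- table$usable
  table <- trim_block_starts(table, n_trim)
  trim_removed <- tapply(before & !table$usable, table$subject, sum)
  attr(table, "report") <- data.frame(
    subject = names(out_removed),
    outlier_and_follower = as.integer(out_removed),
    block_start = as.integer(trim_removed),
    usable = as.integer(tapply(table$usable, table$subject, sum)))
  table
}

#' Write a preprocessing report as JSON
#'
#' @param table A preprocessed `"trial_table"` (from [preprocess()]).
#' @param path Output path.
#' @export
write_preprocess_report <- function(table, path) {
  rep <- attr(table, "report")
  if (is.null(rep)) stop("table carries no preprocessing report",
                         call. = FALSE)
  jsonlite::write_json(rep, path, dataframe = "rows", digits = NA)
  invisible(path)
}
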