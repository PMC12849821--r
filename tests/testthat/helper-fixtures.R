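## Shared helpers: small deterministic objects built in code.

noiseless_series <- function(model = "delta_s", a = 4.8, w = 0.03,
                             n = 500, seed = 11) {
  simulate_series(generator_config(model, dog_params(a, w),
                                   n_trials = n, noise_sd = 0,
                                   seed = seed))
}

## A minimal hand-built trial table: `blocks` blocks of `n` trials each,
## errors supplied by `err_fn(stimulus)` plus optional explicit values.
toy_table <- function(n = 50, blocks = 1, subjects = "S1", seed = 5,
                      err_fn = function(x) rep(0, length(x))) {
  set.seed(seed)
  rows <- list()
  for (s in subjects) for (b in seq_len(blocks)) {
    x <- runif(n, 0, 180)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, block = b, trial = seq_len(n), stimulus = x,
      response = x + err_fn(x))
  }
  as_trial_table(do.call(rbind, rows))
}
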