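# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk.

# small fully-shared cohort: every stimulus seen by every subject
tiny_config <- function(n_subjects = 2L, n_regions = 1L, n_stimuli = 40L,
                        feature_dim = 6L, noise_sd = 0.5, repeats = 2L,
                        idiosyncratic_signal_sd = 0.3, seed = 1L, ...) {
  synthetic_config(n_subjects = n_subjects, n_regions = n_regions,
                   n_stimuli = n_stimuli, n_shared_stimuli = n_stimuli,
                   feature_dim = feature_dim, noise_sd = noise_sd,
                   repeats = repeats,
                   idiosyncratic_signal_sd = idiosyncratic_signal_sd,
                   seed = seed, ...)
}

# hand-built 2-subject, 1-region, 4-stimulus cohort (8 records)
toy_cohort <- function() {
  st <- stimulus_set(paste0("s", 1:4), matrix(seq_len(8) / 4, 4, 2),
                     shared = TRUE)
  resp <- expand.grid(subject_id = c("a", "b"), region_id = "R",
                      stimulus_id = paste0("s", 1:4),
                      repeat_index = 0L, stringsAsFactors = FALSE)
  resp$response <- seq_len(nrow(resp)) / 2
  cohort(st, resp)
}

# random readout for a given dimension
random_readout <- function(subject_id, region_id, d, seed) {
  set.seed(seed)
  readout_model(subject_id, region_id, rnorm(d), rnorm(1))
}

# closed-form least squares with intercept
ols_oracle <- function(x, y) {
  xm <- cbind(1, x)
  drop(solve(crossprod(xm), crossprod(xm, y)))
}
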