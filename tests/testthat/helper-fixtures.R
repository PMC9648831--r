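# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small two-class cohort used by several integration tests
small_cohort <- function() {
  cached("small_cohort", function() {
    generate_cohort(cohort_config(n_subjects = 4L, n_trials_per_subject = 4L,
                                  effect_size = 1.0, seed = 101L))
  })
}

small_prep <- function() {
  cached("small_prep", function() prepare_dataset(small_cohort(), seed = 7L))
}

# wrap a raw channels x samples matrix as a recording
make_recording <- function(signal, sampling_rate = 500,
                           trigger_index = 1L, subject_id = "SX",
                           trial_id = "SX_T01", score = 8L) {
  structure(list(subject_id = subject_id, trial_id = trial_id,
                 cream_id = 1L, score = score, signal = signal,
                 sampling_rate = sampling_rate,
                 trigger_index = as.integer(trigger_index)),
            class = "eeg_recording")
}

# single-channel sinusoid recording
sine_recording <- function(freq, duration = 10, fs = 500, amp = 1,
                           nch = 1L) {
  t <- seq_len(duration * fs) / fs
  x <- matrix(rep(amp * sin(2 * pi * freq * t), each = nch), nrow = nch)
  rownames(x) <- paste0("ch", seq_len(nch))
  make_recording(x, fs, trigger_index = as.integer(duration * fs / 2))
}

# synthetic spectrogram with arbitrary power content
fake_spectrogram <- function(power, time_axis, freq_axis = 1:120,
                             trial_id = "SX_T01") {
  structure(list(power = power, freq_axis = freq_axis,
                 time_axis = time_axis,
                 channel_names = dimnames(power)[[1]],
                 subject_id = "SX", trial_id = trial_id, cream_id = 1L,
                 score = 8L),
            class = "eeg_spectrogram")
}

# feature array shaped like featurize_recording() output, with metadata;
# values random but reproducible
fake_features <- function(subject_id, trial_id, score, n_windows = 28L,
                          seed = 1L, values = NULL) {
  f <- if (is.null(values)) {
    withr::with_seed(seed,
      array(stats::runif(4 * 19 * n_windows, 0.5, 1.5),
            c(4, 19, n_windows)))
  } else array(values, c(4, 19, n_windows))
  dimnames(f) <- list(eeg_bands()$name, eeg_channels(), NULL)
  structure(f, subject_id = subject_id, trial_id = trial_id, score = score)
}

# a subject's worth of fake features: one element per trial score
fake_subject_features <- function(subject_id, scores, n_windows = 28L,
                                  seed = 1L) {
  lapply(seq_along(scores), function(i) {
    fake_features(subject_id, sprintf("%s_T%02d", subject_id, i),
                  scores[i], n_windows, seed = seed + i)
  })
}

# brute-force sliding-majority oracle (replicate padding), independent of
# the implementation under test
majority_filter_oracle <- function(x, kernel) {
  n <- length(x)
  h <- (kernel - 1) %/% 2
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  vapply(seq_len(n), function(i) {
    win <- xp[i:(i + kernel - 1)]
    as.integer(sum(win == 1) > length(win) / 2)
  }, integer(1))
}
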