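#' Canonical 19-channel 10-20 montage
#'
#' The electrode set used throughout the package, in canonical order:
#' prefrontal to occipital, left to right. T5/T6 are the classical names of
#' the posterior temporal sites (P7/P8 in the modern nomenclature).
#'
#' @return Character vector of 19 channel labels.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' Configuration for a synthetic cream-application EEG cohort
#'
#' Defines the statistical structure of a simulated study: per-subject trials
#' of 19-channel EEG around an application trigger, a 1/f-type background
#' with an alpha rhythm, 60 Hz line contamination, per-subject gain/offset
#' domain shift, and a class-dependent band-power effect confined to the
#' 0--30 s application span.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_trials_per_subject Trials per subject; the study protocol is 8
#'   (4 creams x 2 sessions).
#' @param sampling_rate Sampling rate in Hz; must exceed twice the highest
#'   analyzed frequency (120 Hz).
#' @param segment_span Two-element numeric, seconds relative to the trigger
#'   that every recording must cover (default -15..55).
#' @param channel_names Channel labels; default [eeg_channels()].
#' @param effect_size Dimensionless multiplier on class-dependent band power:
#'   positive-scored trials carry band power multiplied by `1 + effect_size`
#'   in `effect_band` on `effect_channels` during 0--30 s.
#' @param effect_global_frac Fraction of `effect_size` expressed as a
#'   broadband power increase on every channel during the application span
#'   (default 0.15). Emotional state modulates spectral power diffusely
#'   across the scalp, not only at the focal sites, and this diffuse
#'   component is what keeps the per-subject two-class baseline correction
#'   well conditioned (the class-conditional means it divides by must differ
#'   at every cell, as they do in real recordings). Scales with
#'   `effect_size`, so a null cohort (`effect_size = 0`) carries no class
#'   information anywhere.
#' @param effect_band One of `"alpha"`, `"beta"`, `"low_gamma"`,
#'   `"high_gamma"`.
#' @param effect_channels Subset of `channel_names` carrying the effect;
#'   default is a fronto-temporal set.
#' @param subject_gain_sd SD of the log-normal per-subject, per-channel
#'   multiplicative gain (log scale).
#' @param subject_offset_sd SD (muV) of the per-subject, per-channel additive
#'   DC offset.
#' @param line_noise_amp Amplitude (muV) of the 60 Hz line component.
#' @param background_rms Target RMS (muV) of the 1/f background.
#' @param alpha_rms Target RMS (muV) of the 10 Hz alpha bump component.
#' @param score_model `"balanced"` (creams 1-2 disliked, creams 3-4 liked,
#'   giving each subject both classes), `"random"` (each trial positive with
#'   probability 1/2), or a function `(subject, trial, cream) -> score 1..9`.
#' @param seed Master integer seed; per-subject and per-trial streams are
#'   derived from it so generation order never matters.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 16L,
                          n_trials_per_subject = 8L,
                          sampling_rate = 500,
                          segment_span = c(-15, 55),
                          channel_names = eeg_channels(),
                          effect_size = 1.0,
                          effect_band = "low_gamma",
                          effect_channels = c("Fp1", "Fp2", "F7", "F8", "T3", "T4"),
                          effect_global_frac = 0.15,
                          subject_gain_sd = 0.3,
                          subject_offset_sd = 5,
                          line_noise_amp = 2,
                          background_rms = 10,
                          alpha_rms = 3,
                          score_model = "balanced",
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials_per_subject = as.integer(n_trials_per_subject),
              sampling_rate = sampling_rate,
              segment_span = segment_span,
              channel_names = channel_names,
              effect_size = effect_size,
              effect_band = effect_band,
              effect_channels = effect_channels,
              effect_global_frac = effect_global_frac,
              subject_gain_sd = subject_gain_sd,
              subject_offset_sd = subject_offset_sd,
              line_noise_amp = line_noise_amp,
              background_rms = background_rms,
              alpha_rms = alpha_rms,
              score_model = score_model,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects < 2L)
    stop("invalid cohort config: 'n_subjects' must be >= 2", call. = FALSE)
  if (cfg$n_trials_per_subject < 1L)
    stop("invalid cohort config: 'n_trials_per_subject' must be >= 1", call. = FALSE)
  if (cfg$sampling_rate <= 2 * 120)
    stop("invalid cohort config: 'sampling_rate' must exceed 240 Hz (2 x 120 Hz)",
         call. = FALSE)
  if (length(cfg$segment_span) != 2L || diff(cfg$segment_span) <= 0)
    stop("invalid cohort config: 'segment_span' must be an increasing pair",
         call. = FALSE)
  if (!cfg$effect_band %in% c("alpha", "beta", "low_gamma", "high_gamma"))
    stop("invalid cohort config: 'effect_band' must be one of alpha/beta/low_gamma/high_gamma",
         call. = FALSE)
  if (!all(cfg$effect_channels %in% cfg$channel_names))
    stop("invalid cohort config: 'effect_channels' must be a subset of 'channel_names'",
         call. = FALSE)
  if (cfg$effect_size < 0)
    stop("invalid cohort config: 'effect_size' must be >= 0", call. = FALSE)
  if (is.character(cfg$score_model) &&
      !cfg$score_model %in% c("balanced", "random"))
    stop("invalid cohort config: 'score_model' must be \"balanced\", \"random\" or a function",
         call. = FALSE)
  invisible(cfg)
}

# Counter-based seed derivation on a 31-bit modulus; all intermediates stay
# below 2^53 so double arithmetic is exact.
derive_seed <- function(...) {
  h <- 0
  for (x in c(...)) h <- (h * 69069 + as.numeric(x) + 1) %% 2147483563
  as.integer(h)
}

# run `expr` in an isolated RNG stream seeded with `seed`
with_rng_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# continuous band edges used by the generator (Hz); featurization applies its
# own 1 Hz bin convention on top of the same edges
band_edges <- function(band) {
  switch(band,
         alpha      = c(7, 15),
         beta       = c(15, 33),
         low_gamma  = c(33, 70),
         high_gamma = c(70, 120),
         stop("unknown band: ", band, call. = FALSE))
}

# Synthesize a Gaussian process in the frequency domain from an amplitude
# profile A(f) defined on the rfft grid; returns a real series of length n.
# The profile is calibrated by the caller; E[var(x)] = 4 * sum(A^2) / n^2.
freq_domain_noise <- function(n, amp) {
  nh <- n %/% 2L
  z <- complex(real = stats::rnorm(nh - 1L), imaginary = stats::rnorm(nh - 1L)) *
    amp[2:nh]
  spec <- complex(length.out = n)
  spec[2:nh] <- z
  spec[nh + 1L] <- complex(real = stats::rnorm(1L)) * amp[nh + 1L]
  spec[n:(nh + 2L)] <- Conj(spec[2:nh])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# expected sd of freq_domain_noise for a given profile
profile_sd <- function(n, amp) {
  nh <- n %/% 2L
  sqrt(4 * sum(amp[2:nh]^2) + amp[nh + 1L]^2) / n
}

# amplitude profiles on the rfft frequency grid
background_profile <- function(f, chi = 1) 1 / pmax(f, 0.5)^(chi / 2)
alpha_profile <- function(f) exp(-(f - 10)^2 / (2 * 1.5^2))

synth_trial_signal <- function(cfg, n, fs, positive, t_rel) {
  nh <- n %/% 2L
  f <- (0:nh) * fs / n
  a_bg <- background_profile(f)
  a_bg <- a_bg * cfg$background_rms / profile_sd(n, a_bg)
  a_al <- alpha_profile(f)
  a_al <- a_al * cfg$alpha_rms / profile_sd(n, a_al)
  amp <- sqrt(a_bg^2 + a_al^2)  # power profiles add

  nch <- length(cfg$channel_names)
  x <- matrix(0, nrow = nch, ncol = n,
              dimnames = list(cfg$channel_names, NULL))
  for (ch in seq_len(nch)) x[ch, ] <- freq_domain_noise(n, amp)

  # 60 Hz line contamination, common phase across channels
  phi <- stats::runif(1L, 0, 2 * pi)
  x <- x + matrix(cfg$line_noise_amp * sin(2 * pi * 60 * t_rel + phi),
                  nrow = nch, ncol = n, byrow = TRUE)

  # Class-dependent power elevation, gated to the 0-30 s application span:
  # a focal band-limited component on the effect channels plus a diffuse
  # broadband component on every channel, partitioned so that in-band power
  # on the effect channels is multiplied by (1 + effect_size) in total.
  if (positive && cfg$effect_size > 0) {
    gate <- as.numeric(t_rel >= 0 & t_rel < 30)
    g_frac <- min(cfg$effect_global_frac, 1)
    edges <- band_edges(cfg$effect_band)
    in_band <- f >= edges[1] & f < edges[2]
    a_focal <- amp * in_band * sqrt(cfg$effect_size * (1 - g_frac))
    a_diffuse <- amp * sqrt(cfg$effect_size * g_frac)
    for (ch in seq_len(nch)) {
      add <- freq_domain_noise(n, a_diffuse)
      if (rownames(x)[ch] %in% cfg$effect_channels)
        add <- add + freq_domain_noise(n, a_focal)
      x[ch, ] <- x[ch, ] + gate * add
    }
  }
  x
}

draw_score <- function(cfg, subject, trial, cream) {
  if (is.function(cfg$score_model)) {
    s <- cfg$score_model(subject, trial, cream)
    if (!s %in% 1:9) stop("score_model must return an integer 1..9", call. = FALSE)
    return(as.integer(s))
  }
  positive <- switch(cfg$score_model,
                     balanced = cream >= 3,
                     random = stats::runif(1L) < 0.5)
  if (positive) sample(8:9, 1L) else sample(1:4, 1L)
}

generate_trial <- function(cfg, subject_index, trial, gain, offset,
                           subject_id) {
  fs <- cfg$sampling_rate
  pre  <- ceiling(-cfg$segment_span[1]) + 1  # 1 s margin each side
  post <- ceiling(cfg$segment_span[2]) + 1
  n <- as.integer((pre + post) * fs)
  trigger_index <- as.integer(pre * fs) + 1L
  t_rel <- (seq_len(n) - trigger_index) / fs
  cream <- ((trial - 1L) %% 4L) + 1L

  with_rng_stream(derive_seed(cfg$seed, subject_index, trial), {
    score <- draw_score(cfg, subject_index, trial, cream)
    positive <- score >= 8L
    x <- synth_trial_signal(cfg, n, fs, positive, t_rel)
    x <- x * gain + offset  # per-subject domain shift
    structure(list(subject_id = subject_id,
                   trial_id = sprintf("%s_T%02d", subject_id, trial),
                   cream_id = cream,
                   score = as.integer(score),
                   signal = x,
                   sampling_rate = fs,
                   trigger_index = trigger_index),
              class = "eeg_recording")
  })
}

subject_shift <- function(cfg, subject_index) {
  with_rng_stream(derive_seed(cfg$seed, subject_index, 0L), {
    nch <- length(cfg$channel_names)
    list(gain = exp(stats::rnorm(nch, 0, cfg$subject_gain_sd)),
         offset = stats::rnorm(nch, 0, cfg$subject_offset_sd))
  })
}

#' Generate a synthetic EEG cohort
#'
#' Produces `n_subjects * n_trials_per_subject` recordings with the structure
#' described in [cohort_config()]. Positive-scored trials carry elevated band
#' power in the configured band and channels during the 0--30 s application
#' span; each subject has a fixed per-channel gain and offset applied to all
#' its recordings. Identical config and seed give bit-identical output,
#' independent of generation order.
#'
#' @param config A [cohort_config()].
#' @return A list of `eeg_recording` objects with class `eeg_cohort`; the
#'   config is attached as attribute `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  recs <- list()
  for (s in seq_len(config$n_subjects)) {
    subject_id <- sprintf("S%02d", s)
    shift <- subject_shift(config, s)
    for (tr in seq_len(config$n_trials_per_subject)) {
      recs[[length(recs) + 1L]] <-
        generate_trial(config, s, tr, shift$gain, shift$offset, subject_id)
    }
  }
  structure(recs, class = "eeg_cohort", config = config)
}

#' Generate a single-class subject
#'
#' Fixture for the subject-exclusion rule: all trials of the generated
#' subject map to one class (scores in 8--9 for positive, 1--4 for negative).
#'
#' @param config A [cohort_config()].
#' @param class_label `"positive"` or `"negative"`.
#' @param subject_index Integer stream index for the subject (default
#'   `n_subjects + 1` so it never collides with [generate_cohort()]).
#' @param subject_id Label for the subject.
#' @return List of `eeg_recording` objects for one subject.
#' @export
generate_single_class_subject <- function(config, class_label,
                                          subject_index = config$n_subjects + 1L,
                                          subject_id = sprintf("S%02d", subject_index)) {
  stopifnot(inherits(config, "cohort_config"))
  class_label <- match.arg(class_label, c("positive", "negative"))
  forced <- if (class_label == "positive") {
    function(subject, trial, cream) sample(8:9, 1L)
  } else {
    function(subject, trial, cream) sample(1:4, 1L)
  }
  cfg <- config
  cfg$score_model <- forced
  shift <- subject_shift(cfg, subject_index)
  lapply(seq_len(cfg$n_trials_per_subject), function(tr) {
    generate_trial(cfg, subject_index, tr, shift$gain, shift$offset, subject_id)
  })
}

#' Write / read a cohort container
#'
#' Persists a cohort as an R-native serialized container plus a plain CSV
#' manifest (subject_id, trial_id, cream_id, score).
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns the
#'   cohort.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(cohort, file.path(dir, "cohort.rds"))
  utils::write.csv(cohort_manifest(cohort),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) readRDS(file.path(dir, "cohort.rds"))

#' Cohort manifest table
#'
#' @param cohort An `eeg_cohort` or list of recordings.
#' @return data.frame with one row per trial.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    data.frame(subject_id = r$subject_id, trial_id = r$trial_id,
               cream_id = r$cream_id, score = r$score,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Synthetic EEG cohort: %d recordings (%d subjects x %d trials), %g Hz, %d channels\n",
              length(x), cfg$n_subjects, cfg$n_trials_per_subject,
              cfg$sampling_rate, length(cfg$channel_names)))
  invisible(x)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording %s (subject %s, cream %d, score %d): %d ch x %d samples @ %g Hz\n",
              x$trial_id, x$subject_id, x$cream_id, x$score,
              nrow(x$signal), ncol(x$signal), x$sampling_rate))
  invisible(x)
}
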