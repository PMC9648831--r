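#' Morlet decomposition parameters
#'
#' Parameters of the fixed-cycle Morlet wavelet filter bank. Each center
#' frequency `f` uses the same cycle count `C`, giving spectral bandwidth
#' `sigma_f = 2 f / C` (Hz) and wavelet duration
#' `sigma_t = 1 / (2 pi sigma_f)` (s), so `sigma_t * sigma_f = 1 / (2 pi)`
#' at every frequency. Wavelets are unit-energy, which keeps power
#' comparable across frequencies.
#'
#' @param C Wavelet cycle count (default 14).
#' @param freqs Center-frequency grid in Hz (default 1:120, 1 Hz steps).
#' @param time_resolution Output time-bin width in seconds (default 0.05).
#' @param n_sigma Truncation of the Gaussian envelope, in units of
#'   `sigma_t` (default 4; the effective edge-effect span is about
#'   `3 * sigma_t`, i.e. ~3.3 s at 1 Hz).
#' @return Object of class `morlet_params`.
#' @export
morlet_params <- function(C = 14, freqs = 1:120, time_resolution = 0.05,
                          n_sigma = 4) {
  if (C <= 0) stop("morlet_params: 'C' must be > 0", call. = FALSE)
  if (any(freqs < 1) || any(diff(freqs) <= 0))
    stop("morlet_params: 'freqs' must be strictly increasing and >= 1 Hz",
         call. = FALSE)
  if (time_resolution <= 0)
    stop("morlet_params: 'time_resolution' must be > 0", call. = FALSE)
  structure(list(C = C, freqs = as.numeric(freqs),
                 time_resolution = time_resolution, n_sigma = n_sigma),
            class = "morlet_params")
}

#' Morlet bandwidth and duration at a center frequency
#'
#' @param params A [morlet_params()].
#' @param f Center frequency (Hz), vectorized.
#' @return List with `sigma_f` (Hz) and `sigma_t` (s).
#' @export
morlet_sigma <- function(params, f) {
  sigma_f <- 2 * f / params$C
  list(sigma_f = sigma_f, sigma_t = 1 / (2 * pi * sigma_f))
}

#' Remove 60 Hz line noise with a zero-phase band-stop filter
#'
#' Order-4 Butterworth band-stop (58--62 Hz) applied forward-backward
#' (`signal::filtfilt`), so the filter is zero-phase and the trigger
#' alignment is preserved. Attenuation at 60 Hz far exceeds 20 dB while the
#' passband (<= 50 Hz, >= 70 Hz) is altered by well under 1 dB.
#'
#' @param recording An `eeg_recording`.
#' @param band Stop band in Hz (default `c(58, 62)`).
#' @param order Butterworth order (default 4).
#' @return The recording with filtered signal, same shape and metadata.
#' @export
bandstop_60hz <- function(recording, band = c(58, 62), order = 4) {
  fs <- recording$sampling_rate
  if (fs <= 2 * band[2])
    stop("bandstop_60hz: sampling rate ", fs,
         " Hz is too low for a ", band[1], "-", band[2], " Hz stop band",
         call. = FALSE)
  bf <- signal::butter(order, band / (fs / 2), type = "stop")
  out <- recording
  for (ch in seq_len(nrow(out$signal)))
    out$signal[ch, ] <- signal::filtfilt(bf, recording$signal[ch, ])
  out
}

#' Extract a fixed segment around the trigger
#'
#' Cuts the signal to `[span[1], span[2])` seconds relative to the trigger,
#' yielding exactly `diff(span) * sampling_rate` samples, and re-anchors the
#' trigger index.
#'
#' @param recording An `eeg_recording`.
#' @param span Two-element numeric, seconds relative to trigger
#'   (default `c(-15, 55)`).
#' @return The cut recording.
#' @export
extract_segment <- function(recording, span = c(-15, 55)) {
  fs <- recording$sampling_rate
  ns <- ncol(recording$signal)
  first <- recording$trigger_index + round(span[1] * fs)
  len <- round(diff(span) * fs)
  last <- first + len - 1L
  if (first < 1L || last > ns)
    stop("extract_segment: span [", span[1], ", ", span[2],
         ") s is outside the recorded samples", call. = FALSE)
  out <- recording
  out$signal <- recording$signal[, first:last, drop = FALSE]
  out$trigger_index <- as.integer(recording$trigger_index - first + 1L)
  out
}

#' Morlet time-frequency decomposition
#'
#' Computes squared-magnitude Morlet wavelet power for every channel on the
#' 1 Hz frequency grid and the `time_resolution` time grid. Time-bin centers
#' sit at integer multiples of the time resolution relative to the trigger
#' (..., -0.05, 0, 0.05, ... s). Power near the segment edges (within about
#' `3 * sigma_t` of either end) is attenuated by envelope clipping; with the
#' standard -15..55 s segment the 0--30 s analysis span lies well inside the
#' valid region at every frequency.
#'
#' @param recording An `eeg_recording` (typically after [bandstop_60hz()]
#'   and [extract_segment()]).
#' @param params A [morlet_params()].
#' @param tmin,tmax Optional bin-center range (s, relative to trigger);
#'   defaults to the full segment. Restricting the range to the analysis
#'   span makes the decomposition proportionally cheaper.
#' @return Object of class `eeg_spectrogram`: list with `power`
#'   (channels x freqs x time bins, muV^2), `freq_axis`, `time_axis`,
#'   `channel_names`, and the recording's identity fields.
#' @export
morlet_tfr <- function(recording, params = morlet_params(),
                       tmin = NULL, tmax = NULL) {
  fs <- recording$sampling_rate
  if (max(params$freqs) >= fs / 2)
    stop("morlet_tfr: maximum analysis frequency ", max(params$freqs),
         " Hz is not below the Nyquist frequency ", fs / 2, " Hz",
         call. = FALSE)
  ns <- ncol(recording$signal)
  dt <- params$time_resolution
  t_first <- (1 - recording$trigger_index) / fs
  t_last  <- (ns - recording$trigger_index) / fs
  if (is.null(tmin)) tmin <- t_first
  if (is.null(tmax)) tmax <- t_last
  centers_t <- seq(ceiling(round(tmin / dt, 9)) * dt,
                   floor(round(tmax / dt, 9)) * dt, by = dt)
  centers_t <- round(centers_t, 9)
  idx0 <- recording$trigger_index - 1L + round(centers_t * fs)  # 0-based
  keep <- idx0 >= 0 & idx0 <= ns - 1
  centers_t <- centers_t[keep]; idx0 <- idx0[keep]

  p <- cpp_morlet_power(recording$signal, fs, params$freqs, params$C,
                        as.integer(idx0), params$n_sigma)
  dim(p) <- c(nrow(recording$signal), length(params$freqs), length(centers_t))
  dimnames(p) <- list(rownames(recording$signal), NULL, NULL)
  structure(list(power = p,
                 freq_axis = params$freqs,
                 time_axis = centers_t,
                 channel_names = rownames(recording$signal),
                 subject_id = recording$subject_id,
                 trial_id = recording$trial_id,
                 cream_id = recording$cream_id,
                 score = recording$score),
            class = "eeg_spectrogram")
}

#' @export
print.eeg_spectrogram <- function(x, ...) {
  cat(sprintf("EEG spectrogram %s: %d ch x %d freqs (%g-%g Hz) x %d bins (%g..%g s)\n",
              x$trial_id, dim(x$power)[1], dim(x$power)[2],
              min(x$freq_axis), max(x$freq_axis), dim(x$power)[3],
              min(x$time_axis), max(x$time_axis)))
  invisible(x)
}
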