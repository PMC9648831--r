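#' The four analysis frequency bands
#'
#' Alpha 7--15, beta 15--33, low gamma 33--70, high gamma 70--120 Hz. The
#' printed edges touch, so on the 1 Hz bin grid the bands are made disjoint
#' with a half-open convention (boundary bins assigned upward): alpha bins
#' 7--14, beta 15--32, low gamma 33--69, high gamma 70--120. Bins 1--6 Hz
#' (delta/theta) belong to no band.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("alpha", "beta", "low_gamma", "high_gamma"),
             lo = c(7, 15, 33, 70),
             hi = c(15, 33, 70, 120),
             stringsAsFactors = FALSE)
}

band_names <- function() eeg_bands()$name

#' 1 Hz bins belonging to a band
#'
#' @param band Band name.
#' @param freqs The frequency grid (default 1:120).
#' @return Integer vector of bin center frequencies in the band.
#' @export
band_bins <- function(band, freqs = 1:120) {
  b <- eeg_bands()
  row <- b[b$name == band, ]
  if (nrow(row) != 1L) stop("unknown band: ", band, call. = FALSE)
  if (band == "high_gamma") freqs[freqs >= row$lo & freqs <= row$hi]
  else freqs[freqs >= row$lo & freqs < row$hi]
}

#' Sliding-window specification
#'
#' @param length Window length in seconds (default 3).
#' @param hop Hop between window starts in seconds (default 1, i.e. 2 s
#'   overlap, 66.7 percent).
#' @param span Analysis span in seconds relative to the trigger
#'   (default `c(0, 30)`, the application period).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(length = 3, hop = 1, span = c(0, 30)) {
  if (length <= 0) stop("window_spec: 'length' must be > 0", call. = FALSE)
  if (hop <= 0 || hop > length)
    stop("window_spec: 'hop' must satisfy 0 < hop <= length", call. = FALSE)
  if (diff(span) < length)
    stop("window_spec: span must be at least one window long", call. = FALSE)
  structure(list(length = length, hop = hop, span = span),
            class = "window_spec")
}

#' Number of sliding windows over a span
#' @param spec A [window_spec()].
#' @return Integer count `floor((span - length) / hop) + 1`.
#' @export
n_windows <- function(spec) {
  as.integer(floor(round((diff(spec$span) - spec$length) / spec$hop, 9)) + 1L)
}

#' Cut a spectrogram into sliding windows
#'
#' Window `i` (1-based) covers `[span[1] + (i-1) * hop,
#' span[1] + (i-1) * hop + length)` seconds; a time bin belongs to the
#' window when its center lies in that half-open interval. With the default
#' 3 s / 1 s / 0--30 s specification each trial yields 28 windows.
#'
#' @param spectrogram An `eeg_spectrogram`.
#' @param spec A [window_spec()].
#' @return List of window spectrograms, each with a `window_index` field.
#' @export
make_windows <- function(spectrogram, spec = window_spec()) {
  ta <- round(spectrogram$time_axis, 9)
  if (min(ta) > spec$span[1] + 1e-9 ||
      max(ta) < spec$span[2] - spec$hop - 1e-9)
    stop("make_windows: spectrogram does not cover the analysis span [",
         spec$span[1], ", ", spec$span[2], ") s", call. = FALSE)
  nw <- n_windows(spec)
  lapply(seq_len(nw), function(i) {
    start <- spec$span[1] + (i - 1) * spec$hop
    sel <- ta >= start - 1e-9 & ta < start + spec$length - 1e-9
    w <- spectrogram
    w$power <- spectrogram$power[, , sel, drop = FALSE]
    w$time_axis <- spectrogram$time_axis[sel]
    w$window_index <- i
    w
  })
}

#' Average window power into the four bands
#'
#' For each band and channel, the mean power over the window's time bins and
#' over the 1 Hz frequency bins whose center lies in the band.
#'
#' @param window A window spectrogram from [make_windows()].
#' @param bands Band table (default [eeg_bands()]).
#' @return 4 x 19 matrix (band x channel) of mean power, class
#'   `band_power_window`.
#' @export
band_average <- function(window, bands = eeg_bands()) {
  freqs <- window$freq_axis
  out <- matrix(NA_real_, nrow = nrow(bands), ncol = dim(window$power)[1],
                dimnames = list(bands$name, window$channel_names))
  for (b in seq_len(nrow(bands))) {
    bins <- band_bins(bands$name[b], freqs)
    sel <- freqs %in% bins
    out[b, ] <- apply(window$power[, sel, , drop = FALSE], 1, mean)
  }
  structure(out, class = c("band_power_window", "matrix"),
            window_index = window$window_index)
}

# Fixed 5x5 electrode layout. Positive entries are channel indices in the
# canonical order of eeg_channels(); the six corner fills are averages of
# their neighboring channels (circled cells 1-6 of the layout figure).
layout_map <- function() {
  ch <- eeg_channels()
  idx <- function(x) match(x, ch)
  grid <- matrix(NA_integer_, 5, 5)
  grid[1, ] <- c(NA, idx("Fp1"), NA, idx("Fp2"), NA)
  grid[2, ] <- idx(c("F7", "F3", "Fz", "F4", "F8"))
  grid[3, ] <- idx(c("T3", "C3", "Cz", "C4", "T4"))
  grid[4, ] <- idx(c("T5", "P3", "Pz", "P4", "T6"))
  grid[5, ] <- c(NA, idx("O1"), NA, idx("O2"), NA)
  fills <- list(
    `1,1` = idx(c("Fp1", "F7", "F3")),
    `1,3` = idx(c("Fp1", "Fz", "Fp2")),
    `1,5` = idx(c("Fp2", "F4", "F8")),
    `5,1` = idx(c("T5", "P3", "O1")),   # T5 = P7
    `5,3` = idx(c("Pz", "O1", "O2")),
    `5,5` = idx(c("T6", "P4", "O2")))   # T6 = P8
  list(grid = grid, fills = fills)
}

#' Arrange 19 channel values on the 5x5 electrode-layout grid
#'
#' Channel values are placed at their scalp positions (rows front to back);
#' the six empty corner cells are filled with the arithmetic mean of their
#' neighboring channels, e.g. the front-left corner with
#' mean(Fp1, F7, F3) and the back-center cell with mean(Pz, O1, O2).
#'
#' @param channel_values Numeric vector of 19 finite values in canonical
#'   channel order (see [eeg_channels()]); names, if present, are checked.
#' @param band Band name stored with the frame.
#' @return 5 x 5 matrix of class `layout_frame` with attribute `band`.
#' @export
layout_5x5 <- function(channel_values, band = NA_character_) {
  if (length(channel_values) != 19L)
    stop("layout_5x5: expected 19 channel values, got ",
         length(channel_values), call. = FALSE)
  if (!all(is.finite(channel_values)))
    stop("layout_5x5: channel values must be finite", call. = FALSE)
  if (!is.null(names(channel_values)) &&
      !identical(names(channel_values), eeg_channels()))
    stop("layout_5x5: channel values must be in canonical channel order",
         call. = FALSE)
  lm <- layout_map()
  g <- matrix(NA_real_, 5, 5)
  g[!is.na(lm$grid)] <- channel_values[lm$grid[!is.na(lm$grid)]]
  for (key in names(lm$fills)) {
    rc <- as.integer(strsplit(key, ",")[[1]])
    g[rc[1], rc[2]] <- mean(channel_values[lm$fills[[key]]])
  }
  structure(g, class = c("layout_frame", "matrix"), band = band)
}

#' Quadrant assignment of bands in the merged matrix
#' @return Named list mapping band name to quadrant label.
#' @export
band_quadrants <- function() {
  list(alpha = "top_left", beta = "top_right",
       low_gamma = "bottom_left", high_gamma = "bottom_right")
}

#' Merge four band-layout frames into the 10x10 network input
#'
#' Quadrants in reading order: alpha top-left, beta top-right, low gamma
#' bottom-left, high gamma bottom-right. Slicing a quadrant recovers the
#' corresponding 5x5 frame exactly.
#'
#' @param frames Named list with one `layout_frame` per band.
#' @return 10 x 10 matrix of class `merged_frame` with attribute
#'   `band_quadrants`.
#' @export
merge_bands <- function(frames) {
  need <- band_names()
  if (!all(need %in% names(frames)))
    stop("merge_bands: missing band frame(s): ",
         paste(setdiff(need, names(frames)), collapse = ", "), call. = FALSE)
  m <- matrix(NA_real_, 10, 10)
  m[1:5, 1:5]   <- frames$alpha
  m[1:5, 6:10]  <- frames$beta
  m[6:10, 1:5]  <- frames$low_gamma
  m[6:10, 6:10] <- frames$high_gamma
  structure(m, class = c("merged_frame", "matrix"),
            band_quadrants = band_quadrants())
}

#' Slice a merged frame back into its four band quadrants
#' @param merged A `merged_frame`.
#' @return Named list of four 5x5 matrices.
#' @export
split_bands <- function(merged) {
  list(alpha = unclass(merged)[1:5, 1:5],
       beta = unclass(merged)[1:5, 6:10],
       low_gamma = unclass(merged)[6:10, 1:5],
       high_gamma = unclass(merged)[6:10, 6:10])
}

#' Featurize one recording into windowed band powers
#'
#' Runs the per-trial feature path: 60 Hz band-stop, segment extraction,
#' Morlet decomposition restricted to the analysis span, sliding windows,
#' and per-band averaging. The spectrogram is transient, so memory stays
#' bounded for large cohorts.
#'
#' @param recording An `eeg_recording`.
#' @param params [morlet_params()].
#' @param wspec [window_spec()].
#' @param segment_span Segment to cut before decomposition.
#' @return Array `(band 4, channel 19, window)` with trial metadata in
#'   attributes `subject_id`, `trial_id`, `score`.
#' @export
featurize_recording <- function(recording, params = morlet_params(),
                                wspec = window_spec(),
                                segment_span = c(-15, 55)) {
  rec <- bandstop_60hz(recording)
  rec <- extract_segment(rec, segment_span)
  sp <- morlet_tfr(rec, params, tmin = wspec$span[1],
                   tmax = wspec$span[2])
  wins <- make_windows(sp, wspec)
  vals <- vapply(wins, function(w) unclass(band_average(w)),
                 matrix(0, 4, dim(sp$power)[1]))
  dimnames(vals) <- list(band_names(), sp$channel_names, NULL)
  structure(vals, subject_id = recording$subject_id,
            trial_id = recording$trial_id, score = recording$score)
}
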