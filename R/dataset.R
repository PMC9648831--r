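#' Map a preference score to a class label
#'
#' Scores 1--4 are labeled negative (dislike), 8--9 positive (like), and the
#' neutral midrange 5--7 is excluded from modeling.
#'
#' @param score Integer vector of scores in 1..9.
#' @return Character vector in `{"negative", "positive", "excluded"}`.
#' @export
label_from_score <- function(score) {
  if (any(is.na(score)) || any(score != as.integer(score)) ||
      any(score < 1L) || any(score > 9L))
    stop("label_from_score: scores must be integers in 1..9", call. = FALSE)
  ifelse(score <= 4L, "negative", ifelse(score >= 8L, "positive", "excluded"))
}

#' Assemble windowed features into a model-ready dataset
#'
#' Converts per-trial feature arrays (from [featurize_recording()]) into a
#' dataset of labeled samples: per-band 5x5 layout frames, the 10x10 merged
#' frame, and a metadata table with subject/trial/window provenance.
#'
#' @param features List of feature arrays `(band, channel, window)` as
#'   returned by [featurize_recording()].
#' @return Object of class `eeg_dataset`: list with `meta` (data.frame:
#'   subject_id, trial_id, window_index, score, label, augmented), `band`
#'   (5 x 5 x 4 x N array of layout frames), `merged` (10 x 10 x 1 x N).
#' @export
assemble_dataset <- function(features) {
  n_tot <- sum(vapply(features, function(f) dim(f)[3], 0L))
  band <- array(NA_real_, c(5, 5, 4, n_tot),
                dimnames = list(NULL, NULL, band_names(), NULL))
  merged <- array(NA_real_, c(10, 10, 1, n_tot))
  meta <- vector("list", length(features))
  k <- 0L
  for (fi in seq_along(features)) {
    f <- features[[fi]]
    nw <- dim(f)[3]
    for (w in seq_len(nw)) {
      k <- k + 1L
      frames <- lapply(stats::setNames(band_names(), band_names()),
                       function(b) layout_5x5(f[b, , w], b))
      for (b in seq_along(frames)) band[, , b, k] <- frames[[b]]
      merged[, , 1, k] <- merge_bands(frames)
    }
    meta[[fi]] <- data.frame(subject_id = attr(f, "subject_id"),
                             trial_id = attr(f, "trial_id"),
                             window_index = seq_len(nw),
                             score = attr(f, "score"),
                             stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  meta$label <- label_from_score(meta$score)
  meta$augmented <- FALSE
  structure(list(meta = meta, band = band, merged = merged,
                 corrected = FALSE),
            class = "eeg_dataset")
}

subset_dataset <- function(ds, idx) {
  ds$meta <- ds$meta[idx, , drop = FALSE]
  rownames(ds$meta) <- NULL
  ds$band <- ds$band[, , , idx, drop = FALSE]
  ds$merged <- ds$merged[, , , idx, drop = FALSE]
  ds
}

#' Number of samples in a dataset
#' @param ds An `eeg_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$meta)

#' Drop neutral windows and single-class subjects
#'
#' Removes windows whose score falls in the excluded midrange (5--7), then
#' removes entirely any subject whose remaining windows all share one label:
#' the per-subject baseline correction and class balancing both require two
#' classes per subject.
#'
#' @param ds An `eeg_dataset`.
#' @return List with `dataset` (the reduced dataset) and
#'   `excluded_subjects` (character vector).
#' @export
exclude_single_class_subjects <- function(ds) {
  ds <- subset_dataset(ds, ds$meta$label != "excluded")
  tab <- table(ds$meta$subject_id, ds$meta$label)
  n_classes <- rowSums(tab > 0)
  single <- rownames(tab)[n_classes < 2L]
  keep <- !(ds$meta$subject_id %in% single)
  if (!any(keep))
    stop("exclude_single_class_subjects: no two-class subjects remain; ",
         "the dataset is empty", call. = FALSE)
  list(dataset = subset_dataset(ds, keep),
       excluded_subjects = single)
}

#' Balance classes per subject by random oversampling
#'
#' Within each subject, minority-class samples are duplicated uniformly at
#' random with replacement until the class counts are equal. All original
#' samples are retained; duplicates are flagged `augmented`.
#'
#' @param ds An `eeg_dataset` with both classes for every subject.
#' @param seed Integer seed for the duplicate draw.
#' @return The balanced dataset.
#' @export
balance_by_oversampling <- function(ds, seed = 1L) {
  tab <- table(ds$meta$subject_id, ds$meta$label)
  if (any(rowSums(tab > 0) < 2L))
    stop("balance_by_oversampling: subject(s) with a single class present: ",
         paste(rownames(tab)[rowSums(tab > 0) < 2L], collapse = ", "),
         call. = FALSE)
  extra <- with_rng_stream(derive_seed(seed, 777L), {
    unlist(lapply(sort(unique(ds$meta$subject_id)), function(s) {
      sel <- which(ds$meta$subject_id == s)
      lab <- ds$meta$label[sel]
      n_pos <- sum(lab == "positive"); n_neg <- sum(lab == "negative")
      if (n_pos == n_neg) return(integer(0))
      minority <- if (n_pos < n_neg) "positive" else "negative"
      pool <- sel[lab == minority]
      sample(pool, abs(n_pos - n_neg), replace = TRUE)
    }))
  })
  if (!length(extra)) return(ds)
  out <- ds
  out$meta <- rbind(ds$meta, transform(ds$meta[extra, , drop = FALSE],
                                       augmented = TRUE))
  rownames(out$meta) <- NULL
  out$band <- array(c(ds$band, ds$band[, , , extra, drop = FALSE]),
                    dim = c(5, 5, 4, n_samples(ds) + length(extra)),
                    dimnames = dimnames(ds$band))
  out$merged <- array(c(ds$merged, ds$merged[, , , extra, drop = FALSE]),
                      dim = c(10, 10, 1, n_samples(ds) + length(extra)))
  out
}

#' Per-subject class-conditional baseline statistics
#'
#' For every subject, grid cell, and band, the mean power of that subject's
#' positive-class and negative-class samples. These are the two anchors of
#' the baseline correction: after correction the negative-class mean maps to
#' 0 and the positive-class mean to 1.
#'
#' @param ds An `eeg_dataset` where every subject has both classes
#'   (typically after balancing).
#' @return Object of class `baseline_stats`: per subject, arrays `f_pos` and
#'   `f_neg` (5 x 5 x 4).
#' @export
baseline_stats <- function(ds) {
  subjects <- sort(unique(ds$meta$subject_id))
  stats <- lapply(stats::setNames(subjects, subjects), function(s) {
    sel_pos <- ds$meta$subject_id == s & ds$meta$label == "positive"
    sel_neg <- ds$meta$subject_id == s & ds$meta$label == "negative"
    if (!any(sel_pos) || !any(sel_neg))
      stop("baseline_stats: subject ", s, " lacks one of the two classes",
           call. = FALSE)
    mean4 <- function(sel) {
      a <- ds$band[, , , sel, drop = FALSE]
      apply(a, c(1, 2, 3), mean)
    }
    list(f_pos = mean4(sel_pos), f_neg = mean4(sel_neg))
  })
  structure(stats, class = "baseline_stats")
}

#' Per-subject two-class baseline correction
#'
#' Applies, element-wise per grid cell and band,
#' `f' = (f - f_neg_mean) / (f_pos_mean - f_neg_mean)` using the subject's
#' own class-conditional means, so that within every subject the corrected
#' negative-class mean is exactly 0 and the positive-class mean exactly 1.
#' This removes per-subject scale and offset differences (the cross-subject
#' domain shift) from the feature space.
#'
#' Cells where the two class means coincide (relative tolerance
#' `1e-12 * max(|f_pos|, |f_neg|, 1)`) have an undefined correction; the
#' `degenerate` policy either raises an error (default) or passes through 0
#' with a warning.
#'
#' @param ds An `eeg_dataset`.
#' @param stats A [baseline_stats()] for the same subjects; computed from
#'   `ds` when `NULL`.
#' @param degenerate `"error"` or `"zero"`.
#' @return The corrected dataset (merged frames rebuilt from corrected band
#'   frames; `corrected` flag set).
#' @export
baseline_correct <- function(ds, stats = NULL,
                             degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  if (is.null(stats)) stats <- baseline_stats(ds)
  out <- ds
  for (s in names(stats)) {
    sel <- which(ds$meta$subject_id == s)
    if (!length(sel)) next
    fp <- stats[[s]]$f_pos; fn <- stats[[s]]$f_neg
    denom <- fp - fn
    tol <- 1e-12 * pmax(abs(fp), abs(fn), 1)
    bad <- abs(denom) < tol
    if (any(bad)) {
      if (degenerate == "error")
        stop("baseline_correct: degenerate cell(s) for subject ", s,
             " (|f_pos - f_neg| below tolerance); use degenerate = \"zero\" ",
             "to pass through 0", call. = FALSE)
      warning("baseline_correct: ", sum(bad), " degenerate cell(s) for subject ",
              s, " set to 0", call. = FALSE)
      denom[bad] <- Inf  # (f - fn) / Inf -> 0
    }
    for (i in sel) {
      out$band[, , , i] <- (ds$band[, , , i] - fn) / denom
      frames <- lapply(stats::setNames(seq_len(4), band_names()),
                       function(b) out$band[, , b, i])
      out$merged[, , 1, i] <- merge_bands(frames)
    }
  }
  out$corrected <- TRUE
  out
}

#' One-shot dataset preparation from a cohort
#'
#' Featurizes every recording, assembles samples, labels them, drops the
#' neutral midrange and single-class subjects, balances classes per subject
#' by oversampling, and applies the per-subject baseline correction.
#'
#' Baseline statistics are computed per subject over all that subject's
#' balanced windows, including when the subject later serves as the test
#' subject — faithful to the evaluated protocol, but note this uses the test
#' subject's own labels, which is a leakage concern for deployment (the
#' correction anchors require two labeled classes per subject).
#'
#' @param cohort An `eeg_cohort` (or list of recordings).
#' @param params [morlet_params()].
#' @param wspec [window_spec()].
#' @param balance Balance classes per subject (default TRUE).
#' @param correct Apply baseline correction (default TRUE).
#' @param degenerate Degenerate-cell policy for [baseline_correct()].
#' @param seed Seed for the oversampling draw.
#' @param progress Print one line per recording.
#' @return List with `dataset`, `excluded_subjects`, `stats`.
#' @export
prepare_dataset <- function(cohort, params = morlet_params(),
                            wspec = window_spec(), balance = TRUE,
                            correct = TRUE, degenerate = "error",
                            seed = 1L, progress = FALSE) {
  features <- lapply(cohort, function(rec) {
    if (progress) message("featurizing ", rec$trial_id)
    featurize_recording(rec, params, wspec)
  })
  ds <- assemble_dataset(features)
  ex <- exclude_single_class_subjects(ds)
  ds <- ex$dataset
  if (balance) ds <- balance_by_oversampling(ds, seed = seed)
  stats <- baseline_stats(ds)
  if (correct) ds <- baseline_correct(ds, stats, degenerate = degenerate)
  list(dataset = ds, excluded_subjects = ex$excluded_subjects,
       stats = stats)
}

#' Per-subject class counts
#' @param ds An `eeg_dataset`.
#' @return data.frame subject_id, negative, positive, augmented counts.
#' @export
class_counts <- function(ds) {
  tab <- as.data.frame.matrix(table(ds$meta$subject_id, ds$meta$label))
  data.frame(subject_id = rownames(tab),
             negative = tab$negative, positive = tab$positive,
             augmented = as.integer(tapply(ds$meta$augmented,
                                           ds$meta$subject_id, sum)[rownames(tab)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Persist / load a model-ready dataset
#'
#' R-native serialized container plus a CSV manifest of per-subject class
#' counts.
#'
#' @param ds An `eeg_dataset`.
#' @param dir Output directory.
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` the
#'   dataset.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ds, file.path(dir, "dataset.rds"))
  utils::write.csv(class_counts(ds), file.path(dir, "class_counts.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) readRDS(file.path(dir, "dataset.rds"))

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("EEG dataset: %d samples, %d subjects, %scorrected\n",
              n_samples(x), length(unique(x$meta$subject_id)),
              if (isTRUE(x$corrected)) "baseline-" else "not "))
  print(class_counts(x))
  invisible(x)
}
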