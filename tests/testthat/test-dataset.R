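test_that("scores map to labels with the neutral midrange excluded", {
  expect_equal(label_from_score(3L), "negative")
  expect_equal(label_from_score(9L), "positive")
  expect_equal(label_from_score(6L), "excluded")
  expect_equal(label_from_score(c(1, 4, 5, 7, 8)),
               c("negative", "negative", "excluded", "excluded", "positive"))
  expect_error(label_from_score(0L), "1..9")
  expect_error(label_from_score(10L), "1..9")
  expect_error(label_from_score(4.5), "1..9")
})

test_that("assembly produces labeled frames with provenance", {
  feats <- c(fake_subject_features("S01", c(8, 2)),
             fake_subject_features("S02", c(9, 3), seed = 50L))
  ds <- assemble_dataset(feats)
  expect_s3_class(ds, "eeg_dataset")
  expect_equal(n_samples(ds), 4L * 28L)
  expect_equal(dim(ds$band), c(5L, 5L, 4L, 112L))
  expect_equal(dim(ds$merged), c(10L, 10L, 1L, 112L))
  expect_false(any(ds$meta$augmented))
  # merged quadrants equal the band frames for every sample
  for (i in c(1L, 57L)) {
    expect_equal(ds$merged[1:5, 1:5, 1, i], ds$band[, , "alpha", i])
    expect_equal(ds$merged[6:10, 6:10, 1, i], ds$band[, , "high_gamma", i])
  }
  # frames agree with an independently computed layout
  f1 <- feats[[1]]
  expect_equal(ds$band[, , "beta", 3], unclass(layout_5x5(f1["beta", , 3])),
               ignore_attr = TRUE)
})

test_that("neutral windows and single-class subjects are excluded", {
  feats <- c(fake_subject_features("S01", c(8, 2, 6)),     # two-class + neutral
             fake_subject_features("S02", c(9, 9)),        # positive only
             fake_subject_features("S03", c(1, 3)),        # negative only
             fake_subject_features("S04", c(8, 1)))
  ex <- exclude_single_class_subjects(assemble_dataset(feats))
  expect_setequal(ex$excluded_subjects, c("S02", "S03"))
  expect_setequal(unique(ex$dataset$meta$subject_id), c("S01", "S04"))
  expect_false(any(ex$dataset$meta$label == "excluded"))
  expect_equal(n_samples(ex$dataset), 4L * 28L)  # neutral trial dropped

  # a cohort with every subject two-class passes through unchanged
  feats2 <- c(fake_subject_features("S01", c(8, 2)),
              fake_subject_features("S02", c(9, 1)))
  ex2 <- exclude_single_class_subjects(assemble_dataset(feats2))
  expect_length(ex2$excluded_subjects, 0L)
  expect_equal(n_samples(ex2$dataset), 4L * 28L)

  # all subjects single-class is an empty dataset
  feats3 <- c(fake_subject_features("S01", c(8, 9)),
              fake_subject_features("S02", c(1, 2)))
  expect_error(exclude_single_class_subjects(assemble_dataset(feats3)),
               "empty")
})

test_that("oversampling balances 140/56 to 140/140 and keeps originals", {
  feats <- fake_subject_features("S01", c(8, 9, 8, 9, 8, 2, 1))  # 5 pos, 2 neg
  ds <- assemble_dataset(feats)
  expect_equal(sum(ds$meta$label == "positive"), 140L)
  expect_equal(sum(ds$meta$label == "negative"), 56L)
  bal <- balance_by_oversampling(ds, seed = 5L)
  cc <- class_counts(bal)
  expect_equal(cc$positive, 140L)
  expect_equal(cc$negative, 140L)
  expect_equal(sum(bal$meta$augmented), 84L)
  # every original sample still present, duplicates are real copies
  expect_identical(bal$meta[seq_len(n_samples(ds)), "trial_id"],
                   ds$meta$trial_id)
  dup <- which(bal$meta$augmented)[1]
  src <- which(!bal$meta$augmented &
               bal$meta$trial_id == bal$meta$trial_id[dup] &
               bal$meta$window_index == bal$meta$window_index[dup])
  expect_equal(bal$band[, , , dup], bal$band[, , , src])
  # deterministic given the seed
  expect_identical(balance_by_oversampling(ds, seed = 5L)$meta,
                   bal$meta)
  # already balanced input is returned unchanged
  feats2 <- fake_subject_features("S02", c(8, 1))
  ds2 <- assemble_dataset(feats2)
  expect_identical(balance_by_oversampling(ds2, seed = 1L), ds2)
  # single-class input is a precondition failure
  feats3 <- fake_subject_features("S03", c(8, 9))
  expect_error(balance_by_oversampling(assemble_dataset(feats3)),
               "single class")
})

test_that("baseline statistics are exact class-conditional means", {
  feats <- list(fake_features("S01", "S01_T01", 8L, values = 4),
                fake_features("S01", "S01_T02", 2L, values = 2))
  ds <- assemble_dataset(feats)
  st <- baseline_stats(ds)
  expect_equal(unique(as.vector(st$S01$f_pos)), 4)
  expect_equal(unique(as.vector(st$S01$f_neg)), 2)
  # one positive sample: its own values are the mean
  feats2 <- list(fake_features("S02", "S02_T01", 9L, n_windows = 1L, seed = 2L),
                 fake_features("S02", "S02_T02", 1L, seed = 3L))
  ds2 <- assemble_dataset(feats2)
  st2 <- baseline_stats(ds2)
  expect_equal(st2$S02$f_pos, ds2$band[, , , 1], ignore_attr = TRUE)
  feats3 <- list(fake_features("S03", "S03_T01", 8L))
  expect_error(baseline_stats(assemble_dataset(feats3)), "lacks one")
})

test_that("baseline correction maps the class anchors to 0 and 1", {
  feats <- list(fake_features("S01", "S01_T01", 8L, values = 4),
                fake_features("S01", "S01_T02", 2L, values = 2))
  ds <- assemble_dataset(feats)
  cor <- baseline_correct(ds)
  expect_true(all(abs(cor$band[, , , ds$meta$label == "positive"] - 1) < 1e-12))
  expect_true(all(abs(cor$band[, , , ds$meta$label == "negative"]) < 1e-12))
  # midpoint maps to 0.5
  mid <- ds; mid$band[, , , 1] <- 3
  expect_true(all(abs(baseline_correct(mid,
    stats = baseline_stats(ds))$band[, , , 1] - 0.5) < 1e-12))
  expect_true(cor$corrected)
})

test_that("post-correction class means are 0 and 1 at every cell and band", {
  prep <- small_prep()
  ds <- prep$dataset
  for (s in unique(ds$meta$subject_id)) {
    for (lab in c("negative", "positive")) {
      sel <- ds$meta$subject_id == s & ds$meta$label == lab
      m <- apply(ds$band[, , , sel, drop = FALSE], c(1, 2, 3), mean)
      expect_lt(max(abs(m - (lab == "positive"))), 1e-9)
    }
  }
})

test_that("degenerate cells follow the configured policy", {
  feats <- list(fake_features("S01", "S01_T01", 8L, values = 2),
                fake_features("S01", "S01_T02", 2L, values = 2))
  ds <- assemble_dataset(feats)  # identical class means everywhere
  expect_error(baseline_correct(ds), "degenerate")
  expect_warning(cor <- baseline_correct(ds, degenerate = "zero"),
                 "degenerate")
  expect_true(all(cor$band == 0))
})

test_that("prepare_dataset chains exclusion, balancing and correction", {
  prep <- small_prep()
  ds <- prep$dataset
  expect_true(ds$corrected)
  cc <- class_counts(ds)
  expect_equal(cc$positive, cc$negative)
  expect_length(prep$excluded_subjects, 0L)
  # every retained window has exactly one label
  expect_true(all(ds$meta$label %in% c("positive", "negative")))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_equal(read_dataset(dir)$meta, ds$meta)
})
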