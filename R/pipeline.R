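#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end pipeline: cohort generation,
#' Morlet parameters, windowing, dataset policies, model list, training
#' parameters, and evaluation options, under one master seed. Any field can
#' be overridden via `modifyList()`-style nested lists (see
#' [load_pipeline_config()] for YAML files).
#'
#' @param seed Master seed.
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    cohort = list(n_subjects = 16L, n_trials_per_subject = 8L,
                  effect_size = 1.0, effect_band = "low_gamma"),
    morlet = list(C = 14, time_resolution = 0.05),
    windows = list(length = 3, hop = 1, span = c(0, 30)),
    dataset = list(balance = TRUE, correct = TRUE, degenerate = "error",
                   test_balanced = TRUE),
    models = list(architectures = "stacked_merged", dropout_rate = 0.5),
    training = list(batch_size = 128L, learning_rate = 2e-4,
                    max_epochs = 300L),
    evaluation = list(kernel = 7L),
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Demonstration configuration
#'
#' A small configuration (4 subjects, 2 architectures, 20 epochs) that runs
#' the whole pipeline in a couple of minutes on one CPU.
#'
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1L) {
  cfg <- default_pipeline_config(seed)
  cfg$cohort$n_subjects <- 4L
  cfg$cohort$n_trials_per_subject <- 4L
  cfg$models$architectures <- c("stacked_merged", "single_low_gamma")
  cfg$training$max_epochs <- 20L
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Values in the file override the defaults field by field.
#'
#' @param path YAML file.
#' @param base Base configuration to override (default
#'   [default_pipeline_config()]).
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, base = default_pipeline_config()) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("load_pipeline_config requires the 'yaml' package", call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(base, user)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(config) {
  bad <- setdiff(config$models$architectures, architectures())
  if (length(bad))
    stop("pipeline config: unknown architecture(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (config$training$max_epochs < 1L)
    stop("pipeline config: 'training$max_epochs' must be >= 1", call. = FALSE)
  invisible(config)
}

#' Hash a configuration for provenance
#' @param config Any R object.
#' @return 32-character md5 string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(config, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

write_provenance_csv <- function(df, path, hash, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a pipeline CSV (skipping the provenance header)
#' @param path CSV written by the pipeline.
#' @return data.frame.
#' @export
read_pipeline_csv <- function(path)
  utils::read.csv(path, comment.char = "#")

stage_fresh <- function(path, hash_file, hash) {
  file.exists(path) && file.exists(hash_file) &&
    identical(readLines(hash_file, warn = FALSE)[1], hash)
}

#' Run the full pipeline: simulate, featurize, assemble, evaluate, report
#'
#' Executes every stage from synthetic cohort to evaluation report, caching
#' each stage's output under `out_dir` so a rerun with the same
#' configuration resumes from the completed stages. Identical configuration
#' and seed reproduce the report byte for byte.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @param out_dir Output directory.
#' @param resume Reuse cached stage outputs with a matching config hash
#'   (default TRUE).
#' @param progress Log stage progress.
#' @return List with `report` (an `evaluation_report`), `results` (per
#'   architecture `loso_result`s), `paths`, and `config_hash`; invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         resume = TRUE, progress = FALSE) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  say <- function(...) if (progress) message(sprintf(...))
  stamp <- function(name) file.path(out_dir, paste0(name, ".hash"))
  done <- function(name) writeLines(hash, stamp(name))
  fresh <- function(name, file) resume && stage_fresh(file, stamp(name), hash)

  # -- simulate --------------------------------------------------------------
  cohort_file <- file.path(out_dir, "cohort.rds")
  if (fresh("simulate", cohort_file)) {
    say("simulate: cached")
    cohort <- readRDS(cohort_file)
  } else {
    say("simulate: generating cohort")
    ccfg <- do.call(cohort_config,
                    utils::modifyList(config$cohort, list(seed = seed)))
    cohort <- generate_cohort(ccfg)
    saveRDS(cohort, cohort_file)
    write_provenance_csv(cohort_manifest(cohort),
                         file.path(out_dir, "manifest.csv"), hash, seed)
    done("simulate")
  }

  # -- featurize (streams per trial; spectrograms stay transient) ------------
  features_file <- file.path(out_dir, "features.rds")
  mp <- do.call(morlet_params, config$morlet)
  ws <- do.call(window_spec, config$windows)
  if (fresh("featurize", features_file)) {
    say("featurize: cached")
    features <- readRDS(features_file)
  } else {
    say("featurize: %d recordings", length(cohort))
    features <- lapply(cohort, featurize_recording, params = mp, wspec = ws)
    saveRDS(features, features_file)
    done("featurize")
  }

  # -- assemble --------------------------------------------------------------
  dataset_file <- file.path(out_dir, "dataset.rds")
  if (fresh("assemble", dataset_file)) {
    say("assemble: cached")
    asm <- readRDS(dataset_file)
  } else {
    say("assemble: labeling, exclusion, balancing, baseline correction")
    ds <- assemble_dataset(features)
    ex <- exclude_single_class_subjects(ds)
    ds <- ex$dataset
    if (isTRUE(config$dataset$balance))
      ds <- balance_by_oversampling(ds, seed = derive_seed(seed, 5L))
    if (isTRUE(config$dataset$correct))
      ds <- baseline_correct(ds, degenerate = config$dataset$degenerate)
    asm <- list(dataset = ds, excluded_subjects = ex$excluded_subjects)
    saveRDS(asm, dataset_file)
    write_provenance_csv(class_counts(ds),
                         file.path(out_dir, "class_counts.csv"), hash, seed)
    done("assemble")
  }

  # -- train / evaluate ------------------------------------------------------
  tp <- do.call(training_params, config$training)
  results <- list()
  for (arch in config$models$architectures) {
    res_file <- file.path(out_dir, paste0("loso_", arch, ".rds"))
    if (fresh(paste0("evaluate_", arch), res_file)) {
      say("evaluate %s: cached", arch)
      results[[arch]] <- readRDS(res_file)
    } else {
      say("evaluate %s: LOSO over %d subjects", arch,
          length(unique(asm$dataset$meta$subject_id)))
      results[[arch]] <- run_loso(asm$dataset, arch, params = tp,
                                  kernel = config$evaluation$kernel,
                                  seed = derive_seed(seed, 11L),
                                  dropout_rate = config$models$dropout_rate,
                                  test_balanced = config$dataset$test_balanced,
                                  progress = progress)
      saveRDS(results[[arch]], res_file)
      done(paste0("evaluate_", arch))
    }
  }

  # -- report ----------------------------------------------------------------
  say("report: aggregating")
  report <- aggregate_report(unname(results))
  write_provenance_csv(fold_table(unname(results)),
                       file.path(out_dir, "folds.csv"), hash, seed)
  write_provenance_csv(report$per_subject,
                       file.path(out_dir, "report_per_subject.csv"), hash, seed)
  write_provenance_csv(report$summary,
                       file.path(out_dir, "report_summary.csv"), hash, seed)
  manifest <- list(
    config_hash = hash, seed = seed, config = unclass(config),
    excluded_subjects = asm$excluded_subjects,
    schedule = lapply(results[[1]]$schedule, function(f)
      list(test = f$test, validation = f$validation)),
    checkpoint_epochs = lapply(results, function(res)
      lapply(res$folds, function(fr)
        list(max_val_acc = fr$result$max_val_acc$epoch,
             min_val_loss = fr$result$min_val_loss$epoch))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, results = results,
                 paths = list(out_dir = out_dir),
                 config_hash = hash))
}
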