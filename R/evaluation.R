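#' Training hyperparameters
#'
#' Defaults follow the evaluated protocol: mini-batch 128, Adam at learning
#' rate 2e-4 (beta1 0.9, beta2 0.999, eps 1e-8), cross-entropy loss, 300
#' epochs with shuffling every epoch and one validation pass per epoch, no
#' learning-rate schedule, no early stopping.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param max_epochs Number of epochs (checkpoints are selected post hoc).
#' @param shuffle Reshuffle the training set every epoch.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param seed Integer seed controlling shuffling and dropout.
#' @return Object of class `training_params`.
#' @export
training_params <- function(batch_size = 128L, learning_rate = 2e-4,
                            max_epochs = 300L, shuffle = TRUE,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                            seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            beta1 > 0, beta2 > 0, eps > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 shuffle = isTRUE(shuffle),
                 loss = "cross_entropy", optimizer = "adam",
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "training_params")
}

#' Leave-one-subject-out schedule with rotating validation subject
#'
#' One fold per ordered (test, validation) pair of distinct subjects; the
#' remaining subjects train. With n subjects this yields n(n-1) folds
#' (240 for n = 16).
#'
#' @param subject_ids Character vector of at least 3 subject IDs.
#' @return List of folds, each `list(test, validation, training)`.
#' @export
loso_schedule <- function(subject_ids) {
  subject_ids <- sort(unique(subject_ids))
  if (length(subject_ids) < 3L)
    stop("loso_schedule: at least 3 subjects are required", call. = FALSE)
  folds <- list()
  for (te in subject_ids) for (va in subject_ids) {
    if (te == va) next
    folds[[length(folds) + 1L]] <-
      list(test = te, validation = va,
           training = setdiff(subject_ids, c(te, va)))
  }
  folds
}

eval_loss_acc <- function(net, x, y, batch_size = 512L) {
  n <- input_batch_size(x)
  loss_sum <- 0; correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    logits <- nn_forward(net, slice_input(x, idx), train = FALSE)$y
    ls <- softmax_xent(logits, y[idx])
    loss_sum <- loss_sum + ls$loss * length(idx)
    correct <- correct + sum(max.col(ls$probs, ties.method = "first") == y[idx])
  }
  list(loss = loss_sum / n, acc = correct / n)
}

#' Train a model, recording validation curves and running-best checkpoints
#'
#' Runs the full epoch budget, computing validation accuracy and loss once
#' per epoch, and keeps the two running-best parameter sets (highest
#' validation accuracy, lowest validation loss; ties resolved to the
#' earliest epoch). Keeping only the running best is selection-equivalent to
#' storing every epoch. Deterministic for a given seed.
#'
#' @param model An `eeg_cnn`.
#' @param x,y Training input tensor(s) (see [model_input()]) and integer
#'   class labels (1 = negative, 2 = positive).
#' @param val_x,val_y Validation input and labels.
#' @param params A [training_params()].
#' @return Object of class `train_artifacts`: per-epoch `val_acc`,
#'   `val_loss`, `train_loss`, and `checkpoint_by_val_acc` /
#'   `checkpoint_by_val_loss` (each `list(epoch, net)`).
#' @export
train_network <- function(model, x, y, val_x, val_y,
                          params = training_params()) {
  n <- input_batch_size(x)
  if (is.null(n) || n == 0L)
    stop("train_network: empty training set", call. = FALSE)
  stopifnot(length(y) == n)
  net <- model$net
  state <- adam_init(net)
  ne <- params$max_epochs
  val_acc <- numeric(ne); val_loss <- numeric(ne); train_loss <- numeric(ne)
  best_acc <- -Inf; best_loss <- Inf
  ck_acc <- NULL; ck_loss <- NULL
  with_rng_stream(derive_seed(params$seed, 9001L), {
    step <- 0L
    for (epoch in seq_len(ne)) {
      ord <- if (params$shuffle) sample.int(n) else seq_len(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = params$batch_size)) {
        idx <- ord[start:min(start + params$batch_size - 1L, n)]
        fw <- nn_forward(net, slice_input(x, idx), train = TRUE)
        ls <- softmax_xent(fw$y, y[idx])
        bw <- nn_backward(net, fw$cache, ls$dlogits, need_dx = FALSE,
                          reuse = TRUE)
        step <- step + 1L
        up <- adam_update(net, bw$grads, state, params$learning_rate, step,
                          params$beta1, params$beta2, params$eps)
        net <- up$layer; state <- up$state
        ep_loss <- ep_loss + ls$loss * length(idx)
      }
      train_loss[epoch] <- ep_loss / n
      ev <- eval_loss_acc(net, val_x, val_y)
      val_acc[epoch] <- ev$acc; val_loss[epoch] <- ev$loss
      if (ev$acc > best_acc) {
        best_acc <- ev$acc
        ck_acc <- list(epoch = epoch, net = net)
      }
      if (ev$loss < best_loss) {
        best_loss <- ev$loss
        ck_loss <- list(epoch = epoch, net = net)
      }
    }
  })
  structure(list(val_acc = val_acc, val_loss = val_loss,
                 train_loss = train_loss,
                 checkpoint_by_val_acc = ck_acc,
                 checkpoint_by_val_loss = ck_loss,
                 architecture = model$architecture, input = model$input,
                 params = params),
            class = "train_artifacts")
}

#' Select a checkpoint from training artifacts
#'
#' `max_val_acc` picks the epoch with the highest validation accuracy,
#' `min_val_loss` the epoch with the lowest validation loss; ties break to
#' the earliest epoch.
#'
#' @param artifacts A `train_artifacts`.
#' @param criterion `"max_val_acc"` or `"min_val_loss"`.
#' @return `list(epoch, net)`.
#' @export
select_checkpoint <- function(artifacts,
                              criterion = c("max_val_acc", "min_val_loss")) {
  criterion <- match.arg(criterion)
  if (!length(artifacts$val_acc))
    stop("select_checkpoint: empty validation curves", call. = FALSE)
  ck <- if (criterion == "max_val_acc") artifacts$checkpoint_by_val_acc
        else artifacts$checkpoint_by_val_loss
  want <- if (criterion == "max_val_acc") which.max(artifacts$val_acc)
          else which.min(artifacts$val_loss)
  stopifnot(ck$epoch == want)  # running-best bookkeeping matches the curves
  ck
}

#' Temporal median filter on a predicted label sequence
#'
#' Sliding-majority (binary median) smoothing of one trial's window-ordered
#' class sequence: each position is replaced by the majority label of its
#' kernel-length neighborhood. Windows hop 1 s, so a 7-window kernel spans
#' 7 s. Edges use replicated padding; the filter must never cross trial
#' boundaries (pass one trial's sequence at a time).
#'
#' @param labels Character (`"negative"`/`"positive"`), logical, or 0/1
#'   numeric sequence from a single trial.
#' @param kernel Odd positive window length (default 7).
#' @return Filtered sequence of the same type.
#' @export
median_filter_labels <- function(labels, kernel = 7L) {
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("median_filter_labels: 'kernel' must be odd and positive",
         call. = FALSE)
  n <- length(labels)
  if (n == 0L || kernel == 1L) return(labels)
  as_bin <- function(l) {
    if (is.character(l)) as.integer(l == "positive")
    else if (is.logical(l)) as.integer(l)
    else as.integer(l)
  }
  x <- as_bin(labels)
  h <- (kernel - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  out <- integer(n)
  for (i in seq_len(n))
    out[i] <- as.integer(sum(xp[i:(i + kernel - 1L)]) * 2L > kernel)
  if (is.character(labels)) c("negative", "positive")[out + 1L]
  else if (is.logical(labels)) as.logical(out)
  else out
}

#' Confusion matrix counts (positive = "like")
#'
#' @param predicted,truth Character vectors in
#'   `{"negative", "positive"}`.
#' @return Named integer vector TP, TN, FP, FN of class `confusion_matrix`.
#' @export
confusion_matrix <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  structure(c(TP = sum(predicted == "positive" & truth == "positive"),
              TN = sum(predicted == "negative" & truth == "negative"),
              FP = sum(predicted == "positive" & truth == "negative"),
              FN = sum(predicted == "negative" & truth == "positive")),
            class = "confusion_matrix")
}

#' Accuracy, sensitivity, specificity from a confusion matrix
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), accuracy =
#' (TP + TN) / total. A metric with an empty denominator is returned as
#' `NA` with a warning and is excluded from report averages.
#'
#' @param cm A [confusion_matrix()] (or named vector with TP, TN, FP, FN).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
metrics <- function(cm) {
  tp <- cm[["TP"]]; tn <- cm[["TN"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("metrics: no positive samples; sensitivity undefined", call. = FALSE)
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("metrics: no negative samples; specificity undefined", call. = FALSE)
    NA_real_
  }
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = sens, specificity = spec)
}

# Per-trial window predictions for a test subset: predicts each unique
# window once, median-filters within each trial, and maps window-level
# labels back to every sample (so augmented duplicates inherit their
# window's prediction).
predict_test_labels <- function(net, input_desc, test_ds, kernel) {
  key <- paste(test_ds$meta$trial_id, test_ds$meta$window_index)
  first <- !duplicated(key)
  uds <- subset_dataset(test_ds, first)
  ord <- order(uds$meta$trial_id, uds$meta$window_index)
  uds <- subset_dataset(uds, ord)
  x <- model_input(uds, input_desc)
  n <- input_batch_size(x)
  probs <- matrix(NA_real_, n, 2)
  for (start in seq(1L, n, by = 512L)) {
    idx <- start:min(start + 511L, n)
    logits <- nn_forward(net, slice_input(x, idx), train = FALSE)$y
    probs[idx, ] <- softmax_probs(logits)
  }
  raw <- c("negative", "positive")[max.col(probs, ties.method = "first")]
  filt <- character(n)
  for (ii in split(seq_len(n), uds$meta$trial_id))
    filt[ii] <- median_filter_labels(raw[ii], kernel)
  ukey <- paste(uds$meta$trial_id, uds$meta$window_index)
  m <- match(key, ukey)
  list(raw = raw[m], filtered = filt[m])
}

#' Evaluate selected checkpoints on a held-out test subject
#'
#' Predicts every test window with both selected checkpoints, applies the
#' temporal median filter per trial, and tabulates confusion matrices
#' before and after filtering.
#'
#' @param artifacts A `train_artifacts`.
#' @param test_ds `eeg_dataset` subset containing only the test subject.
#' @param kernel Median-filter length in windows (default 7).
#' @param training_subjects Optional character vector used for a strict
#'   leakage audit: evaluation hard-fails if the test subject appears in it.
#' @return List per criterion (`max_val_acc`, `min_val_loss`), each with
#'   `raw` and `filtered` confusion matrices and the checkpoint `epoch`.
#' @export
evaluate_fold <- function(artifacts, test_ds, kernel = 7L,
                          training_subjects = NULL) {
  test_subjects <- unique(test_ds$meta$subject_id)
  if (!is.null(training_subjects) &&
      length(intersect(test_subjects, training_subjects)))
    stop("evaluate_fold: leakage detected -- test subject(s) ",
         paste(intersect(test_subjects, training_subjects), collapse = ", "),
         " present in the training set", call. = FALSE)
  truth <- test_ds$meta$label
  out <- list()
  for (criterion in c("max_val_acc", "min_val_loss")) {
    ck <- select_checkpoint(artifacts, criterion)
    pl <- predict_test_labels(ck$net, artifacts$input, test_ds, kernel)
    out[[criterion]] <- list(epoch = ck$epoch,
                             raw = confusion_matrix(pl$raw, truth),
                             filtered = confusion_matrix(pl$filtered, truth))
  }
  out
}

#' Run the full leave-one-subject-out evaluation for one architecture
#'
#' For every (test, validation) fold: builds a freshly initialized model,
#' trains on the remaining subjects, selects both checkpoints, and evaluates
#' the test subject with and without median filtering. A strict subject-ID
#' audit guarantees no test or validation sample (including augmented
#' duplicates) reaches training. Per-fold seeds derive from `seed` and the
#' fold index, so the run is reproducible and folds are order-independent.
#'
#' @param ds A prepared (balanced, corrected) `eeg_dataset`.
#' @param architecture One of [architectures()].
#' @param params A [training_params()]; its `seed` field is ignored in
#'   favor of per-fold derived seeds.
#' @param kernel Median-filter length (windows).
#' @param seed Master seed.
#' @param dropout_rate Dropout fraction for the models.
#' @param test_balanced Evaluate on the balanced test windows (default
#'   TRUE); if FALSE, augmented test duplicates are dropped first.
#' @param folds Optional restriction to a subset of fold indices.
#' @param progress Print one line per fold.
#' @return Object of class `loso_result`: per-fold confusion matrices and
#'   checkpoint epochs, plus the schedule and configuration.
#' @export
run_loso <- function(ds, architecture, params = training_params(),
                     kernel = 7L, seed = 1L, dropout_rate = 0.5,
                     test_balanced = TRUE, folds = NULL, progress = FALSE) {
  schedule <- loso_schedule(unique(ds$meta$subject_id))
  if (is.null(folds)) folds <- seq_along(schedule)
  results <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    fi <- folds[k]
    fold <- schedule[[fi]]
    fold_seed <- derive_seed(seed, fi)
    tr_idx <- ds$meta$subject_id %in% fold$training
    va_idx <- ds$meta$subject_id == fold$validation
    te_idx <- ds$meta$subject_id == fold$test
    # strict separation audit
    leak <- intersect(unique(ds$meta$subject_id[tr_idx]),
                      c(fold$test, fold$validation))
    if (length(leak))
      stop("run_loso: leakage -- subject(s) ", paste(leak, collapse = ", "),
           " in training set", call. = FALSE)
    model <- build_model(architecture, dropout_rate = dropout_rate,
                         seed = fold_seed)
    tr_ds <- subset_dataset(ds, tr_idx)
    va_ds <- subset_dataset(ds, va_idx)
    te_ds <- subset_dataset(ds, te_idx)
    if (!test_balanced) te_ds <- subset_dataset(te_ds, !te_ds$meta$augmented)
    p <- params; p$seed <- derive_seed(fold_seed, 2L)
    artifacts <- train_network(model, model_input(tr_ds, model),
                               class_index(tr_ds),
                               model_input(va_ds, model), class_index(va_ds),
                               p)
    ev <- evaluate_fold(artifacts, te_ds, kernel,
                        training_subjects = fold$training)
    results[[k]] <- list(fold_index = fi, test = fold$test,
                         validation = fold$validation, result = ev)
    if (progress)
      message(sprintf("fold %d/%d: test %s val %s (acc %.3f)", k,
                      length(folds), fold$test, fold$validation,
                      metrics(ev$max_val_acc$filtered)[["accuracy"]]))
  }
  structure(list(architecture = architecture, folds = results,
                 schedule = schedule, kernel = kernel, seed = seed,
                 params = params),
            class = "loso_result")
}

#' Per-fold results as a long table
#'
#' @param result A `loso_result` (or list of them).
#' @return data.frame with one row per fold x criterion x filter state:
#'   counts TP/TN/FP/FN and the three metrics.
#' @export
fold_table <- function(result) {
  if (inherits(result, "loso_result")) result <- list(result)
  do.call(rbind, lapply(result, function(res) {
    do.call(rbind, lapply(res$folds, function(fr) {
      do.call(rbind, lapply(c("max_val_acc", "min_val_loss"), function(cr) {
        do.call(rbind, lapply(c("raw", "filtered"), function(st) {
          cm <- fr$result[[cr]][[st]]
          mm <- suppressWarnings(metrics(cm))
          data.frame(architecture = res$architecture,
                     fold_index = fr$fold_index, test_subject = fr$test,
                     validation_subject = fr$validation,
                     criterion = cr, filtered = (st == "filtered"),
                     checkpoint_epoch = fr$result[[cr]]$epoch,
                     TP = cm[["TP"]], TN = cm[["TN"]],
                     FP = cm[["FP"]], FN = cm[["FN"]],
                     accuracy = mm[["accuracy"]],
                     sensitivity = mm[["sensitivity"]],
                     specificity = mm[["specificity"]],
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
  }))
}

#' Aggregate fold results into the evaluation report
#'
#' Per test subject, metrics are averaged over that subject's folds (one per
#' validation subject); the report is the unweighted mean and standard
#' deviation of the per-subject means across subjects, per architecture,
#' checkpoint-selection criterion, and filter state. Undefined (NA) metrics
#' are excluded from the averages.
#'
#' @param result A `loso_result` or list of them (one per architecture).
#' @return Object of class `evaluation_report`: list with `per_subject` and
#'   `summary` data.frames.
#' @export
aggregate_report <- function(result) {
  ft <- fold_table(result)
  agg <- function(df, by) {
    stats::aggregate(df[c("accuracy", "sensitivity", "specificity")],
                     by = df[by], FUN = mean, na.rm = TRUE)
  }
  per_subject <- agg(ft, c("architecture", "criterion", "filtered",
                           "test_subject"))
  per_subject <- per_subject[order(per_subject$architecture,
                                   per_subject$criterion,
                                   !per_subject$filtered,
                                   per_subject$test_subject), ]
  rownames(per_subject) <- NULL
  mean_part <- agg(per_subject, c("architecture", "criterion", "filtered"))
  sd_part <- stats::aggregate(
    per_subject[c("accuracy", "sensitivity", "specificity")],
    by = per_subject[c("architecture", "criterion", "filtered")],
    FUN = stats::sd)
  names(sd_part)[4:6] <- paste0(names(sd_part)[4:6], "_sd")
  summary <- merge(mean_part, sd_part,
                   by = c("architecture", "criterion", "filtered"))
  summary <- summary[order(summary$architecture, summary$criterion,
                           !summary$filtered), ]
  rownames(summary) <- NULL
  structure(list(per_subject = per_subject, summary = summary),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Leave-one-subject-out evaluation (mean over subjects, sd across subjects)\n")
  df <- x$summary
  df$accuracy <- sprintf("%.3f (%.3f)", df$accuracy, df$accuracy_sd)
  df$sensitivity <- sprintf("%.3f (%.3f)", df$sensitivity, df$sensitivity_sd)
  df$specificity <- sprintf("%.3f (%.3f)", df$specificity, df$specificity_sd)
  print(df[c("architecture", "criterion", "filtered", "accuracy",
             "sensitivity", "specificity")], row.names = FALSE)
  invisible(x)
}
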