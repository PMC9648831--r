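#' The seven CNN architectures
#'
#' @return Character vector of valid architecture names.
#' @export
architectures <- function() {
  c("inception_merged", "stacked_merged", "parallel_bands",
    "single_alpha", "single_beta", "single_low_gamma", "single_high_gamma")
}

# three-conv stack shared by the single-band models and the parallel branches
single_band_trunk <- function() {
  nn_seq(nn_conv(2, 2, 1, 10, act = "elu"),
         nn_conv(2, 2, 10, 10, act = "elu"),
         nn_conv(3, 3, 10, 10, act = "elu"))
}

# Inception module: four ten-filter branches on a cin-channel 10x10 map --
# 1x1 bottleneck feeding 2x2 / 3x3 / 5x5 convolutions, plus 3x3 max pooling
# (stride 1) feeding a 1x1 bottleneck -- concatenated to 40 channels, ELU
# after the concatenation. Every layer keeps the 10x10 spatial size
# ('same' zero padding).
inception_module <- function(cin) {
  list(nn_concat(list(
         nn_seq(nn_conv(1, 1, cin, 10, act = "elu"), nn_conv(2, 2, 10, 10)),
         nn_seq(nn_conv(1, 1, cin, 10, act = "elu"), nn_conv(3, 3, 10, 10)),
         nn_seq(nn_conv(1, 1, cin, 10, act = "elu"), nn_conv(5, 5, 10, 10)),
         nn_seq(nn_pool3(), nn_conv(1, 1, cin, 10)))),
       nn_elu())
}

#' Build one of the seven CNN classifiers
#'
#' All architectures use stride-1 convolutions with 'same' zero padding (the
#' spatial size is preserved through every layer), ELU activations, ten
#' filters per convolution, a single dropout layer before the head, and a
#' two-unit fully connected softmax head. Weights use Glorot-uniform
#' initialization, biases zeros.
#'
#' * `stacked_merged` — five conv layers (2x2, 2x2, 3x3, 3x3, 3x3) on the
#'   10x10 merged input.
#' * `single_alpha` / `single_beta` / `single_low_gamma` /
#'   `single_high_gamma` — three conv layers (2x2, 2x2, 3x3) on one 5x5
#'   band frame.
#' * `parallel_bands` — four weight-independent three-conv branches, one per
#'   band frame, channel-concatenated before the head.
#' * `inception_merged` — three sequential inception modules on the 10x10
#'   input; each module concatenates four ten-filter branches
#'   (bottleneck->2x2, bottleneck->3x3, bottleneck->5x5,
#'   3x3 max pool->bottleneck) to a 40-channel output.
#'
#' @param architecture One of [architectures()].
#' @param dropout_rate Dropout fraction before the head (default 0.5).
#' @param seed Optional integer seed for the weight draw; when `NULL` the
#'   current RNG stream is used.
#' @return Object of class `eeg_cnn`.
#' @export
build_model <- function(architecture, dropout_rate = 0.5, seed = NULL) {
  architecture <- match.arg(architecture, architectures())
  build <- function() {
    if (architecture == "stacked_merged") {
      net <- nn_seq(nn_conv(2, 2, 1, 10, act = "elu"),
                    nn_conv(2, 2, 10, 10, act = "elu"),
                    nn_conv(3, 3, 10, 10, act = "elu"),
                    nn_conv(3, 3, 10, 10, act = "elu"),
                    nn_conv(3, 3, 10, 10, act = "elu"),
                    nn_dropout(dropout_rate), nn_flatten(),
                    nn_dense(10 * 10 * 10, 2))
      input <- list(kind = "merged", shape = c(10, 10, 1))
    } else if (architecture == "parallel_bands") {
      net <- nn_seq(nn_multi(lapply(1:4, function(i) single_band_trunk())),
                    nn_dropout(dropout_rate), nn_flatten(),
                    nn_dense(5 * 5 * 40, 2))
      input <- list(kind = "bands", shape = c(5, 5, 1))
    } else if (architecture == "inception_merged") {
      net <- do.call(nn_seq, c(inception_module(1),
                               inception_module(40),
                               inception_module(40),
                               list(nn_dropout(dropout_rate), nn_flatten(),
                                    nn_dense(10 * 10 * 40, 2))))
      input <- list(kind = "merged", shape = c(10, 10, 1))
    } else {
      band <- sub("^single_", "", architecture)
      net <- nn_seq(nn_conv(2, 2, 1, 10, act = "elu"),
                    nn_conv(2, 2, 10, 10, act = "elu"),
                    nn_conv(3, 3, 10, 10, act = "elu"),
                    nn_dropout(dropout_rate), nn_flatten(),
                    nn_dense(5 * 5 * 10, 2))
      input <- list(kind = "band", band = band, shape = c(5, 5, 1))
    }
    net <- number_conv_slots(net)
    structure(list(architecture = architecture, input = input, net = net,
                   dropout_rate = dropout_rate, n_classes = 2L),
              class = "eeg_cnn")
  }
  if (is.null(seed)) build() else with_rng_stream(derive_seed(seed), build())
}

#' Extract a model's input tensor(s) from a dataset
#'
#' @param ds An `eeg_dataset`.
#' @param model An `eeg_cnn` (or its `input` descriptor).
#' @return A `(10,10,1,N)` array for merged input, a list of four
#'   `(5,5,1,N)` arrays for parallel-band input, or one `(5,5,1,N)` array
#'   for a single-band model.
#' @export
model_input <- function(ds, model) {
  input <- if (inherits(model, "eeg_cnn")) model$input else model
  n <- n_samples(ds)
  band_arr <- function(b) {
    a <- ds$band[, , b, , drop = FALSE]
    dim(a) <- c(5, 5, 1, n)
    a
  }
  switch(input$kind,
         merged = ds$merged,
         bands = lapply(band_names(), band_arr),
         band = band_arr(input$band),
         stop("unknown input kind: ", input$kind))
}

#' Class labels as integers for the loss (negative = 1, positive = 2)
#' @param ds An `eeg_dataset`.
#' @return Integer vector.
#' @export
class_index <- function(ds) ifelse(ds$meta$label == "positive", 2L, 1L)

#' Forward pass: class probabilities or labels
#'
#' @param object An `eeg_cnn`.
#' @param x Input tensor(s) as produced by [model_input()].
#' @param type `"prob"` (B x 2 matrix, columns negative/positive) or
#'   `"class"` (character labels).
#' @param batch_size Forward-pass chunk size.
#' @param ... Unused.
#' @return Matrix of probabilities or character vector.
#' @export
predict.eeg_cnn <- function(object, x, type = c("prob", "class"),
                            batch_size = 512L, ...) {
  type <- match.arg(type)
  n <- input_batch_size(x)
  probs <- matrix(NA_real_, n, 2,
                  dimnames = list(NULL, c("negative", "positive")))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    logits <- nn_forward(object$net, slice_input(x, idx), train = FALSE)$y
    probs[idx, ] <- softmax_probs(logits)
  }
  if (type == "prob") probs
  else c("negative", "positive")[max.col(probs, ties.method = "first")]
}

# ---- summaries -------------------------------------------------------------

n_params_layer <- function(layer) {
  switch(layer$type,
    seq = sum(vapply(layer$layers, n_params_layer, 0)),
    conv = length(layer$W) + length(layer$b),
    dense = length(layer$W) + length(layer$b),
    concat = ,
    multi = sum(vapply(layer$branches, n_params_layer, 0)),
    0)
}

summarize_walk <- function(layer, shape, prefix, rows) {
  fmt <- function(s) paste(s, collapse = "x")
  add <- function(op, kernel, out_shape, np) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = paste0(prefix, op), kernel = kernel,
      output_shape = fmt(out_shape), n_params = np,
      stringsAsFactors = FALSE)
  }
  switch(layer$type,
    seq = {
      for (l in layer$layers) {
        r <- summarize_walk(l, shape, prefix, rows)
        shape <- r$shape; rows <- r$rows
      }
    },
    conv = {
      shape <- c(shape[1], shape[2], layer$cout)
      add("conv", sprintf("%dx%dx%d", layer$cout, layer$kh, layer$kw),
          shape, n_params_layer(layer))
      if (identical(layer$act, "elu")) add("elu", "", shape, 0)
    },
    elu = add("elu", "", shape, 0),
    pool3 = add("max_pool", "3x3", shape, 0),
    dropout = add(sprintf("dropout(p=%.2g)", layer$p), "", shape, 0),
    flatten = {
      shape <- prod(shape)
      add("flatten", "", shape, 0)
    },
    dense = {
      shape <- layer$dout
      add("dense", sprintf("%dx%d", layer$din, layer$dout), shape,
          n_params_layer(layer))
    },
    concat = ,
    multi = {
      couts <- integer(length(layer$branches))
      for (i in seq_along(layer$branches)) {
        r <- summarize_walk(layer$branches[[i]], shape,
                            sprintf("%sbranch%d/", prefix, i), rows)
        rows <- r$rows
        couts[i] <- r$shape[3]
      }
      shape <- c(shape[1], shape[2], sum(couts))
      add("concat", "", shape, 0)
    })
  list(shape = shape, rows = rows)
}

#' Layer-by-layer model summary
#'
#' Deterministic per-layer table of operator names, kernel specs, output
#' shapes, and parameter counts, followed by the softmax head.
#'
#' @param model An `eeg_cnn`.
#' @return data.frame with columns `layer`, `kernel`, `output_shape`,
#'   `n_params`; attributes `architecture` and `total_params`.
#' @export
summarize <- function(model) {
  stopifnot(inherits(model, "eeg_cnn"))
  r <- summarize_walk(model$net, model$input$shape, "", list())
  rows <- do.call(rbind, r$rows)
  rows <- rbind(rows, data.frame(layer = "softmax", kernel = "",
                                 output_shape = "2", n_params = 0,
                                 stringsAsFactors = FALSE))
  structure(rows, architecture = model$architecture,
            total_params = n_params_layer(model$net))
}

#' Number of convolution layers in a model
#' @param model An `eeg_cnn`.
#' @return Integer count (branch convolutions all counted).
#' @export
n_conv_layers <- function(model) {
  s <- summarize(model)
  sum(grepl("(^|/)conv$", s$layer))
}

#' @export
print.eeg_cnn <- function(x, ...) {
  cat(sprintf("eeg_cnn '%s' (%s input, %d parameters)\n", x$architecture,
              x$input$kind, n_params_layer(x$net)))
  print(summarize(x), row.names = FALSE)
  invisible(x)
}
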