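# Minimal CNN engine: stride-1 'same' convolutions, 3x3 max pooling, ELU,
# inverted dropout, dense head, softmax cross-entropy, Adam. Feature maps are
# (H, W, C, B) arrays; the conv/pool hot path runs in C++ (im2col + GEMM).
# Composite nodes express branching graphs: `concat` feeds one input to
# several branches and concatenates their outputs along channels; `multi`
# does the same with one input per branch.

nn_seq <- function(...) list(type = "seq", layers = list(...))

# act = "elu" fuses the activation into the convolution kernels
nn_conv <- function(kh, kw, cin, cout, act = "none", alpha = 1) {
  fan_in <- kh * kw * cin; fan_out <- kh * kw * cout
  a <- sqrt(6 / (fan_in + fan_out))  # Glorot uniform
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       act = act, alpha = if (identical(act, "elu")) alpha else -1,
       W = array(stats::runif(kh * kw * cin * cout, -a, a),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

nn_dense <- function(din, dout) {
  a <- sqrt(6 / (din + dout))
  list(type = "dense", din = din, dout = dout,
       W = matrix(stats::runif(din * dout, -a, a), din, dout),
       b = numeric(dout))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assign each conv layer a unique scratch slot for the forward/backward
# im2col reuse; called once per built network
number_conv_slots <- function(layer, counter = new.env()) {
  if (is.null(counter$n)) counter$n <- 0L
  if (layer$type == "conv") {
    layer$slot <- counter$n
    counter$n <- counter$n + 1L
  } else if (layer$type == "seq") {
    layer$layers <- lapply(layer$layers, number_conv_slots, counter = counter)
  } else if (layer$type %in% c("concat", "multi")) {
    layer$branches <- lapply(layer$branches, number_conv_slots,
                             counter = counter)
  }
  layer
}

nn_elu <- function(alpha = 1) list(type = "elu", alpha = alpha)
nn_pool3 <- function() list(type = "pool3")
nn_dropout <- function(p = 0.5) list(type = "dropout", p = p)
nn_flatten <- function() list(type = "flatten")
nn_concat <- function(branches) list(type = "concat", branches = branches)
nn_multi <- function(branches) list(type = "multi", branches = branches)

concat_channels <- function(outs) {
  d <- dim(outs[[1]])
  ctot <- sum(vapply(outs, function(o) dim(o)[3], 0))
  y <- array(0, c(d[1], d[2], ctot, d[4]))
  off <- 0L
  for (o in outs) {
    cc <- dim(o)[3]
    y[, , off + seq_len(cc), ] <- o
    off <- off + cc
  }
  y
}

nn_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    seq = {
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        r <- nn_forward(layer$layers[[i]], x, train)
        x <- r$y; caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    conv = {
      if (length(dim(x)) != 4L || dim(x)[3] != layer$cin)
        stop(sprintf("conv layer (%dx%d, %d->%d filters): input has shape [%s], expected %d channels",
                     layer$kh, layer$kw, layer$cin, layer$cout,
                     paste(dim(x), collapse = ","), layer$cin), call. = FALSE)
      y <- cpp_conv2d_fwd(x, dim(x), layer$W, dim(layer$W), layer$b,
                          layer$alpha, layer$slot %||% -1L)
      list(y = y, cache = list(x = x, y = y))
    },
    dense = {
      y <- x %*% layer$W
      y <- sweep(y, 2, layer$b, "+")
      list(y = y, cache = x)
    },
    elu = {
      y <- cpp_elu_fwd(x, layer$alpha)
      list(y = y, cache = y)
    },
    pool3 = {
      r <- cpp_pool3_fwd(x, dim(x))
      list(y = r$y, cache = list(idx = r$idx, xd = dim(x)))
    },
    dropout = {
      if (train && layer$p > 0) {
        mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
        y <- x * mask
        dim(y) <- dim(x)
        list(y = y, cache = mask)
      } else list(y = x, cache = NULL)
    },
    flatten = {
      d <- dim(x)
      list(y = t(matrix(x, prod(d[1:3]), d[4])), cache = d)
    },
    concat = {
      rs <- lapply(layer$branches, nn_forward, x = x, train = train)
      list(y = concat_channels(lapply(rs, `[[`, "y")),
           cache = lapply(rs, `[[`, "cache"))
    },
    multi = {
      if (!is.list(x) || length(x) != length(layer$branches))
        stop("multi-input network: expected a list of ",
             length(layer$branches), " input tensors, got ",
             if (is.list(x)) length(x) else 1L, call. = FALSE)
      rs <- mapply(function(br, xi) nn_forward(br, xi, train),
                   layer$branches, x, SIMPLIFY = FALSE)
      list(y = concat_channels(lapply(rs, `[[`, "y")),
           cache = lapply(rs, `[[`, "cache"))
    },
    stop("unknown layer type: ", layer$type))
}

# Returns list(dx, grads); grads mirrors the layer tree. need_dx = FALSE
# skips the input-gradient computation for a network's first layer.
nn_backward <- function(layer, cache, dy, need_dx = TRUE, reuse = FALSE) {
  switch(layer$type,
    seq = {
      grads <- vector("list", length(layer$layers))
      for (i in rev(seq_along(layer$layers))) {
        r <- nn_backward(layer$layers[[i]], cache[[i]], dy,
                         need_dx = need_dx || i > 1L, reuse = reuse)
        dy <- r$dx; grads[i] <- list(r$grads)
      }
      list(dx = dy, grads = grads)
    },
    conv = {
      r <- cpp_conv2d_bwd(cache$x, dim(cache$x), layer$W, dim(layer$W),
                          cache$y, dy, layer$alpha, need_dx,
                          if (reuse) layer$slot %||% -1L else -1L)
      list(dx = r$dx, grads = list(W = r$dw, b = r$db))
    },
    dense = {
      list(dx = dy %*% t(layer$W),
           grads = list(W = crossprod(cache, dy), b = colSums(dy)))
    },
    elu = list(dx = cpp_elu_bwd(cache, dy, layer$alpha), grads = NULL),
    pool3 = {
      if (!need_dx) list(dx = NULL, grads = NULL)
      else list(dx = cpp_pool3_bwd(cache$idx, dy, cache$xd), grads = NULL)
    },
    dropout = {
      if (is.null(cache)) list(dx = dy, grads = NULL)
      else {
        dx <- dy * cache
        dim(dx) <- dim(dy)
        list(dx = dx, grads = NULL)
      }
    },
    flatten = {
      dx <- t(dy)
      dim(dx) <- cache
      list(dx = dx, grads = NULL)
    },
    concat = {
      off <- 0L; dxs <- NULL; grads <- vector("list", length(layer$branches))
      for (i in seq_along(layer$branches)) {
        cc <- branch_channels(layer$branches[[i]])
        dyi <- dy[, , off + seq_len(cc), , drop = FALSE]
        off <- off + cc
        r <- nn_backward(layer$branches[[i]], cache[[i]], dyi,
                         need_dx = need_dx, reuse = reuse)
        grads[i] <- list(r$grads)
        if (need_dx) dxs <- if (is.null(dxs)) r$dx else dxs + r$dx
      }
      list(dx = dxs, grads = grads)
    },
    multi = {
      off <- 0L; dxs <- vector("list", length(layer$branches))
      grads <- vector("list", length(layer$branches))
      for (i in seq_along(layer$branches)) {
        cc <- branch_channels(layer$branches[[i]])
        dyi <- dy[, , off + seq_len(cc), , drop = FALSE]
        off <- off + cc
        r <- nn_backward(layer$branches[[i]], cache[[i]], dyi,
                         need_dx = need_dx, reuse = reuse)
        grads[i] <- list(r$grads); dxs[i] <- list(r$dx)
      }
      list(dx = dxs, grads = grads)
    },
    stop("unknown layer type: ", layer$type))
}

# output channel count of a branch (last channel-defining layer)
branch_channels <- function(layer) {
  switch(layer$type,
    seq = {
      for (l in rev(layer$layers)) {
        cc <- branch_channels(l)
        if (!is.na(cc)) return(cc)
      }
      NA_integer_
    },
    conv = layer$cout,
    concat = sum(vapply(layer$branches, branch_channels, 0L)),
    multi = sum(vapply(layer$branches, branch_channels, 0L)),
    NA_integer_)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layer) {
  switch(layer$type,
    seq = lapply(layer$layers, adam_init),
    conv = ,
    dense = list(mW = layer$W * 0, vW = layer$W * 0,
                 mb = layer$b * 0, vb = layer$b * 0),
    concat = ,
    multi = lapply(layer$branches, adam_init),
    NULL)
}

adam_step_param <- function(p, g, m, v, lr, t, beta1, beta2, eps) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_update <- function(layer, grads, state, lr, t, beta1, beta2, eps) {
  switch(layer$type,
    seq = {
      for (i in seq_along(layer$layers)) {
        r <- adam_update(layer$layers[[i]], grads[[i]], state[[i]],
                         lr, t, beta1, beta2, eps)
        layer$layers[[i]] <- r$layer; state[i] <- list(r$state)
      }
      list(layer = layer, state = state)
    },
    conv = ,
    dense = {
      rW <- adam_step_param(layer$W, grads$W, state$mW, state$vW,
                            lr, t, beta1, beta2, eps)
      rb <- adam_step_param(layer$b, grads$b, state$mb, state$vb,
                            lr, t, beta1, beta2, eps)
      layer$W <- rW$p; layer$b <- rb$p
      list(layer = layer,
           state = list(mW = rW$m, vW = rW$v, mb = rb$m, vb = rb$v))
    },
    concat = ,
    multi = {
      for (i in seq_along(layer$branches)) {
        r <- adam_update(layer$branches[[i]], grads[[i]], state[[i]],
                         lr, t, beta1, beta2, eps)
        layer$branches[[i]] <- r$layer; state[i] <- list(r$state)
      }
      list(layer = layer, state = state)
    },
    list(layer = layer, state = state))
}

# ---- loss ------------------------------------------------------------------

# logits: B x K; y: integer class in 1..K
softmax_xent <- function(logits, y) {
  m <- apply(logits, 1, max)
  z <- logits - m
  ez <- exp(z)
  sz <- rowSums(ez)
  p <- ez / sz
  n <- nrow(logits)
  ly <- z[cbind(seq_len(n), y)] - log(sz)
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), y)] <- 1
  list(loss = -mean(ly), probs = p, dlogits = (p - onehot) / n)
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# slice a model input (array or list of arrays) along the batch dimension
slice_input <- function(x, idx) {
  if (is.list(x)) lapply(x, function(a) a[, , , idx, drop = FALSE])
  else x[, , , idx, drop = FALSE]
}

input_batch_size <- function(x) {
  if (is.list(x)) dim(x[[1]])[4] else dim(x)[4]
}
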