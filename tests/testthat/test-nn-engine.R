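# Finite-difference gradient checks of the backpropagation engine. The
# convolutions compute in single precision, so comparisons use a combined
# absolute/relative tolerance well above float noise but far below any real
# gradient defect.
expect_grad_close <- function(analytic, numeric) {
  expect_lt(abs(analytic - numeric), 1e-3 + 2e-2 * abs(numeric))
}

loss_of <- function(net, x, y) {
  fw <- eegpref:::nn_forward(net, x, train = FALSE)
  eegpref:::softmax_xent(fw$y, y)$loss
}

check_input_grads <- function(arch, x, n_checks = 6, eps = 1e-3) {
  m <- build_model(arch, dropout_rate = 0, seed = 17)
  y <- rep(c(1L, 2L), length.out = eegpref:::input_batch_size(x))
  fw <- eegpref:::nn_forward(m$net, x, train = FALSE)
  ls <- eegpref:::softmax_xent(fw$y, y)
  bw <- eegpref:::nn_backward(m$net, fw$cache, ls$dlogits)
  for (k in seq_len(n_checks)) {
    if (is.list(x)) {
      b <- (k %% 4) + 1; i <- withr::with_seed(k, sample(length(x[[b]]), 1))
      xp <- x; xp[[b]][i] <- xp[[b]][i] + eps
      xm <- x; xm[[b]][i] <- xm[[b]][i] - eps
      g_num <- (loss_of(m$net, xp, y) - loss_of(m$net, xm, y)) / (2 * eps)
      expect_grad_close(bw$dx[[b]][i], g_num)
    } else {
      i <- withr::with_seed(k, sample(length(x), 1))
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      g_num <- (loss_of(m$net, xp, y) - loss_of(m$net, xm, y)) / (2 * eps)
      expect_grad_close(bw$dx[i], g_num)
    }
  }
}

test_that("input gradients match finite differences for all model families", {
  set.seed(1)
  check_input_grads("stacked_merged", array(stats::rnorm(300), c(10, 10, 1, 3)))
  check_input_grads("inception_merged", array(stats::rnorm(200), c(10, 10, 1, 2)))
  check_input_grads("parallel_bands",
                    lapply(1:4, function(i) array(stats::rnorm(50), c(5, 5, 1, 2))))
  check_input_grads("single_low_gamma", array(stats::rnorm(75), c(5, 5, 1, 3)))
})

test_that("weight and bias gradients match finite differences", {
  set.seed(2)
  m <- build_model("stacked_merged", dropout_rate = 0, seed = 23)
  x <- array(stats::rnorm(400), c(10, 10, 1, 4))
  y <- c(1L, 2L, 2L, 1L)
  fw <- eegpref:::nn_forward(m$net, x, train = FALSE)
  ls <- eegpref:::softmax_xent(fw$y, y)
  bw <- eegpref:::nn_backward(m$net, fw$cache, ls$dlogits, need_dx = FALSE)
  eps <- 1e-3
  # a conv weight and bias in layers 1, 3, 5, and the dense head
  for (li in c(1L, 3L, 5L)) {
    wi <- withr::with_seed(li, sample(length(m$net$layers[[li]]$W), 2))
    for (i in wi) {
      mp <- m; mp$net$layers[[li]]$W[i] <- mp$net$layers[[li]]$W[i] + eps
      mm <- m; mm$net$layers[[li]]$W[i] <- mm$net$layers[[li]]$W[i] - eps
      g_num <- (loss_of(mp$net, x, y) - loss_of(mm$net, x, y)) / (2 * eps)
      expect_grad_close(bw$grads[[li]]$W[i], g_num)
    }
    mp <- m; mp$net$layers[[li]]$b[1] <- mp$net$layers[[li]]$b[1] + eps
    mm <- m; mm$net$layers[[li]]$b[1] <- mm$net$layers[[li]]$b[1] - eps
    g_num <- (loss_of(mp$net, x, y) - loss_of(mm$net, x, y)) / (2 * eps)
    expect_grad_close(bw$grads[[li]]$b[1], g_num)
  }
  di <- length(m$net$layers)  # dense
  mp <- m; mp$net$layers[[di]]$W[7, 2] <- mp$net$layers[[di]]$W[7, 2] + eps
  mm <- m; mm$net$layers[[di]]$W[7, 2] <- mm$net$layers[[di]]$W[7, 2] - eps
  g_num <- (loss_of(mp$net, x, y) - loss_of(mm$net, x, y)) / (2 * eps)
  expect_grad_close(bw$grads[[di]]$W[7, 2], g_num)
})

test_that("max pooling forwards neighborhood maxima and routes gradients", {
  x <- array(0, c(4, 4, 1, 1))
  x[2, 2, 1, 1] <- 5; x[4, 4, 1, 1] <- 3
  r <- eegpref:::cpp_pool3_fwd(x, dim(x))
  y <- r$y
  expect_equal(y[1, 1, 1, 1], 5)   # corner sees the (2,2) max
  expect_equal(y[3, 3, 1, 1], 5)
  expect_equal(y[4, 4, 1, 1], 3)
  dy <- array(1, dim(x))
  dx <- eegpref:::cpp_pool3_bwd(r$idx, dy, dim(x))
  expect_equal(sum(dx), 16)        # all gradient mass routed somewhere
  expect_gt(dx[2, 2, 1, 1], 0)     # argmax receives it
  expect_equal(dx[1, 1, 1, 1], 0)
})

test_that("training on separable data drives loss down to perfect accuracy", {
  xs <- array(0, c(10, 10, 1, 200))
  xs[, , , 101:200] <- 1; xs[, , , 1:100] <- -1
  ys <- rep(1:2, each = 100)
  m <- build_model("stacked_merged", dropout_rate = 0, seed = 31)
  a <- train_network(m, xs, ys, xs, ys,
                     training_params(max_epochs = 10, seed = 41))
  expect_length(a$val_acc, 10L)
  expect_true(all(diff(a$train_loss) < 0))  # strictly decreasing
  expect_equal(utils::tail(a$val_acc, 1), 1.0)
})

test_that("training is deterministic for a fixed seed", {
  xs <- array(stats::rnorm(10 * 10 * 64), c(10, 10, 1, 64))
  ys <- rep(1:2, 32)
  tp <- training_params(max_epochs = 4, seed = 5)
  a1 <- train_network(build_model("stacked_merged", seed = 6), xs, ys, xs, ys, tp)
  a2 <- train_network(build_model("stacked_merged", seed = 6), xs, ys, xs, ys, tp)
  expect_identical(a1$val_acc, a2$val_acc)
  expect_identical(a1$val_loss, a2$val_loss)
  expect_identical(a1$checkpoint_by_val_acc$epoch, a2$checkpoint_by_val_acc$epoch)
  expect_identical(a1$checkpoint_by_val_acc$net, a2$checkpoint_by_val_acc$net)
  expect_error(train_network(build_model("stacked_merged", seed = 1),
                             array(0, c(10, 10, 1, 0)), integer(0), xs, ys, tp),
               "empty")
})

test_that("dropout perturbs training-mode forward passes only", {
  m <- build_model("stacked_merged", dropout_rate = 0.5, seed = 8)
  x <- array(stats::rnorm(200), c(10, 10, 1, 2))
  e1 <- eegpref:::nn_forward(m$net, x, train = FALSE)$y
  e2 <- eegpref:::nn_forward(m$net, x, train = FALSE)$y
  expect_identical(e1, e2)
  set.seed(1); t1 <- eegpref:::nn_forward(m$net, x, train = TRUE)$y
  set.seed(2); t2 <- eegpref:::nn_forward(m$net, x, train = TRUE)$y
  expect_false(identical(t1, t2))
})
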