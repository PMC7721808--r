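# Architecture, gradients, training behaviour and inference of the U-Net.

test_that("parameter count matches a hand-computed closed form on a tiny spec", {
  # depth 1, width 2, in = out = 1, batch norm + residual:
  #   conv1: (9*1+1)*2 = 20, bn1: 2*2 = 4
  #   conv2: (9*2+1)*2 = 38, bn2: 2*2 = 4
  #   final 1x1: 2*1 + 1 = 3            -> total 69
  expect_identical(count_parameters(unet_spec(depth = 1, base_width = 2)), 69L)
  # same without batch norm: 20 + 38 + 3 = 61
  expect_identical(
    count_parameters(unet_spec(depth = 1, base_width = 2,
                               batch_norm = FALSE)), 61L)
})

test_that("parameter count scales ~quadratically with base width", {
  n16 <- count_parameters(unet_spec(base_width = 16, batch_norm = FALSE,
                                    residual = FALSE))
  n64 <- count_parameters(unet_spec(base_width = 64, batch_norm = FALSE,
                                    residual = FALSE))
  expect_lt(abs(n64 / n16 - 16), 1.6)  # within 10% of the factor 16
})

test_that("residual spec requires matching channel counts", {
  expect_error(unet_spec(in_channels = 1, out_channels = 2, residual = TRUE))
  expect_silent(unet_spec(in_channels = 1, out_channels = 2,
                          residual = FALSE))
})

test_that("analytic gradients agree with finite differences", {
  spec <- unet_spec(depth = 2, base_width = 2)
  m <- build_model(spec, seed = 3)
  withr::with_seed(4, {
    m$par$final$W[] <- stats::rnorm(length(m$par$final$W), 0, 0.1)
    H <- 8; W <- 8; N <- 2
    X <- matrix(stats::runif(H * W * N), ncol = 1)
    Tt <- matrix(stats::runif(H * W * N), ncol = 1)
    grids <- pics:::unet_grids(spec, H, W, N)
    loss_of <- function(par) {
      fw <- pics:::unet_forward(par, spec, X, grids, train = TRUE)
      mean((fw$Y - Tt)^2)
    }
    fw <- pics:::unet_forward(m$par, spec, X, grids, train = TRUE)
    grad <- pics:::unet_backward(m$par, spec, X, fw$cache,
                                 2 * (fw$Y - Tt) / length(fw$Y), grids)
    probes <- list(
      list(get = function(p) p$enc[[1]]$c1$W,
           set = function(p, w) { p$enc[[1]]$c1$W[] <- w; p },
           g = grad$enc[[1]]$c1$W),
      list(get = function(p) p$dec[[1]]$up$W,
           set = function(p, w) { p$dec[[1]]$up$W[] <- w; p },
           g = grad$dec[[1]]$up$W),
      list(get = function(p) p$enc[[2]]$c2$bn$gamma,
           set = function(p, w) { p$enc[[2]]$c2$bn$gamma[] <- w; p },
           g = grad$enc[[2]]$c2$bn$gamma),
      list(get = function(p) p$final$W,
           set = function(p, w) { p$final$W[] <- w; p },
           g = grad$final$W))
    eps <- 1e-6
    for (pr in probes) {
      w <- pr$get(m$par)
      for (k in sample(length(w), min(3, length(w)))) {
        wp <- w; wp[k] <- wp[k] + eps
        wm <- w; wm[k] <- wm[k] - eps
        num <- (loss_of(pr$set(m$par, wp)) - loss_of(pr$set(m$par, wm))) /
          (2 * eps)
        expect_lt(abs(num - pr$g[k]) /
                    max(abs(num), abs(pr$g[k]), 1e-10), 1e-4)
      }
    }
  })
})

test_that("zeroed final block with residual path is the exact identity", {
  m <- zero_final_block(build_model(unet_spec(depth = 3, base_width = 4),
                                    seed = 5))
  withr::with_seed(6, x <- matrix(stats::runif(60 * 44), 60, 44))
  expect_identical(infer(m, x, pad_px = 8), x)
  # output shape equals input shape for non-divisible sizes too
  withr::with_seed(7, x2 <- matrix(stats::runif(75 * 53), 75, 53))
  expect_identical(dim(infer(m, x2, pad_px = 8)), dim(x2))
})

test_that("an untrained residual model already starts at the identity", {
  m <- build_model(unet_spec(depth = 2, base_width = 4), seed = 8)
  withr::with_seed(9, x <- matrix(stats::runif(32 * 32), 32, 32))
  expect_identical(infer(m, x, pad_px = 4), x)
})

test_that("training on the identity task reaches tiny MSE within a few epochs", {
  withr::with_seed(10, pairs <- lapply(1:6, function(i) {
    x <- matrix(stats::runif(32 * 32), 32, 32)
    list(x = x, y = x)
  }))
  m <- build_model(unet_spec(depth = 2, base_width = 4), seed = 11)
  # knock the final block away from the identity so training has work to do
  withr::with_seed(12,
    m$par$final$W[] <- stats::rnorm(length(m$par$final$W), 0, 0.1))
  fit <- train(m, pairs, train_config(lr = 1e-2, epochs = 10, batch_size = 2,
                                      val_fraction = 1 / 3, seed = 13))
  expect_lt(min(fit$history$val_loss), 1e-4)
  expect_equal(nrow(fit$history), 10)
  expect_lt(fit$history$train_loss[10], fit$history$train_loss[1])
})

test_that("training is reproducible given the seed and rejects bad input", {
  withr::with_seed(14, pairs <- lapply(1:4, function(i) {
    x <- matrix(stats::runif(16 * 16), 16, 16)
    list(x = x, y = 1 - x)
  }))
  cfg <- train_config(epochs = 3, batch_size = 2, seed = 15)
  f1 <- train(build_model(unet_spec(depth = 2, base_width = 2), seed = 16),
              pairs, cfg)
  f2 <- train(build_model(unet_spec(depth = 2, base_width = 2), seed = 16),
              pairs, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$par, f2$model$par)
  expect_error(train(f1$model, list(), cfg), "at least one")
  bad <- list(list(x = matrix(0, 16, 16), y = matrix(0, 8, 8)))
  expect_error(train(f1$model, bad, cfg), "shape")
})

test_that("padded and unpadded inference agree in the field interior", {
  fx <- fixture_staining_pairs(n = 8, seed0 = 300)
  m <- build_model(unet_spec(depth = 3, base_width = 4), seed = 17)
  fit <- train(m, fx$pairs[seq_len(fx$n_train)],
               train_config(epochs = 2, batch_size = 4, seed = 18))
  x <- fx$pairs[[fx$n_train + 1]]$x
  p32 <- infer(fit$model, x, pad_px = 32)
  p0 <- infer(fit$model, x, pad_px = 0)
  n <- nrow(x); core <- seq.int(ceiling(n * 0.3), floor(n * 0.7))
  expect_lt(max(abs(p32[core, core] - p0[core, core])), 0.05)
  expect_identical(dim(p32), dim(x))
})

test_that("pooled Pearson quality behaves as a correlation", {
  withr::with_seed(19, {
    a <- matrix(stats::runif(120 * 120), 120, 120)
    b <- matrix(stats::runif(120 * 120), 120, 120)
  })
  expect_equal(pearson_quality(a, a), 1)
  expect_equal(pearson_quality(list(a, b), list(a, b)), 1)
  expect_equal(pearson_quality(-a, a), -1)
  expect_lt(abs(pearson_quality(a, b)), 0.05)
  expect_error(pearson_quality(matrix(1, 4, 4), matrix(1, 4, 4)),
               "variance")
})
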