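test_that("a perfectly confused discriminator sits at 2 ln 2", {
  logits <- array(0, dim = c(4, 4, 1, 2))
  expect_equal(bce_with_logits(logits, 1) + bce_with_logits(logits, 0),
               2 * log(2))
})

test_that("training is bit-reproducible under a fixed seed", {
  pairs <- desk_pairs(6, seed = 70)
  cfg <- train_config(epochs = 2, crop_size = 32, batch_size = 2,
                      val_every = 1, seed = 5)
  f1 <- fit_cgan(pairs[1:4], pairs[5:6], config = cfg)
  f2 <- fit_cgan(pairs[1:4], pairs[5:6], config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$val_history, f2$val_history)
})

test_that("empty or malformed datasets are rejected", {
  pairs <- desk_pairs(2, seed = 71)
  expect_error(fit_cgan(list(), pairs, config = train_config(epochs = 1)),
               "empty")
  expect_error(fit_cgan(pairs, list(), config = train_config(epochs = 1)),
               "empty")
  bad <- list(list(x = pairs[[1]]$x, y = pairs[[1]]$y[1:32, 1:32, ]))
  expect_error(fit_cgan(bad, pairs, config = train_config(epochs = 1)),
               "differ")
})

test_that("pure L1 training converges to the conditional median, MSE to the mean", {
  # fixed input; constant target 0.2, 0.2 or 0.8 with equal probability:
  # median 0.2, mean 0.4
  size <- 16L
  set.seed(8)
  x <- array(runif(size * size), dim = c(size, size, 1))
  mk <- function(v) array(v, dim = c(size, size, 1))
  train <- lapply(rep(c(0.2, 0.2, 0.8), 10), function(v) list(x = x, y = mk(v)))
  val <- list(list(x = x, y = mk(0.2)))
  cfg <- function(seed) train_config(epochs = 250, batch_size = 6,
                                     crop_size = size, lr = 2e-3,
                                     augment = FALSE, adv_weight = 0,
                                     val_every = 50, seed = seed)
  gcfg <- generator_config(in_channels = 1, out_channels = 1, depth = 2,
                           width = 4)
  l1_fit <- fit_cgan(train, val, gen_config = gcfg, config = cfg(1))
  out_l1 <- mean(predict(l1_fit, x))
  expect_lt(abs(out_l1 - 0.2), 0.08)

  mse_fit <- fit_unet(train, val, channel = 1,
                      net_config = unet_config(in_channels = 1, depth = 2,
                                               width = 4),
                      config = cfg(1))
  out_mse <- mean(predict(mse_fit, x))
  expect_lt(abs(out_mse - 0.4), 0.08)
})

test_that("a single sample is memorized to below 1e-3 of target variance", {
  size <- 16L
  set.seed(3)
  x <- array(runif(size * size * 2), dim = c(size, size, 2))
  y <- array(runif(size * size, 0.1, 0.9), dim = c(size, size, 1))
  pair <- list(x = x, y = y)
  fit <- fit_unet(list(pair), list(pair), channel = 1,
                  net_config = unet_config(in_channels = 2, depth = 2,
                                           width = 8),
                  config = train_config(epochs = 2000, batch_size = 1,
                                        crop_size = size, lr = 3e-3,
                                        augment = FALSE, val_every = 500,
                                        seed = 2))
  pred <- predict(fit, x)[, , 1]
  expect_lt(mean((pred - y[, , 1])^2), 1e-3 * var(as.vector(y)))
})

test_that("tiled prediction contracts hold", {
  set.seed(6)
  g <- build_generator(generator_config())
  # field equal to one tile: output equals the direct model call
  x <- array(runif(64 * 64 * 7), dim = c(64, 64, 7))
  direct <- forward(g, x)[, , , 1]
  expect_equal(predict_tiled(g, x, tile = 64L, overlap = 16L),
               array(direct, dim = dim(direct)))
  # constant input: near-constant output away from the field border.
  # Each tile is zero-padded independently, so tiles must comfortably
  # exceed the receptive field; Hann blending suppresses the residual
  # tile-edge perturbation.
  xc <- array(0.5, dim = c(192, 160, 7))
  yc <- predict_tiled(g, xc, tile = 128L, overlap = 64L)
  interior <- yc[48:144, 48:112, , drop = FALSE]
  for (ch in 1:3) {
    expect_lt(max(interior[, , ch]) - min(interior[, , ch]), 0.02)
  }
  # rectangular field, declared contract
  xs <- array(runif(128 * 96 * 7), dim = c(128, 96, 7))
  expect_equal(dim(predict_tiled(g, xs, tile = 64L, overlap = 16L)),
               c(128, 96, 3))
})

test_that("validation history tracks the declared schedule", {
  pairs <- desk_pairs(6, seed = 77)
  fit <- fit_cgan(pairs[1:4], pairs[5:6],
                  config = train_config(epochs = 5, crop_size = 32,
                                        batch_size = 2, val_every = 2,
                                        seed = 3))
  expect_identical(fit$val_history$epoch, c(1L, 2L, 4L, 5L))
  expect_identical(nrow(fit$history), 5L)
  expect_true(all(is.finite(fit$history$loss_gen)))
  expect_true(all(is.finite(fit$history$loss_disc)))
})
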