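test_that("generator maps stacks to bounded 3-channel images", {
  set.seed(1)
  g <- build_generator(generator_config())
  x <- array(runif(64 * 64 * 7), dim = c(64, 64, 7))
  y <- forward(g, x)
  expect_equal(dim(y), c(64, 64, 3, 1))
  expect_true(all(y >= 0 & y <= 1))
  # bounded output even for inputs far outside the normalized range
  y2 <- forward(g, x * 1e4)
  expect_true(all(y2 >= 0 & y2 <= 1))
})

test_that("non-divisible field sizes raise a shape error naming the constraint", {
  set.seed(1)
  g <- build_generator(generator_config(depth = 4))
  x <- array(runif(63 * 63 * 7), dim = c(63, 63, 7))
  expect_error(forward(g, x), "divisible")
})

test_that("initialization is randomized across seeds and reproducible within", {
  x <- array(runif(32 * 32 * 7), dim = c(32, 32, 7))
  set.seed(1); g1 <- build_generator()
  set.seed(2); g2 <- build_generator()
  set.seed(1); g3 <- build_generator()
  expect_gt(max(abs(forward(g1, x) - forward(g2, x))), 1e-4)
  expect_identical(forward(g1, x), forward(g3, x))
})

test_that("discriminator returns a reduced patch score map", {
  set.seed(1)
  d <- build_discriminator(discriminator_config(10, depth = 3))
  x <- array(runif(64 * 64 * 10), dim = c(64, 64, 10))
  s <- forward(d, x)
  expect_equal(dim(s), c(8, 8, 1, 1))
  # deterministic inference
  expect_identical(forward(d, x), forward(d, x))
  # wrong channel count
  xb <- array(runif(64 * 64 * 9), dim = c(64, 64, 9))
  expect_error(forward(d, xb), "channels")
})

test_that("per-channel U-Net instances share the parameter count", {
  cfg <- unet_config()
  set.seed(1); n1 <- build_unet(cfg)
  set.seed(2); n2 <- build_unet(cfg)
  set.seed(3); n3 <- build_unet(cfg)
  expect_identical(n_params(n1), n_params(n2))
  expect_identical(n_params(n2), n_params(n3))
  x <- array(runif(32 * 32 * 7), dim = c(32, 32, 7))
  expect_equal(dim(forward(n1, x)), c(32, 32, 1, 1))
})

test_that("tiled prediction agrees with whole-field inference", {
  # tiles are zero-padded independently, so agreement requires tiles well
  # beyond the receptive field; Hann blending suppresses tile-edge effects
  set.seed(4)
  g <- build_generator(generator_config())
  pair <- desk_pairs(1, seed = 60,
                     params = phantom_params(field_size = c(192, 160),
                                             n_cells = 3L,
                                             cell_radius = 30,
                                             nucleus_radius = 8,
                                             droplets_per_cell = 8L,
                                             r_large_median = 9))[[1]]
  whole <- predict_tiled(g, pair$x)
  tiled <- predict_tiled(g, pair$x, tile = 128L, overlap = 64L)
  expect_equal(dim(tiled), dim(whole))
  expect_lt(max(abs(tiled - whole)), 0.02)
  expect_lt(mean(abs(tiled - whole)), 1e-3)
})
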