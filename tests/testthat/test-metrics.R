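test_that("nMAE_px has its closed-form values and scale invariance", {
  set.seed(1)
  t <- matrix(runif(32 * 32, 0.1, 1), 32)
  expect_equal(nmae_px(t, t), 0)
  expect_equal(nmae_px(2 * t, t), 1)
  for (a in c(0.01, 1, 65535)) {
    p <- t + matrix(rnorm(length(t), sd = 0.05), 32)
    expect_equal(nmae_px(a * p, a * t), nmae_px(p, t), tolerance = 1e-12)
  }
  expect_error(nmae_px(t, matrix(0, 32, 32)), "zero mean")
  expect_error(nmae_px(t, t[1:16, ]), "shape")
})

test_that("SSIM identity, symmetry, bound and anticorrelation", {
  set.seed(2)
  t <- matrix(runif(32 * 32), 32)
  expect_equal(ssim(t, t), 1)
  p <- matrix(pmin(1, pmax(0, t + rnorm(length(t), sd = 0.1))), 32)
  expect_equal(ssim(p, t), ssim(t, p))
  expect_lte(ssim(p, t), 1)
  # inverted binary structure: strongly negative similarity
  set.seed(3)
  b <- matrix(rbinom(32 * 32, 1, 0.5), 32)
  expect_lt(ssim(1 - b, b), 0)
  expect_error(ssim(t[1:8, 1:8], t[1:8, 1:8], window = 11), "window")
})

test_that("independent noise images have near-zero SSIM on average", {
  vals <- vapply(1:100, function(s) {
    set.seed(s)
    ssim(matrix(runif(64 * 64), 64), matrix(runif(64 * 64), 64))
  }, 0)
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("PSNR closed forms and monotonicity", {
  t <- matrix(0.5, 16, 16)
  expect_equal(psnr(t + 0.1, t), 20)            # MSE 0.01, MAX 1
  expect_equal(psnr(t + sqrt(1e-3), t), 30, tolerance = 1e-9)
  expect_identical(psnr(t, t), Inf)
  set.seed(4)
  base <- matrix(runif(32 * 32), 32)
  noise <- matrix(rnorm(32 * 32), 32)
  p1 <- psnr(base + 0.01 * noise, base)
  p2 <- psnr(base + 0.05 * noise, base)
  expect_gt(p1, p2)
})

test_that("evaluate_set aggregates per-channel metrics", {
  set.seed(5)
  imgs <- lapply(1:3, function(i) array(runif(24 * 24 * 3), c(24, 24, 3)))
  rep0 <- evaluate_set(imgs, imgs)
  expect_true(all(rep0$per_image$nmae_px == 0))
  expect_true(all(rep0$per_image$ssim == 1))
  one <- evaluate_set(imgs[1], imgs[1])
  expect_true(all(one$summary$nmae_sd == 0))
  expect_error(evaluate_set(imgs, imgs[1:2]), "length")
})

test_that("mean nMAE_px under additive Gaussian error matches E|N(0,s)|", {
  # target constant c, prediction c + eps: nMAE = E|eps| / c = s*sqrt(2/pi)/c
  s <- 0.04; cval <- 0.5
  set.seed(6)
  targets <- lapply(1:15, function(i) array(cval, c(64, 64, 1)))
  preds <- lapply(1:15, function(i) {
    targets[[i]] + array(rnorm(64 * 64, sd = s), c(64, 64, 1))
  })
  rep <- evaluate_set(preds, targets, channels = "ch")
  expected <- s * sqrt(2 / pi) / cval
  expect_lt(abs(rep$summary$nmae_mean - expected) / expected, 0.05)
})
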