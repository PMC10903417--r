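test_that("scene sampling honours counts, determinism and separation", {
  p0 <- phantom_params(n_cells = 0L, seed = 3)
  expect_length(sample_scene(p0)$cells, 0)

  p1 <- phantom_params(field_size = 96, n_cells = 1L, cell_radius = 30,
                       nucleus_radius = 8, droplets_per_cell = 10L,
                       r_large_median = 8, seed = 7)
  expect_identical(sample_scene(p1), sample_scene(p1))

  p5 <- phantom_params(field_size = 256, n_cells = 5L, cell_radius = 40,
                       nucleus_radius = 12, droplets_per_cell = 4L, seed = 11)
  sc <- sample_scene(p5)
  centres <- t(vapply(sc$cells, function(cl) cl$nucleus$centre, numeric(2)))
  d <- as.matrix(dist(centres))
  expect_true(all(d[upper.tri(d)] >= 2 * p5$nucleus_radius))
})

test_that("impossible cell packing raises a placement error", {
  p <- phantom_params(field_size = 48, n_cells = 30L, cell_radius = 20,
                      nucleus_radius = 16, droplets_per_cell = 0L, seed = 1)
  expect_error(sample_scene(p, max_attempts = 50L), "place cell")
})

test_that("fluorescence rendering matches analytic geometry", {
  # single droplet of radius 10, no noise: foreground area ~ pi r^2
  dr <- data.frame(x = 32, y = 32, r = 10, pop = "large",
                   stringsAsFactors = FALSE)
  sc <- manual_scene(64, droplets = dr)
  p <- noiseless_params(64)
  set.seed(1)
  out <- render_fluorescence(sc, p)
  ch <- out$image[, , 1]
  half <- p$fluor_bg[1] + (max(ch) - p$fluor_bg[1]) / 2
  area <- sum(ch > half)
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.02)

  # empty scene, sigma = 0: all three channels identically at background
  sc0 <- structure(list(field_size = c(32L, 32L), cells = list(),
                        seed = NULL), class = "vs_scene")
  p0 <- noiseless_params(32)
  out0 <- render_fluorescence(sc0, p0)
  for (k in 1:3) {
    expect_true(all(out0$image[, , k] == round(p0$fluor_bg[k])))
  }
})

test_that("ground truth counts and areas are exact", {
  p <- phantom_params(field_size = 128, n_cells = 2L, cell_radius = 34,
                      nucleus_radius = 9, droplets_per_cell = 15L,
                      r_large_median = 9, seed = 21)
  sc <- sample_scene(p)
  K <- sum(vapply(sc$cells, function(cl) nrow(cl$droplets), 0L))
  out <- render_fluorescence(sc, p)
  lab <- out$ground_truth$labels$droplets
  expect_identical(length(unique(lab[lab > 0])), as.integer(K))
  # per-object area records equal label-map pixel counts exactly
  obj <- out$ground_truth$objects
  dro <- obj[obj$class == "droplets", ]
  counted <- tabulate(lab[lab > 0], nbins = max(lab))
  expect_identical(dro$area, counted[dro$label])
})

test_that("bright-field stack has the stated optical structure", {
  # nuclei are invisible at zero contrast weight: on a droplet-free scene
  # (droplet defocus rings would otherwise shadow the cytoplasm baseline)
  # the nucleus mean matches the surrounding cytoplasm within the noise
  # level, and becomes clearly separated once the weight is nonzero
  p <- phantom_params(field_size = 128, n_cells = 2L, cell_radius = 30,
                      nucleus_radius = 9, droplets_per_cell = 0L, seed = 5)
  sc <- sample_scene(p)
  masks <- scene_masks(sc)
  set.seed(5)
  bf <- render_brightfield(sc, p)
  nuc <- masks$nuclei > 0
  cyt <- masks$cytoplasm > 0 & !nuc
  for (s in c(1, 4, 7)) {
    sl <- bf[, , s]
    expect_lt(abs(mean(sl[nuc]) - mean(sl[cyt])), p$bf_noise_sd)
  }
  p_vis <- p
  p_vis$nucleus_contrast <- 3000
  set.seed(5)
  bf_vis <- render_brightfield(sc, p_vis)
  expect_gt(abs(mean(bf_vis[, , 4][nuc]) - mean(bf_vis[, , 4][cyt])),
            5 * p$bf_noise_sd)

  # all contrast weights zero: pure background noise
  p0 <- phantom_params(field_size = 64, n_cells = 1L, cell_radius = 22,
                       nucleus_radius = 7, droplets_per_cell = 5L,
                       r_large_median = 8, droplet_contrast = 0,
                       cyto_contrast = 0, nucleus_contrast = 0, seed = 9)
  sc0 <- sample_scene(p0)
  set.seed(9)
  bf0 <- render_brightfield(sc0, p0)
  expect_lt(abs(mean(bf0) - p0$bf_level), 20)
  expect_lt(abs(sd(bf0[, , 1]) - p0$bf_noise_sd) / p0$bf_noise_sd, 0.1)
})

test_that("droplet contrast flips polarity across the defocus stack", {
  dr <- data.frame(x = 32, y = 32, r = 8, pop = "large",
                   stringsAsFactors = FALSE)
  sc <- manual_scene(64, droplets = dr)
  p <- noiseless_params(64)
  set.seed(2)
  bf <- render_brightfield(sc, p)
  core <- function(s) {
    sl <- bf[, , s]
    ys <- 29:35
    mean(sl[ys, 29:35]) - mean(sl[1:10, 1:10])   # centre minus far field
  }
  expect_lt(core(1) * core(7), 0)
})

test_that("bright-field stack is more informative about droplets than nuclei", {
  pair <- desk_pairs(1, seed = 33)[[1]]
  X <- apply(pair$x, 3, as.vector)
  r2 <- function(y) {
    fit <- lm.fit(cbind(1, X), as.vector(y))
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  expect_gt(r2(pair$y[, , 1]), r2(pair$y[, , 3]))
})

test_that("make_dataset writes a reproducible indexed dataset", {
  p <- phantom_params(field_size = 48, n_cells = 1L, cell_radius = 16,
                      nucleus_radius = 5, droplets_per_cell = 3L,
                      r_large_median = 6, seed = 50)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  suppressWarnings(make_dataset(3, p, d1, val_fraction = 1 / 3))
  suppressWarnings(make_dataset(3, p, d2))
  idx <- load_index(d1)
  expect_length(idx$entries, 3)
  expect_true(all(file.exists(vapply(idx$entries, `[[`, "", "brightfield"))))
  expect_identical(vapply(idx$entries, `[[`, "", "split"),
                   c("train", "train", "val"))
  # same seed: bit-identical pixel data
  a <- read_stack_tiff(file.path(d1, "field_0001_bf.tif"))
  b <- read_stack_tiff(file.path(d2, "field_0001_bf.tif"))
  expect_identical(a, b)
  expect_error(make_dataset(0, p, tempdir()), "n_fields")
})
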