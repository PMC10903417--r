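disk_image <- function(size, centres, r, fg = 0.8, bg = 0.02) {
  img <- matrix(bg, size, size)
  for (i in seq_len(nrow(centres))) {
    for (row in seq_len(size)) {
      for (col in seq_len(size)) {
        if ((row - centres[i, 1])^2 + (col - centres[i, 2])^2 <= r^2) {
          img[row, col] <- fg
        }
      }
    }
  }
  img
}

test_that("disjoint bright disks are identified individually", {
  img <- disk_image(64, rbind(c(14, 14), c(14, 48), c(48, 30)), r = 7)
  lab <- identify_primary(img, segmentation_params(c(6, 30), "global",
                                                   declump = "none",
                                                   smoothing_sigma = 0))
  expect_identical(max(lab), 3L)
  # labels contiguous 1..K
  expect_identical(sort(unique(as.vector(lab[lab > 0]))), 1:3)
})

test_that("constant and empty images yield empty label maps", {
  flat <- matrix(0.4, 32, 32)
  expect_warning(
    lab <- identify_primary(flat, segmentation_params(c(4, 20), "adaptive")),
    "constant")
  expect_identical(max(lab), 0L)
})

test_that("secondary objects conserve the seed count and cover their seeds", {
  set.seed(1)
  img <- disk_image(64, rbind(c(24, 32)), r = 22, fg = 0.5)
  img <- img + matrix(rnorm(64 * 64, sd = 0.01), 64)
  seeds <- matrix(0L, 64, 64)
  seeds[20:26, 18:24] <- 1L
  seeds[20:26, 40:46] <- 2L
  lab <- identify_secondary(img, seeds,
                            segmentation_params(c(10, 64), "global",
                                                declump = "none",
                                                smoothing_sigma = 1))
  expect_identical(length(unique(lab[lab > 0])), 2L)
  expect_true(all(lab[seeds == 1L] == 1L))
  expect_true(all(lab[seeds == 2L] == 2L))
  # the two objects partition the thresholded blob
  expect_gt(sum(lab == 1L), 0)
  expect_gt(sum(lab == 2L), 0)
  # empty seeds: empty result
  expect_identical(max(identify_secondary(img, matrix(0L, 64, 64))), 0L)
})

test_that("two-pass droplet segmentation merges small and large objects", {
  set.seed(2)
  small_c <- as.matrix(expand.grid(c(10, 30, 50, 70, 90), c(10, 30)))
  large_c <- as.matrix(expand.grid(c(15, 45, 75), 70))
  img <- disk_image(100, small_c, r = 3)
  img2 <- disk_image(100, large_c, r = 9)
  img <- pmax(img, img2)
  ps <- segmentation_params(c(2, 10), "global", declump = "intensity",
                            smoothing_sigma = 0.5)
  pl <- segmentation_params(c(10, 30), "global", declump = "intensity",
                            smoothing_sigma = 1)
  lab <- segment_droplets(img, ps, pl)
  expect_identical(length(unique(lab[lab > 0])), nrow(small_c) + nrow(large_c))
  # a disk caught by both passes is counted once: identical params reduce
  # to a single identify_primary
  lab1 <- segment_droplets(img, ps, ps)
  ref <- identify_primary(img, ps)
  expect_identical(length(unique(lab1[lab1 > 0])),
                   length(unique(ref[ref > 0])))
  # empty image allowed
  expect_identical(max(segment_droplets(matrix(0, 32, 32), ps, pl)), 0L)
})

test_that("feature extraction has its closed-form values", {
  img <- disk_image(48, rbind(c(24, 24)), r = 8, fg = 0.6, bg = 0)
  lab <- matrix(0L, 48, 48)
  lab[img > 0.3] <- 1L
  A <- sum(lab == 1L)
  f <- extract_features(lab, img, "droplets", "img1")
  expect_identical(f$count, 1L)
  expect_equal(f$mean_area, A)
  expect_equal(f$integrated_intensity, 0.6 * A)
  expect_equal(f$mean_intensity, 0.6)
  expect_equal(f$sd_intensity, 0)

  # two uniform disks at 0.2 and 0.4: mean 0.3, population sd 0.1
  img2 <- matrix(0, 48, 48)
  lab2 <- matrix(0L, 48, 48)
  img2[10:15, 10:15] <- 0.2; lab2[10:15, 10:15] <- 1L
  img2[30:35, 30:35] <- 0.4; lab2[30:35, 30:35] <- 2L
  f2 <- extract_features(lab2, img2)
  expect_equal(f2$mean_intensity, 0.3)
  expect_equal(f2$sd_intensity, 0.1)

  # empty map: count 0 and undefined features
  f0 <- extract_features(matrix(0L, 8, 8), matrix(0, 8, 8))
  expect_identical(f0$count, 0L)
  expect_true(is.na(f0$mean_area))
})

test_that("integrated intensity is additive over objects", {
  set.seed(7)
  img <- matrix(runif(64 * 64), 64)
  lab <- matrix(0L, 64, 64)
  lab[5:20, 5:20] <- 1L
  lab[30:60, 30:50] <- 2L
  lab[2:10, 40:60] <- 3L
  total <- extract_features(lab, img)$integrated_intensity
  per_obj <- vapply(1:3, function(l) sum(img[lab == l]), 0)
  expect_identical(total, sum(per_obj))
})

test_that("full-image profiling recovers phantom structures", {
  pair <- desk_pairs(1, seed = 91,
                     params = phantom_params(field_size = 128, n_cells = 2L,
                                             cell_radius = 34,
                                             nucleus_radius = 9,
                                             droplets_per_cell = 8L,
                                             r_large_median = 9))[[1]]
  res <- profile_image(pair$y, profiling_params(), "f1")
  ft <- res$features
  expect_identical(ft$count[ft$class == "nuclei"], 2L)
  expect_identical(ft$count[ft$class == "cytoplasm"], 2L)
  K <- length(unique(pair$ground_truth$labels$droplets
                     [pair$ground_truth$labels$droplets > 0]))
  expect_lt(abs(ft$count[ft$class == "droplets"] - K) / K, 0.35)
})
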