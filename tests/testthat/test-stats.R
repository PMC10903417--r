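test_that("nMAE_cp closed forms, exclusions and invariance", {
  t <- c(100, 200, 300)
  r0 <- nmae_cp(t, t)
  expect_equal(r0$mean_pct, 0)
  one <- nmae_cp(1.5 * 400, 400)
  expect_equal(one$mean_pct, 50)
  expect_equal(one$sd_pct, 0)
  expect_warning(out <- nmae_cp(c(1, 2), c(1, 0)), "zero")
  expect_identical(out$n_excluded, 1L)
  # invariance under joint rescaling of units
  set.seed(1)
  p <- runif(10, 50, 150); q <- runif(10, 50, 150)
  expect_equal(nmae_cp(p, q)$mean_pct, nmae_cp(1e3 * p, 1e3 * q)$mean_pct)
})

test_that("Pearson correlation with Fisher-z interval behaves at the limits", {
  x <- 1:10
  perfect <- pearson_ci(x, 2 * x + 1)
  expect_equal(perfect$rho, 1)
  expect_equal(perfect$ci, c(1, 1))
  expect_equal(pearson_ci(x, -x)$rho, -1)
  expect_error(pearson_ci(x, rep(1, 10)), "constant")
  expect_error(pearson_ci(1:2, 1:2), "3")
  # affine invariance with positive slope
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_ci(a, b)$rho, pearson_ci(3 * a + 5, b)$rho)
})

test_that("t test star mapping follows the declared thresholds", {
  expect_identical(p_stars(0.2), "ns")
  expect_identical(p_stars(0.05), "*")
  expect_identical(p_stars(0.004), "**")
  expect_identical(p_stars(0.0005), "***")
  expect_identical(p_stars(3e-5), "****")
  set.seed(3)
  out <- ttest_stars(rnorm(10), rnorm(10, 5))
  expect_lt(out$p, 1e-4)
  expect_identical(out$stars, "****")
  expect_error(ttest_stars(rep(1, 5), rep(1, 5)), "variance")
})

test_that("systematic multiplicative bias gives high rho with nonzero nMAE_cp", {
  set.seed(4)
  target <- data.frame(
    image = paste0("i", 1:12), class = "droplets",
    count = rpois(12, 50), mean_area = runif(12, 300, 500),
    integrated_intensity = runif(12, 10, 20),
    mean_intensity = runif(12, 0.02, 0.03),
    sd_intensity = runif(12, 0.003, 0.004), stringsAsFactors = FALSE)
  pred <- target
  pred$mean_area <- 1.2 * target$mean_area
  rep <- build_report(pred, target)
  row <- rep$table[rep$table$feature == "mean_area", ]
  expect_equal(row$nmae_pct, 20, tolerance = 1e-9)
  expect_equal(row$rho, 1, tolerance = 1e-12)
  expect_true(row$ci_lo <= row$rho && row$rho <= row$ci_hi)
  # identical tables: zero error everywhere
  rep0 <- build_report(target, target)
  expect_true(all(rep0$table$nmae_pct == 0))
  # row ordering: classes in input order, features in declared order
  expect_identical(unique(rep0$table$feature),
                   c("count", "mean_area", "integrated_intensity",
                     "mean_intensity", "sd_intensity"))
})

test_that("star category is consistent with the p value in reports", {
  set.seed(5)
  target <- data.frame(image = paste0("i", 1:10), class = "nuclei",
                       count = rnorm(10, 30, 2), mean_area = rnorm(10, 7000, 300),
                       integrated_intensity = rnorm(10, 170, 10),
                       mean_intensity = rnorm(10, 0.022, 0.001),
                       sd_intensity = rnorm(10, 0.006, 0.0005),
                       stringsAsFactors = FALSE)
  pred <- target
  pred$count <- target$count + rnorm(10, 0, 0.5)
  rep <- build_report(pred, target)
  for (i in seq_len(nrow(rep$table))) {
    r <- rep$table[i, ]
    if (!is.na(r$p_value)) {
      expect_identical(r$stars, p_stars(r$p_value))
    }
  }
})
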