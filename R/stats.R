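# Comparison statistics between feature tables from virtually and
# chemically stained images.
#
# nMAE_cp is computed per image (|pred - target| / target, averaged as
# mean +/- sd over images, in %), not as a ratio of aggregates; the
# aggregate ratio is reported alongside as a consistency diagnostic. The
# t test is the classic equal-variance Student test, two-tailed, unpaired.
# All "+/- sd" aggregates use the sample (n-1) standard deviation.

#' Per-image normalized feature error (nMAE_cp)
#'
#' For each image `i`, `r_i = |pred_i - target_i| / target_i`; the
#' aggregate is `mean(r_i) +/- sd(r_i)` in percent. Images with a zero
#' target value are excluded with a warning and counted in the report.
#'
#' @param pred,target numeric vectors of per-image feature values, aligned
#'   by image.
#' @return list with `rel_errors` (per image, fraction), `mean_pct`,
#'   `sd_pct`, `mae`, `mae_sd` (absolute units), `aggregate_ratio_pct`
#'   (ratio-of-aggregates diagnostic), and `n_excluded`.
#' @export
nmae_cp <- function(pred, target) {
  if (length(pred) != length(target)) stop("length mismatch", call. = FALSE)
  zero <- target == 0 | is.na(target) | is.na(pred)
  n_exc <- sum(zero)
  if (n_exc > 0) {
    warning(n_exc, " image(s) with zero or missing target excluded from nMAE_cp")
  }
  p <- pred[!zero]; t <- target[!zero]
  if (length(p) == 0) {
    return(list(rel_errors = numeric(0), mean_pct = NA_real_, sd_pct = NA_real_,
                mae = NA_real_, mae_sd = NA_real_,
                aggregate_ratio_pct = NA_real_, n_excluded = n_exc))
  }
  ae <- abs(p - t)
  r <- ae / t
  list(rel_errors = r,
       mean_pct = 100 * mean(r),
       sd_pct = if (length(r) > 1) 100 * sd(r) else 0,
       mae = mean(ae),
       mae_sd = if (length(ae) > 1) sd(ae) else 0,
       aggregate_ratio_pct = 100 * mean(ae) / mean(t),
       n_excluded = n_exc)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y numeric vectors, equal length >= 3, both with nonzero
#'   variance.
#' @param level confidence level (default 0.95).
#' @return list with `rho`, `ci` (length 2) and `n`. For `|rho| = 1` the
#'   interval degenerates to `[rho, rho]`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  rho <- cor(x, y)
  if (abs(rho) >= 1 - 1e-15) {
    return(list(rho = rho, ci = c(rho, rho), n = n))
  }
  z <- atanh(rho)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  list(rho = rho, ci = tanh(c(z - q * se, z + q * se)), n = n)
}

#' Two-tailed unpaired Student t test with significance stars
#'
#' Equal-variance Student test; the star category is the most significant
#' applicable one: `ns` (p > 0.05), `*` (p <= 0.05), `**` (p <= 0.01),
#' `***` (p <= 0.001), `****` (p <= 0.0001).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `p`, `statistic` and `stars`.
#' @export
ttest_stars <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each series needs at least 2 values", call. = FALSE)
  }
  if (sd(c(x - mean(x), y - mean(y))) == 0) {
    stop("zero pooled variance: t test degenerate", call. = FALSE)
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(p = tt$p.value, statistic = unname(tt$statistic),
       stars = p_stars(tt$p.value))
}

#' Map a p-value to its significance-star category
#'
#' @param p p-value.
#' @return character: `"ns"`, `"*"`, `"**"`, `"***"` or `"****"`.
#' @export
p_stars <- function(p) {
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**"
  else if (p <= 0.05) "*"
  else "ns"
}

#' Build the full feature-comparison report
#'
#' Compares predicted and target feature tables over the same image set:
#' per feature and structure class it reports target and prediction
#' aggregates (mean +/- sd), MAE, nMAE_cp (%), Pearson rho with 95% CI and
#' the Student-t significance category.
#'
#' @param pred_tables,target_tables data.frames as produced by
#'   [profile_image()] (rows keyed by image and class), covering the same
#'   images.
#' @param features feature columns to compare.
#' @return object of class `comparison_report`: data.frame `table` plus a
#'   list of excluded pairs.
#' @export
build_report <- function(pred_tables, target_tables,
                         features = c("count", "mean_area",
                                      "integrated_intensity",
                                      "mean_intensity", "sd_intensity")) {
  key <- function(d) paste(d$image, d$class)
  common <- intersect(key(pred_tables), key(target_tables))
  missing <- union(setdiff(key(pred_tables), common),
                   setdiff(key(target_tables), common))
  if (length(missing)) {
    warning(length(missing), " unmatched (image, class) pair(s) excluded")
  }
  p <- pred_tables[key(pred_tables) %in% common, ]
  t <- target_tables[key(target_tables) %in% common, ]
  p <- p[order(key(p)), ]
  t <- t[order(key(t)), ]

  rows <- list()
  for (cl in unique(t$class)) {
    ps <- p[p$class == cl, ]
    ts <- t[t$class == cl, ]
    for (f in features) {
      pv <- ps[[f]]; tv <- ts[[f]]
      nm <- nmae_cp(pv, tv)
      ok <- !(is.na(pv) | is.na(tv))
      rho <- NA_real_; ci <- c(NA_real_, NA_real_)
      pval <- NA_real_; stars <- NA_character_
      if (sum(ok) >= 3 && sd(pv[ok]) > 0 && sd(tv[ok]) > 0) {
        pc <- pearson_ci(pv[ok], tv[ok])
        rho <- pc$rho; ci <- pc$ci
      }
      if (sum(ok) >= 2) {
        tt <- tryCatch(ttest_stars(pv[ok], tv[ok]), error = function(e) NULL)
        if (!is.null(tt)) { pval <- tt$p; stars <- tt$stars }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, feature = f,
        target_mean = mean(tv[ok]), target_sd = if (sum(ok) > 1) sd(tv[ok]) else 0,
        pred_mean = mean(pv[ok]), pred_sd = if (sum(ok) > 1) sd(pv[ok]) else 0,
        mae = nm$mae, mae_sd = nm$mae_sd,
        nmae_pct = nm$mean_pct, nmae_sd_pct = nm$sd_pct,
        nmae_aggregate_pct = nm$aggregate_ratio_pct,
        rho = rho, ci_lo = ci[1], ci_hi = ci[2],
        p_value = pval, stars = stars,
        n = sum(ok), n_excluded = nm$n_excluded,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), excluded = missing),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Feature comparison (virtual vs chemical staining):\n")
  cols <- c("class", "feature", "target_mean", "pred_mean", "mae",
            "nmae_pct", "rho", "stars")
  print(x$table[, cols], digits = 3, row.names = FALSE)
  invisible(x)
}
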