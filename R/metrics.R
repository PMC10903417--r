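# Image-quality metrics comparing virtually stained to chemically stained
# channels.
#
# nMAE_px normalizes the mean absolute error by the mean of the target
# image: this is the unique common convention consistent with published
# per-channel MAE/target pairs (e.g. an MAE of 150 counts on a target of
# mean 1300 counts is an nMAE_px of 0.12). It is invariant under joint
# positive rescaling of both images, so it does not matter whether it is
# computed on raw 16-bit or on [0, 1]-normalized data.

#' Pixel-value normalized mean absolute error
#'
#' `mean(|pred - target|) / mean(target)`.
#'
#' @param pred,target numeric matrices/arrays of identical shape.
#' @return dimensionless non-negative scalar.
#' @export
nmae_px <- function(pred, target) {
  if (is.null(dim(pred)) || is.null(dim(target)) ||
      !all(dim(pred) == dim(target))) {
    stop("shape mismatch", call. = FALSE)
  }
  mt <- mean(target)
  if (mt == 0) {
    stop("target has zero mean; nMAE normalization undefined", call. = FALSE)
  }
  mean(abs(pred - target)) / mt
}

gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# local filtering with edge-replication padding
filter_replicate <- function(m, k) {
  as.matrix(EBImage::filter2(EBImage::Image(m), k, boundary = "replicate"))
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with a Gaussian window (default 11 px, sigma 1.5) and
#' stability constants K1 = 0.01, K2 = 0.03 relative to the declared
#' dynamic range; local statistics use edge-replication padding and the
#' SSIM map is averaged over all pixels.
#'
#' @param pred,target numeric matrices of identical shape.
#' @param dynamic_range declared data range (1 for normalized images).
#' @param window window size in pixels (odd).
#' @param sigma Gaussian window standard deviation.
#' @param K1,K2 stability constants.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(pred, target, dynamic_range = 1, window = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  if (!is.matrix(pred) || !is.matrix(target) ||
      !all(dim(pred) == dim(target))) {
    stop("shape mismatch: ssim expects two matrices of equal size",
         call. = FALSE)
  }
  if (window > min(dim(pred)[1:2])) {
    stop("SSIM window larger than the image", call. = FALSE)
  }
  k <- gaussian_kernel(window, sigma)
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  mu_x <- filter_replicate(pred, k)
  mu_y <- filter_replicate(target, k)
  xx <- filter_replicate(pred * pred, k) - mu_x^2
  yy <- filter_replicate(target * target, k) - mu_y^2
  xy <- filter_replicate(pred * target, k) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * xy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (xx + yy + C2)
  mean(num / den)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `20 log10(MAX) - 10 log10(MSE)`; identical images give `Inf`.
#'
#' @param pred,target numeric matrices of identical shape.
#' @param max_value declared peak value (1 for normalized images).
#' @return PSNR in decibels.
#' @export
psnr <- function(pred, target, max_value = 1) {
  if (is.null(dim(pred)) || is.null(dim(target)) ||
      !all(dim(pred) == dim(target))) {
    stop("shape mismatch", call. = FALSE)
  }
  mse <- mean((pred - target)^2)
  if (mse == 0) return(Inf)
  20 * log10(max_value) - 10 * log10(mse)
}

#' Evaluate a validation set of predicted vs target stainings
#'
#' Computes nMAE_px, SSIM and PSNR per image and channel, and aggregates
#' each metric as mean +/- standard deviation over the set (sample sd;
#' reported as 0 for a single pair).
#'
#' @param preds,targets lists of `H x W x C` arrays (same length, matching
#'   shapes), values in the declared range.
#' @param dynamic_range declared data range for SSIM/PSNR.
#' @param channels channel names (defaults to the staining convention).
#' @return object of class `metric_report`: data.frame `per_image` and
#'   data.frame `summary` (mean, sd per channel and metric).
#' @export
evaluate_set <- function(preds, targets, dynamic_range = 1,
                         channels = NULL) {
  if (length(preds) != length(targets)) {
    stop("preds and targets differ in length", call. = FALSE)
  }
  if (length(preds) == 0) stop("empty evaluation set", call. = FALSE)
  nc <- dim(preds[[1]])[3]
  if (is.null(channels)) {
    channels <- if (nc == 3) channel_names() else paste0("ch", seq_len(nc))
  }
  rows <- list()
  for (i in seq_along(preds)) {
    p <- preds[[i]]; t <- targets[[i]]
    if (!all(dim(p) == dim(t))) stop("pair ", i, ": shape mismatch",
                                     call. = FALSE)
    for (c in seq_len(nc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, channel = channels[c],
        nmae_px = nmae_px(p[, , c], t[, , c]),
        ssim = ssim(p[, , c], t[, , c], dynamic_range = dynamic_range),
        psnr = psnr(p[, , c], t[, , c], max_value = dynamic_range),
        stringsAsFactors = FALSE)
    }
  }
  per_image <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  summ <- do.call(rbind, lapply(channels, function(ch) {
    sub <- per_image[per_image$channel == ch, ]
    data.frame(channel = ch,
               nmae_mean = mean(sub$nmae_px), nmae_sd = agg(sub$nmae_px)[2],
               ssim_mean = mean(sub$ssim), ssim_sd = agg(sub$ssim)[2],
               psnr_mean = mean(sub$psnr), psnr_sd = agg(sub$psnr)[2],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_image = per_image, summary = summ),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Image-quality metrics over", length(unique(x$per_image$image)),
      "image(s):\n")
  print(x$summary, digits = 3)
  invisible(x)
}
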