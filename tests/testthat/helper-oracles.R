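# Independent reference implementations used as oracles. These deliberately
# avoid the code paths of the package (direct shift-and-add convolution in
# plain R instead of filter2; exhaustive distance computation; priority
# flooding instead of the package watershed).

pad_replicate <- function(m, h) {
  H <- nrow(m); W <- ncol(m)
  ih <- pmin(pmax(seq_len(H + 2 * h) - h, 1), H)
  iw <- pmin(pmax(seq_len(W + 2 * h) - h, 1), W)
  m[ih, iw]
}

# direct windowed convolution by explicit shift accumulation
conv_direct <- function(m, k) {
  h <- (nrow(k) - 1) / 2
  mp <- pad_replicate(m, h)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (di in seq_len(nrow(k))) {
    for (dj in seq_len(ncol(k))) {
      out <- out + k[di, dj] * mp[(di - 1) + seq_len(H), (dj - 1) + seq_len(W)]
    }
  }
  out
}

ssim_ref <- function(p, t, dynamic_range = 1, window = 11, sigma = 1.5,
                     K1 = 0.01, K2 = 0.03) {
  half <- (window - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  mx <- conv_direct(p, k); my <- conv_direct(t, k)
  vx <- conv_direct(p * p, k) - mx^2
  vy <- conv_direct(t * t, k) - my^2
  cxy <- conv_direct(p * t, k) - mx * my
  mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
         ((mx^2 + my^2 + C1) * (vx + vy + C2)))
}

psnr_ref <- function(p, t, max_value = 1) {
  10 * log10(max_value^2 / mean((p - t)^2))
}

# exact Euclidean distance of every foreground pixel to the nearest
# background pixel, by exhaustive search
dt_bruteforce <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(d2))
  }
  out
}

# brute-force seeded watershed: grow regions from the seeds, always
# absorbing the unassigned masked pixel with the highest height among those
# 4-adjacent to a region
watershed_flood <- function(height, seeds, mask) {
  lab <- seeds
  H <- nrow(mask); W <- ncol(mask)
  repeat {
    cand <- which(mask & lab == 0, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    best <- NULL; bh <- -Inf; bl <- 0
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      nb <- c(
        if (r > 1) lab[r - 1, c] else 0L,
        if (r < H) lab[r + 1, c] else 0L,
        if (c > 1) lab[r, c - 1] else 0L,
        if (c < W) lab[r, c + 1] else 0L
      )
      nb <- nb[nb > 0]
      if (length(nb) && height[r, c] > bh) {
        bh <- height[r, c]
        best <- c(r, c)
        bl <- nb[1]
      }
    }
    if (is.null(best)) break   # disconnected remainder
    lab[best[1], best[2]] <- bl
  }
  lab
}

# analytic dumbbell: two equal overlapping disks
dumbbell_mask <- function(size = 48, r = 10, sep = 16) {
  c1 <- c(size / 2, size / 2 - sep / 2)
  c2 <- c(size / 2, size / 2 + sep / 2)
  xy <- expand.grid(row = seq_len(size), col = seq_len(size))
  m1 <- (xy$row - c1[1])^2 + (xy$col - c1[2])^2 <= r^2
  m2 <- (xy$row - c2[1])^2 + (xy$col - c2[2])^2 <= r^2
  list(mask = matrix(m1 | m2, size, size), centres = rbind(c1, c2))
}

# single disk with two interior intensity peaks
twin_peak_disk <- function(size = 48, r = 14, peak_sep = 14) {
  ctr <- c(size / 2, size / 2)
  p1 <- c(size / 2, size / 2 - peak_sep / 2)
  p2 <- c(size / 2, size / 2 + peak_sep / 2)
  xy <- expand.grid(row = seq_len(size), col = seq_len(size))
  inside <- (xy$row - ctr[1])^2 + (xy$col - ctr[2])^2 <= r^2
  g1 <- exp(-((xy$row - p1[1])^2 + (xy$col - p1[2])^2) / (2 * 3^2))
  g2 <- exp(-((xy$row - p2[1])^2 + (xy$col - p2[2])^2) / (2 * 3^2))
  img <- matrix(0, size, size)
  img[matrix(c(xy$row, xy$col), ncol = 2)] <-
    inside * (0.3 + 0.7 * pmax(g1, g2))
  list(image = img, mask = matrix(inside, size, size),
       peaks = rbind(p1, p2))
}
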