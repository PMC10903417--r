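# Adversarial training of the cGAN, MSE training of the U-Net baseline,
# epoch-wise validation tracking, and tiled full-field prediction.
#
# Losses follow the pix2pix convention: the discriminator minimizes
# BCE(D(x, y), 1) + BCE(D(x, G(x)), 0); the generator minimizes the
# non-saturating adversarial term BCE(D(x, G(x)), 1) plus lambda times the
# mean absolute reconstruction error. A perfectly confused discriminator
# (probability 0.5 everywhere) therefore sits at a loss of 2 ln 2 per
# real/fake pair.

#' Training configuration
#'
#' One configuration drives both the cGAN and the U-Net baseline, so the
#' two can be compared under identical training parameters.
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size crops per gradient step.
#' @param crop_size side of the random square training crops (must be
#'   divisible by `2^depth` of the networks).
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates (0.5/0.999, the stable GAN
#'   setting).
#' @param lambda weight of the L1 reconstruction term in the generator
#'   loss.
#' @param adv_weight weight of the adversarial term; 0 disables the
#'   discriminator entirely and training reduces to pure L1 regression.
#' @param disc_input_noise standard deviation of Gaussian instance noise
#'   added to real and generated images before the discriminator sees
#'   them; smooths the discriminator's decision landscape on very small
#'   or low-diversity datasets (0 disables).
#' @param val_every validation frequency in epochs.
#' @param augment apply random 90-degree rotations and flips to crops.
#' @param seed RNG seed controlling initialization, shuffling, cropping and
#'   augmentation; fixed seed gives bit-identical loss series.
#' @param verbose print a line per validation point.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L, crop_size = 48L,
                         lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         lambda = 100, adv_weight = 1,
                         disc_input_noise = 0, val_every = 10L,
                         augment = TRUE, seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, crop_size >= 1, lr > 0,
            lambda >= 0, adv_weight >= 0, disc_input_noise >= 0,
            val_every >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size), lr = lr, beta1 = beta1,
                 beta2 = beta2, lambda = lambda, adv_weight = adv_weight,
                 disc_input_noise = disc_input_noise,
                 val_every = as.integer(val_every), augment = augment,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Binary cross-entropy on logits
#'
#' `mean(softplus(l) - target * l)`; numerically stable for large |l|.
#'
#' @param logits numeric array of unbounded scores.
#' @param target 0, 1, or an array of the same shape.
#' @return scalar loss.
#' @export
bce_with_logits <- function(logits, target) {
  sp <- pmax(logits, 0) + log1p(exp(-abs(logits)))
  mean(sp - target * logits)
}

# dBCE/dlogits for the mean reduction
bce_grad <- function(logits, target) {
  (1 / (1 + exp(-logits)) - target) / length(logits)
}

check_pairs <- function(pairs, what) {
  if (length(pairs) == 0) stop(what, " dataset is empty", call. = FALSE)
  for (p in pairs) {
    if (is.null(p$x) || is.null(p$y)) {
      stop(what, " entries must be lists with arrays x and y", call. = FALSE)
    }
    if (!all(dim(p$x)[1:2] == dim(p$y)[1:2])) {
      stop(what, ": x and y field sizes differ", call. = FALSE)
    }
  }
  invisible(TRUE)
}

rot90_hw <- function(a, k) {
  k <- k %% 4
  if (k == 0) return(a)
  for (i in seq_len(k)) {
    a <- aperm(a, c(2, 1, 3))
    a <- a[dim(a)[1]:1, , , drop = FALSE]
  }
  a
}

sample_crop <- function(pair, crop, augment) {
  H <- dim(pair$x)[1]; W <- dim(pair$x)[2]
  r0 <- if (H > crop) sample.int(H - crop + 1L, 1L) else 1L
  c0 <- if (W > crop) sample.int(W - crop + 1L, 1L) else 1L
  x <- pair$x[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L), , drop = FALSE]
  y <- pair$y[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L), , drop = FALSE]
  if (augment) {
    k <- sample.int(4L, 1L) - 1L
    x <- rot90_hw(x, k); y <- rot90_hw(y, k)
    if (runif(1) < 0.5) {
      x <- x[dim(x)[1]:1, , , drop = FALSE]
      y <- y[dim(y)[1]:1, , , drop = FALSE]
    }
  }
  list(x = x, y = y)
}

make_batch <- function(pairs, idx, crop, augment) {
  cs <- lapply(idx, function(i) sample_crop(pairs[[i]], crop, augment))
  cx <- dim(cs[[1]]$x)[3]; cy <- dim(cs[[1]]$y)[3]
  xb <- array(0, dim = c(crop, crop, cx, length(idx)))
  yb <- array(0, dim = c(crop, crop, cy, length(idx)))
  for (i in seq_along(cs)) {
    xb[, , , i] <- cs[[i]]$x
    yb[, , , i] <- cs[[i]]$y
  }
  list(x = xb, y = yb)
}

val_nmae <- function(net, val_pairs, channels) {
  out <- matrix(NA_real_, length(val_pairs), length(channels))
  for (i in seq_along(val_pairs)) {
    p <- val_pairs[[i]]
    pred <- predict_tiled(net, p$x)
    for (c in seq_along(channels)) {
      out[i, c] <- nmae_px(pred[, , channels[c]], p$y[, , channels[c]])
    }
  }
  colMeans(out)
}

#' Fit the conditional GAN
#'
#' Trains generator and discriminator simultaneously with alternating Adam
#' updates: for each batch the discriminator is updated on a real and a
#' generated pair, then the generator is updated on the non-saturating
#' adversarial loss plus `lambda` times the L1 reconstruction error.
#' Validation nMAE_px per output channel is tracked at `val_every`-epoch
#' intervals and the generator with the lowest mean validation nMAE_px is
#' retained as the fitted model.
#'
#' @param train_pairs,val_pairs lists of `list(x, y)` with `x` an
#'   `H x W x C_in` bright-field array and `y` an `H x W x C_out`
#'   fluorescence array, both in `[0, 1]`; `val_pairs` must be nonempty.
#' @param gen_config a [generator_config()].
#' @param disc_config a [discriminator_config()]; by default derived from
#'   `gen_config` (conditional pairing: bright-field plus fluorescence
#'   channels).
#' @param config a [train_config()].
#' @return object of class `cgan_fit` with elements `generator` (best by
#'   validation), `final_generator`, `discriminator`, `history` (per-epoch
#'   `loss_gen`, `loss_disc`), `val_history` (per-validation-point nMAE_px
#'   per channel), and the configurations. Methods: `print`, `summary`,
#'   `coef`, `plot`, `predict`.
#' @export
fit_cgan <- function(train_pairs, val_pairs,
                     gen_config = generator_config(),
                     disc_config = NULL,
                     config = train_config()) {
  check_pairs(train_pairs, "training")
  check_pairs(val_pairs, "validation")
  set.seed(config$seed)
  if (is.null(disc_config)) {
    disc_config <- discriminator_config(
      in_channels = gen_config$in_channels + gen_config$out_channels)
  }
  gen <- build_generator(gen_config)
  use_disc <- config$adv_weight > 0
  disc <- if (use_disc) build_discriminator(disc_config) else NULL
  opt_g <- adam_init(gen)
  opt_d <- if (use_disc) adam_init(disc) else NULL

  n <- length(train_pairs)
  steps <- max(1L, n %/% config$batch_size)
  hist <- data.frame(epoch = integer(), loss_gen = numeric(),
                     loss_disc = numeric())
  vh <- NULL
  best <- list(nmae = Inf, net = gen, epoch = 0L)
  channels <- seq_len(gen_config$out_channels)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    lg <- 0; ld <- 0
    for (s in seq_len(steps)) {
      idx <- ord[((s - 1L) * config$batch_size + 1L):
                   min(n, s * config$batch_size)]
      b <- make_batch(train_pairs, idx, config$crop_size, config$augment)
      fw <- unet_forward(gen, b$x, cache = TRUE)
      fake <- fw$y
      l1 <- mean(abs(fake - b$y))

      if (use_disc) {
        real_in <- concat_c(b$x, b$y)
        fake_in <- concat_c(b$x, fake)
        if (config$disc_input_noise > 0) {
          real_in <- real_in + array(rnorm(length(real_in),
                                           sd = config$disc_input_noise),
                                     dim(real_in))
          fake_in <- fake_in + array(rnorm(length(fake_in),
                                           sd = config$disc_input_noise),
                                     dim(fake_in))
        }
        # discriminator update (generator detached)
        fr <- disc_forward(disc, real_in, cache = TRUE)
        ff <- disc_forward(disc, fake_in, cache = TRUE)
        loss_d <- bce_with_logits(fr$y, 1) + bce_with_logits(ff$y, 0)
        gr <- disc_backward(disc, fr$cache, bce_grad(fr$y, 1))$grads
        gf <- disc_backward(disc, ff$cache, bce_grad(ff$y, 0))$grads
        gd <- sum_grads(gr, gf)
        st <- adam_step(disc, gd, opt_d, config$lr, config$beta1, config$beta2)
        disc <- st$net; opt_d <- st$state
        # generator update through the refreshed discriminator
        ff2 <- disc_forward(disc, fake_in, cache = TRUE)
        loss_adv <- bce_with_logits(ff2$y, 1)
        bi <- disc_backward(disc, ff2$cache,
                            config$adv_weight * bce_grad(ff2$y, 1))
        g_fake <- bi$gx[, , gen_config$in_channels + channels, , drop = FALSE]
      } else {
        loss_d <- NA_real_
        loss_adv <- 0
        g_fake <- array(0, dim = dim(fake))
      }
      g_l1 <- config$lambda * sign(fake - b$y) / length(fake)
      gg <- unet_backward(gen, fw$cache, g_fake + g_l1)
      st <- adam_step(gen, gg, opt_g, config$lr, config$beta1, config$beta2)
      gen <- st$net; opt_g <- st$state

      loss_g <- config$adv_weight * loss_adv + config$lambda * l1
      if (!is.finite(loss_g) || (use_disc && !is.finite(loss_d))) {
        stop(sprintf("non-finite loss at epoch %d step %d; lower the learning rate",
                     epoch, s), call. = FALSE)
      }
      lg <- lg + loss_g / steps
      ld <- ld + if (use_disc) loss_d / steps else 0
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss_gen = lg,
                                   loss_disc = if (use_disc) ld else NA_real_))
    if (epoch == 1L || epoch %% config$val_every == 0L ||
        epoch == config$epochs) {
      nm <- val_nmae(gen, val_pairs, channels)
      vh <- rbind(vh, data.frame(epoch = epoch,
                                 t(stats::setNames(nm, paste0("nmae_ch", channels)))))
      if (mean(nm) < best$nmae) {
        best <- list(nmae = mean(nm), net = gen, epoch = epoch)
      }
      if (config$verbose) {
        message(sprintf("epoch %4d  l_gen %.4f  l_disc %s  val nMAE %s",
                        epoch, lg, format(ld, digits = 4),
                        paste(sprintf("%.3f", nm), collapse = "/")))
      }
    }
  }
  rownames(vh) <- NULL
  structure(list(generator = best$net, final_generator = gen,
                 discriminator = disc, history = hist, val_history = vh,
                 best_epoch = best$epoch, gen_config = gen_config,
                 disc_config = if (use_disc) disc_config else NULL,
                 config = config),
            class = c("cgan_fit", "vstain_fit"))
}

sum_grads <- function(a, b) {
  if (is.list(a) && !is.null(a$w)) {
    list(w = a$w + b$w, b = a$b + b$b)
  } else {
    out <- a
    for (i in seq_along(a)) out[[i]] <- sum_grads(a[[i]], b[[i]])
    out
  }
}

#' Fit the single-channel U-Net baseline
#'
#' Mean-squared-error regression of one fluorescence channel from the
#' bright-field stack, under the same training configuration semantics as
#' [fit_cgan()] (one U-Net instance per channel). Being an MSE estimator it
#' converges to the per-pixel conditional mean of the target distribution.
#'
#' @inheritParams fit_cgan
#' @param channel index of the target channel in `y` (1 droplets,
#'   2 cytoplasm, 3 nuclei).
#' @param net_config a [unet_config()].
#' @return object of class `unet_fit` (same surface as `cgan_fit`).
#' @export
fit_unet <- function(train_pairs, val_pairs, channel = 1L,
                     net_config = unet_config(),
                     config = train_config()) {
  check_pairs(train_pairs, "training")
  check_pairs(val_pairs, "validation")
  if (!channel %in% 1:3 && channel > dim(train_pairs[[1]]$y)[3]) {
    stop("invalid target channel", call. = FALSE)
  }
  set.seed(config$seed)
  net <- build_unet(net_config)
  opt <- adam_init(net)
  n <- length(train_pairs)
  steps <- max(1L, n %/% config$batch_size)
  hist <- data.frame(epoch = integer(), loss = numeric())
  vh <- NULL
  best <- list(nmae = Inf, net = net, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    le <- 0
    for (s in seq_len(steps)) {
      idx <- ord[((s - 1L) * config$batch_size + 1L):
                   min(n, s * config$batch_size)]
      b <- make_batch(train_pairs, idx, config$crop_size, config$augment)
      yb <- b$y[, , channel, , drop = FALSE]
      fw <- unet_forward(net, b$x, cache = TRUE)
      loss <- mean((fw$y - yb)^2)
      if (!is.finite(loss)) {
        stop("non-finite loss; lower the learning rate", call. = FALSE)
      }
      g <- 2 * (fw$y - yb) / length(yb)
      gg <- unet_backward(net, fw$cache, g)
      st <- adam_step(net, gg, opt, config$lr, config$beta1, config$beta2)
      net <- st$net; opt <- st$state
      le <- le + loss / steps
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = le))
    if (epoch == 1L || epoch %% config$val_every == 0L ||
        epoch == config$epochs) {
      nm <- mean(vapply(val_pairs, function(p) {
        nmae_px(predict_tiled(net, p$x)[, , 1], p$y[, , channel])
      }, 0))
      vh <- rbind(vh, data.frame(epoch = epoch, nmae = nm))
      if (nm < best$nmae) best <- list(nmae = nm, net = net, epoch = epoch)
      if (config$verbose) {
        message(sprintf("epoch %4d  mse %.6f  val nMAE %.3f", epoch, le, nm))
      }
    }
  }
  rownames(vh) <- NULL
  structure(list(generator = best$net, final_generator = net,
                 history = hist, val_history = vh, best_epoch = best$epoch,
                 channel = channel, net_config = net_config, config = config),
            class = c("unet_fit", "vstain_fit"))
}

# ---- prediction ----------------------------------------------------------

pad_to_multiple <- function(x, f) {
  H <- dim(x)[1]; W <- dim(x)[2]
  Hp <- as.integer(ceiling(H / f) * f); Wp <- as.integer(ceiling(W / f) * f)
  if (Hp == H && Wp == W) return(list(x = x, H = H, W = W))
  out <- array(0, dim = c(Hp, Wp, dim(x)[3]))
  out[seq_len(H), seq_len(W), ] <- x
  if (Hp > H) out[(H + 1):Hp, seq_len(W), ] <- x[rep(H, Hp - H), seq_len(W), ]
  if (Wp > W) out[, (W + 1):Wp, ] <- out[, rep(W, Wp - W), , drop = FALSE]
  list(x = out, H = H, W = W)
}

#' Predict a full field by tiled inference
#'
#' Applies a generator to a bright-field stack. Fields larger than `tile`
#' are processed as overlapping tiles blended by linear feathering
#' (weights ramp to zero at tile edges, normalized over the covering
#' tiles), which suppresses seams; fields not exceeding the tile are
#' predicted whole. Sizes that are not divisible by `2^depth` are
#' edge-padded and cropped back. Deterministic.
#'
#' @param net a generator network (or use [predict()] on a fitted model).
#' @param stack array `H x W x C_in` in `[0, 1]`.
#' @param tile tile side in px (`NULL` = whole field).
#' @param overlap overlap between neighbouring tiles in px (< tile).
#' @return array `H x W x C_out` in `[0, 1]`.
#' @export
predict_tiled <- function(net, stack, tile = NULL, overlap = 32L) {
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  H <- dim(stack)[1]; W <- dim(stack)[2]
  f <- 2L^net$depth
  whole <- function(x) {
    p <- pad_to_multiple(x, f)
    dim(p$x) <- c(dim(p$x), 1L)
    y <- unet_forward(net, p$x)
    array(y[seq_len(p$H), seq_len(p$W), , 1], dim = c(p$H, p$W, dim(y)[3]))
  }
  if (is.null(tile) || (H <= tile && W <= tile)) {
    return(whole(stack))
  }
  if (overlap >= tile) stop("overlap must be smaller than tile", call. = FALSE)
  if (tile %% f != 0) {
    stop(sprintf("tile size %d not divisible by 2^depth = %d", tile, f),
         call. = FALSE)
  }
  starts <- function(total) {
    if (total <= tile) return(1L)
    s <- seq(1L, total - tile + 1L, by = tile - overlap)
    if (tail(s, 1) != total - tile + 1L) s <- c(s, total - tile + 1L)
    s
  }
  # Hann-window blending: tile borders (where per-tile zero padding
  # perturbs the prediction) get near-zero weight, and for 50% overlap the
  # windows form a partition of unity
  hann <- sin(pi * (seq_len(tile) - 0.5) / tile)^2
  wt <- outer(hann, hann)
  c_out <- net$c_out
  acc <- array(0, dim = c(H, W, c_out))
  wacc <- matrix(0, H, W)
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      rows <- r0:(r0 + tile - 1L); cols <- c0:(c0 + tile - 1L)
      xt <- stack[rows, cols, , drop = FALSE]
      dim(xt) <- c(tile, tile, dim(stack)[3], 1L)
      yt <- unet_forward(net, xt)
      for (ch in seq_len(c_out)) {
        acc[rows, cols, ch] <- acc[rows, cols, ch] + wt * yt[, , ch, 1]
      }
      wacc[rows, cols] <- wacc[rows, cols] + wt
    }
  }
  for (ch in seq_len(c_out)) acc[, , ch] <- acc[, , ch] / wacc
  acc
}

#' @export
predict.vstain_fit <- function(object, newdata, tile = NULL, overlap = 32L,
                               ...) {
  net <- object$generator
  one <- function(x) {
    if (is.list(x) && !is.null(x$x)) x <- x$x
    predict_tiled(net, x, tile = tile, overlap = overlap)
  }
  if (is.list(newdata) && is.null(dim(newdata)) && is.null(newdata$x)) {
    lapply(newdata, one)
  } else {
    one(newdata)
  }
}

#' @export
print.cgan_fit <- function(x, ...) {
  cat("Conditional GAN virtual-staining model\n")
  cat(sprintf("  generator: depth %d, width %d, %d -> %d channels (%d parameters)\n",
              x$gen_config$depth, x$gen_config$width, x$gen_config$in_channels,
              x$gen_config$out_channels, n_params(x$generator)))
  if (!is.null(x$discriminator)) {
    cat(sprintf("  discriminator: depth %d, width %d (%d parameters)\n",
                x$disc_config$depth, x$disc_config$width,
                n_params(x$discriminator)))
  }
  cat(sprintf("  trained %d epochs, lambda = %g; best epoch %d (mean val nMAE_px %.3f)\n",
              x$config$epochs, x$config$lambda, x$best_epoch,
              min(rowMeans(x$val_history[, -1, drop = FALSE]))))
  invisible(x)
}

#' @export
print.unet_fit <- function(x, ...) {
  cat("U-Net baseline (MSE) virtual-staining model\n")
  cat(sprintf("  channel %d, depth %d, width %d (%d parameters)\n",
              x$channel, x$net_config$depth, x$net_config$width,
              n_params(x$generator)))
  cat(sprintf("  trained %d epochs; best epoch %d (val nMAE_px %.3f)\n",
              x$config$epochs, x$best_epoch, min(x$val_history$nmae)))
  invisible(x)
}

#' @export
summary.vstain_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history (last rows):\n")
  print(tail(object$history, 3), row.names = FALSE)
  cat("\nValidation history:\n")
  print(object$val_history, row.names = FALSE)
  invisible(object)
}

#' @export
coef.vstain_fit <- function(object, ...) {
  layers <- nn_layers(object$generator)
  out <- list()
  for (l in layers) {
    nm <- paste(vapply(l$path, as.character, ""), collapse = ".")
    out[[paste0(nm, ".w")]] <- l$layer$w
    out[[paste0(nm, ".b")]] <- l$layer$b
  }
  out
}

#' @export
plot.vstain_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  h <- x$history
  ycol <- if ("loss_gen" %in% names(h)) "loss_gen" else "loss"
  plot(h$epoch, h[[ycol]], type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss", ...)
  if ("loss_disc" %in% names(h) && any(is.finite(h$loss_disc))) {
    lines(h$epoch, h$loss_disc, lty = 2)
    legend("topright", c("generator", "discriminator"), lty = 1:2, bty = "n")
  }
  vh <- x$val_history
  ncols <- setdiff(names(vh), "epoch")
  plot(vh$epoch, vh[[ncols[1]]], type = "l",
       ylim = range(vh[, ncols]), xlab = "epoch", ylab = "validation nMAE_px",
       main = "validation error")
  if (length(ncols) > 1) {
    for (i in seq_along(ncols)[-1]) lines(vh$epoch, vh[[ncols[i]]], lty = i)
    legend("topright", ncols, lty = seq_along(ncols), bty = "n")
  }
  invisible(x)
}

# ---- checkpoints ---------------------------------------------------------

#' Save a fitted model with a JSON sidecar
#'
#' Writes the model object in R's native serialization plus a JSON sidecar
#' recording configuration and the normalization constant.
#'
#' @param object a fitted model.
#' @param path output path (`.rds`); the sidecar gets the extension
#'   `.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(object, path) {
  saveRDS(object, path)
  side <- sub("\\.rds$", ".json", path)
  meta <- list(class = class(object)[1],
               config = unclass(object$config),
               normalization = list(divisor = 65535),
               best_epoch = object$best_epoch)
  if (!is.null(object$gen_config)) meta$gen_config <- unclass(object$gen_config)
  if (!is.null(object$net_config)) meta$net_config <- unclass(object$net_config)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model saved with [save_model()]
#'
#' @param path path to the `.rds` checkpoint.
#' @return the fitted model object.
#' @export
load_model <- function(path) readRDS(path)
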