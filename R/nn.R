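# Internal convolutional-network engine.
#
# Tensors are numeric arrays dim (H, W, C, N), values in the normalized
# intensity range [0, 1] for images. All randomness (weight init, shuffling,
# augmentation) goes through R's RNG so runs are reproducible under set.seed().

nn_conv_init <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L) {
  sd <- sqrt(2 / (k * k * cin))
  list(
    w = array(stats::rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout)),
    b = numeric(cout),
    stride = as.integer(stride),
    pad = as.integer(pad)
  )
}

# activation codes shared with the C++ kernels
ACT_NONE <- 0L
ACT_RELU <- 1L
ACT_LRELU <- 2L
ACT_SIGMOID <- 3L

nn_conv_apply <- function(layer, x, act = ACT_NONE) {
  conv2d_fwd(x, layer$w, layer$b, layer$stride, layer$pad, act)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

concat_c <- function(a, b) concat_chan(a, b)

check_div <- function(h, w, depth) {
  f <- 2L^depth
  if (h %% f != 0L || w %% f != 0L) {
    stop(sprintf(
      "field size %d x %d is not divisible by 2^depth = %d; pad or crop the field",
      h, w, f
    ), call. = FALSE)
  }
}

# ---- generator (U-Net with skip connections, bounded sigmoid output) ----

unet_init <- function(c_in, c_out, depth, width) {
  widths <- width * 2L^(seq_len(depth) - 1L)
  enc <- vector("list", depth)
  cin <- c_in
  for (l in seq_len(depth)) {
    enc[[l]] <- nn_conv_init(3L, cin, widths[l])
    cin <- widths[l]
  }
  bott <- nn_conv_init(3L, cin, cin)
  dec <- vector("list", depth)
  up <- cin
  for (l in rev(seq_len(depth))) {
    dec[[l]] <- nn_conv_init(3L, up + widths[l], widths[l])
    up <- widths[l]
  }
  out <- nn_conv_init(1L, widths[1], c_out, pad = 0L)
  structure(
    list(enc = enc, bott = bott, dec = dec, out = out,
         c_in = c_in, c_out = c_out, depth = depth, width = width),
    class = "vs_unet"
  )
}

unet_forward <- function(net, x, cache = FALSE) {
  d <- dim(x)
  if (d[3] != net$c_in) {
    stop(sprintf("input has %d channels, model expects %d", d[3], net$c_in),
         call. = FALSE)
  }
  check_div(d[1], d[2], net$depth)
  depth <- net$depth
  cc <- if (cache) list(x0 = x) else NULL
  skips <- vector("list", depth)
  pools <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    a <- nn_conv_apply(net$enc[[l]], h, ACT_RELU)
    skips[[l]] <- a
    p <- maxpool2_fwd(a)
    if (cache) {
      cc[[paste0("enc_in", l)]] <- h
      pools[[l]] <- p$idx
    }
    h <- p$y
  }
  bott_in <- h
  h <- nn_conv_apply(net$bott, h, ACT_RELU)
  if (cache) {
    cc$bott_in <- bott_in
    cc$bott_out <- h
  }
  dec_in <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    u <- upsample2_fwd(h)
    cat_in <- concat_c(u, skips[[l]])
    h <- nn_conv_apply(net$dec[[l]], cat_in, ACT_RELU)
    if (cache) {
      dec_in[[l]] <- cat_in
      cc[[paste0("dec_out", l)]] <- h
    }
  }
  y <- nn_conv_apply(net$out, h, ACT_SIGMOID)
  if (cache) {
    cc$skips <- skips
    cc$pools <- pools
    cc$dec_in <- dec_in
    cc$out_in <- h
    cc$y <- y
    list(y = y, cache = cc)
  } else {
    y
  }
}

# gradient of the scalar loss wrt all parameters; gy is dLoss/dy
unet_backward <- function(net, cc, gy) {
  depth <- net$depth
  bo <- conv2d_bwd(cc$out_in, net$out$w, cc$y, gy, net$out$stride,
                   net$out$pad, ACT_SIGMOID)
  grads <- list(enc = vector("list", depth), dec = vector("list", depth))
  grads$out <- list(w = bo$gw, b = bo$gb)
  gh <- bo$gx
  gskip <- vector("list", depth)
  for (l in seq_len(depth)) {
    bd <- conv2d_bwd(cc$dec_in[[l]], net$dec[[l]]$w,
                     cc[[paste0("dec_out", l)]], gh,
                     net$dec[[l]]$stride, net$dec[[l]]$pad, ACT_RELU)
    grads$dec[[l]] <- list(w = bd$gw, b = bd$gb)
    nu <- dim(bd$gx)[3] - dim(cc$skips[[l]])[3]
    gu <- bd$gx[, , seq_len(nu), , drop = FALSE]
    gskip[[l]] <- bd$gx[, , nu + seq_len(dim(cc$skips[[l]])[3]), , drop = FALSE]
    gh <- upsample2_bwd(gu)
  }
  # gh is now the gradient at the bottleneck output
  bb <- conv2d_bwd(cc$bott_in, net$bott$w, cc$bott_out, gh,
                   net$bott$stride, net$bott$pad, ACT_RELU)
  grads$bott <- list(w = bb$gw, b = bb$gb)
  gpool <- bb$gx
  for (l in rev(seq_len(depth))) {
    ga <- maxpool2_bwd(gpool, cc$pools[[l]], dim(cc$skips[[l]])) + gskip[[l]]
    be <- conv2d_bwd(cc[[paste0("enc_in", l)]], net$enc[[l]]$w,
                     cc$skips[[l]], ga,
                     net$enc[[l]]$stride, net$enc[[l]]$pad, ACT_RELU)
    grads$enc[[l]] <- list(w = be$gw, b = be$gb)
    gpool <- be$gx
  }
  grads
}

# ---- conditional patch discriminator (stride-2 stack, logit score map) ----

disc_init <- function(c_in, depth, width) {
  widths <- width * 2L^(seq_len(depth) - 1L)
  convs <- vector("list", depth)
  cin <- c_in
  for (l in seq_len(depth)) {
    convs[[l]] <- nn_conv_init(3L, cin, widths[l], stride = 2L)
    cin <- widths[l]
  }
  out <- nn_conv_init(1L, cin, 1L, pad = 0L)
  structure(
    list(convs = convs, out = out, c_in = c_in, depth = depth, width = width),
    class = "vs_disc"
  )
}

disc_forward <- function(net, x, cache = FALSE) {
  d <- dim(x)
  if (d[3] != net$c_in) {
    stop(sprintf("input has %d channels, discriminator expects %d",
                 d[3], net$c_in), call. = FALSE)
  }
  check_div(d[1], d[2], net$depth)
  cc <- if (cache) list() else NULL
  h <- x
  for (l in seq_along(net$convs)) {
    if (cache) cc[[paste0("in", l)]] <- h
    h <- nn_conv_apply(net$convs[[l]], h, ACT_LRELU)
    if (cache) cc[[paste0("act", l)]] <- h
  }
  logits <- nn_conv_apply(net$out, h)
  if (cache) {
    cc$out_in <- h
    cc$y <- logits
    list(y = logits, cache = cc)
  } else {
    logits
  }
}

# returns parameter grads and the gradient wrt the input (for generator
# updates through the discriminator)
disc_backward <- function(net, cc, gy) {
  bo <- conv2d_bwd(cc$out_in, net$out$w, cc$y, gy, net$out$stride,
                   net$out$pad, ACT_NONE)
  grads <- list(convs = vector("list", length(net$convs)),
                out = list(w = bo$gw, b = bo$gb))
  gh <- bo$gx
  for (l in rev(seq_along(net$convs))) {
    bl <- conv2d_bwd(cc[[paste0("in", l)]], net$convs[[l]]$w,
                     cc[[paste0("act", l)]], gh,
                     net$convs[[l]]$stride, net$convs[[l]]$pad, ACT_LRELU)
    grads$convs[[l]] <- list(w = bl$gw, b = bl$gb)
    gh <- bl$gx
  }
  list(grads = grads, gx = gh)
}

# ---- parameter plumbing and Adam ----

# walk a model/grad structure and return the conv layers as a flat list
nn_layers <- function(net) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x) && !is.null(x$w)) {
      out[[length(out) + 1L]] <<- list(path = path, layer = x)
    } else if (is.list(x)) {
      for (nm in seq_along(x)) {
        key <- if (!is.null(names(x)) && nzchar(names(x)[nm])) names(x)[nm] else nm
        walk(x[[nm]], c(path, list(key)))
      }
    }
  }
  walk(net[setdiff(names(net), c("c_in", "c_out", "depth", "width"))], list())
  out
}

nn_get <- function(net, path) {
  for (p in path) net <- net[[p]]
  net
}

nn_set <- function(net, path, value) {
  if (length(path) == 1L) {
    net[[path[[1L]]]] <- value
  } else {
    net[[path[[1L]]]] <- nn_set(net[[path[[1L]]]], path[-1L], value)
  }
  net
}

nn_n_params <- function(net) {
  sum(vapply(nn_layers(net), function(l) length(l$layer$w) + length(l$layer$b), 0))
}

adam_init <- function(net) {
  st <- lapply(nn_layers(net), function(l) {
    list(path = l$path,
         mw = array(0, dim(l$layer$w)), vw = array(0, dim(l$layer$w)),
         mb = numeric(length(l$layer$b)), vb = numeric(length(l$layer$b)))
  })
  list(t = 0L, slots = st)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(state$slots)) {
    s <- state$slots[[i]]
    g <- nn_get(grads, s$path)
    layer <- nn_get(net, s$path)
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    layer$w <- layer$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layer$b <- layer$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    net <- nn_set(net, s$path, layer)
    state$slots[[i]] <- s
  }
  list(net = net, state = state)
}
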