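#' Generator configuration
#'
#' Describes the fully convolutional image-to-image generator: a U-Net-shaped
#' encoder--decoder with skip connections and a bounded (sigmoid) output, so
#' predictions always lie in the normalized intensity range \[0, 1\]. The
#' generator maps a bright-field z-stack (one input channel per defocus
#' slice) to the three fluorescence channels (lipid droplets, cytoplasm,
#' nuclei).
#'
#' @param in_channels number of input channels (bright-field slices).
#' @param out_channels number of output channels (fluorescence stains).
#' @param depth number of 2x down-/up-sampling stages; any field processed
#'   must have height and width divisible by `2^depth`.
#' @param width number of feature maps at the first encoder stage; doubled
#'   at each deeper stage.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(in_channels = 7L, out_channels = 3L,
                             depth = 3L, width = 8L) {
  stopifnot(in_channels >= 1, out_channels >= 1, depth >= 1, width >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth), width = as.integer(width)),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Describes the conditional patch discriminator. It receives the
#' bright-field stack concatenated with a (real or generated) fluorescence
#' image and returns a spatial map of unbounded logit scores; each score
#' judges one receptive-field patch, so the discriminator decides locally
#' whether a staining looks authentic given the bright-field evidence.
#'
#' @param in_channels total input channels: bright-field slices plus
#'   fluorescence channels.
#' @param depth number of stride-2 convolution stages; the score map is the
#'   input size divided by `2^depth`.
#' @param width feature maps at the first stage (doubled per stage).
#' @return an object of class `discriminator_config`.
#' @export
discriminator_config <- function(in_channels = 10L, depth = 3L, width = 8L) {
  stopifnot(in_channels >= 1, depth >= 1, width >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 depth = as.integer(depth), width = as.integer(width)),
            class = "discriminator_config")
}

#' Single-channel U-Net baseline configuration
#'
#' The baseline regressor: identical U-Net topology to the generator but
#' with exactly one output channel. One instance is trained per fluorescence
#' channel with a mean-squared-error objective, so it estimates the
#' per-pixel conditional mean of that channel given the bright-field stack.
#'
#' @inheritParams generator_config
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 7L, depth = 3L, width = 8L) {
  stopifnot(in_channels >= 1, depth >= 1, width >= 1)
  structure(list(in_channels = as.integer(in_channels), out_channels = 1L,
                 depth = as.integer(depth), width = as.integer(width)),
            class = "unet_config")
}

#' Instantiate a generator network
#'
#' Creates the trainable generator with freshly initialized weights
#' (He-scaled Gaussian, drawn from R's RNG, so initialization is
#' reproducible under [set.seed()]).
#'
#' @param config a [generator_config()].
#' @return a network object usable with [fit_cgan()] and
#'   [predict_tiled()].
#' @export
build_generator <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  unet_init(config$in_channels, config$out_channels, config$depth, config$width)
}

#' Instantiate a discriminator network
#'
#' @param config a [discriminator_config()].
#' @return a network object usable with [fit_cgan()].
#' @export
build_discriminator <- function(config = discriminator_config()) {
  stopifnot(inherits(config, "discriminator_config"))
  disc_init(config$in_channels, config$depth, config$width)
}

#' Instantiate a single-channel U-Net baseline
#'
#' @param config a [unet_config()].
#' @return a network object usable with [fit_unet()].
#' @export
build_unet <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  unet_init(config$in_channels, 1L, config$depth, config$width)
}

#' Number of trainable parameters of a network
#'
#' @param net a network built with [build_generator()],
#'   [build_discriminator()] or [build_unet()].
#' @return integer parameter count.
#' @export
n_params <- function(net) nn_n_params(net)

#' Apply a network to a batch of images
#'
#' Low-level forward pass. For full-field prediction with tiling use
#' [predict_tiled()] or the `predict()` method of a fitted model.
#'
#' @param net a network object.
#' @param x numeric array `(H, W, C, N)` or a single image `(H, W, C)`.
#' @return output array `(H', W', C', N)` (the singleton batch dimension is
#'   kept).
#' @export
forward <- function(net, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (inherits(net, "vs_unet")) unet_forward(net, x) else disc_forward(net, x)
}
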