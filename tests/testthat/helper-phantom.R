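# Shared fixture builders. Everything is generated in code at test time.

# 64-px desk-scale paired samples (placement warnings about dense droplet
# packing are irrelevant for these tests)
desk_pairs <- function(n, seed, ...) {
  suppressWarnings(phantom_pairs(n, seed = seed, ...))
}

# a hand-built scene with full control over the geometry
manual_scene <- function(field = 64L, droplets = data.frame(),
                         nucleus_centre = c(20, 20), nucleus_axes = c(6, 5),
                         cell_radius = 25) {
  cell <- list(
    nucleus = list(centre = nucleus_centre, axes = nucleus_axes, theta = 0),
    cyto = list(centre = c(field / 2, field / 2), radius = cell_radius,
                amp = c(0, 0, 0), phase = c(0, 0, 0), harmonics = 2:4),
    droplets = droplets
  )
  structure(list(field_size = c(field, field), cells = list(cell),
                 seed = NULL),
            class = "vs_scene")
}

noiseless_params <- function(field = 64L, ...) {
  phantom_params(field_size = field, noise_sd = c(0, 0, 0), shot_gain = 0,
                 bf_noise_sd = 0, texture_roughness = 0, droplet_dip = 0,
                 psf_sigma = 0.5, ...)
}

# one-to-many toy mapping: a fixed structured input whose target is the
# uniformly bright image A or the uniformly dark image B with probability
# 1/2 — the input carries no information about which
toy_one_to_many <- function(n, size = 16L) {
  x <- array(rep(seq(0.2, 0.8, length.out = size), each = size),
             dim = c(size, size, 1))
  imgs <- toy_images(size)
  pick_a <- rep(c(TRUE, FALSE), length.out = n)
  lapply(seq_len(n), function(i) {
    list(x = x, y = if (pick_a[i]) imgs$A else imgs$B)
  })
}

toy_images <- function(size = 16L) {
  A <- array(0.8, dim = c(size, size, 1))
  B <- array(0.2, dim = c(size, size, 1))
  list(A = A, B = B, M = (A + B) / 2)
}
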