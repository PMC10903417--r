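# Synthetic phantom: paired bright-field stacks and fluorescence targets
# with exact ground truth.
#
# The phantom reproduces the statistical structure the virtual-staining
# problem rests on: lipid droplets have high refractive-index contrast and
# dominate the bright-field signal, the cytoplasm is faint, and nuclei are
# (by default) optically invisible, so any nucleus prediction must be
# inferred from context. Coordinates are pixel-centre, row-major, 0-based;
# images are 16-bit, range [0, 65535].

#' Phantom generation parameters
#'
#' Defaults emulate adipocyte-like fields: a few large cells whose cytoplasm
#' is packed with lipid droplets drawn from two log-normal size populations
#' (small median 4 px, large median 15 px), an elliptical nucleus per cell,
#' an uneven multiplicative cytoplasm texture (emulating irreproducible dye
#' reaction), camera noise with a read (Gaussian) and a shot (Poisson-like,
#' variance proportional to signal) component, and a 7-slice bright-field
#' defocus stack in which droplet contrast flips polarity across focus.
#'
#' @param field_size height/width of the field in pixels (length-2 or
#'   scalar).
#' @param n_cells number of cells per field.
#' @param cell_radius mean cytoplasm radius (px).
#' @param nucleus_radius mean nucleus semi-major axis (px).
#' @param droplets_per_cell lipid droplets per cell.
#' @param frac_large fraction of droplets drawn from the large population.
#' @param r_small_median,r_small_sdlog log-normal radius distribution of the
#'   small droplet population (px).
#' @param r_large_median,r_large_sdlog log-normal radius distribution of the
#'   large droplet population (px).
#' @param droplet_fluor,cyto_fluor,nucleus_fluor foreground fluorescence
#'   levels per channel (16-bit counts).
#' @param fluor_bg background level per channel (length 3, 16-bit counts).
#' @param noise_sd additive (read) noise standard deviation per fluorescence
#'   channel (length 3, counts).
#' @param shot_gain Poisson-like scaling: shot-noise variance equals
#'   `shot_gain * signal` (counts).
#' @param texture_roughness amplitude of the multiplicative cytoplasm
#'   texture (0 disables it).
#' @param texture_scale correlation length of the texture (px).
#' @param droplet_dip relative depth of the darker interior dip rendered in
#'   large droplets (0 disables).
#' @param psf_sigma Gaussian blur emulating the optical point-spread
#'   function (px; 0 disables).
#' @param n_slices number of bright-field defocus slices.
#' @param defocus_step defocus increment between slices (arbitrary units;
#'   only the slice position relative to focus matters).
#' @param bf_level bright-field background level (counts).
#' @param droplet_contrast,cyto_contrast,nucleus_contrast bright-field
#'   contrast weight per structure class; the default hierarchy is
#'   droplet >> cytoplasm > nucleus = 0 (nuclei invisible).
#' @param bf_noise_sd additive bright-field noise standard deviation
#'   (counts).
#' @param seed optional integer seed; when set, scene sampling and rendering
#'   are bit-reproducible.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(field_size = 256L,
                           n_cells = 4L,
                           cell_radius = 48,
                           nucleus_radius = 13,
                           droplets_per_cell = 18L,
                           frac_large = 0.15,
                           r_small_median = 4, r_small_sdlog = 0.25,
                           r_large_median = 15, r_large_sdlog = 0.2,
                           droplet_fluor = 20000,
                           cyto_fluor = 4000,
                           nucleus_fluor = 15000,
                           fluor_bg = c(500, 300, 300),
                           noise_sd = c(200, 150, 150),
                           shot_gain = 2,
                           texture_roughness = 0.35,
                           texture_scale = 8,
                           droplet_dip = 0.3,
                           psf_sigma = 0.7,
                           n_slices = 7L,
                           defocus_step = 1,
                           bf_level = 32000,
                           droplet_contrast = 6000,
                           cyto_contrast = 800,
                           nucleus_contrast = 0,
                           bf_noise_sd = 300,
                           seed = NULL) {
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  p <- list(field_size = as.integer(field_size), n_cells = as.integer(n_cells),
            cell_radius = cell_radius, nucleus_radius = nucleus_radius,
            droplets_per_cell = as.integer(droplets_per_cell),
            frac_large = frac_large,
            r_small_median = r_small_median, r_small_sdlog = r_small_sdlog,
            r_large_median = r_large_median, r_large_sdlog = r_large_sdlog,
            droplet_fluor = droplet_fluor, cyto_fluor = cyto_fluor,
            nucleus_fluor = nucleus_fluor,
            fluor_bg = rep_len(fluor_bg, 3L),
            noise_sd = rep_len(noise_sd, 3L), shot_gain = shot_gain,
            texture_roughness = texture_roughness,
            texture_scale = texture_scale,
            droplet_dip = droplet_dip, psf_sigma = psf_sigma,
            n_slices = as.integer(n_slices), defocus_step = defocus_step,
            bf_level = bf_level, droplet_contrast = droplet_contrast,
            cyto_contrast = cyto_contrast, nucleus_contrast = nucleus_contrast,
            bf_noise_sd = bf_noise_sd, seed = seed)
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  stopifnot(
    all(p$field_size >= 1L), p$n_cells >= 0L, p$droplets_per_cell >= 0L,
    p$frac_large >= 0, p$frac_large <= 1,
    p$r_small_median > 0, p$r_large_median > 0,
    all(p$noise_sd >= 0), p$shot_gain >= 0, p$bf_noise_sd >= 0,
    p$n_slices >= 1L,
    p$droplet_contrast >= 0, p$cyto_contrast >= 0, p$nucleus_contrast >= 0
  )
  invisible(p)
}

channel_names <- function() c("droplets", "cytoplasm", "nuclei")

#' Sample a synthetic scene
#'
#' Places `n_cells` cells in the field by rejection sampling: nucleus
#' centres are pairwise separated by at least one mean nucleus diameter;
#' each cell's cytoplasm support is a smooth star-convex blob guaranteed to
#' contain its nucleus; droplets are placed inside the cytoplasm, outside
#' the nucleus, and (by default) without mutual overlap.
#'
#' @param params a [phantom_params()] object.
#' @param max_attempts rejection-sampling budget per placed object.
#' @return an object of class `vs_scene`: field size plus one record per
#'   cell (nucleus geometry, cytoplasm boundary harmonics, droplet table).
#' @export
sample_scene <- function(params = phantom_params(), max_attempts = 500L) {
  validate_phantom_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  H <- params$field_size[1]; W <- params$field_size[2]
  nd <- 2 * params$nucleus_radius        # mean nucleus diameter
  margin <- min(params$cell_radius * 0.6, min(H, W) / 4)

  centres <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(params$n_cells)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cx <- runif(1, margin, W - 1 - margin)
      cy <- runif(1, margin, H - 1 - margin)
      if (nrow(centres) == 0 ||
          all(sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2) >= nd)) {
        centres <- rbind(centres, c(cx, cy))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "failed to place cell %d without nucleus collision after %d attempts; reduce n_cells or the nucleus radius",
        i, max_attempts), call. = FALSE)
    }
  }

  cells <- vector("list", params$n_cells)
  for (i in seq_len(params$n_cells)) {
    cx <- centres[i, 1]; cy <- centres[i, 2]
    a <- params$nucleus_radius * runif(1, 0.9, 1.1)
    b <- a * runif(1, 0.65, 0.95)
    theta <- runif(1, 0, pi)
    R <- params$cell_radius * runif(1, 0.85, 1.1)
    amp <- runif(3, 0, 0.08)
    phs <- runif(3, 0, 2 * pi)
    # the blob must contain the nucleus: min radius above nucleus extent
    rmin <- R * (1 - sum(amp))
    if (rmin < a + 3) {
      amp <- amp * max(0, (R - a - 3) / (R * sum(amp) + 1e-9))
    }

    drops <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                        pop = character(0), stringsAsFactors = FALSE)
    for (k in seq_len(params$droplets_per_cell)) {
      large <- runif(1) < params$frac_large
      r <- if (large) {
        rlnorm(1, log(params$r_large_median), params$r_large_sdlog)
      } else {
        rlnorm(1, log(params$r_small_median), params$r_small_sdlog)
      }
      r <- max(1.5, r)
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * max(0, 0.88 * R - r)
        dx <- rad * cos(ang); dy <- rad * sin(ang)
        px <- cx + dx; py <- cy + dy
        # outside the (dilated) nucleus ellipse
        rx <- px - cx; ry <- py - cy
        u <- rx * cos(theta) + ry * sin(theta)
        v <- -rx * sin(theta) + ry * cos(theta)
        if ((u / (a + r))^2 + (v / (b + r))^2 < 1) next
        # no overlap with already placed droplets (any cell)
        if (nrow(drops) > 0 &&
            any(sqrt((drops$x - px)^2 + (drops$y - py)^2) < drops$r + r + 1)) next
        if (px - r < 0 || px + r > W - 1 || py - r < 0 || py + r > H - 1) next
        drops <- rbind(drops, data.frame(x = px, y = py, r = r,
                                         pop = if (large) "large" else "small",
                                         stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) {
        warning(sprintf("cell %d: could not place droplet %d; scene has fewer droplets than requested", i, k))
      }
    }
    cells[[i]] <- list(
      nucleus = list(centre = c(cx, cy), axes = c(a, b), theta = theta),
      cyto = list(centre = c(cx, cy), radius = R, amp = amp, phase = phs,
                  harmonics = 2:4),
      droplets = drops
    )
  }
  structure(list(field_size = c(H, W), cells = cells, seed = params$seed),
            class = "vs_scene")
}

# ---- rasterization helpers ------------------------------------------------

# pixel-centre coordinate grids for a bounding box (0-based coords)
bbox_of <- function(cx, cy, r, H, W) {
  x0 <- max(0L, floor(cx - r)); x1 <- min(W - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(H - 1L, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(NULL)
  list(rows = (y0:y1) + 1L, cols = (x0:x1) + 1L, xs = x0:x1, ys = y0:y1)
}

disk_mask_bbox <- function(cx, cy, r, bb) {
  outer(bb$ys - cy, bb$xs - cx, function(dy, dx) dx^2 + dy^2 <= r^2)
}

ellipse_mask <- function(H, W, cx, cy, a, b, theta) {
  bb <- bbox_of(cx, cy, max(a, b) + 1, H, W)
  m <- matrix(FALSE, H, W)
  if (is.null(bb)) return(m)
  dx <- outer(rep(1, length(bb$ys)), bb$xs - cx)
  dy <- outer(bb$ys - cy, rep(1, length(bb$xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  m[bb$rows, bb$cols] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

blob_mask <- function(H, W, cyto) {
  R <- cyto$radius
  bb <- bbox_of(cyto$centre[1], cyto$centre[2], R * 1.35, H, W)
  m <- matrix(FALSE, H, W)
  if (is.null(bb)) return(m)
  dx <- outer(rep(1, length(bb$ys)), bb$xs - cyto$centre[1])
  dy <- outer(bb$ys - cyto$centre[2], rep(1, length(bb$xs)))
  d <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  rb <- R * (1 + Reduce(`+`, Map(function(a, p, k) a * cos(k * ang + p),
                                 cyto$amp, cyto$phase, cyto$harmonics)))
  m[bb$rows, bb$cols] <- d <= rb
  m
}

#' Ground-truth label maps of a scene
#'
#' Rasterizes the scene geometry into one integer label map per structure
#' class (0 = background). Droplets are labelled in placement order;
#' cytoplasm and nucleus labels share the cell index.
#'
#' @param scene a `vs_scene`.
#' @return named list of integer matrices `droplets`, `cytoplasm`, `nuclei`.
#' @export
scene_masks <- function(scene) {
  H <- scene$field_size[1]; W <- scene$field_size[2]
  lab_d <- matrix(0L, H, W)
  lab_c <- matrix(0L, H, W)
  lab_n <- matrix(0L, H, W)
  k <- 0L
  for (i in seq_along(scene$cells)) {
    cell <- scene$cells[[i]]
    cm <- blob_mask(H, W, cell$cyto)
    lab_c[cm] <- i
    nm <- ellipse_mask(H, W, cell$nucleus$centre[1], cell$nucleus$centre[2],
                       cell$nucleus$axes[1], cell$nucleus$axes[2],
                       cell$nucleus$theta)
    lab_n[nm] <- i
  }
  for (i in seq_along(scene$cells)) {
    dr <- scene$cells[[i]]$droplets
    for (j in seq_len(nrow(dr))) {
      k <- k + 1L
      bb <- bbox_of(dr$x[j], dr$y[j], dr$r[j], H, W)
      if (is.null(bb)) next
      m <- disk_mask_bbox(dr$x[j], dr$y[j], dr$r[j], bb)
      sub <- lab_d[bb$rows, bb$cols]
      sub[m] <- k
      lab_d[bb$rows, bb$cols] <- sub
    }
  }
  list(droplets = lab_d, cytoplasm = lab_c, nuclei = lab_n)
}

# low-pass filtered seeded noise, mean 1 (multiplicative texture)
texture_field <- function(H, W, roughness, scale) {
  if (roughness <= 0) return(matrix(1, H, W))
  z <- gaussian_blur(matrix(rnorm(H * W), H, W), scale)
  z <- z / stats::sd(z)
  pmax(0, 1 + roughness * z)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  # kernel clipped to the image size so small fields remain blurrable
  size <- min(2L * ceiling(3 * sigma) + 1L,
              (min(dim(m)) - 1L) %/% 2L * 2L + 1L)
  if (size < 3L) return(m)
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  as.matrix(EBImage::filter2(EBImage::Image(m), k / sum(k),
                             boundary = "replicate"))
}

add_camera_noise <- function(m, read_sd, shot_gain) {
  v <- read_sd^2 + shot_gain * pmax(m, 0)
  m + matrix(rnorm(length(m), sd = sqrt(as.vector(v))), nrow(m), ncol(m))
}

to_uint16 <- function(m) {
  m <- round(m)
  m[m < 0] <- 0
  m[m > 65535] <- 65535
  m
}

#' Render the fluorescence target of a scene
#'
#' Produces the 3-channel 16-bit fluorescence image (channel order lipid
#' droplets, cytoplasm, nuclei) together with exact ground truth. Each
#' channel is nonzero only over its structure class (plus background level
#' and noise); large droplets optionally carry a darker interior dip, and
#' the cytoplasm is modulated by a seeded low-pass texture emulating uneven
#' dye reaction.
#'
#' @param scene a `vs_scene`.
#' @param params the [phantom_params()] used to sample it.
#' @return list with `image` (array `H x W x 3`, 16-bit values) and
#'   `ground_truth` (label maps + per-object table with exact pixel areas
#'   and rendered mean intensities).
#' @export
render_fluorescence <- function(scene, params) {
  H <- scene$field_size[1]; W <- scene$field_size[2]
  if (!all(scene$field_size == params$field_size)) {
    stop("scene and params disagree on field size", call. = FALSE)
  }
  masks <- scene_masks(scene)

  ch_d <- matrix(0, H, W)
  for (i in seq_along(scene$cells)) {
    dr <- scene$cells[[i]]$droplets
    for (j in seq_len(nrow(dr))) {
      bb <- bbox_of(dr$x[j], dr$y[j], dr$r[j] + 1, H, W)
      if (is.null(bb)) next
      dx <- outer(rep(1, length(bb$ys)), bb$xs - dr$x[j])
      dy <- outer(bb$ys - dr$y[j], rep(1, length(bb$xs)))
      d <- sqrt(dx^2 + dy^2)
      prof <- as.numeric(d <= dr$r[j])
      if (params$droplet_dip > 0 && dr$r[j] >= 7) {
        prof <- prof * (1 - params$droplet_dip *
                          exp(-(d / (0.45 * dr$r[j]))^2))
      }
      amp <- params$droplet_fluor * exp(rnorm(1, 0, 0.1))
      ch_d[bb$rows, bb$cols] <- pmax(ch_d[bb$rows, bb$cols],
                                     amp * matrix(prof, length(bb$rows)))
    }
  }

  tex <- texture_field(H, W, params$texture_roughness, params$texture_scale)
  ch_c <- params$cyto_fluor * (masks$cytoplasm > 0) * tex
  ch_n <- matrix(0, H, W)
  for (i in seq_along(scene$cells)) {
    nm <- masks$nuclei == i
    ch_n[nm] <- params$nucleus_fluor * exp(rnorm(1, 0, 0.05))
  }

  chans <- list(ch_d, ch_c, ch_n)
  img <- array(0, dim = c(H, W, 3))
  for (k in 1:3) {
    m <- gaussian_blur(chans[[k]], params$psf_sigma) + params$fluor_bg[k]
    m <- add_camera_noise(m, params$noise_sd[k], params$shot_gain)
    img[, , k] <- to_uint16(m)
  }

  gt_objects <- do.call(rbind, lapply(seq_along(masks), function(k) {
    lab <- masks[[k]]
    K <- max(lab)
    if (K == 0) return(NULL)
    area <- tabulate(lab[lab > 0], nbins = K)
    keep <- which(area > 0)
    mi <- vapply(keep, function(l) mean(img[, , k][lab == l]), 0)
    data.frame(class = channel_names()[k], label = keep, area = area[keep],
               mean_intensity = mi, stringsAsFactors = FALSE)
  }))

  dimnames(img) <- list(NULL, NULL, channel_names())
  list(image = img,
       ground_truth = list(labels = masks, objects = gt_objects))
}

#' Render the bright-field defocus stack of a scene
#'
#' Each droplet is rendered as a difference-of-Gaussians ring whose signed
#' central contrast varies linearly with slice defocus and flips polarity
#' across the stack (a cheap stand-in for the through-focus contrast
#' inversion of high-refractive-index objects). Cytoplasm adds a weak
#' textured offset; nuclei have zero contrast by default and are therefore
#' statistically invisible against the surrounding cytoplasm.
#'
#' @param scene a `vs_scene`.
#' @param params the matching [phantom_params()].
#' @return array `H x W x n_slices`, 16-bit values, slices in z-order.
#' @export
render_brightfield <- function(scene, params) {
  H <- scene$field_size[1]; W <- scene$field_size[2]
  if (!all(scene$field_size == params$field_size)) {
    stop("scene and params disagree on field size", call. = FALSE)
  }
  masks <- scene_masks(scene)
  n <- params$n_slices
  tex <- texture_field(H, W, params$texture_roughness * 0.5,
                       params$texture_scale)
  base <- params$bf_level +
    params$cyto_contrast * gaussian_blur((masks$cytoplasm > 0) * tex, 2) +
    params$nucleus_contrast * gaussian_blur(1.0 * (masks$nuclei > 0), 2)

  drops <- do.call(rbind, lapply(scene$cells, function(cl) cl$droplets))
  stack <- array(0, dim = c(H, W, n))
  mid <- (n + 1) / 2
  dmax <- max(1, (n - 1) / 2) * params$defocus_step
  for (s in seq_len(n)) {
    d_rel <- if (n == 1) 0 else ((s - mid) * params$defocus_step) / dmax
    sl <- base
    amp <- params$droplet_contrast * (0.35 + d_rel)
    if (!is.null(drops) && nrow(drops) > 0) {
      for (j in seq_len(nrow(drops))) {
        sig <- 0.6 * drops$r[j] * (1 + 0.5 * abs(d_rel))
        bb <- bbox_of(drops$x[j], drops$y[j], 3.5 * sig, H, W)
        if (is.null(bb)) next
        dx <- outer(rep(1, length(bb$ys)), bb$xs - drops$x[j])
        dy <- outer(bb$ys - drops$y[j], rep(1, length(bb$xs)))
        r2 <- dx^2 + dy^2
        dog <- 2 * exp(-r2 / (2 * sig^2)) - exp(-r2 / (2 * (1.8 * sig)^2))
        sl[bb$rows, bb$cols] <- sl[bb$rows, bb$cols] + amp * dog
      }
    }
    sl <- sl + matrix(rnorm(H * W, sd = params$bf_noise_sd), H, W)
    stack[, , s] <- to_uint16(sl)
  }
  stack
}

#' Generate an in-memory set of paired phantom samples
#'
#' Convenience wrapper producing normalized training pairs directly (no
#' disk round trip): each element is `list(x, y)` with `x` the bright-field
#' stack and `y` the fluorescence target, both scaled to `[0, 1]`. The
#' default geometry is scaled for small training fields (one adipocyte per
#' 64-px field).
#'
#' @param n number of paired fields.
#' @param seed base seed; field `i` uses `seed + i - 1`.
#' @param params a [phantom_params()]; the default is the 64-px desk-scale
#'   configuration.
#' @return list of `n` pairs, each `list(x, y, ground_truth)`.
#' @export
phantom_pairs <- function(n, seed = 1L,
                          params = phantom_params(
                            field_size = 64L, n_cells = 1L,
                            cell_radius = 22, nucleus_radius = 7,
                            droplets_per_cell = 5L, r_large_median = 8)) {
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- seed + i - 1L
    scene <- sample_scene(p)
    fl <- render_fluorescence(scene, p)
    bf <- render_brightfield(scene, p)
    list(x = bf / 65535, y = fl$image / 65535,
         ground_truth = fl$ground_truth)
  })
}

#' Write a paired phantom dataset to disk
#'
#' Generates `n_fields` scenes, renders each as a bright-field stack, a
#' fluorescence target and ground-truth label maps, writes them as
#' multi-page 16-bit TIFF files and records them in a JSON index.
#'
#' @param n_fields number of paired fields (>= 1).
#' @param params a [phantom_params()]; if it carries a `seed`, field `i`
#'   uses `seed + i - 1`, making the dataset reproducible.
#' @param out_dir output directory (created if missing).
#' @param val_fraction fraction of fields tagged as validation split (the
#'   last fields in order).
#' @return the dataset index (invisibly): list of entries with id, paths,
#'   and split tag; also written to `index.json`.
#' @export
make_dataset <- function(n_fields, params = phantom_params(), out_dir,
                         val_fraction = 0) {
  if (n_fields < 1) stop("n_fields must be >= 1", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_val <- floor(n_fields * val_fraction)
  entries <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    p <- params
    if (!is.null(params$seed)) p$seed <- params$seed + i - 1L
    scene <- sample_scene(p)
    fl <- render_fluorescence(scene, p)
    bf <- render_brightfield(scene, p)
    id <- sprintf("field_%04d", i)
    bf_path <- file.path(out_dir, paste0(id, "_bf.tif"))
    fl_path <- file.path(out_dir, paste0(id, "_fl.tif"))
    gt_path <- file.path(out_dir, paste0(id, "_gt.tif"))
    write_stack_tiff(bf, bf_path)
    write_stack_tiff(fl$image, fl_path)
    write_stack_tiff(
      array(unlist(fl$ground_truth$labels),
            dim = c(dim(fl$ground_truth$labels$droplets), 3)),
      gt_path)
    entries[[i]] <- list(
      id = id, brightfield = basename(bf_path), fluorescence = basename(fl_path),
      ground_truth = basename(gt_path),
      split = if (i > n_fields - n_val) "val" else "train"
    )
  }
  index <- list(n_slices = params$n_slices,
                field_size = as.integer(params$field_size),
                seed = params$seed, entries = entries)
  jsonlite::write_json(index, file.path(out_dir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(index)
}
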