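# Segmentation and feature extraction for the three structure classes.
#
# The pipeline mirrors the cell-profiling convention: nuclei are found
# first (adaptive threshold, shape declumping), cytoplasm is grown as one
# secondary object per nucleus seed (constrained propagation), and lipid
# droplets are segmented independently in two size-targeted global-threshold
# passes with intensity declumping. Intensities are measured on
# [0, 1]-rescaled images.

#' Segmentation parameters for one structure class
#'
#' @param diameter_range accepted equivalent-diameter range in px
#'   (objects outside it are removed).
#' @param strategy `"global"` (one Otsu threshold for the image) or
#'   `"adaptive"` (block-wise Otsu interpolated to a per-pixel threshold
#'   surface, for structures of uneven intensity).
#' @param window adaptive block size in px (ignored for global).
#' @param declump `"shape"` (watershed on the distance transform, splits at
#'   necks), `"intensity"` (watershed on smoothed intensity, splits at
#'   saddle points), or `"none"`.
#' @param smoothing_sigma Gaussian pre-smoothing in px (0 disables).
#' @param fill_holes fill holes inside thresholded objects before
#'   declumping.
#' @param declump_tolerance watershed merge tolerance: px of distance-map
#'   depth for shape declumping, intensity units for intensity declumping
#'   (`NULL` = 1 px / 0.03 respectively).
#' @param threshold_correction multiplicative factor applied to the
#'   threshold.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(diameter_range = c(4, 60),
                                strategy = c("global", "adaptive"),
                                window = 50,
                                declump = c("shape", "intensity", "none"),
                                smoothing_sigma = 1,
                                fill_holes = TRUE,
                                declump_tolerance = NULL,
                                threshold_correction = 1) {
  strategy <- match.arg(strategy)
  declump <- match.arg(declump)
  stopifnot(length(diameter_range) == 2, diameter_range[1] < diameter_range[2],
            window > 0, smoothing_sigma >= 0, threshold_correction > 0)
  if (strategy == "adaptive" && window < diameter_range[2]) {
    warning("adaptive window (", window,
            " px) is smaller than the largest expected diameter (",
            diameter_range[2], " px); large objects may be fragmented")
  }
  structure(list(diameter_range = diameter_range, strategy = strategy,
                 window = window, declump = declump,
                 smoothing_sigma = smoothing_sigma, fill_holes = fill_holes,
                 declump_tolerance = declump_tolerance,
                 threshold_correction = threshold_correction),
            class = "segmentation_params")
}

relabel_contiguous <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0) return(lab)
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], u)
  storage.mode(out) <- "integer"
  out
}

# global or block-wise-interpolated Otsu threshold surface
threshold_surface <- function(img, params) {
  rng <- range(img)
  if (diff(rng) < 1e-6) return(NULL)     # constant image: nothing to split
  t_global <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  if (params$strategy == "global") {
    return(matrix(t_global * params$threshold_correction,
                  nrow(img), ncol(img)))
  }
  w <- params$window
  H <- nrow(img); W <- ncol(img)
  nbr <- max(1L, ceiling(H / w)); nbc <- max(1L, ceiling(W / w))
  grid <- matrix(t_global, nbr, nbc)
  for (i in seq_len(nbr)) {
    rows <- (floor((i - 1) * H / nbr) + 1):floor(i * H / nbr)
    for (j in seq_len(nbc)) {
      cols <- (floor((j - 1) * W / nbc) + 1):floor(j * W / nbc)
      block <- img[rows, cols]
      if (diff(range(block)) > 1e-6) {
        tb <- EBImage::otsu(EBImage::Image(block), range = c(0, 1))
        # guard against blocks that split pure background noise
        grid[i, j] <- min(max(tb, 0.7 * t_global), 1.5 * t_global)
      }
    }
  }
  surf <- as.matrix(EBImage::resize(EBImage::Image(grid), w = H, h = W,
                                    filter = "bilinear"))
  surf * params$threshold_correction
}

declump_labels <- function(mask, img_smooth, params) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  ext <- max(1, floor(params$diameter_range[1] / 4))
  lab <- switch(
    params$declump,
    none = EBImage::bwlabel(EBImage::Image(mask)),
    shape = {
      tol <- params$declump_tolerance %||% 1
      dm <- EBImage::distmap(EBImage::Image(mask))
      EBImage::watershed(dm, tolerance = tol, ext = ext)
    },
    intensity = {
      tol <- params$declump_tolerance %||% 0.03
      x <- EBImage::Image(img_smooth * mask)
      EBImage::watershed(x, tolerance = tol, ext = ext)
    }
  )
  m <- as.matrix(EBImage::imageData(lab))
  storage.mode(m) <- "integer"
  m
}

size_filter <- function(lab, diameter_range) {
  if (max(lab) == 0) return(lab)
  area <- tabulate(lab[lab > 0], nbins = max(lab))
  eqd <- 2 * sqrt(area / pi)
  bad <- which(area == 0 | eqd < diameter_range[1] | eqd > diameter_range[2])
  if (length(bad)) lab[lab %in% bad] <- 0L
  relabel_contiguous(lab)
}

#' Identify primary objects in one channel
#'
#' Thresholds the (optionally smoothed) image globally or adaptively,
#' fills holes, declumps touching objects by shape or intensity, and
#' removes objects outside the configured diameter range. An all-background
#' result is a valid empty label map, not an error.
#'
#' @param image single-channel numeric matrix, values in `[0, 1]`.
#' @param params a [segmentation_params()].
#' @return integer label matrix (0 = background, labels contiguous 1..K)
#'   with the parameters attached as attribute `provenance`.
#' @export
identify_primary <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image))
  sm <- if (params$smoothing_sigma > 0) {
    gaussian_blur(image, params$smoothing_sigma)
  } else {
    image
  }
  surf <- threshold_surface(sm, params)
  if (is.null(surf)) {
    if (params$strategy == "adaptive") {
      warning("constant image: adaptive threshold undefined, returning an empty label map")
    }
    lab <- matrix(0L, nrow(image), ncol(image))
    attr(lab, "provenance") <- params
    return(lab)
  }
  mask <- sm > surf
  if (params$fill_holes) {
    mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
  }
  lab <- declump_labels(mask, sm, params)
  lab <- size_filter(lab, params$diameter_range)
  attr(lab, "provenance") <- params
  lab
}

#' Identify secondary objects around seed objects
#'
#' Grows exactly one secondary object per seed by constrained propagation
#' (region growing on the intensity image restricted to the thresholded
#' foreground), the standard way cell boundaries are derived from nucleus
#' seeds. Secondary objects are supersets of their seeds and carry the seed
#' labels.
#'
#' @param image single-channel numeric matrix in `[0, 1]` (e.g. cytoplasm
#'   stain).
#' @param seeds integer label matrix of primary objects.
#' @param params a [segmentation_params()] (typically adaptive with a
#'   window larger than the one used for the seeds).
#' @param lambda regularization of the propagation metric (trade-off
#'   between image gradient and Euclidean distance).
#' @return integer label matrix; `max(result)` labels correspond to seed
#'   labels and the object count equals the seed count.
#' @export
identify_secondary <- function(image, seeds,
                               params = segmentation_params(
                                 diameter_range = c(40, 200),
                                 strategy = "adaptive", window = 200,
                                 declump = "none"),
                               lambda = 1e-4) {
  if (!all(dim(image) == dim(seeds))) stop("shape mismatch", call. = FALSE)
  if (max(seeds) == 0) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  sm <- if (params$smoothing_sigma > 0) {
    gaussian_blur(image, params$smoothing_sigma)
  } else {
    image
  }
  surf <- threshold_surface(sm, params)
  fg <- if (is.null(surf)) seeds > 0 else (sm > surf | seeds > 0)
  if (params$fill_holes) {
    fg <- as.matrix(EBImage::fillHull(EBImage::Image(fg))) > 0
  }
  lab <- EBImage::propagate(EBImage::Image(sm), EBImage::Image(seeds),
                            mask = EBImage::Image(fg), lambda = lambda)
  m <- as.matrix(EBImage::imageData(lab))
  storage.mode(m) <- "integer"
  m
}

#' Segment lipid droplets in two size-targeted passes
#'
#' Runs [identify_primary()] once with the small-droplet and once with the
#' large-droplet parameters (both global threshold, intensity declumping),
#' keeps every large-pass object, adds small-pass objects that do not
#' overlap a large-pass object beyond `overlap_threshold` of their own
#' area, and relabels contiguously.
#'
#' @param image droplet-channel matrix in `[0, 1]`.
#' @param params_small,params_large [segmentation_params()] for the two
#'   size populations.
#' @param overlap_threshold small-pass objects overlapping large-pass
#'   objects by more than this fraction of their area are discarded.
#' @return integer label matrix.
#' @export
segment_droplets <- function(image,
                             params_small = segmentation_params(
                               diameter_range = c(3, 14),
                               strategy = "global", declump = "intensity",
                               smoothing_sigma = 1),
                             params_large = segmentation_params(
                               diameter_range = c(12, 60),
                               strategy = "global", declump = "intensity",
                               smoothing_sigma = 1),
                             overlap_threshold = 0.5) {
  lab_s <- identify_primary(image, params_small)
  lab_l <- identify_primary(image, params_large)
  if (max(lab_s) == 0 && max(lab_l) == 0) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  out <- lab_l
  nl <- max(lab_l)
  if (max(lab_s) > 0) {
    on_large <- lab_l > 0
    area_s <- tabulate(lab_s[lab_s > 0], nbins = max(lab_s))
    ov <- tabulate(lab_s[lab_s > 0 & on_large], nbins = max(lab_s))
    keep <- which(area_s > 0 & ov / pmax(area_s, 1) <= overlap_threshold)
    for (l in keep) {
      sel <- lab_s == l & out == 0L
      if (any(sel)) {
        nl <- nl + 1L
        out[sel] <- nl
      }
    }
  }
  relabel_contiguous(out)
}

#' Extract per-structure features from a label map
#'
#' The five profiling features: object count, mean object area (px),
#' integrated intensity (sum of intensities over all object pixels), mean
#' intensity (mean over objects of the per-object mean) and the population
#' standard deviation of the per-object mean intensities. For an empty
#' label map the count is 0 and the remaining features `NA`.
#'
#' @param labels integer label matrix.
#' @param intensity matching intensity matrix, rescaled to `[0, 1]`.
#' @param class_name structure-class tag for the output row.
#' @param image_id image tag for the output row.
#' @return one-row data.frame.
#' @export
extract_features <- function(labels, intensity, class_name = NA_character_,
                             image_id = NA_character_) {
  if (!all(dim(labels) == dim(intensity))) stop("shape mismatch", call. = FALSE)
  K <- length(unique(labels[labels > 0]))
  if (K == 0) {
    return(data.frame(image = image_id, class = class_name, count = 0L,
                      mean_area = NA_real_, integrated_intensity = NA_real_,
                      mean_intensity = NA_real_, sd_intensity = NA_real_,
                      stringsAsFactors = FALSE))
  }
  sel <- labels > 0
  lv <- labels[sel]
  iv <- intensity[sel]
  area <- tabulate(lv, nbins = max(lv))
  isum <- as.vector(rowsum(iv, lv))   # ordered by sorted label
  keep <- which(area > 0)
  means <- isum / area[keep]
  data.frame(
    image = image_id, class = class_name, count = K,
    mean_area = mean(area[keep]),
    integrated_intensity = sum(iv),
    mean_intensity = mean(means),
    sd_intensity = sqrt(mean((means - mean(means))^2)),
    stringsAsFactors = FALSE
  )
}

#' Default per-structure profiling parameters
#'
#' Nuclei: adaptive threshold (window 50 px), shape declumping, wide
#' diameter range. Cytoplasm: adaptive threshold with a larger window
#' (200 px), grown as secondary objects from the nucleus seeds. Droplets:
#' two global-threshold passes (small/large) with intensity declumping.
#'
#' @param nucleus_diameter,cell_diameter,droplet_small,droplet_large
#'   diameter ranges (px) per structure.
#' @param nucleus_window,cyto_window adaptive window sizes (px); the
#'   cytoplasm window must be the larger one.
#' @return named list of [segmentation_params()] used by [profile_image()].
#' @export
profiling_params <- function(nucleus_diameter = c(12, 48),
                             cell_diameter = c(40, 200),
                             droplet_small = c(3, 14),
                             droplet_large = c(12, 60),
                             nucleus_window = 50,
                             cyto_window = 200) {
  list(
    nuclei = segmentation_params(nucleus_diameter, "adaptive",
                                 window = nucleus_window, declump = "shape",
                                 smoothing_sigma = 1),
    cytoplasm = segmentation_params(cell_diameter, "adaptive",
                                    window = cyto_window, declump = "none",
                                    smoothing_sigma = 2),
    droplets_small = segmentation_params(droplet_small, "global",
                                         declump = "intensity",
                                         smoothing_sigma = 1),
    droplets_large = segmentation_params(droplet_large, "global",
                                         declump = "intensity",
                                         smoothing_sigma = 1)
  )
}

#' Profile one 3-channel stained image
#'
#' Runs the full nuclei-first pipeline on a (target or virtually stained)
#' fluorescence image and extracts the five features per structure class.
#'
#' @param image array `H x W x 3` (droplets, cytoplasm, nuclei), values in
#'   `[0, 1]`.
#' @param params a [profiling_params()] list.
#' @param image_id tag recorded in the feature rows.
#' @return list with `labels` (per-class label maps) and `features`
#'   (data.frame, one row per structure class).
#' @export
profile_image <- function(image, params = profiling_params(),
                          image_id = "image") {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  nuc <- identify_primary(image[, , 3], params$nuclei)
  cyt <- identify_secondary(image[, , 2], nuc, params$cytoplasm)
  dro <- segment_droplets(image[, , 1], params$droplets_small,
                          params$droplets_large)
  labels <- list(droplets = dro, cytoplasm = cyt, nuclei = nuc)
  features <- rbind(
    extract_features(dro, image[, , 1], "droplets", image_id),
    extract_features(cyt, image[, , 2], "cytoplasm", image_id),
    extract_features(nuc, image[, , 3], "nuclei", image_id)
  )
  list(labels = labels, features = features)
}
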