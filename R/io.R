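# Multi-page 16-bit TIFF I/O and dataset indexing.
#
# Page-order convention: bright-field slices in acquisition z-order;
# fluorescence channels ordered lipid droplets, cytoplasm, nuclei; label
# maps in the same structure order. Pixel values are stored in the original
# 16-bit range [0, 65535]; in memory, model-facing code works on the
# normalized range [0, 1] with a fixed divisor of 65535 (never per-image
# min-max), so intensity features remain comparable across images.

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param x array `H x W x P` (or a matrix for a single page), values in
#'   `[0, 65535]`; they are rounded to integers on write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(x, path) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  pages <- lapply(seq_len(dim(x)[3]), function(k) {
    m <- round(x[, , k])
    if (any(m < 0 | m > 65535)) {
      stop("pixel values outside [0, 65535] in ", path, call. = FALSE)
    }
    m / 65535
  })
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "none")
  if (!isTRUE(ok > 0) && !isTRUE(ok)) stop("failed to write ", path, call. = FALSE)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF as an integer-valued stack
#'
#' @param path TIFF file.
#' @param expect_pages optional page count; a mismatch is a format error.
#' @return array `H x W x P` with values in `[0, 65535]`.
#' @export
read_stack_tiff <- function(path, expect_pages = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(expect_pages) && length(pages) != expect_pages) {
    stop(sprintf("%s: expected %d pages, found %d", path, expect_pages,
                 length(pages)), call. = FALSE)
  }
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pk <- pages[[k]]
    if (length(dim(pk)) == 3L) pk <- pk[, , 1]
    if (!all(dim(pk)[1:2] == dim(arr)[1:2])) {
      stop(path, ": pages differ in size", call. = FALSE)
    }
    arr[, , k] <- round(pk * 65535)
  }
  arr
}

#' Load a dataset index written by [make_dataset()]
#'
#' @param dir dataset directory containing `index.json`.
#' @return the index with absolute paths resolved; errors if a referenced
#'   file is missing.
#' @export
load_index <- function(dir) {
  path <- file.path(dir, "index.json")
  if (!file.exists(path)) stop("no index.json in ", dir, call. = FALSE)
  index <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- vapply(index$entries, function(e) e$id, "")
  if (anyDuplicated(ids)) stop("duplicate sample ids in index", call. = FALSE)
  index$entries <- lapply(index$entries, function(e) {
    for (f in c("brightfield", "fluorescence", "ground_truth")) {
      if (!is.null(e[[f]])) {
        e[[f]] <- file.path(dir, e[[f]])
        if (!file.exists(e[[f]])) {
          stop("missing file referenced by index: ", e[[f]], call. = FALSE)
        }
      }
    }
    e
  })
  index
}

#' Load one paired sample in normalized form
#'
#' Reads the bright-field stack and the fluorescence target of one index
#' entry, checks page counts and sizes, and rescales both to `[0, 1]` by
#' the fixed 16-bit divisor.
#'
#' @param entry one element of `load_index(dir)$entries`.
#' @param n_slices declared number of bright-field slices.
#' @return list with `x` (array `H x W x n_slices`), `y` (array
#'   `H x W x 3`), and `divisor` (65535).
#' @export
load_pair <- function(entry, n_slices = 7L) {
  x <- read_stack_tiff(entry$brightfield, expect_pages = n_slices)
  y <- read_stack_tiff(entry$fluorescence, expect_pages = 3L)
  if (!all(dim(x)[1:2] == dim(y)[1:2])) {
    stop(entry$id, ": bright-field and fluorescence sizes differ",
         call. = FALSE)
  }
  list(x = x / 65535, y = y / 65535, divisor = 65535, id = entry$id)
}

#' Load a whole split of a dataset into memory
#'
#' @param dir dataset directory.
#' @param split `"train"`, `"val"`, or `NULL` for everything.
#' @return list of pairs as returned by [load_pair()].
#' @export
load_split <- function(dir, split = NULL) {
  index <- load_index(dir)
  n_slices <- index$n_slices %||% 7L
  entries <- index$entries
  if (!is.null(split)) {
    entries <- Filter(function(e) identical(e$split, split), entries)
  }
  lapply(entries, load_pair, n_slices = n_slices)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
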