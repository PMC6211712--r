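#' Raster image with per-pixel validity
#'
#' A `raster_image` is the package's grid data model: a height x width matrix
#' of normalized pixel intensities in \[0, 1\] together with a logical matrix
#' of the same shape flagging which pixels take part in statistics and
#' selection.  Pixels removed by gross segmentation (manually zeroed regions
#' outside the cellular layer of interest) are represented by `valid = FALSE`,
#' not by an intensity of zero, so that "removed" is never conflated with
#' "dark".  The grid is indexed `[row, col]` with row 1 at the top of the
#' image.
#'
#' @param intensity Numeric matrix of intensities, all finite and in \[0, 1\].
#' @param valid Logical matrix of the same dimensions (default: all `TRUE`).
#' @return An object of class `raster_image` with fields `intensity` and
#'   `valid`.
#' @seealso [normalize_image()] to build one from raw integer pixel data,
#'   [read_image()] to load one from a TIFF or PNG file.
#' @export
#' @examples
#' img <- raster_image(matrix(runif(25), 5, 5))
#' image_stats(img)
raster_image <- function(intensity, valid = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("'intensity' must be a numeric matrix")
  if (nrow(intensity) < 3L || ncol(intensity) < 3L)
    stop("raster images must be at least 3x3")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensities must all be finite")
  if (any(intensity < 0) || any(intensity > 1))
    stop("intensities must lie in [0, 1]")
  if (is.null(valid)) {
    valid <- matrix(TRUE, nrow(intensity), ncol(intensity))
  }
  if (!is.matrix(valid) || !is.logical(valid) ||
      !identical(dim(valid), dim(intensity)))
    stop("'valid' must be a logical matrix with the same dimensions")
  if (anyNA(valid)) stop("'valid' must not contain NA")
  structure(list(intensity = intensity, valid = valid),
            class = "raster_image")
}

#' Masking image ("sketchpad") on the coordinates of a source image
#'
#' A `mask_image` holds computed per-pixel values (neighborhood means, local
#' Moran coefficients, or 0/1 logical values) on the same coordinate grid as
#' its source [raster_image()].  Values are unbounded: local Moran
#' coefficients may be negative or exceed 1.  Pixels in the indeterminate
#' border frame left by a focal operation, and pixels invalid in the source,
#' carry `valid = FALSE`.
#'
#' @param value Numeric matrix of computed values (NA allowed only where
#'   invalid).
#' @param valid Logical matrix of the same dimensions.
#' @return An object of class `mask_image`.
#' @export
mask_image <- function(value, valid = NULL) {
  if (!is.matrix(value) || !is.numeric(value))
    stop("'value' must be a numeric matrix")
  if (is.null(valid)) valid <- !is.na(value)
  if (!identical(dim(valid), dim(value)))
    stop("'valid' must match the dimensions of 'value'")
  if (any(is.na(value[valid])))
    stop("mask values must be defined wherever valid")
  structure(list(value = value, valid = valid), class = "mask_image")
}

img_width  <- function(x) ncol(x$intensity %||% x$value)
img_height <- function(x) nrow(x$intensity %||% x$value)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d pixels (%d valid)\n",
              img_width(x), img_height(x), sum(x$valid)))
  s <- image_stats(x)
  cat(sprintf("  mean %.4g  sd %.4g  skewness %.4g\n", s$mean, s$sd,
              s$skewness))
  invisible(x)
}

#' @export
print.mask_image <- function(x, ...) {
  v <- x$value[x$valid]
  cat(sprintf("<mask_image> %d x %d pixels (%d valid), values in [%.4g, %.4g]\n",
              img_width(x), img_height(x), sum(x$valid),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Normalize raw integer pixel data to a raster image
#'
#' Scales raw camera counts to the \[0, 1\] range by dividing by
#' `2^bit_depth - 1`.  By default, pixels that are exactly zero are flagged
#' invalid (`zero_invalid = TRUE`): gross segmentation writes excluded
#' regions as zero, so a zero pixel is treated as "removed" rather than
#' "dark".  Set `zero_invalid = FALSE` to keep zeros in all statistics (as
#' needed for whole-image bin-count arithmetic).
#'
#' @param raw_pixels Integer (or whole-number numeric) matrix of raw values.
#' @param bit_depth Either 8 or 16.
#' @param zero_invalid Flag exact zeros as invalid? Default `TRUE`.
#' @return A [raster_image()].
#' @export
#' @examples
#' normalize_image(matrix(c(0L, 128L, 255L, 64L, 1L, 255L, 0L, 32L, 7L), 3),
#'                 bit_depth = 8)
normalize_image <- function(raw_pixels, bit_depth = c(8, 16),
                            zero_invalid = TRUE) {
  bit_depth <- match.arg(as.character(bit_depth[1L]), c("8", "16"))
  bit_depth <- as.integer(bit_depth)
  if (!is.matrix(raw_pixels) || !is.numeric(raw_pixels))
    stop("'raw_pixels' must be a numeric matrix")
  if (anyNA(raw_pixels)) stop("raw pixel values must not be NA")
  top <- 2^bit_depth - 1
  if (any(raw_pixels < 0) || any(raw_pixels > top))
    stop(sprintf("raw values out of range [0, %d] for declared %d-bit depth",
                 top, bit_depth))
  if (any(raw_pixels != round(raw_pixels)))
    stop("raw pixel values must be whole numbers")
  intensity <- raw_pixels / top
  valid <- if (zero_invalid) raw_pixels != 0 else
    matrix(TRUE, nrow(raw_pixels), ncol(raw_pixels))
  raster_image(intensity, valid)
}

## moment (population) skewness g1 = m3 / m2^(3/2)
moment_skewness <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 <= 0) return(NA_real_)
  mean(d^3) / m2^1.5
}

#' Summary statistics over the valid pixels of an image
#'
#' Mean, sample standard deviation, retained-pixel count and moment
#' skewness, computed over valid pixels only.  With no valid pixels the
#' statistics are reported as `NA` (undefined), never as zeros.
#'
#' @param img A [raster_image()].
#' @return A list of class `summary_stats` with fields `mean`, `sd`, `n`,
#'   `skewness`.
#' @export
image_stats <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  x <- img$intensity[img$valid]
  n <- length(x)
  structure(
    list(mean     = if (n) mean(x) else NA_real_,
         sd       = if (n > 1L) stats::sd(x) else NA_real_,
         n        = n,
         skewness = if (n > 2L) moment_skewness(x) else NA_real_),
    class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g, sd = %.4g, skewness = %.4g\n",
              x$n, x$mean, x$sd, x$skewness))
  invisible(x)
}

## coerce arbitrary numeric matrix in [0,1] to raster_image, for tests etc.
#' @export
as_raster_image <- function(x, valid = NULL) {
  if (inherits(x, "raster_image")) return(x)
  raster_image(as.matrix(x), valid)
}
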