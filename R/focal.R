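## Map-algebra focal (neighborhood) operations.
##
## Neighborhood sums are accumulated by shifting zero-padded copies of the
## matrix over the kernel offsets, which keeps the k x k focal mean O(k^2)
## matrix additions instead of a per-pixel loop.

## out[i, j] <- m[i + di, j + dj], zero outside the grid
shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r1 <- max(1L, 1L - di); r2 <- min(nr, nr - di)
  c1 <- max(1L, 1L - dj); c2 <- min(nc, nc - dj)
  if (r1 <= r2 && c1 <= c2)
    out[r1:r2, c1:c2] <- m[(r1 + di):(r2 + di), (c1 + dj):(c2 + dj)]
  out
}

## sum of m over the k x k window centered at each pixel (zero padded)
window_sum <- function(m, k) {
  h <- (k - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (di in -h:h)
    for (dj in -h:h)
      out <- out + shift_matrix(m, di, dj)
  out
}

border_frame <- function(nr, nc, width) {
  keep <- matrix(FALSE, nr, nc)
  if (width == 0L) return(!keep)
  if (nr > 2L * width && nc > 2L * width)
    keep[(width + 1L):(nr - width), (width + 1L):(nc - width)] <- TRUE
  keep
}

check_kernel <- function(kernel_size, img, min_size = 1L) {
  if (length(kernel_size) != 1L || is.na(kernel_size) ||
      kernel_size != round(kernel_size))
    stop("'kernel_size' must be a single integer")
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L == 0L)
    stop("'kernel_size' must be odd")
  if (kernel_size < min_size)
    stop(sprintf("'kernel_size' must be >= %d", min_size))
  if (kernel_size > min(img_width(img), img_height(img)))
    stop("'kernel_size' exceeds the image dimensions")
  kernel_size
}

#' Focal (neighborhood) statistic of a raster image
#'
#' Replaces each pixel by a statistic of its `kernel_size` x `kernel_size`
#' neighborhood, computed over valid source pixels only, and returns the
#' result as a [mask_image()].  This is the map-algebra focal function: the
#' default neighborhood mean produces the smoothed masking image that the
#' segmentation methods threshold, and the discrepancy between a pixel and
#' its neighborhood mean implicitly measures local conformance, so mean
#' filtering suppresses anomalous isolated pixels.
#'
#' A border frame of `floor(kernel_size / 2)` pixels is indeterminate (the
#' centered kernel extends past the image edge there) and is flagged
#' invalid, as are pixels invalid in the source and pixels whose
#' neighborhood contains no valid pixel.  Invalid pixels inside a
#' neighborhood are simply ignored, so gross-segmentation boundaries do not
#' erode the region of interest by a kernel width.  `kernel_size = 1`
#' returns a copy of the source values.
#'
#' @param img A [raster_image()].
#' @param kernel_size Odd integer >= 1, the neighborhood width in pixels.
#' @param statistic One of `"mean"`, `"mode"`, `"max"`, or `"custom"` (in
#'   which case `fun` is applied to the vector of valid neighborhood
#'   values).  The mode is the most frequent neighborhood value (smallest on
#'   ties).
#' @param fun For `statistic = "custom"`: a function mapping a non-empty
#'   numeric vector to a single number.
#' @return A [mask_image()] on the same grid.
#' @seealso [local_moran()], [select_between()]
#' @export
#' @examples
#' img <- raster_image(matrix(runif(64), 8, 8))
#' sm <- focal_apply(img, 3)
focal_apply <- function(img, kernel_size,
                        statistic = c("mean", "mode", "max", "custom"),
                        fun = NULL) {
  stopifnot(inherits(img, "raster_image"))
  statistic <- match.arg(statistic)
  k <- check_kernel(kernel_size, img)
  nr <- img_height(img); nc <- img_width(img)

  if (k == 1L) {
    value <- img$intensity
    value[!img$valid] <- NA_real_
    return(mask_image(value, img$valid))
  }

  h <- (k - 1L) %/% 2L
  interior <- border_frame(nr, nc, h)
  v <- img$valid * 1

  if (statistic == "mean") {
    cnt <- window_sum(v, k)
    tot <- window_sum(img$intensity * v, k)
    value <- ifelse(cnt > 0, tot / cnt, NA_real_)
    valid <- interior & img$valid & cnt > 0
  } else if (statistic == "max") {
    neg <- ifelse(img$valid, img$intensity, -Inf)
    mx <- matrix(-Inf, nr, nc)
    for (di in -h:h) for (dj in -h:h) {
      sh <- shift_matrix(neg, di, dj)
      sh[shift_matrix(matrix(1, nr, nc), di, dj) == 0] <- -Inf
      mx <- pmax(mx, sh)
    }
    value <- ifelse(is.finite(mx), mx, NA_real_)
    valid <- interior & img$valid & is.finite(mx)
  } else {
    f <- if (statistic == "mode") {
      function(vals) {
        tb <- table(vals)
        as.numeric(names(tb)[which.max(tb)])
      }
    } else {
      if (!is.function(fun)) stop("statistic 'custom' requires 'fun'")
      fun
    }
    value <- matrix(NA_real_, nr, nc)
    valid <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) {
      if (i <= h || i > nr - h) next
      ri <- (i - h):(i + h)
      for (j in (h + 1L):(nc - h)) {
        if (!img$valid[i, j]) next
        cj <- (j - h):(j + h)
        vals <- img$intensity[ri, cj][img$valid[ri, cj]]
        if (!length(vals)) next
        value[i, j] <- f(vals)
        valid[i, j] <- TRUE
      }
    }
  }
  value[!valid] <- NA_real_
  mask_image(value, valid)
}

#' Local Moran spatial autocorrelation of a raster image
#'
#' Computes, for every pixel, the local Moran coefficient
#' \deqn{I_i = \frac{x_i - \mu}{m_2} \cdot
#'       \frac{1}{|N_i|} \sum_{j \in N_i} (x_j - \mu)}
#' where \eqn{\mu} and \eqn{m_2} are the global mean and population variance
#' of the valid pixels and \eqn{N_i} are the valid pixels of the
#' `kernel_size` x `kernel_size` window excluding the center.  Averaging
#' (rather than summing) the neighbor deviations keeps the coefficient
#' comparable across kernel sizes.
#'
#' High positive values mark locally homogeneous regions far from the global
#' mean — both the dim background and saturated vessels — while the
#' heterogeneous mid-intensity cytoplasm scores low, which is why a single
#' Moran cutoff separates it from both flanking regions.  Values are
#' unbounded and may be negative.  The border frame, source-invalid pixels,
#' and pixels with no valid neighbor are flagged invalid.
#'
#' @param img A [raster_image()]; must not be constant over its valid pixels
#'   (the standardization is undefined for zero variance).
#' @param kernel_size Odd integer >= 3.
#' @return A [mask_image()] of local Moran coefficients.
#' @export
local_moran <- function(img, kernel_size = 7L) {
  stopifnot(inherits(img, "raster_image"))
  k <- check_kernel(kernel_size, img, min_size = 3L)
  x <- img$intensity[img$valid]
  if (length(x) < 2L) stop("need at least two valid pixels")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 <= .Machine$double.eps)
    stop("degenerate input: image is constant over its valid pixels, ",
         "local Moran is undefined")
  nr <- img_height(img); nc <- img_width(img)
  h <- (k - 1L) %/% 2L
  v <- img$valid * 1
  dev <- (img$intensity - mu) * v
  nb_sum <- window_sum(dev, k) - dev
  nb_cnt <- window_sum(v, k) - v
  value <- ifelse(nb_cnt > 0,
                  ((img$intensity - mu) / m2) * nb_sum / nb_cnt,
                  NA_real_)
  valid <- border_frame(nr, nc, h) & img$valid & nb_cnt > 0
  value[!valid] <- NA_real_
  mask_image(value, valid)
}

#' Select original pixels through a masking image
#'
#' Returns a copy of `img` in which a pixel is valid iff it was valid in
#' `img`, valid in `mask`, and the *mask* value lies in `[low, high]`
#' (inclusive at both ends).  Retained pixels keep the original image
#' intensities, never the mask values: the mask is only the sketchpad
#' through which the original is read.
#'
#' @param img A [raster_image()].
#' @param mask A [mask_image()] coregistered with `img`.
#' @param low,high Selection interval in the mask's value units;
#'   `-Inf`/`Inf` select everything on that side.
#' @return A [raster_image()].
#' @export
select_between <- function(img, mask, low = -Inf, high = Inf) {
  stopifnot(inherits(img, "raster_image"), inherits(mask, "mask_image"))
  if (!identical(dim(img$intensity), dim(mask$value)))
    stop("mask dimensions do not match the image")
  if (length(low) != 1L || length(high) != 1L || is.na(low) || is.na(high))
    stop("'low' and 'high' must be single non-NA numbers")
  if (low > high) stop("'low' must not exceed 'high'")
  inband <- mask$valid & !is.na(mask$value) &
    mask$value >= low & mask$value <= high
  raster_image(img$intensity, img$valid & inband)
}
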