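## Percentile-curve machinery.  The percentile curve is the inverse of the
## empirical cumulative distribution function: entry p is the smallest
## intensity such that at least p% of counted pixels are at or below it.

#' Percentile curve of a raster image
#'
#' Entry `p` (for `p` in 1..100) is the `ceil(p * n / 100)`-th order
#' statistic of the counted intensities — the type-1 empirical quantile,
#' with no interpolation, matching the definition "the pixel intensity for
#' which the percentage of pixels at or below it is at least p".  Entry 100
#' is the maximum counted intensity.
#'
#' The counted set is the valid pixels; with `count_zeros = TRUE`,
#' exact-zero pixels (gross-segmented regions are written as zero) are
#' counted as well, which reproduces whole-image bin arithmetic such as
#' 1048576 / 100 = 10486 pixels per bin on a 1024 x 1024 image.
#'
#' The `delta` field is the first difference of the curve,
#' `delta[p] = q[p+1] - q[p]`: the intensity step bought by one percentile
#' point.  Small steps mean pixels bunched at that intensity (homogeneous
#' regions); the heterogeneous region of interest shows moderate, even
#' steps; empty stretches of the intensity axis show up as large jumps.
#'
#' @param img A [raster_image()].
#' @param count_zeros Also count exact-zero pixels excluded by the
#'   zero-as-gross-segmented rule? Default `FALSE`.
#' @return An object of class `percentile_curve`: `intensity` (100 values,
#'   non-decreasing), `delta` (99), `n` (pixels counted), `pixels_per_bin`
#'   (`round(n / 100)`).
#' @export
build_percentile_curve <- function(img, count_zeros = FALSE) {
  stopifnot(inherits(img, "raster_image"))
  counted <- img$valid
  if (isTRUE(count_zeros)) counted <- counted | img$intensity == 0
  x <- img$intensity[counted]
  n <- length(x)
  if (n < 100L)
    stop("insufficient data: need at least 100 counted pixels, have ", n)
  xs <- sort(x)
  p <- 1:100
  q <- xs[ceiling(p * n / 100)]
  structure(list(intensity = q, delta = diff(q), n = n,
                 pixels_per_bin = round(n / 100)),
            class = "percentile_curve")
}

#' @export
print.percentile_curve <- function(x, ...) {
  cat(sprintf(
    "<percentile_curve> %d pixels (%d per bin); q20 = %.4g, q70 = %.4g\n",
    x$n, x$pixels_per_bin, x$intensity[20], x$intensity[70]))
  invisible(x)
}

#' @export
as.data.frame.percentile_curve <- function(x, ...) {
  data.frame(percentile = 1:100, intensity = x$intensity,
             delta = c(x$delta, NA))
}

## mode of delta values rounded to 3 decimals (continuous values have no
## repeated mode otherwise); ties resolve to the smallest value
delta_mode <- function(delta) {
  d <- round(delta, 3)
  tb <- table(d)
  cand <- as.numeric(names(tb)[tb == max(tb)])
  min(cand)
}

#' Locate the heterogeneous plateau of the percentile-delta curve
#'
#' On tripartite images the per-percentile intensity steps are small and
#' even across the heterogeneous region of interest, and inflect upward at
#' its edges (where the intensity axis empties out toward the flanking
#' homogeneous regions).  The plateau is the longest contiguous run of
#' percentile steps whose `delta` does not exceed `inflection_factor`
#' times a reference level, the mode of the `delta` values rounded to 3
#' decimals.  Its endpoints are candidate segmentation thresholds; this is
#' a diagnostic aid, and production percentile segmentation uses fixed
#' percentiles.
#'
#' @param curve A [build_percentile_curve()] result.
#' @param inflection_factor Multiple of the reference level at which the
#'   basin is deemed to inflect upward (default 2).
#' @return A list with `low`, `high` (intensities at the plateau
#'   endpoints), `low_pct`, `high_pct` (the corresponding percentiles), and
#'   `reference` (the delta mode).
#' @export
find_plateau <- function(curve, inflection_factor = 2) {
  stopifnot(inherits(curve, "percentile_curve"))
  delta <- curve$delta
  ref <- delta_mode(delta)
  ok <- delta <= inflection_factor * ref
  r <- rle(ok)
  if (!any(r$values & r$lengths >= 3L))
    stop("no plateau: no run of at least 3 bins at the reference level")
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  start <- sum(r$lengths[seq_len(best - 1L)]) + 1L
  end <- start + r$lengths[best] - 1L
  list(low = curve$intensity[start], high = curve$intensity[end + 1L],
       low_pct = start, high_pct = end + 1L, reference = ref)
}
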