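## Histogram-space machinery: the integrated-intensity vector, its first and
## second differences, and the landmarks (optimum, root crossings) that the
## integrated-intensity segmentation methods threshold on.

N_BINS <- 100L

## bin index for intensities in [0,1]: bins [e_k, e_{k+1}), last bin closed
bin_index <- function(x) pmin(floor(x * N_BINS) + 1L, N_BINS)

#' Intensity profile of a raster image
#'
#' Builds the 100-bin histogram of valid pixel intensities over \[0, 1\] and
#' the integrated-intensity vector: the cumulative sum over bins of
#' (bin frequency x bin midpoint intensity).  The first difference (99
#' values) and second difference (98 values) of the integrated vector carry
#' the rate-of-change information used to locate morphological transitions
#' in intensity space.  The bin midpoint is used as the representative pixel
#' value of a bin, so the final integrated value equals the mean of the
#' midpoint-quantized intensities (a conservation identity the tests
#' exercise).
#'
#' @param img A [raster_image()] with at least one valid pixel.
#' @return An object of class `intensity_profile` with fields `bin_edges`
#'   (101), `mids` (100), `frequency` (100, sums to 1), `integrated` (100),
#'   `first_diff` (99), `second_diff` (98), `n` (pixels counted).
#' @seealso [find_optimum()], [find_root_crossings()],
#'   [build_percentile_curve()]
#' @export
build_profile <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  x <- img$intensity[img$valid]
  if (!length(x)) stop("empty input: no valid pixels to profile")
  edges <- seq(0, 1, length.out = N_BINS + 1L)
  mids <- (edges[-(N_BINS + 1L)] + edges[-1L]) / 2
  freq <- tabulate(bin_index(x), nbins = N_BINS) / length(x)
  integrated <- cumsum(freq * mids)
  fd <- diff(integrated)
  structure(
    list(bin_edges = edges, mids = mids, frequency = freq,
         integrated = integrated, first_diff = fd, second_diff = diff(fd),
         n = length(x)),
    class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d pixels in %d bins, integrated mean %.4g\n",
              x$n, N_BINS, x$integrated[N_BINS]))
  invisible(x)
}

#' @export
as.data.frame.intensity_profile <- function(x, ...) {
  data.frame(bin = seq_len(N_BINS),
             edge_low = x$bin_edges[-(N_BINS + 1L)],
             edge_high = x$bin_edges[-1L],
             mid = x$mids,
             frequency = x$frequency,
             integrated = x$integrated,
             first_diff = c(x$first_diff, NA),
             second_diff = c(x$second_diff, NA, NA))
}

## intensity represented by first/second-difference index m: difference m
## measures the mass entering at bin m+1
diff_intensity <- function(profile, m) profile$mids[m + 1L]

#' Optimum of the first-difference curve
#'
#' Locates the index at which the first difference of the integrated
#' intensity reaches its maximum before decreasing in value — the center of
#' the predominant (cytoplasmic) intensity band.  The maximum must be
#' interior: a monotone first difference (maximum at either end, so the
#' curve never turns over) raises a no-optimum error, signalling that
#' another method must be chosen.
#'
#' An optional 3-bin moving-average smoothing of the first difference
#' (`smooth = TRUE`, default off) can be applied before the search when the
#' curve is noisy; whether it was used is recorded in the return value.
#'
#' @param profile An [build_profile()] result.
#' @param smooth Smooth the first difference with a 3-bin moving average
#'   before locating the maximum?
#' @return A list with `index` (into the first-difference vector),
#'   `intensity` (midpoint of the bin whose mass the difference measures),
#'   and `smoothed`.
#' @export
find_optimum <- function(profile, smooth = FALSE) {
  stopifnot(inherits(profile, "intensity_profile"))
  fd <- profile$first_diff
  if (isTRUE(smooth)) fd <- stats::filter(fd, rep(1 / 3, 3), sides = 2)
  n <- length(fd)
  m <- which.max(fd)
  if (is.na(fd[m]) || m == 1L || m == n ||
      is.na(fd[m + 1L]) || !(fd[m] > fd[m + 1L]) ||
      is.na(fd[m - 1L]) || !(fd[m] >= fd[m - 1L]))
    stop("no optimum: first difference has no interior maximum ",
         "followed by a decrease; choose another segmentation method")
  list(index = as.integer(m),
       intensity = diff_intensity(profile, m),
       smoothed = isTRUE(smooth))
}

#' Root crossings of the second-difference curve
#'
#' Finds the indices where the second difference of the integrated
#' intensity changes sign: `down` for + to -, `up` for - to +.  A crossing
#' is reported at the index of the first element carrying the new sign;
#' exact zeros attach to the following sign.  The downward root crossing at
#' the first-difference optimum is the primary landmark; the ascending
#' crossing after it roughly marks the upper segmentation threshold.
#'
#' The tail of the curve is asymptotic and noisy, so an arbitrary
#' termination rule is required: an ascending crossing is suppressed when
#' `|second_diff|` stays below `eps` for `run` consecutive bins from the
#' crossing on (or through the end of the curve, if fewer bins remain) —
#' such a crossing is bookkeeping noise on a flat tail, not a morphological
#' transition.  By default `eps` adapts to the curve: 2% of the peak
#' `|first_diff|`, floored at 1e-4, so that "flat" is judged relative to
#' the profile's own dynamic range rather than in absolute units (counting
#' noise in the tail scales with the histogram mass).
#'
#' @param profile An [build_profile()] result.
#' @param eps Flatness tolerance for asymptote termination; `NA` (default)
#'   selects the adaptive tolerance above.
#' @param run Number of consecutive flat bins that suppress an ascending
#'   crossing (default 5).
#' @return A data frame with columns `index` (into the second-difference
#'   vector), `direction` (`"down"`/`"up"`), `intensity`; zero rows when the
#'   curve never changes sign.
#' @export
find_root_crossings <- function(profile, eps = NA, run = 5L) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (is.na(eps))
    eps <- max(1e-4, 0.02 * max(abs(profile$first_diff)))
  sd2 <- profile$second_diff
  n <- length(sd2)
  s <- sign(sd2)
  ## zeros attach to the following sign
  for (i in rev(seq_len(n - 1L))) if (s[i] == 0) s[i] <- s[i + 1L]
  idx <- which(s[-n] != 0 & s[-1L] != 0 & s[-n] != s[-1L]) + 1L
  if (!length(idx))
    return(data.frame(index = integer(), direction = character(),
                      intensity = numeric()))
  dir <- ifelse(s[idx] < 0, "down", "up")
  keep <- rep(TRUE, length(idx))
  for (j in seq_along(idx)) {
    if (dir[j] != "up") next
    span <- idx[j]:min(idx[j] + run - 1L, n)
    if (all(abs(sd2[span]) < eps)) keep[j] <- FALSE
  }
  data.frame(index = idx[keep], direction = dir[keep],
             intensity = diff_intensity(profile, idx[keep]))
}

## the primary downward crossing: the one bracketing the largest first
## difference (generically the first-difference optimum's index)
primary_down_crossing <- function(profile, crossings) {
  down <- crossings[crossings$direction == "down", , drop = FALSE]
  if (!nrow(down)) return(NULL)
  down[which.max(profile$first_diff[down$index]), , drop = FALSE]
}

#' Export an intensity profile or percentile curve to CSV
#'
#' @param x An `intensity_profile` or `percentile_curve`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
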