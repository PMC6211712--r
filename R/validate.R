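## Validation battery: arithmetic perturbation robustness, trend comparison
## against a manual-segmentation surrogate, z-stack consistency, and
## distribution (histogram-reshaping) diagnostics.

#' Arithmetic perturbation of an image
#'
#' Adds a constant to, or multiplies by a factor, the intensity of every
#' valid pixel, clipping the result to \[0, 1\].  Validity flags are
#' unchanged.  A robust segmentation method's result should track such
#' transformations: the segmented mean of the perturbed image should equal
#' the transformed baseline mean.
#'
#' @param img A [raster_image()].
#' @param kind `"additive"` or `"multiplicative"`.
#' @param parameter The constant `c` (additive: `x + c`) or factor `f`
#'   (multiplicative: `x * f`).
#' @return A [raster_image()] with attribute `clipped_fraction`, the
#'   fraction of valid pixels whose value was altered by clipping; a
#'   warning is issued when it exceeds 1%.
#' @export
perturb <- function(img, kind = c("additive", "multiplicative"),
                    parameter) {
  stopifnot(inherits(img, "raster_image"))
  kind <- match.arg(kind)
  x <- img$intensity
  y <- x
  y[img$valid] <- if (kind == "additive") x[img$valid] + parameter
                  else x[img$valid] * parameter
  clipped <- mean(y[img$valid] < 0 | y[img$valid] > 1)
  y <- clip01(y)
  if (clipped > 0.01)
    warning(sprintf("perturbation clipped %.2f%% of valid pixels",
                    100 * clipped))
  out <- raster_image(y, img$valid)
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Perturbation robustness test of a segmentation method
#'
#' Segments the image, perturbs it, re-segments the perturbed image with
#' the *same* configuration — thresholds are recomputed on the perturbed
#' image, since e.g. percentile thresholds are image-relative, so this
#' probes the robustness of the method, not of frozen cutoffs — and
#' compares the observed segmented mean with the transformed expectation
#' (`baseline + c` or `baseline * f`).
#'
#' Two clipping fractions are reported: over all valid pixels (saturated
#' vessels necessarily clip under a positive shift) and over the pixels the
#' baseline segmentation retained, which is the set the expected-mean
#' arithmetic concerns; the robustness criterion requires the latter to be
#' under 1%.
#'
#' @param img A [raster_image()].
#' @param config A [seg_config()].
#' @param kind,parameter As in [perturb()].
#' @return An object of class `perturbation_report`: `kind`, `parameter`,
#'   `baseline_mean`, `expected_mean`, `observed_mean`,
#'   `relative_error_pct`, `clipped_fraction` (valid pixels),
#'   `clipped_fraction_retained` (baseline retained set).
#' @export
perturbation_test <- function(img, config = seg_config(),
                              kind = c("additive", "multiplicative"),
                              parameter) {
  kind <- match.arg(kind)
  base <- segment_image(img, config)
  pert <- suppressWarnings(perturb(img, kind, parameter))
  keep <- base$segmented$valid
  x0 <- img$intensity[keep]
  y0 <- if (kind == "additive") x0 + parameter else x0 * parameter
  clipped_roi <- mean(y0 < 0 | y0 > 1)
  res <- segment_image(pert, config)
  baseline <- base$stats$mean
  expected <- if (kind == "additive") baseline + parameter
              else baseline * parameter
  observed <- res$stats$mean
  structure(
    list(kind = kind, parameter = parameter,
         baseline_mean = baseline, expected_mean = expected,
         observed_mean = observed,
         relative_error_pct = abs(observed - expected) / expected * 100,
         clipped_fraction = attr(pert, "clipped_fraction"),
         clipped_fraction_retained = clipped_roi),
    class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat(sprintf(
    "<perturbation_report> %s %.4g: expected %.5g, observed %.5g (err %.3g%%)\n",
    x$kind, x$parameter, x$expected_mean, x$observed_mean,
    x$relative_error_pct))
  invisible(x)
}

#' Compare reference and machine segmentation trends
#'
#' Given one mean per image from a reference segmentation (e.g. the
#' ground-truth cytoplasm label, the package's manual-segmentation
#' surrogate) and from a machine method, computes the cosine similarity of
#' the two vectors (inner product over the product of norms: 1 for
#' parallel trends), the mean percentage offset, the standard deviations of
#' the two sets of means, and a two-sided paired t-test p-value.  A high
#' cosine similarity with a consistent offset indicates parallel trends —
#' the machine tracks the reference ranking even when biased.
#'
#' @param reference_means,machine_means Equal-length numeric vectors
#'   (length >= 2), neither all-zero.
#' @return An object of class `trend_comparison` with fields
#'   `reference_means`, `machine_means`, `cosine_similarity`,
#'   `mean_offset_pct`, `sd_reference`, `sd_machine`, `paired_t_p`.
#' @export
compare_trend <- function(reference_means, machine_means) {
  if (length(reference_means) != length(machine_means))
    stop("vectors must have equal length")
  if (length(reference_means) < 2L)
    stop("need at least two images to compare trends")
  if (anyNA(reference_means) || anyNA(machine_means))
    stop("means must not contain NA")
  nr <- sqrt(sum(reference_means^2))
  nm <- sqrt(sum(machine_means^2))
  if (nr == 0 || nm == 0)
    stop("undefined similarity: zero-norm vector")
  structure(
    list(reference_means = reference_means, machine_means = machine_means,
         cosine_similarity = sum(reference_means * machine_means) / (nr * nm),
         mean_offset_pct =
           mean((reference_means - machine_means) / reference_means) * 100,
         sd_reference = stats::sd(reference_means),
         sd_machine = stats::sd(machine_means),
         paired_t_p = stats::t.test(reference_means, machine_means,
                                    paired = TRUE)$p.value),
    class = "trend_comparison")
}

#' @export
print.trend_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<trend_comparison> n = %d: cosine %.4f, offset %.2f%%, ",
           "sd ref %.4g vs machine %.4g, paired t p = %.3g\n"),
    length(x$reference_means), x$cosine_similarity, x$mean_offset_pct,
    x$sd_reference, x$sd_machine, x$paired_t_p))
  invisible(x)
}

#' Consistency of segmentation across an ordered stack
#'
#' Adjacent slices of a z-stack image tissue a short optical step apart, so
#' their segmented statistics should change gradually; abrupt jumps flag a
#' method that is not robust across the stack.  Reports the per-pair
#' absolute changes in retained-pixel mean and count and their maxima.
#'
#' @param results An ordered list of `segmentation_result`s (length >= 2).
#' @return A list with `max_delta_mean`, `max_delta_n`, and `table` (per
#'   slice: mean, n, delta_mean, delta_n).
#' @export
stack_consistency <- function(results) {
  if (length(results) < 2L) stop("need at least two slices")
  means <- vapply(results, function(r) r$stats$mean, 0)
  ns <- vapply(results, function(r) as.numeric(r$stats$n), 0)
  dmean <- c(NA, abs(diff(means)))
  dn <- c(NA, abs(diff(ns)))
  list(max_delta_mean = max(dmean, na.rm = TRUE),
       max_delta_n = max(dn, na.rm = TRUE),
       table = data.frame(slice = seq_along(results), mean = means, n = ns,
                          delta_mean = dmean, delta_n = dn))
}

#' Distribution diagnostics: histogram reshaping by segmentation
#'
#' The raw tripartite image has a skewed intensity distribution; retaining
#' only the region of interest should reshape it toward an approximately
#' normal one.  Returns the moment skewness of the raw and segmented valid
#' pixels and 100-bin histograms of both for plotting or export.  With an
#' empty retained set the segmented diagnostics are `NA` (undefined).
#'
#' @param raw,segmented [raster_image()]s on the same grid.
#' @return A list with `skewness_raw`, `skewness_segmented`,
#'   `histogram_raw`, `histogram_segmented` (frequency vectors over the
#'   100 bins), `mids`.
#' @export
distribution_diagnostics <- function(raw, segmented) {
  stopifnot(inherits(raw, "raster_image"),
            inherits(segmented, "raster_image"))
  xr <- raw$intensity[raw$valid]
  if (!length(xr)) stop("raw image has no valid pixels")
  xs <- segmented$intensity[segmented$valid]
  edges <- seq(0, 1, length.out = N_BINS + 1L)
  hist_of <- function(x) {
    if (!length(x)) return(rep(NA_real_, N_BINS))
    tabulate(bin_index(x), nbins = N_BINS) / length(x)
  }
  list(skewness_raw = moment_skewness(xr),
       skewness_segmented = if (length(xs) > 2L) moment_skewness(xs)
                            else NA_real_,
       histogram_raw = hist_of(xr),
       histogram_segmented = hist_of(xs),
       mids = (edges[-(N_BINS + 1L)] + edges[-1L]) / 2)
}

#' Write raw-versus-segmented histograms as a PNG plot
#'
#' Renders the two 100-bin histograms from [distribution_diagnostics()]
#' side by side, annotated with the skewness pair, for visual supervision
#' of the histogram reshaping.
#'
#' @param diag A [distribution_diagnostics()] result.
#' @param path Output PNG path.
#' @param width,height Plot size in pixels.
#' @return `path`, invisibly.
#' @export
write_histogram_png <- function(diag, path, width = 900, height = 450) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::barplot(diag$histogram_raw, names.arg = NULL, border = NA,
                    col = "grey40", space = 0, xlab = "intensity bin",
                    ylab = "frequency",
                    main = sprintf("raw (skewness %.2f)", diag$skewness_raw))
  graphics::barplot(diag$histogram_segmented, names.arg = NULL, border = NA,
                    col = "steelblue", space = 0, xlab = "intensity bin",
                    ylab = "frequency",
                    main = sprintf("segmented (skewness %.2f)",
                                   diag$skewness_segmented))
  invisible(path)
}
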