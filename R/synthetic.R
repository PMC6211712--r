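## Seeded generator of tripartite strial-like images: a mid-intensity
## cell-layer band with spatially correlated texture, thin dim background
## margins, bright branching vessel ridges, and a zeroed gross-segmented
## edge band, with per-pixel ground-truth labels standing in for manual
## segmentation.

GT_LEVELS <- c("excluded", "background", "cytoplasm", "vessel")

#' Specification of a synthetic tripartite image
#'
#' Collects the generator parameters.  The defaults emulate confocal images
#' of the stria vascularis intermediate-cell layer: a dim, homogeneous
#' background (mean 0.05), a heterogeneous mid-intensity cytoplasm (mean
#' 0.45 with spatially correlated texture), and bright, near-saturated
#' branching vessels (mean 0.95), with one image-edge band zeroed to mimic
#' gross manual segmentation.  `brightness_scale` multiplies all
#' intensities (then clips to \[0, 1\]) for dim/medium/bright sweeps.
#'
#' @param width,height Image size in pixels (defaults 256 x 256).
#' @param seed Integer seed; the generator is a pure function of the spec
#'   including the seed.
#' @param background_mean,background_sd Background intensity distribution
#'   (defaults 0.05, 0.01).
#' @param cytoplasm_mean,cytoplasm_sd Cytoplasm intensity distribution
#'   (defaults 0.45, 0.08).
#' @param cytoplasm_texture_scale Spatial correlation length of the
#'   cytoplasm texture, in pixels (default 4).
#' @param vessel_count,vessel_width,vessel_mean,vessel_sd Vessel ridges:
#'   how many random-walk ridges (default 3), their width in pixels
#'   (default 8), and their intensity distribution (defaults 0.95, 0.02).
#' @param gross_excluded_fraction Fraction of the image width zeroed as a
#'   gross-segmented edge band (default 0.1).
#' @param brightness_scale Global intensity multiplier (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(width = 256L, height = 256L, seed = 1L,
                           background_mean = 0.05, background_sd = 0.01,
                           cytoplasm_mean = 0.45, cytoplasm_sd = 0.08,
                           cytoplasm_texture_scale = 4,
                           vessel_count = 3L, vessel_width = 8L,
                           vessel_mean = 0.95, vessel_sd = 0.02,
                           gross_excluded_fraction = 0.1,
                           brightness_scale = 1.0) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               seed = as.integer(seed),
               background_mean = background_mean,
               background_sd = background_sd,
               cytoplasm_mean = cytoplasm_mean, cytoplasm_sd = cytoplasm_sd,
               cytoplasm_texture_scale = cytoplasm_texture_scale,
               vessel_count = as.integer(vessel_count),
               vessel_width = as.integer(vessel_width),
               vessel_mean = vessel_mean, vessel_sd = vessel_sd,
               gross_excluded_fraction = gross_excluded_fraction,
               brightness_scale = brightness_scale)
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  if (spec$width < 32L || spec$height < 32L)
    stop("synthetic images must be at least 32x32")
  if (!(spec$background_mean < spec$cytoplasm_mean &&
        spec$cytoplasm_mean < spec$vessel_mean))
    stop("region means must be ordered: background < cytoplasm < vessel")
  if (spec$gross_excluded_fraction < 0 || spec$gross_excluded_fraction > 0.5)
    stop("'gross_excluded_fraction' must be in [0, 0.5]")
  if (spec$brightness_scale <= 0) stop("'brightness_scale' must be positive")
  if (spec$vessel_count < 0L || spec$vessel_width < 1L)
    stop("invalid vessel parameters")
  invisible(spec)
}

#' Ground-truth label grid
#'
#' Integer matrix of per-pixel region labels emitted by the synthetic
#' generator, standing in for manual segmentation: 0 = excluded,
#' 1 = background, 2 = cytoplasm, 3 = vessel.
#'
#' @param labels Integer matrix with values 0..3.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(labels) {
  stopifnot(is.matrix(labels), all(labels %in% 0:3))
  structure(labels, class = "ground_truth", levels = GT_LEVELS)
}

#' Logical mask of a ground-truth region
#'
#' @param gt A [ground_truth()].
#' @param label One of `"excluded"`, `"background"`, `"cytoplasm"`,
#'   `"vessel"`.
#' @return Logical matrix.
#' @export
gt_mask <- function(gt, label = GT_LEVELS) {
  label <- match.arg(label)
  unclass(gt) == (match(label, GT_LEVELS) - 1L)
}

#' @export
print.ground_truth <- function(x, ...) {
  counts <- tabulate(as.vector(unclass(x)) + 1L, 4L)
  cat("<ground_truth> ", paste(sprintf("%s: %d", GT_LEVELS, counts),
                               collapse = ", "), "\n")
  invisible(x)
}

## evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## ---- geometry -------------------------------------------------------------
## Margin depths and vessel paths are drawn separately from the pixel noise
## so that a z-stack can keep the geometry (from the base seed) while
## refreshing the noise per slice.

## wavy background margin depths per column; each margin ~2% of the height
synth_margins <- function(spec) {
  w <- spec$width; h <- spec$height
  base <- 0.02 * h
  amp <- 0.012 * h
  ph <- stats::runif(2, 0, 2 * pi)
  cols <- seq_len(w)
  top <- pmax(1, round(base + amp * sin(2 * pi * cols / w * 2 + ph[1])))
  bot <- pmax(1, round(base + amp * sin(2 * pi * cols / w * 3 + ph[2])))
  list(top = top, bottom = bot)
}

## vessels as biased random walks spanning ~70% of the cell-layer band,
## with one bifurcation per walk with probability 0.5
synth_vessel_paths <- function(spec) {
  w <- spec$width; h <- spec$height
  paths <- list()
  for (v in seq_len(spec$vessel_count)) {
    len <- round(0.7 * h)
    r0 <- sample.int(max(1L, h - len), 1L) + round(0.05 * h)
    rows <- r0:min(h, r0 + len - 1L)
    drift <- stats::runif(1, -0.6, 0.6)
    col0 <- stats::runif(1, 0.15 * w, 0.85 * w)
    cols <- col0 + cumsum(drift + stats::rnorm(length(rows), 0, 0.9))
    paths[[length(paths) + 1L]] <- list(rows = rows, cols = cols)
    if (stats::runif(1) < 0.5) {
      bi <- sample.int(length(rows) - 2L, 1L) + 1L
      rows2 <- rows[bi:length(rows)]
      cols2 <- cols[bi] +
        cumsum(-drift + stats::rnorm(length(rows2), 0, 0.9))
      paths[[length(paths) + 1L]] <- list(rows = rows2, cols = cols2)
    }
  }
  paths
}

synth_geometry <- function(spec) {
  list(margins = synth_margins(spec), vessels = synth_vessel_paths(spec))
}

## spatially correlated standard field: white noise box-smoothed over the
## texture scale then re-standardized (generated on a padded grid so the
## smoothing has no border effects)
correlated_field <- function(h, w, scale) {
  k <- max(1L, 2L * floor(scale / 2) + 1L)
  p <- (k - 1L) %/% 2L
  z <- matrix(stats::rnorm((h + 2L * p) * (w + 2L * p)), h + 2L * p)
  if (k > 1L) z <- window_sum(z, k)
  z <- z[(p + 1L):(p + h), (p + 1L):(p + w), drop = FALSE]
  (z - mean(z)) / stats::sd(as.vector(z))
}

## render labels + intensities from a geometry (RNG state supplies noise)
synth_render <- function(spec, geom, col_shift = 0) {
  w <- spec$width; h <- spec$height
  lab <- matrix(2L, h, w)  # cytoplasm
  for (j in seq_len(w)) {
    lab[seq_len(geom$margins$top[j]), j] <- 1L
    lab[(h - geom$margins$bottom[j] + 1L):h, j] <- 1L
  }
  half <- spec$vessel_width %/% 2L
  for (p in geom$vessels) {
    cols <- round(p$cols + col_shift)
    for (i in seq_along(p$rows)) {
      r <- p$rows[i]
      c1 <- max(1L, cols[i] - half)
      c2 <- min(w, cols[i] + (spec$vessel_width - 1L - half))
      if (c1 <= c2) {
        span <- c1:c2
        span <- span[lab[r, span] == 2L]  # vessels live in the cell layer
        lab[r, span] <- 3L
      }
    }
  }
  n_ex <- round(spec$gross_excluded_fraction * w)
  if (n_ex > 0L) lab[, seq_len(n_ex)] <- 0L

  x <- matrix(0, h, w)
  bg <- lab == 1L
  vs <- lab == 3L
  cy <- lab == 2L
  x[bg] <- stats::rnorm(sum(bg), spec$background_mean, spec$background_sd)
  x[vs] <- stats::rnorm(sum(vs), spec$vessel_mean, spec$vessel_sd)
  field <- correlated_field(h, w, spec$cytoplasm_texture_scale)
  x[cy] <- spec$cytoplasm_mean + spec$cytoplasm_sd * field[cy]
  x <- clip01(x * spec$brightness_scale)
  x[lab == 0L] <- 0
  list(image = raster_image(x, lab != 0L), truth = ground_truth(lab))
}

#' Generate a synthetic tripartite image with ground truth
#'
#' Draws background margins, vessel ridges, and pixel noise from a RNG
#' stream seeded with `spec$seed`; the same spec always yields a
#' bit-identical image.  See [synthetic_spec()] for what the image
#' emulates.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `image` (a [raster_image()]; the gross-excluded band
#'   has intensity 0 and `valid = FALSE`) and `truth` (a [ground_truth()]).
#' @export
#' @examples
#' gen <- generate_image(synthetic_spec(seed = 42))
#' image_stats(gen$image)
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  with_seed(spec$seed, {
    geom <- synth_geometry(spec)
    synth_render(spec, geom)
  })
}

#' Generate a synthetic z-stack
#'
#' Slices share the geometry of the base seed; slice `k` (1-based) shifts
#' the cytoplasm mean by `(k - 1) * drift_per_slice` intensity units,
#' drifts the vessel paths laterally by a cumulative random walk of
#' `drift_per_slice / 0.005` pixels per slice, and draws fresh pixel noise
#' from a seed derived as `spec$seed + k`.  With `drift_per_slice = 0`
#' adjacent slices differ only by the seed-derived noise.
#'
#' @param spec A [synthetic_spec()].
#' @param n_slices Number of slices, >= 2.
#' @param drift_per_slice Per-slice cytoplasm-mean drift in intensity units
#'   (default 0.005).
#' @return A list of `n_slices` elements, each as [generate_image()].
#' @export
generate_stack <- function(spec, n_slices, drift_per_slice = 0.005) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  if (n_slices < 2L) stop("'n_slices' must be at least 2")
  geom <- with_seed(spec$seed, synth_geometry(spec))
  px_per_slice <- drift_per_slice / 0.005
  shift <- 0
  out <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    spec_k <- spec
    spec_k$cytoplasm_mean <- spec$cytoplasm_mean +
      (k - 1L) * drift_per_slice
    out[[k]] <- with_seed(spec$seed + k, {
      if (px_per_slice > 0)
        shift <- shift + stats::rnorm(1, 0, px_per_slice)
      synth_render(spec_k, geom, col_shift = shift)
    })
  }
  out
}

#' Serialize a synthetic spec to the flat key=value config format
#'
#' @param spec A [synthetic_spec()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  writeLines(sprintf("%s=%s", names(spec),
                     vapply(spec, format, "", digits = 15)), path)
  invisible(path)
}

#' Read a synthetic spec from a flat key=value file
#'
#' @param path File written by [write_spec()] (or by hand).
#' @return A [synthetic_spec()].
#' @export
read_spec <- function(path) {
  kv <- read_keyvalue(path)
  args <- lapply(kv, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  do.call(synthetic_spec, args[names(args) %in% names(formals(synthetic_spec))])
}
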