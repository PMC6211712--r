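## Readers and writers for single-channel grayscale images.  TIFF (8/16-bit)
## and PNG are read through the tiff and png packages; multi-page TIFFs are
## read as z-stacks in page order.

single_channel <- function(a, path) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3L] == 1L) return(a[, , 1L])
    ## grayscale saved with identical channels is accepted
    ch <- lapply(seq_len(min(dim(a)[3L], 3L)), function(k) a[, , k])
    if (all(vapply(ch[-1L], function(m) identical(m, ch[[1L]]), TRUE)))
      return(ch[[1L]])
    stop("multi-channel image not supported: ", path)
  }
  stop("unsupported image layout in ", path)
}

read_tiff_page <- function(page, path, zero_invalid) {
  m <- single_channel(page, path)
  bits <- attr(page, "bits.per.sample") %||% 16L
  if (is.double(m) && max(m) <= 1 && any(m != round(m))) {
    ## already normalized by the reader
    valid <- if (zero_invalid) m != 0 else NULL
    return(raster_image(clip01(m), valid))
  }
  normalize_image(m, bit_depth = if (bits <= 8) 8L else 16L,
                  zero_invalid = zero_invalid)
}

#' Read a grayscale image file
#'
#' Reads a single-channel 8- or 16-bit grayscale TIFF or PNG into a
#' [raster_image()], normalizing intensities to \[0, 1\].  By default,
#' exact-zero pixels are flagged invalid (gross segmentation zeroes the
#' regions it removes).  Multi-channel files are rejected unless all
#' channels are identical.
#'
#' @param path File path (`.tif`, `.tiff`, `.png`).
#' @param zero_invalid Treat exact zeros as gross-segmented (invalid)?
#'   Default `TRUE`.
#' @return A [raster_image()].
#' @export
read_image <- function(path, zero_invalid = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    read_tiff_page(a, path, zero_invalid)
  } else if (ext == "png") {
    a <- png::readPNG(path)
    m <- single_channel(a, path)
    valid <- if (zero_invalid) m != 0 else NULL
    raster_image(clip01(m), valid)
  } else stop("unsupported image format: .", ext)
}

#' Read a multi-page TIFF as a z-stack
#'
#' @param path TIFF file path.
#' @param zero_invalid As in [read_image()].
#' @return A list of [raster_image()]s in page order.
#' @export
read_stack <- function(path, zero_invalid = TRUE) {
  pages <- tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = TRUE)
  lapply(pages, read_tiff_page, path = path, zero_invalid = zero_invalid)
}

#' Write a segmented image as 16-bit TIFF
#'
#' Excluded (invalid) pixels are written as 0, matching the convention that
#' gross segmentation blacks out removed regions.
#'
#' @param img A [raster_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmented <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  m <- img$intensity
  m[!img$valid] <- 0
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a mask image as 32-bit TIFF
#'
#' Mask values (e.g. local Moran coefficients) are unbounded, but the TIFF
#' writer stores \[0, 1\] data, so the values are affinely rescaled to
#' \[0, 1\] and the original range is recorded in a plain-text sidecar file
#' `<path>.range.txt` (two numbers: min and max).  Invalid pixels are
#' written as 0.
#'
#' @param mask A [mask_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_image"))
  v <- mask$value[mask$valid]
  lo <- min(v); hi <- max(v)
  m <- matrix(0, nrow(mask$value), ncol(mask$value))
  if (hi > lo) m[mask$valid] <- (v - lo) / (hi - lo)
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  writeLines(format(c(lo, hi), digits = 15), paste0(path, ".range.txt"))
  invisible(path)
}

#' Write ground-truth labels as an 8-bit label TIFF
#'
#' Label codes: 0 = excluded, 1 = background, 2 = cytoplasm, 3 = vessel.
#'
#' @param gt A [ground_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  tiff::writeTIFF(unclass(gt) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read ground-truth labels written by [write_labels()]
#'
#' @param path Label TIFF path.
#' @return A [ground_truth()].
#' @export
read_labels <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  ground_truth(matrix(as.integer(m), nrow(m), ncol(m)))
}

## flat key=value file -> named character list (comments with # allowed)
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  vals <- lapply(kv, function(p) trimws(paste(p[-1L], collapse = "=")))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
  vals
}
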