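# Independent brute-force oracles, deliberately written as plain double loops
# over pixel neighborhoods so they share no code with the implementation.

oracle_focal_mean <- function(img, k) {
  h <- (k - 1) %/% 2
  nr <- nrow(img$intensity); nc <- ncol(img$intensity)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i <= h || j <= h || i > nr - h || j > nc - h) next
    if (!img$valid[i, j]) next
    acc <- 0; cnt <- 0
    for (di in -h:h) for (dj in -h:h) {
      if (img$valid[i + di, j + dj]) {
        acc <- acc + img$intensity[i + di, j + dj]
        cnt <- cnt + 1
      }
    }
    if (cnt > 0) out[i, j] <- acc / cnt
  }
  out
}

oracle_local_moran <- function(img, k) {
  h <- (k - 1) %/% 2
  x <- img$intensity[img$valid]
  mu <- mean(x)
  m2 <- sum((x - mu)^2) / length(x)
  nr <- nrow(img$intensity); nc <- ncol(img$intensity)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i <= h || j <= h || i > nr - h || j > nc - h) next
    if (!img$valid[i, j]) next
    acc <- 0; cnt <- 0
    for (di in -h:h) for (dj in -h:h) {
      if (di == 0 && dj == 0) next
      if (img$valid[i + di, j + dj]) {
        acc <- acc + (img$intensity[i + di, j + dj] - mu)
        cnt <- cnt + 1
      }
    }
    if (cnt > 0)
      out[i, j] <- (img$intensity[i, j] - mu) / m2 * acc / cnt
  }
  out
}

# cumulative integrated-intensity vector computed via hist() rather than
# tabulate, as an independent route
oracle_integrated <- function(x) {
  edges <- seq(0, 1, by = 0.01)
  # right = FALSE gives bins [e_k, e_{k+1}); include.lowest closes the last
  counts <- hist(x, breaks = edges, include.lowest = TRUE, right = FALSE,
                 plot = FALSE)$counts
  counts <- counts / length(x)
  mids <- edges[-101] + 0.005
  cumsum(counts * mids)
}

# random raster image with a sprinkling of invalid pixels
random_image <- function(nr, nc, seed, invalid_frac = 0.1) {
  set.seed(seed)
  val <- matrix(runif(nr * nc, 0.01, 0.99), nr, nc)
  ok <- matrix(runif(nr * nc) > invalid_frac, nr, nc)
  raster_image(val, ok)
}

# fabricate an intensity_profile with a prescribed first-difference vector,
# for unit tests of the landmark-scanning logic
fake_profile_fd <- function(fd) {
  n <- length(fd) + 1
  mids <- seq_len(n) / n - 0.5 / n
  structure(list(bin_edges = seq(0, 1, length.out = n + 1), mids = mids,
                 frequency = rep(1 / n, n),
                 integrated = cumsum(c(0, fd)), first_diff = fd,
                 second_diff = diff(fd), n = 1000L),
            class = "intensity_profile")
}

fake_profile_sd <- function(sd2) {
  fd <- cumsum(c(0, sd2))
  fake_profile_fd(fd)
}

moment_skew <- function(x) {
  d <- x - mean(x)
  mean(d^3) / mean(d^2)^1.5
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
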