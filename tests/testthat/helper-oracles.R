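# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (loops, direct sums, quadrature)
# and never call the implementation paths they check.

# all-pairs windowed nearest neighbour (square per-axis window)
oracle_nn <- function(qx, qy, rx, ry, window) {
  out <- rep(NA_real_, length(qx))
  for (i in seq_along(qx)) {
    best <- Inf
    for (j in seq_along(rx)) {
      dx <- abs(rx[j] - qx[i])
      dy <- abs(ry[j] - qy[i])
      if (dx <= window && dy <= window) {
        d <- sqrt(dx^2 + dy^2)
        if (d < best) best <- d
      }
    }
    if (is.finite(best)) out[i] <- best
  }
  out
}

# direct discrete Gaussian convolution with replicated borders
oracle_gauss_conv <- function(m, sigma_px, radius) {
  off <- -radius:radius
  k <- outer(off, off, function(a, b) exp(-(a^2 + b^2) / (2 * sigma_px^2)))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in off) for (b in off) {
      ii <- min(max(i + a, 1), nr)
      jj <- min(max(j + b, 1), nc)
      acc <- acc + m[ii, jj] * k[a + radius + 1, b + radius + 1]
    }
    out[i, j] <- acc
  }
  out
}

# grayscale opening by the documented ball structuring element
# (depth at rim = intensity range), explicit nested loops
oracle_ball_opening <- function(m, radius, depth) {
  off <- expand.grid(di = -radius:radius, dj = -radius:radius)
  off <- off[off$di^2 + off$dj^2 <= radius^2, ]
  z <- (sqrt(radius^2 - (off$di^2 + off$dj^2)) - radius) / radius * depth
  nr <- nrow(m); nc <- ncol(m)
  at <- function(mm, i, j) mm[min(max(i, 1), nr), min(max(j, 1), nc)]
  ero <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ero[i, j] <- min(mapply(function(a, b, zz) at(m, i + a, j + b) - zz,
                            off$di, off$dj, z))
  }
  dil <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dil[i, j] <- max(mapply(function(a, b, zz) at(ero, i + a, j + b) + zz,
                            off$di, off$dj, z))
  }
  dil
}

# paint filled disks onto a blank raster; returns image matrix and centres
make_disk_image <- function(nr, nc, centres_px, radius_px, value = 100) {
  m <- matrix(0, nr, nc)
  for (k in seq_len(nrow(centres_px))) {
    ci <- centres_px[k, 1]; cj <- centres_px[k, 2]; r <- radius_px[k]
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- value
    }
  }
  m
}

# numerical quadrature of r * DD(r) (mean of the mixture distance law),
# independent of dd_cdf's grid
oracle_mixture_mean <- function(params) {
  f <- function(r) r * punctaprox::dd_density(r, params)
  amps <- as.numeric(params[c("a1", "a2")])
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value / sum(amps)
}

# random valid mixture parameter draws for property tests
random_mixture <- function() {
  punctaprox::mixture_params(
    a1 = runif(1, 0.2, 2), a2 = runif(1, 0.2, 2),
    mu1 = runif(1, 0, 0.1), mu2 = runif(1, 0.05, 0.4),
    sigma1 = runif(1, 0.005, 0.05), sigma2 = runif(1, 0.01, 0.08))
}
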