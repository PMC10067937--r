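#' Extract an intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation at pixel-size spacing along
#' the segment from `p0` to `p1` (µm coordinates) and, for `width_px > 1`,
#' averages over perpendicular offsets at 1 px spacing centred on the line
#' — the usual wide-line profile of image-analysis software.
#'
#' @param image An [sr_image].
#' @param p0,p1 Segment endpoints, numeric `c(x_um, y_um)`, inside the image.
#' @param width_px Integer line width in pixels (>= 1).
#' @return A tibble with columns `position_um` (distance along the segment,
#'   starting at 0) and `intensity`.
#' @export
extract_line_profile <- function(image, p0, p1, width_px = 1) {
  assert_sr_image(image)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 2 || length(p1) != 2) {
    stop("`p0` and `p1` must be length-2 (x_um, y_um)", call. = FALSE)
  }
  ext <- field_extent(image)
  for (p in list(p0, p1)) {
    if (p[1] < 0 || p[1] > ext[1] || p[2] < 0 || p[2] > ext[2]) {
      stop("segment endpoints must lie inside the image", call. = FALSE)
    }
  }
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) stop("zero-length segment", call. = FALSE)
  if (width_px < 1 || width_px != round(width_px)) {
    stop("`width_px` must be an integer >= 1", call. = FALSE)
  }
  px <- image$pixel_size_um
  n <- max(2L, as.integer(floor(L / px + sqrt(.Machine$double.eps))) + 1L)
  t <- seq(0, L, length.out = n)
  ux <- (p1 - p0) / L                      # unit vector along the line
  un <- c(-ux[2], ux[1])                   # unit normal
  offsets <- (seq_len(width_px) - (width_px + 1) / 2) * px
  acc <- numeric(n)
  for (o in offsets) {
    xs <- p0[1] + t * ux[1] + o * un[1]
    ys <- p0[2] + t * ux[2] + o * un[2]
    acc <- acc + bilinear_at(image, xs, ys)
  }
  tibble::tibble(position_um = t, intensity = acc / width_px)
}

# bilinear interpolation at physical coordinates; replicate beyond borders
bilinear_at <- function(image, x_um, y_um) {
  px <- image$pixel_size_um
  m <- image$data
  nr <- nrow(m); nc <- ncol(m)
  # continuous pixel coordinates: pixel j is centred at (j - 0.5)
  cx <- x_um / px - 0.5
  cy <- y_um / px - 0.5
  j0 <- floor(cx); i0 <- floor(cy)
  fx <- cx - j0; fy <- cy - i0
  cl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  j0c <- cl(j0 + 1, 1, nc); j1c <- cl(j0 + 2, 1, nc)
  i0c <- cl(i0 + 1, 1, nr); i1c <- cl(i0 + 2, 1, nr)
  m[cbind(i0c, j0c)] * (1 - fx) * (1 - fy) +
    m[cbind(i0c, j1c)] * fx * (1 - fy) +
    m[cbind(i1c, j0c)] * (1 - fx) * fy +
    m[cbind(i1c, j1c)] * fx * fy
}

#' Gaussian peak fit and full width at half maximum
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - centre)^2 / (2 sigma^2))`
#' to a line profile; the width is reported as
#' `fwhm = 2 * sqrt(2 * log(2)) * sigma`. A constant offset term is included
#' because junction profiles sit on non-zero background; fitting without it
#' biases the width.
#'
#' @param profile A tibble with `position_um` and `intensity` columns (as
#'   from [extract_line_profile()]), with >= 5 samples and a detectable
#'   peak.
#' @return An object of class `gaussian_fit`: list with `amplitude`,
#'   `centre_um`, `sigma_um`, `offset`, `fwhm_um`, `converged`,
#'   `residual_ss`.
#' @export
gaussian_fwhm <- function(profile) {
  x <- profile$position_um
  y <- profile$intensity
  if (length(x) < 5) stop("profile needs >= 5 samples", call. = FALSE)
  if (any(diff(x) <= 0)) stop("positions must be strictly increasing", call. = FALSE)
  if (diff(range(y)) == 0) stop("flat profile: no peak to fit", call. = FALSE)
  off0 <- min(y)
  amp0 <- max(y) - off0
  ctr0 <- x[which.max(y)]
  # half-max crossing span as a starting width; fall back to a span fraction
  above <- which(y - off0 >= amp0 / 2)
  sig0 <- if (length(above) >= 2) {
    max((x[max(above)] - x[min(above)]) / 2.355, diff(range(x)) / 50)
  } else {
    diff(range(x)) / 10
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(amp = amp0, ctr = ctr0, sig = sig0, off = off0),
      lower = c(0, min(x), 1e-6, -Inf),
      upper = c(Inf, max(x), diff(range(x)) * 2, Inf),
      fn = function(p) p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4] - y,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) stop("Gaussian fit failed to evaluate", call. = FALSE)
  p <- fit$par
  structure(
    list(amplitude = unname(p[1]), centre_um = unname(p[2]),
         sigma_um = unname(p[3]), offset = unname(p[4]),
         fwhm_um = 2 * sqrt(2 * log(2)) * unname(p[3]),
         converged = fit$info %in% 1:4,
         residual_ss = sum(fit$fvec^2)),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_fit> fwhm = %.4g um (sigma %.4g um, centre %.4g um)%s\n",
    x$fwhm_um, x$sigma_um, x$centre_um,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "centre_um", "sigma_um", "offset", "fwhm_um"),
    estimate = c(x$amplitude, x$centre_um, x$sigma_um, x$offset, x$fwhm_um)
  )
}

#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(fwhm_um = x$fwhm_um, sigma_um = x$sigma_um,
                 residual_ss = x$residual_ss, converged = x$converged)
}

#' Coefficient of variance of a line profile
#'
#' Sample standard deviation divided by the mean of the trace, optionally
#' after dividing the trace by its minimum (`normalise = "min"`, the
#' default, matching the convention of normalising each trace to its
#' minimum before computing the statistic). Higher values indicate more
#' organised, higher-contrast staining; a constant trace gives 0.
#'
#' @param profile A tibble with an `intensity` column, or a numeric vector.
#' @param normalise `"min"` or `"none"`.
#' @return A single non-negative number.
#' @export
#' @examples
#' profile_cov(c(2, 4))           # 0.4714
profile_cov <- function(profile, normalise = c("min", "none")) {
  normalise <- match.arg(normalise)
  y <- if (is.data.frame(profile)) profile$intensity else as.numeric(profile)
  if (length(y) < 2) stop("profile needs >= 2 samples", call. = FALSE)
  if (normalise == "min") {
    if (min(y) <= 0) {
      stop(paste("trace minimum is not positive; offset the trace or use",
                 'normalise = "none"'), call. = FALSE)
    }
    y <- y / min(y)
  }
  if (mean(y) == 0) stop("zero-mean trace has no defined CoV", call. = FALSE)
  stats::sd(y) / mean(y)
}

#' Derive a junction mask from a reference channel
#'
#' Smooths the image, thresholds it with Otsu's method and dilates the
#' foreground — the standard way of defining junctional regions from a
#' junction-marker channel (e.g. PECAM1) before measuring another channel
#' inside them.
#'
#' @param image An [sr_image] of the junction-marker channel.
#' @param smooth_sigma_um Gaussian smoothing sigma (µm).
#' @param dilation_um Dilation radius (µm, >= 0).
#' @return A raster [region_mask] of kind `"junctional"`. An empty
#'   foreground yields an empty mask with a warning.
#' @export
mask_from_channel <- function(image, smooth_sigma_um = 0.1, dilation_um = 0.2) {
  assert_sr_image(image)
  sm <- gaussian_blur(image, smooth_sigma_um)
  m <- sm$data
  if (diff(range(m)) == 0) {
    warning("uniform image: empty junction mask")
    return(region_mask(raster = matrix(FALSE, nrow(m), ncol(m)),
                       kind = "junctional",
                       pixel_size_um = image$pixel_size_um))
  }
  thr <- EBImage::otsu(m, range = range(m), levels = 256)
  fg <- m > thr
  if (!any(fg)) {
    warning("empty foreground: empty junction mask")
  } else if (dilation_um > 0) {
    r_px <- max(1L, round(dilation_um / image$pixel_size_um))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    fg <- EBImage::dilate(fg * 1, brush) > 0
  }
  region_mask(raster = matrix(as.logical(fg), nrow(m), ncol(m)),
              kind = "junctional", pixel_size_um = image$pixel_size_um)
}

#' Background-normalised junctional intensity
#'
#' Mean signal intensity inside the junction mask divided by the mean
#' inside the background mask, i.e. intensity in arbitrary fluorescence
#' units normalised to the background. Invariant under global gain changes.
#'
#' @param signal An [sr_image] of the channel to quantify.
#' @param junction_mask,background_mask Raster [region_mask]s (or logical
#'   matrices) aligned with `signal`; they must be non-empty and
#'   non-overlapping.
#' @return The intensity ratio (single number).
#' @export
normalised_junctional_intensity <- function(signal, junction_mask,
                                            background_mask) {
  assert_sr_image(signal, "signal")
  jm <- mask_raster(junction_mask, signal)
  bm <- mask_raster(background_mask, signal)
  if (!any(jm) || !any(bm)) stop("masks must be non-empty", call. = FALSE)
  if (any(jm & bm)) stop("masks must not overlap", call. = FALSE)
  bg <- mean(signal$data[bm])
  if (bg == 0) stop("background mean is zero", call. = FALSE)
  mean(signal$data[jm]) / bg
}

mask_raster <- function(mask, image) {
  if (inherits(mask, "region_mask")) {
    if (is.null(mask$raster)) {
      # rasterise a polygon mask on the image grid
      nr <- nrow(image$data); nc <- ncol(image$data)
      xs <- px_centre_x(rep(seq_len(nc), each = nr), image$pixel_size_um)
      ys <- px_centre_y(rep(seq_len(nr), nc), image$pixel_size_um)
      return(matrix(point_in_polygon(xs, ys, mask$polygon), nr, nc))
    }
    mask <- mask$raster
  }
  m <- mask != 0
  if (!all(dim(m) == dim(image$data))) {
    stop("mask shape differs from image", call. = FALSE)
  }
  m
}

#' Boltzmann sigmoid fit for pressure-response curves
#'
#' Least-squares fit of `y = A2 + (A1 - A2) / (1 + exp((x - x0) / dx))`,
#' where `A1` and `A2` are the lower and upper asymptotes (the minimum and
#' maximum of the sigmoid), `x0` the midpoint (at which
#' `y = (A1 + A2) / 2` for any slope) and `dx` the slope factor in the
#' units of `x` (e.g. mmHg for pressure steps).
#'
#' The parameterisation is two-fold degenerate — swapping `A1` with `A2`
#' and negating `dx` leaves the curve unchanged — so fits are reported in
#' the canonical form `A1 <= A2`; the sign of `dx` then encodes the
#' orientation (`dx > 0` for responses rising with `x`, `dx < 0` for
#' falling ones).
#'
#' @param x Stimulus values (>= 5 points spanning the transition).
#' @param y Responses, same length.
#' @return An object of class `boltzmann_fit`: list with `A1`, `A2`, `x0`,
#'   `dx`, `converged`, `residual_ss` and a `predict` function.
#' @export
#' @examples
#' x <- seq(0, 105, by = 15)
#' y <- 1 / (1 + exp((50 - x) / 10))     # rising sigmoid
#' boltzmann_fit(x, y)$x0
boltzmann_fit <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 5) stop("need >= 5 points", call. = FALSE)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (diff(range(y)) == 0) stop("flat response: no transition to fit", call. = FALSE)
  k <- max(2L, floor(length(x) / 4))
  A1_0 <- mean(y[seq_len(k)])                       # low-x asymptote
  A2_0 <- mean(y[seq(length(y) - k + 1, length(y))])
  x0_0 <- stats::approx(y, x, xout = (A1_0 + A2_0) / 2, ties = mean)$y
  if (!is.finite(x0_0)) x0_0 <- stats::median(x)
  # with A1_0/A2_0 read off the low- and high-x ends, a positive slope
  # factor starts on the data's branch for either orientation
  dx_0 <- diff(range(x)) / 10
  model <- function(p, x) p[2] + (p[1] - p[2]) / (1 + exp((x - p[3]) / p[4]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A1 = A1_0, A2 = A2_0, x0 = x0_0, dx = dx_0),
      fn = function(p) model(p, x) - y,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stop("Boltzmann fit failed to evaluate", call. = FALSE)
  p <- unname(fit$par)
  if (p[1] > p[2]) p <- c(p[2], p[1], p[3], -p[4])  # canonical form A1 <= A2
  structure(
    list(A1 = p[1], A2 = p[2], x0 = p[3], dx = p[4],
         converged = fit$info %in% 1:4,
         residual_ss = sum(fit$fvec^2),
         predict = function(xnew) unname(model(p, xnew))),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> A1 = %.4g, A2 = %.4g, x0 = %.4g, dx = %.4g%s\n",
    x$A1, x$A2, x$x0, x$dx, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(term = c("A1", "A2", "x0", "dx"),
                 estimate = c(x$A1, x$A2, x$x0, x$dx))
}

#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(x0 = x$x0, dx = x$dx, residual_ss = x$residual_ss,
                 converged = x$converged)
}
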