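ramp_image <- function(nr, nc, px) {
  # intensity equal to physical x coordinate: bilinear interpolation is exact
  m <- matrix(rep((seq_len(nc) - 0.5) * px, each = nr), nr, nc)
  sr_image(m, pixel_size_um = px)
}

test_that("line profiles interpolate bilinearly in physical coordinates", {
  px <- 0.1
  flat <- sr_image(matrix(4, 20, 20), pixel_size_um = px)
  prof <- extract_line_profile(flat, c(0.2, 1), c(1.8, 1))
  expect_true(all(prof$intensity == 4))
  expect_equal(prof$position_um[1], 0)
  expect_true(all(diff(prof$position_um) > 0))

  # axis-aligned line through pixel-centre row: exact pixel values
  m <- matrix(seq_len(400), 20, 20)
  img <- sr_image(m, pixel_size_um = px)
  y_row7 <- (7 - 0.5) * px
  prof <- extract_line_profile(img, c(0.05, y_row7), c(1.95, y_row7))
  expect_equal(prof$intensity, m[7, 1:20], tolerance = 1e-12)

  # diagonal line on a linear ramp: matches the analytic ramp
  rimg <- ramp_image(30, 30, px)
  p0 <- c(0.5, 0.5); p1 <- c(2.5, 2.2)
  prof <- extract_line_profile(rimg, p0, p1)
  t <- prof$position_um / sqrt(sum((p1 - p0)^2))
  expect_equal(prof$intensity, p0[1] + t * (p1[1] - p0[1]), tolerance = 1e-9)

  expect_error(extract_line_profile(flat, c(1, 1), c(1, 1)), "zero-length")
  expect_error(extract_line_profile(flat, c(-1, 0), c(1, 1)), "inside")
})

test_that("Gaussian peak fits recover the FWHM identity exactly", {
  x <- seq(0, 2, by = 0.01)
  sigma <- 0.1
  prof <- tibble::tibble(position_um = x,
                         intensity = 3 + 10 * exp(-(x - 1)^2 / (2 * sigma^2)))
  fit <- gaussian_fwhm(prof)
  expect_true(fit$converged)
  expect_equal(fit$fwhm_um, 2 * sqrt(2 * log(2)) * sigma, tolerance = 1e-6)
  expect_equal(fit$fwhm_um / fit$sigma_um, 2 * sqrt(2 * log(2)))
  expect_equal(fit$offset, 3, tolerance = 1e-6)

  flat <- tibble::tibble(position_um = x, intensity = rep(2, length(x)))
  expect_error(gaussian_fwhm(flat), "flat")
  expect_error(gaussian_fwhm(prof[1:3, ]), ">= 5")
})

test_that("every Gaussian fit satisfies fwhm = 2 sqrt(2 ln 2) sigma", {
  set.seed(42)
  x <- seq(0, 3, by = 0.02)
  for (k in 1:10) {
    sigma <- runif(1, 0.05, 0.4)
    y <- runif(1, 0, 5) +
      runif(1, 2, 20) * exp(-(x - runif(1, 1, 2))^2 / (2 * sigma^2)) +
      rnorm(length(x), 0, 0.2)
    fit <- gaussian_fwhm(tibble::tibble(position_um = x, intensity = pmax(y, 0)))
    expect_equal(fit$fwhm_um / fit$sigma_um, 2 * sqrt(2 * log(2)))
  }
})

test_that("profile CoV follows the min-normalised sample-SD convention", {
  expect_equal(profile_cov(rep(5, 10)), 0)
  # {2, 4} -> {1, 2}: mean 1.5, sample SD sqrt(0.5)
  expect_equal(profile_cov(c(2, 4)), sqrt(0.5) / 1.5, tolerance = 1e-9)
  expect_equal(round(profile_cov(c(2, 4)), 5), 0.47140)
  # invariant under positive gain with min-normalisation
  set.seed(1)
  y <- runif(50, 1, 10)
  expect_equal(profile_cov(y), profile_cov(7.3 * y), tolerance = 1e-12)
  # without normalisation CoV is also gain-invariant but shift-sensitive
  expect_equal(profile_cov(y, "none"), profile_cov(2 * y, "none"),
               tolerance = 1e-12)
  expect_error(profile_cov(c(0, 1)), "minimum")

  # organised (periodic, high-contrast) traces score higher than smoothed ones
  x <- seq_len(200)
  organised <- 2 + sin(x / 5)
  smoothed <- 2 + as.numeric(stats::filter(sin(x / 5), rep(1 / 31, 31),
                                           circular = TRUE))
  expect_gt(profile_cov(organised), profile_cov(smoothed))
})

test_that("junction masks from a marker channel cover the junction", {
  spec <- render_spec(pixel_size_um = 0.05, seed = 2)
  jr <- generate_junction_image(0.2, amplitude = 120, baseline = 8,
                                noise_sd = 4, spec = spec, field_size = c(6, 6))
  mask <- mask_from_channel(jr$image, smooth_sigma_um = 0.1, dilation_um = 0.2)
  x <- (seq_len(ncol(jr$image$data)) - 0.5) * 0.05
  true_band <- abs(x - 3) <= jr$true_fwhm_um / 2
  recall <- mean(mask$raster[, true_band])
  expect_gte(recall, 0.95)

  # dilation only grows the mask
  m0 <- mask_from_channel(jr$image, dilation_um = 0)
  m1 <- mask_from_channel(jr$image, dilation_um = 0.3)
  expect_gte(sum(m1$raster), sum(m0$raster))
  expect_true(all(m1$raster[m0$raster]))

  expect_warning(mask_from_channel(sr_image(matrix(5, 10, 10), 0.05)),
                 "empty")
})

test_that("normalised junctional intensity is a gain-invariant mean ratio", {
  m <- matrix(10, 20, 20)
  m[, 9:12] <- 40
  img <- sr_image(m, pixel_size_um = 0.05)
  jm <- matrix(FALSE, 20, 20); jm[, 9:12] <- TRUE
  expect_equal(normalised_junctional_intensity(img, jm, !jm), 4)
  # identical means give 1
  expect_equal(normalised_junctional_intensity(
    sr_image(matrix(7, 10, 10), 0.05),
    rbind(matrix(TRUE, 5, 10), matrix(FALSE, 5, 10)),
    rbind(matrix(FALSE, 5, 10), matrix(TRUE, 5, 10))), 1)
  # global gain cancels
  img2 <- sr_image(3 * m, pixel_size_um = 0.05)
  expect_equal(normalised_junctional_intensity(img2, jm, !jm), 4)
  expect_error(normalised_junctional_intensity(img, jm, jm), "overlap")
  # ratio grows with junctional signal at fixed background
  ratios <- vapply(c(20, 40, 80), function(v) {
    mm <- matrix(10, 20, 20); mm[, 9:12] <- v
    normalised_junctional_intensity(sr_image(mm, 0.05), jm, !jm)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("Boltzmann fits recover exact curves and the midpoint identity", {
  boltz <- function(x, A1, A2, x0, dx) A2 + (A1 - A2) / (1 + exp((x - x0) / dx))
  x <- seq(0, 105, by = 7.5)
  # dx < 0 with A1 < A2: response falls from A2 towards A1 as x grows
  y <- boltz(x, A1 = 0, A2 = 1, x0 = 50, dx = -10)
  fit <- boltzmann_fit(x, y)
  expect_true(fit$converged)
  expect_equal(c(fit$A1, fit$A2, fit$x0, fit$dx), c(0, 1, 50, -10),
               tolerance = 1e-6)
  # midpoint identity for any slope
  expect_equal(fit$predict(fit$x0), (fit$A1 + fit$A2) / 2, tolerance = 1e-9)
  # monotone between asymptotes, falling here
  yy <- fit$predict(seq(0, 105, by = 1))
  expect_true(all(diff(yy) < 0))

  # an equivalent non-canonical truth is reported in canonical form
  y2 <- boltz(x, A1 = 5, A2 = 1, x0 = 40, dx = 8)
  fit2 <- boltzmann_fit(x, y2)
  expect_equal(fit2$x0, 40, tolerance = 1e-6)
  expect_equal(c(fit2$A1, fit2$A2, fit2$dx), c(1, 5, -8), tolerance = 1e-6)

  # rising curve: canonical dx is positive
  y3 <- boltz(x, A1 = 0, A2 = 1, x0 = 50, dx = 10)
  expect_gt(boltzmann_fit(x, y3)$dx, 0)

  expect_error(boltzmann_fit(x[1:4], y[1:4]), ">= 5")
  expect_error(boltzmann_fit(x, rep(1, length(x))), "flat")
})

test_that("noisy Boltzmann curves give midpoints within 5% over seeds", {
  boltz <- function(x, A1, A2, x0, dx) A2 + (A1 - A2) / (1 + exp((x - x0) / dx))
  x <- seq(0, 105, by = 7.5)
  clean <- boltz(x, A1 = 0, A2 = 1, x0 = 50, dx = -12)
  errs <- vapply(1:20, function(sd) {
    y <- clean + withr::with_seed(sd, rnorm(length(x), 0, 0.05))
    abs(boltzmann_fit(x, y)$x0 - 50)
  }, numeric(1))
  expect_lt(median(errs) / 50, 0.05)
})
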