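test_that("gaussian blur works in physical units and matches direct convolution", {
  # constant image unchanged by a normalised filter
  flat <- sr_image(matrix(7, 21, 21), pixel_size_um = 0.02)
  expect_equal(gaussian_blur(flat, 0.015)$data, flat$data, tolerance = 1e-10)
  # sigma 0 is the identity
  expect_identical(gaussian_blur(flat, 0)$data, flat$data)
  expect_error(gaussian_blur(flat, -1), "non-negative")

  # impulse response vs brute-force discrete convolution (interior pixel,
  # so border handling is irrelevant); 0.015 um on 0.02 um/px = 0.75 px
  m <- matrix(0, 21, 21); m[11, 11] <- 100
  img <- sr_image(m, pixel_size_um = 0.02)
  got <- gaussian_blur(img, 0.015)$data
  want <- oracle_gauss_conv(m, sigma_px = 0.75, radius = 5)
  expect_lt(max(abs(got - want)) / max(want), 5e-3)
  expect_equal(sum(got), 100, tolerance = 1e-6)  # blur conserves intensity
})

test_that("rolling-ball background subtraction matches the morphological oracle", {
  flat <- sr_image(matrix(13, 9, 9), pixel_size_um = 0.02)
  expect_true(all(subtract_background(flat, 3)$data == 0))

  set.seed(42)
  m <- matrix(runif(81, 0, 100), 9, 9)
  img <- sr_image(m, pixel_size_um = 0.02)
  got <- subtract_background(img, 3)$data
  bg <- oracle_ball_opening(m, radius = 3, depth = diff(range(m)))
  want <- pmax(m - pmin(bg, m), 0)
  expect_equal(got, want, tolerance = 1e-10)
  expect_true(all(got >= 0))

  expect_error(subtract_background(flat, 5), "too large")
  expect_error(subtract_background(flat, 0), ">= 1")
})

test_that("centre of mass is the intensity-weighted mean of pixel centres", {
  px <- 0.02
  # two pixels on one row, intensities 1 and 3: weighted index 0.75 (0-based)
  m <- matrix(0, 3, 3); m[2, 1] <- 1; m[2, 2] <- 3
  img <- sr_image(m, pixel_size_um = px)
  com <- centre_of_mass(img, m > 0)
  expect_equal(unname(com["x_um"]), (0.75 + 0.5) * px)
  expect_equal(unname(com["y_um"]), 1.5 * px)

  # uniform disk: geometric centre
  dm <- make_disk_image(21, 21, cbind(11, 11), 6, value = 5)
  dimg <- sr_image(dm, pixel_size_um = px)
  dcom <- centre_of_mass(dimg, dm > 0)
  expect_equal(unname(dcom), c(10.5 * px, 10.5 * px), tolerance = 1e-12)

  # random masks and intensities vs the direct-sum oracle
  set.seed(1)
  for (k in 1:10) {
    m <- matrix(runif(100), 10, 10)
    idx <- sample(100, 17)
    img <- sr_image(m, pixel_size_um = px)
    com <- centre_of_mass(img, idx)
    i <- ((idx - 1) %% 10) + 1; j <- ((idx - 1) %/% 10) + 1
    w <- m[idx]
    expect_equal(unname(com["x_um"]), sum(w * (j - 0.5) * px) / sum(w))
    expect_equal(unname(com["y_um"]), sum(w * (i - 0.5) * px) / sum(w))
  }
  expect_error(centre_of_mass(img, matrix(FALSE, 10, 10)), "empty")
})

test_that("segmentation filters by area and circularity with sub-pixel centroids", {
  px <- 0.02
  blank <- sr_image(matrix(0, 50, 50), pixel_size_um = px)
  expect_equal(nrow(segment_particles(blank, blank)), 0)

  # five disks; radius-5 disk (~81 px = 0.0324 um2) exceeds the 0.02 um2 cap
  centres <- rbind(c(15, 15), c(15, 45), c(45, 15), c(45, 45), c(30, 30))
  radii <- c(2, 2, 2.5, 2, 5)
  m <- make_disk_image(60, 60, centres, radii, value = 100)
  img <- sr_image(m, pixel_size_um = px)
  got <- segment_particles(img, img, threshold = 50)
  expect_equal(nrow(got), 4)
  kept <- centres[radii < 5, , drop = FALSE]
  for (k in seq_len(nrow(kept))) {
    err <- sqrt(min((got$com_x_um - (kept[k, 2] - 0.5) * px)^2 +
                      (got$com_y_um - (kept[k, 1] - 0.5) * px)^2))
    expect_lt(err, 0.5 * px)
  }
  expect_true(all(got$circularity >= 0 & got$circularity <= 1))
  expect_true(all(got$area_um2 == got$pixel_count * px^2))
})

test_that("widening area or circularity windows never drops a particle", {
  px <- 0.02
  set.seed(7)
  for (rep in 1:5) {
    centres <- cbind(sample(10:70, 6), sample(10:70, 6))
    radii <- runif(6, 1, 5)
    m <- make_disk_image(80, 80, centres, radii, value = 100)
    img <- sr_image(m, pixel_size_um = px)
    narrow <- segment_particles(img, img, min_area_um2 = 0.001,
                                max_area_um2 = 0.01, circ_min = 0.5,
                                circ_max = 1, threshold = 50)
    wide <- segment_particles(img, img, min_area_um2 = 0,
                              max_area_um2 = 0.05, circ_min = 0,
                              circ_max = 1, threshold = 50)
    key <- function(p) paste(round(p$com_x_um, 9), round(p$com_y_um, 9))
    expect_true(all(key(narrow) %in% key(wide)))
  }
})

test_that("detection is translation-equivariant on noise-free fixtures", {
  px <- 0.02
  m <- make_disk_image(60, 60, rbind(c(20, 20), c(40, 35)), c(2, 3), 100)
  shifted <- matrix(0, 60, 60)
  shifted[6:60, 4:60] <- m[1:55, 1:57]  # shift down 5 px, right 3 px
  a <- segment_particles(sr_image(m, px), sr_image(m, px),
                         max_area_um2 = 0.05, threshold = 50)
  b <- segment_particles(sr_image(shifted, px), sr_image(shifted, px),
                         max_area_um2 = 0.05, threshold = 50)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(b$com_x_um), sort(a$com_x_um) + 3 * px, tolerance = 1e-9)
  expect_equal(sort(b$com_y_um), sort(a$com_y_um) + 5 * px, tolerance = 1e-9)
})

test_that("diagonally touching pixels segment as one 8-connected particle", {
  px <- 0.02
  m <- matrix(0, 9, 9)
  m[3, 3] <- 100; m[4, 4] <- 100; m[5, 5] <- 100
  img <- sr_image(m, pixel_size_um = px)
  got <- segment_particles(img, img, threshold = 50)
  expect_equal(nrow(got), 1)
  expect_equal(got$pixel_count, 3L)
})

test_that("region masks select particles by centre of mass, edges inclusive", {
  parts <- tibble::tibble(particle_id = 1:4,
                          com_x_um = c(1, 3, 5, 2),
                          com_y_um = c(1, 3, 5, 0))
  whole <- region_mask(polygon = rbind(c(0, 0), c(6, 0), c(6, 6), c(0, 6)))
  expect_equal(apply_region_mask(parts, whole), parts)

  # particle 4 sits exactly on the bottom edge: counted inside
  small <- region_mask(polygon = rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)))
  kept <- apply_region_mask(parts, small)
  expect_setequal(kept$particle_id, c(1, 2, 4))

  # random particles: polygon membership agrees with a rasterised oracle
  set.seed(3)
  poly <- rbind(c(1, 1), c(9, 2), c(8, 8), c(2, 7))
  msk <- region_mask(polygon = poly)
  pts <- tibble::tibble(particle_id = 1:200,
                        com_x_um = runif(200, 0, 10),
                        com_y_um = runif(200, 0, 10))
  kept <- apply_region_mask(pts, msk)
  px <- 0.01  # fine raster oracle
  ras <- matrix(FALSE, 1000, 1000)
  for (i in 1:1000) {
    # even-odd scanline on pixel centres
    y <- (i - 0.5) * px
    xs <- (seq_len(1000) - 0.5) * px
    n <- nrow(poly); inside <- rep(FALSE, 1000)
    for (e in seq_len(n)) {
      x1 <- poly[e, 1]; y1 <- poly[e, 2]
      x2 <- poly[e %% n + 1, 1]; y2 <- poly[e %% n + 1, 2]
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        inside <- xor(inside, xs < xint)
      }
    }
    ras[i, ] <- inside
  }
  oracle_in <- ras[cbind(pmin(ceiling(pts$com_y_um / px), 1000),
                         pmin(ceiling(pts$com_x_um / px), 1000))]
  expect_setequal(kept$particle_id, pts$particle_id[oracle_in])
})
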