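#' Gaussian blur in physical units
#'
#' Isotropic Gaussian filtering with the sigma given in micrometres and
#' converted to pixels through the image's pixel size (e.g. sigma 0.015 µm
#' on a 0.02 µm/px raster is a 0.75 px kernel). `sigma_um = 0` is the
#' identity. Borders are handled by replication.
#'
#' @param image An [sr_image].
#' @param sigma_um Gaussian sigma in µm (>= 0).
#' @return A blurred [sr_image].
#' @export
gaussian_blur <- function(image, sigma_um = 0.015) {
  assert_sr_image(image)
  if (!is.numeric(sigma_um) || length(sigma_um) != 1 || sigma_um < 0) {
    stop("`sigma_um` must be a single non-negative number", call. = FALSE)
  }
  if (sigma_um == 0) return(image)
  s_px <- sigma_um / image$pixel_size_um
  # kernel must fit inside the image and have odd size
  radius <- 2L * as.integer(ceiling(3 * s_px)) + 1L
  max_r <- min(dim(image$data))
  if (max_r %% 2 == 0) max_r <- max_r - 1L
  radius <- min(radius, max_r)
  out <- EBImage::gblur(image$data, sigma = s_px, radius = radius,
                        boundary = "replicate")
  out <- pmax(matrix(as.numeric(out), nrow(image$data), ncol(image$data)), 0)
  sr_image(out, image$pixel_size_um, image$channel)
}

# offsets and heights of a non-flat "ball" structuring element of radius r px;
# height scaled so the ball's depth at its rim equals `depth` intensity units
ball_element <- function(radius_px, depth) {
  d <- expand.grid(di = -radius_px:radius_px, dj = -radius_px:radius_px)
  r2 <- d$di^2 + d$dj^2
  keep <- r2 <= radius_px^2
  d <- d[keep, ]
  z <- (sqrt(radius_px^2 - r2[keep]) - radius_px) / radius_px * depth
  list(di = d$di, dj = d$dj, z = z)
}

# grayscale erosion/dilation by a structuring function, replicate borders
gray_morph <- function(m, se, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  ri <- seq_len(nr); ci <- seq_len(nc)
  for (k in seq_along(se$di)) {
    src_i <- pmin(pmax(ri + se$di[k], 1L), nr)
    src_j <- pmin(pmax(ci + se$dj[k], 1L), nc)
    shifted <- m[src_i, src_j, drop = FALSE]
    if (op == "erode") {
      out <- pmin(out, shifted - se$z[k])
    } else {
      out <- pmax(out, shifted + se$z[k])
    }
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background by grayscale opening with a
#' ball-shaped (non-flat) structuring element of the given pixel radius and
#' subtracts it; output is clipped at zero. This is the morphological
#' reading of the sliding-paraboloid/rolling-ball operation of common image
#' software; the ball depth is scaled to the image intensity range.
#'
#' @param image An [sr_image].
#' @param radius_px Structuring-element radius in pixels (>= 1); the default
#'   3 px corresponds to 0.06 µm at a 0.02 µm/px raster.
#' @return A background-subtracted [sr_image].
#' @export
subtract_background <- function(image, radius_px = 3) {
  assert_sr_image(image)
  if (radius_px < 1 || radius_px != round(radius_px)) {
    stop("`radius_px` must be an integer >= 1", call. = FALSE)
  }
  if (2 * radius_px + 1 > min(dim(image$data))) {
    stop("`radius_px` too large for this image", call. = FALSE)
  }
  rng <- diff(range(image$data))
  se <- ball_element(as.integer(radius_px), depth = rng)
  bg <- gray_morph(gray_morph(image$data, se, "erode"), se, "dilate")
  out <- pmax(image$data - pmin(bg, image$data), 0)
  sr_image(out, image$pixel_size_um, image$channel)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass
label_components <- function(binary) {
  lab <- EBImage::bwlabel(binary)
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

# perimeter (pixels) of a binary component via its 0.5-level contour
# (marching-squares polygon through edge midpoints)
component_perimeter_px <- function(mask) {
  pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  cl <- grDevices::contourLines(x = seq_len(nrow(pad)), y = seq_len(ncol(pad)),
                                z = pad, levels = 0.5)
  sum(vapply(cl, function(cc) {
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
  }, numeric(1)))
}

#' Intensity-weighted centre of mass
#'
#' The centre of mass of a pixel region, weighted by the raw image
#' intensities and expressed in micrometres (pixel centres at
#' `(index - 0.5) * pixel_size`). If the region's total intensity is zero
#' the geometric centroid is returned.
#'
#' @param raw An [sr_image]; intensities are taken from here.
#' @param component_mask Logical matrix of the same shape, or an integer
#'   vector of cell indices into the raster.
#' @return Named numeric vector `c(x_um, y_um)`.
#' @export
centre_of_mass <- function(raw, component_mask) {
  assert_sr_image(raw, "raw")
  if (is.matrix(component_mask)) {
    if (!all(dim(component_mask) == dim(raw$data))) {
      stop("mask shape differs from image", call. = FALSE)
    }
    idx <- which(component_mask != 0)
  } else {
    idx <- as.integer(component_mask)
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > length(raw$data))) {
      stop("mask indices outside the raster", call. = FALSE)
    }
  }
  if (length(idx) == 0) stop("empty component mask", call. = FALSE)
  nr <- nrow(raw$data)
  i <- ((idx - 1) %% nr) + 1
  j <- ((idx - 1) %/% nr) + 1
  w <- raw$data[idx]
  if (sum(w) <= 0) w <- rep(1, length(idx))
  c(x_um = sum(w * px_centre_x(j, raw$pixel_size_um)) / sum(w),
    y_um = sum(w * px_centre_y(i, raw$pixel_size_um)) / sum(w))
}

#' Segment puncta with area and circularity filters
#'
#' Thresholds the preprocessed image, labels 8-connected components,
#' filters them by area (µm²) and circularity (4·pi·area / perimeter²,
#' clipped to 1; the perimeter is the length of the component's
#' marching-squares boundary polygon), and measures each surviving particle
#' on the **raw** image: intensity-weighted centre of mass, mean and total
#' intensity.
#'
#' @param preprocessed An [sr_image], typically blurred and
#'   background-subtracted; segmentation runs on this image.
#' @param raw An [sr_image] of identical shape and pixel size; centres of
#'   mass and intensities are measured here.
#' @param min_area_um2,max_area_um2 Inclusive area window (µm²); the default
#'   cap 0.02 µm² equals 50 px at a 0.02 µm/px raster.
#' @param circ_min,circ_max Inclusive circularity window in \[0, 1\].
#' @param threshold `"otsu"` (default) or an explicit numeric threshold on
#'   the preprocessed intensities; pixels strictly above it are foreground.
#'
#' @return A tibble (one row per particle): `particle_id`, `com_x_um`,
#'   `com_y_um`, `area_um2`, `circularity`, `pixel_count`,
#'   `mean_intensity`, `total_intensity`, `channel`. Empty images give an
#'   empty tibble, not an error.
#' @export
segment_particles <- function(preprocessed, raw,
                              min_area_um2 = 0, max_area_um2 = 0.02,
                              circ_min = 0, circ_max = 1,
                              threshold = "otsu") {
  assert_sr_image(preprocessed, "preprocessed")
  assert_sr_image(raw, "raw")
  if (!all(dim(preprocessed$data) == dim(raw$data)) ||
      preprocessed$pixel_size_um != raw$pixel_size_um) {
    stop("`preprocessed` and `raw` must share shape and pixel size", call. = FALSE)
  }
  if (!(0 <= circ_min && circ_min <= circ_max && circ_max <= 1)) {
    stop("need 0 <= circ_min <= circ_max <= 1", call. = FALSE)
  }
  if (min_area_um2 > max_area_um2) stop("min_area_um2 > max_area_um2", call. = FALSE)
  empty <- tibble::tibble(
    particle_id = integer(0), com_x_um = numeric(0), com_y_um = numeric(0),
    area_um2 = numeric(0), circularity = numeric(0), pixel_count = integer(0),
    mean_intensity = numeric(0), total_intensity = numeric(0),
    channel = character(0)
  )
  m <- preprocessed$data
  if (diff(range(m)) == 0) return(empty)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(m, range = range(m), levels = 256)
  } else {
    as.numeric(threshold)
  }
  binary <- m > thr
  if (!any(binary)) return(empty)
  lab <- label_components(binary * 1)
  nlab <- max(lab)
  px <- raw$pixel_size_um
  nr <- nrow(m)
  cells <- split(which(lab > 0), lab[lab > 0])
  rows <- purrr::map(cells, function(idx) {
    npx <- length(idx)
    area <- npx * px^2
    i <- ((idx - 1) %% nr) + 1
    j <- ((idx - 1) %/% nr) + 1
    sub <- matrix(0, diff(range(i)) + 1, diff(range(j)) + 1)
    sub[cbind(i - min(i) + 1, j - min(j) + 1)] <- 1
    per_px <- component_perimeter_px(sub)
    circ <- if (per_px > 0) min(4 * pi * npx / per_px^2, 1) else 1
    com <- centre_of_mass(raw, idx)
    tibble::tibble(
      com_x_um = com[["x_um"]], com_y_um = com[["y_um"]],
      area_um2 = area, circularity = circ, pixel_count = npx,
      mean_intensity = mean(raw$data[idx]),
      total_intensity = sum(raw$data[idx])
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(
    out,
    .data$area_um2 >= min_area_um2, .data$area_um2 <= max_area_um2,
    .data$circularity >= circ_min, .data$circularity <= circ_max
  )
  out$particle_id <- seq_len(nrow(out))
  out$channel <- if (is.na(raw$channel)) NA_character_ else raw$channel
  dplyr::select(out, "particle_id", dplyr::everything())
}

#' Region mask (junctional or non-junctional)
#'
#' A region of the field given either as a polygon (vertices in µm) or as a
#' boolean raster aligned with an image.
#'
#' @param polygon Data frame / matrix of vertices with x, y in µm
#'   (closed implicitly), or `NULL`.
#' @param raster Logical matrix, or `NULL`.
#' @param kind `"junctional"` or `"non_junctional"`.
#' @param pixel_size_um Required with `raster`: its pixel size.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(polygon = NULL, raster = NULL,
                        kind = c("junctional", "non_junctional"),
                        pixel_size_um = NULL) {
  kind <- match.arg(kind)
  if (is.null(polygon) == is.null(raster)) {
    stop("give exactly one of `polygon` or `raster`", call. = FALSE)
  }
  if (!is.null(polygon)) {
    polygon <- as.matrix(as.data.frame(polygon)[, 1:2])
    colnames(polygon) <- c("x_um", "y_um")
    if (nrow(polygon) < 3) stop("polygon needs >= 3 vertices", call. = FALSE)
  }
  if (!is.null(raster)) {
    if (is.null(pixel_size_um) || pixel_size_um <= 0) {
      stop("`pixel_size_um` required for raster masks", call. = FALSE)
    }
    raster <- raster != 0
  }
  structure(list(polygon = polygon, raster = raster, kind = kind,
                 pixel_size_um = pixel_size_um),
            class = "region_mask")
}

# even-odd point-in-polygon; points exactly on an edge count as inside
point_in_polygon <- function(x, y, poly, eps = 1e-9) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  nxt <- c(2:n, 1)
  vapply(seq_along(x), function(k) {
    x0 <- x[k]; y0 <- y[k]
    inside <- FALSE
    for (e in seq_len(n)) {
      x1 <- px[e]; y1 <- py[e]; x2 <- px[nxt[e]]; y2 <- py[nxt[e]]
      # on-segment check
      cross <- (x2 - x1) * (y0 - y1) - (y2 - y1) * (x0 - x1)
      if (abs(cross) <= eps * max(1, abs(x2 - x1), abs(y2 - y1)) &&
          x0 >= min(x1, x2) - eps && x0 <= max(x1, x2) + eps &&
          y0 >= min(y1, y2) - eps && y0 <= max(y1, y2) + eps) {
        return(TRUE)
      }
      if ((y1 > y0) != (y2 > y0)) {
        xint <- x1 + (y0 - y1) / (y2 - y1) * (x2 - x1)
        if (x0 < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Restrict particles to a region mask
#'
#' Keeps the particles whose centre of mass falls inside the mask. For
#' polygon masks membership uses the even-odd rule, with points exactly on
#' an edge counted as inside; for raster masks the centre of mass is mapped
#' to its pixel.
#'
#' @param particles A particle tibble from [segment_particles()].
#' @param mask A [region_mask].
#' @return The filtered particle tibble (possibly empty).
#' @export
apply_region_mask <- function(particles, mask) {
  if (!inherits(mask, "region_mask")) stop("`mask` must be a region_mask", call. = FALSE)
  if (nrow(particles) == 0) return(particles)
  keep <- if (!is.null(mask$polygon)) {
    point_in_polygon(particles$com_x_um, particles$com_y_um, mask$polygon)
  } else {
    px <- mask$pixel_size_um
    i <- pmin(pmax(ceiling(particles$com_y_um / px), 1), nrow(mask$raster))
    j <- pmin(pmax(ceiling(particles$com_x_um / px), 1), ncol(mask$raster))
    mask$raster[cbind(i, j)]
  }
  particles[keep, , drop = FALSE]
}

#' Read / write particle tables
#'
#' CSV round-trip for particle tibbles (columns as produced by
#' [segment_particles()]).
#'
#' @param particles Particle tibble.
#' @param path CSV path.
#' @return `write_particles_csv` returns `path` invisibly;
#'   `read_particles_csv` returns a tibble.
#' @export
write_particles_csv <- function(particles, path) {
  utils::write.csv(particles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles_csv
#' @export
read_particles_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
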