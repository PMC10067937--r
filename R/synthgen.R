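#' Parameters of the two-component localisation-error distance distribution
#'
#' Holds the six parameters of the mixture distance density used both as the
#' generative truth of the synthetic data module and as the fit target of
#' [fit_distance_model()]: component amplitudes `a1`, `a2`, characteristic
#' inter-channel distances `mu1`, `mu2` (µm) and combined two-channel
#' localisation dispersions `sigma1`, `sigma2` (µm). Setting `a2 = 0`
#' selects a single-component model.
#'
#' The defaults mirror a junctional two-protein scenario with a frequent
#' short-range mode near 34 nm and an occasional longer mode near 169 nm.
#'
#' @param a1,a2 Non-negative component amplitudes. In a density-normalised
#'   fit these play the role of mixture proportions.
#' @param mu1,mu2 Characteristic distances in µm (>= 0).
#' @param sigma1,sigma2 Dispersions in µm (> 0 for active components).
#'
#' @return A named numeric vector of class `mixture_params` with elements
#'   `a1, a2, mu1, mu2, sigma1, sigma2`.
#' @export
#' @examples
#' mixture_params()                      # two-component default
#' mixture_params(a1 = 1, a2 = 0, mu1 = 0, sigma1 = 0.02)  # Rayleigh limit
mixture_params <- function(a1 = 0.7, a2 = 0.3,
                           mu1 = 0.034, mu2 = 0.169,
                           sigma1 = 0.010, sigma2 = 0.040) {
  p <- c(a1 = a1, a2 = a2, mu1 = mu1, mu2 = mu2,
         sigma1 = sigma1, sigma2 = sigma2)
  validate_mixture_params(p)
  structure(p, class = c("mixture_params", "numeric"))
}

validate_mixture_params <- function(p) {
  p <- as_mixture_vector(p)
  if (anyNA(p) || any(!is.finite(p))) stop("mixture parameters must be finite", call. = FALSE)
  if (any(p[c("a1", "a2")] < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (sum(p[c("a1", "a2")]) <= 0) stop("at least one amplitude must be > 0", call. = FALSE)
  if (any(p[c("mu1", "mu2")] < 0)) stop("characteristic distances must be >= 0", call. = FALSE)
  if (p["a1"] > 0 && p["sigma1"] <= 0) stop("sigma1 must be > 0 for an active component", call. = FALSE)
  if (p["a2"] > 0 && p["sigma2"] <= 0) stop("sigma2 must be > 0 for an active component", call. = FALSE)
  invisible(p)
}

as_mixture_vector <- function(p) {
  nm <- c("a1", "a2", "mu1", "mu2", "sigma1", "sigma2")
  if (is.list(p)) p <- unlist(p)
  if (is.null(names(p)) && length(p) == 6) names(p) <- nm
  if (!all(nm %in% names(p))) {
    stop("mixture parameters need elements ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  out <- as.numeric(p[nm])
  names(out) <- nm
  out
}

#' Ground-truth description of a synthetic two-channel point pattern
#'
#' @param mixture A [mixture_params] object: the inter-channel displacement
#'   law of the paired puncta.
#' @param n_pairs Number of channel-A/channel-B pairs.
#' @param clutter_density Unpaired puncta per µm² added independently to
#'   each channel (homogeneous Poisson).
#' @param field_size Field `c(width_um, height_um)`.
#' @param junction_path Optional polyline (matrix or data frame with columns
#'   x/y in µm) along which channel-A points are placed; `NULL` places them
#'   uniformly over the field.
#' @param junction_jitter_um Transverse Gaussian jitter (µm) around the
#'   junction path, emulating a junction of finite width.
#' @param seed Integer seed; identical seeds give bit-identical patterns.
#'
#' @return A list of class `synth_truth`.
#' @export
synth_truth <- function(mixture = mixture_params(), n_pairs = 2000,
                        clutter_density = 0.05, field_size = c(20, 20),
                        junction_path = NULL, junction_jitter_um = 0.05,
                        seed = 1L) {
  mixture <- structure(as_mixture_vector(mixture),
                       class = c("mixture_params", "numeric"))
  validate_mixture_params(mixture)
  if (length(n_pairs) != 1 || n_pairs < 0 || n_pairs != round(n_pairs)) {
    stop("`n_pairs` must be a non-negative integer", call. = FALSE)
  }
  if (clutter_density < 0) stop("`clutter_density` must be >= 0", call. = FALSE)
  if (length(field_size) != 2 || any(field_size <= 0)) {
    stop("`field_size` must be two positive lengths in um", call. = FALSE)
  }
  if (!is.null(junction_path)) {
    junction_path <- as.matrix(as.data.frame(junction_path)[, 1:2])
    colnames(junction_path) <- c("x_um", "y_um")
    if (nrow(junction_path) < 2) stop("`junction_path` needs >= 2 vertices", call. = FALSE)
    inx <- junction_path[, 1] >= 0 & junction_path[, 1] <= field_size[1]
    iny <- junction_path[, 2] >= 0 & junction_path[, 2] <= field_size[2]
    if (!all(inx & iny)) stop("`junction_path` lies outside the field", call. = FALSE)
  }
  structure(
    list(mixture = mixture, n_pairs = as.integer(n_pairs),
         clutter_density = clutter_density,
         field_size = as.numeric(field_size),
         junction_path = junction_path,
         junction_jitter_um = junction_jitter_um,
         seed = as.integer(seed)),
    class = "synth_truth"
  )
}

#' Rendering parameters for synthetic image acquisition
#'
#' Emulates acquisition of a punctate super-resolution image: each punctum
#' contributes an integrated-Gaussian point-spread function, a constant
#' background rate is added, and per-pixel Poisson shot noise is applied.
#'
#' @param pixel_size_um Pixel size (µm/px); default 0.02 µm matches a
#'   STED-class raster where 3 px = 0.06 µm and 50 px² = 0.02 µm².
#' @param psf_sigma_um Gaussian PSF sigma (µm); default 0.02 µm corresponds
#'   to ~50 nm full-width-at-half-maximum optical resolution.
#' @param photons_per_punctum Expected integrated photon count per punctum.
#' @param background_rate Expected background counts per pixel.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed for the Poisson noise.
#'
#' @return A list of class `render_spec`.
#' @export
render_spec <- function(pixel_size_um = 0.02, psf_sigma_um = 0.02,
                        photons_per_punctum = 500, background_rate = 1,
                        bit_depth = 16, seed = 1L) {
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0", call. = FALSE)
  if (psf_sigma_um < 0) stop("`psf_sigma_um` must be >= 0", call. = FALSE)
  if (photons_per_punctum < 0 || background_rate < 0) {
    stop("photon and background rates must be >= 0", call. = FALSE)
  }
  if (!bit_depth %in% c(8, 16)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  structure(
    list(pixel_size_um = pixel_size_um, psf_sigma_um = psf_sigma_um,
         photons_per_punctum = photons_per_punctum,
         background_rate = background_rate, bit_depth = bit_depth,
         seed = as.integer(seed)),
    class = "render_spec"
  )
}

#' Sample inter-channel displacement distances from the mixture law
#'
#' Distances are generated mechanistically, mirroring the physical model
#' behind the fitted density: a component is chosen with probability
#' proportional to its amplitude, a true offset of length `mu` is placed in
#' a uniformly random direction, isotropic 2D Gaussian localisation noise of
#' per-axis standard deviation `sigma` is added, and the Euclidean norm is
#' returned.
#'
#' @param mixture A [mixture_params] object (or coercible named vector).
#' @param n Number of distances (>= 0).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `distance_um` and `component` (1 or 2).
#' @export
#' @examples
#' d <- sample_displacement_distances(mixture_params(), n = 1000, seed = 7)
#' mean(d$distance_um)
sample_displacement_distances <- function(mixture, n, seed = 1L) {
  p <- validate_mixture_params(mixture)
  if (length(n) != 1 || is.na(n) || n < 0 || n != round(n)) {
    stop("`n` must be a non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 0) {
    return(tibble::tibble(distance_um = numeric(0), component = integer(0)))
  }
  withr::with_seed(seed, {
    comp <- sample.int(2L, n, replace = TRUE, prob = p[c("a1", "a2")])
    mu <- unname(p[c("mu1", "mu2")][comp])
    sg <- unname(p[c("sigma1", "sigma2")][comp])
    theta <- stats::runif(n, 0, 2 * pi)
    dx <- mu * cos(theta) + stats::rnorm(n, 0, sg)
    dy <- mu * sin(theta) + stats::rnorm(n, 0, sg)
    tibble::tibble(distance_um = sqrt(dx^2 + dy^2), component = comp)
  })
}

# cumulative arclength parametrisation of a polyline; returns function t->(x,y)
polyline_point <- function(path, t) {
  seg <- diff(path)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- t * total
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg))
  frac <- (s - cum[idx]) / len[idx]
  path[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
}

#' Generate a paired two-channel point pattern with known truth
#'
#' Places `n_pairs` channel-A points (uniformly over the field, or along the
#' junction path when one is given), displaces a paired channel-B point from
#' each by a draw from the mixture displacement law, and adds independent
#' homogeneous Poisson clutter to both channels. The full localisation
#' dispersion `sigma` is applied to the B point of each pair; since only the
#' relative displacement matters downstream, this is equivalent to splitting
#' the error between both channels.
#'
#' @param truth A [synth_truth] object.
#'
#' @return A list with elements `points` (tibble: `channel` "A"/"B",
#'   `x_um`, `y_um`, `role` "pair"/"clutter", `pair_id`, `component`) and
#'   `truth` (the input, echoed for downstream assertions).
#' @export
generate_point_pattern <- function(truth) {
  if (!inherits(truth, "synth_truth")) stop("`truth` must be a synth_truth", call. = FALSE)
  p <- truth$mixture
  W <- truth$field_size[1]
  H <- truth$field_size[2]
  n <- truth$n_pairs
  withr::with_seed(truth$seed, {
    if (is.null(truth$junction_path)) {
      ax <- stats::runif(n, 0, W)
      ay <- stats::runif(n, 0, H)
    } else {
      base <- polyline_point(truth$junction_path, stats::runif(n))
      # transverse jitter: isotropic is adequate at jitter << path length
      ax <- pmin(pmax(base[, 1] + stats::rnorm(n, 0, truth$junction_jitter_um), 0), W)
      ay <- pmin(pmax(base[, 2] + stats::rnorm(n, 0, truth$junction_jitter_um), 0), H)
    }
    comp <- if (n > 0) {
      sample.int(2L, n, replace = TRUE, prob = p[c("a1", "a2")])
    } else integer(0)
    mu <- unname(p[c("mu1", "mu2")][comp])
    sg <- unname(p[c("sigma1", "sigma2")][comp])
    theta <- stats::runif(n, 0, 2 * pi)
    bx <- ax + mu * cos(theta) + stats::rnorm(n, 0, sg)
    by <- ay + mu * sin(theta) + stats::rnorm(n, 0, sg)
    n_clut <- stats::rpois(2, truth$clutter_density * W * H)
    clut <- lapply(n_clut, function(k) {
      cbind(stats::runif(k, 0, W), stats::runif(k, 0, H))
    })
  })
  pts <- dplyr::bind_rows(
    tibble::tibble(channel = "A", x_um = ax, y_um = ay, role = "pair",
                   pair_id = seq_len(n), component = comp),
    tibble::tibble(channel = "B", x_um = bx, y_um = by, role = "pair",
                   pair_id = seq_len(n), component = comp),
    tibble::tibble(channel = "A", x_um = clut[[1]][, 1], y_um = clut[[1]][, 2],
                   role = "clutter", pair_id = NA_integer_,
                   component = NA_integer_),
    tibble::tibble(channel = "B", x_um = clut[[2]][, 1], y_um = clut[[2]][, 2],
                   role = "clutter", pair_id = NA_integer_,
                   component = NA_integer_)
  )
  list(points = pts, truth = truth)
}

#' Render a point set to a noisy image
#'
#' Each point contributes a pixel-integrated 2D Gaussian PSF whose expected
#' total intensity is `photons_per_punctum`; the PSF is integrated exactly
#' over pixel areas (difference of Gaussian CDFs), so expected photon count
#' is conserved for spots away from the border. Per-pixel Poisson noise is
#' applied to signal plus background and the result is clipped to the bit
#' depth.
#'
#' @param points Data frame with columns `x_um`, `y_um` (µm), e.g. one
#'   channel of [generate_point_pattern()] output.
#' @param spec A [render_spec].
#' @param field_size Field `c(width_um, height_um)`.
#' @param channel Optional channel label for the resulting image.
#'
#' @return An [sr_image] of Poisson counts.
#' @export
render_image <- function(points, spec, field_size = c(20, 20),
                         channel = NA_character_) {
  if (!inherits(spec, "render_spec")) stop("`spec` must be a render_spec", call. = FALSE)
  pts <- as.data.frame(points)
  if (nrow(pts) > 0 && !all(c("x_um", "y_um") %in% names(pts))) {
    stop("`points` needs columns x_um and y_um", call. = FALSE)
  }
  px <- spec$pixel_size_um
  nx <- as.integer(round(field_size[1] / px))
  ny <- as.integer(round(field_size[2] / px))
  if (nrow(pts) > 0) {
    bad <- pts$x_um < 0 | pts$x_um > field_size[1] |
      pts$y_um < 0 | pts$y_um > field_size[2]
    if (any(bad)) {
      stop(sum(bad), " point(s) fall outside the raster field", call. = FALSE)
    }
  }
  expected <- matrix(0, ny, nx)
  if (nrow(pts) > 0 && spec$photons_per_punctum > 0) {
    s_px <- spec$psf_sigma_um / px
    half <- max(1L, ceiling(5 * max(s_px, 1e-6)))
    for (k in seq_len(nrow(pts))) {
      cx <- pts$x_um[k] / px   # in pixel units, 0 at left edge
      cy <- pts$y_um[k] / px
      j0 <- max(1L, floor(cx - half) + 1L); j1 <- min(nx, ceiling(cx + half))
      i0 <- max(1L, floor(cy - half) + 1L); i1 <- min(ny, ceiling(cy + half))
      if (j0 > j1 || i0 > i1) next
      if (s_px > 0) {
        fx <- stats::pnorm(j0:j1, cx, s_px) - stats::pnorm((j0:j1) - 1, cx, s_px)
        fy <- stats::pnorm(i0:i1, cy, s_px) - stats::pnorm((i0:i1) - 1, cy, s_px)
      } else {
        fx <- as.numeric((j0:j1) - 1 <= cx & cx <= (j0:j1))
        fx <- fx / max(sum(fx), 1)
        fy <- as.numeric((i0:i1) - 1 <= cy & cy <= (i0:i1))
        fy <- fy / max(sum(fy), 1)
      }
      expected[i0:i1, j0:j1] <- expected[i0:i1, j0:j1] +
        spec$photons_per_punctum * (fy %o% fx)
    }
  }
  expected <- expected + spec$background_rate
  counts <- withr::with_seed(spec$seed, {
    matrix(stats::rpois(length(expected), expected), ny, nx)
  })
  counts <- pmin(counts, 2^spec$bit_depth - 1)
  sr_image(counts, pixel_size_um = px, channel = channel)
}

#' Generate a straight-ridge junction image with known width
#'
#' Produces an image whose intensity profile perpendicular to a straight
#' vertical ridge is `baseline + amplitude * exp(-(x - x0)^2 / (2 ridge_sigma^2))`,
#' plus optional Gaussian read noise. The true full width at half maximum of
#' the ridge is returned alongside: `2 * sqrt(2 * log(2)) * ridge_sigma`.
#'
#' @param ridge_sigma_um Gaussian cross-section sigma of the ridge (µm, > 0).
#' @param amplitude Peak height above baseline (counts).
#' @param baseline Constant background level (counts).
#' @param noise_sd Gaussian noise standard deviation (counts).
#' @param spec A [render_spec] (pixel size, bit depth and seed are used).
#' @param field_size Field `c(width_um, height_um)`.
#'
#' @return A list with `image` (an [sr_image]) and `true_fwhm_um`.
#' @export
generate_junction_image <- function(ridge_sigma_um, amplitude = 100,
                                    baseline = 10, noise_sd = 0,
                                    spec = render_spec(),
                                    field_size = c(5, 5)) {
  if (!is.numeric(ridge_sigma_um) || ridge_sigma_um <= 0) {
    stop("`ridge_sigma_um` must be > 0", call. = FALSE)
  }
  px <- spec$pixel_size_um
  nx <- as.integer(round(field_size[1] / px))
  ny <- as.integer(round(field_size[2] / px))
  x <- px_centre_x(seq_len(nx), px)
  x0 <- field_size[1] / 2
  profile <- baseline + amplitude * exp(-(x - x0)^2 / (2 * ridge_sigma_um^2))
  m <- matrix(profile, ny, nx, byrow = TRUE)
  if (noise_sd > 0) {
    m <- withr::with_seed(spec$seed, {
      m + matrix(stats::rnorm(length(m), 0, noise_sd), ny, nx)
    })
  }
  m <- pmin(pmax(m, 0), 2^spec$bit_depth - 1)
  list(image = sr_image(m, pixel_size_um = px, channel = "junction"),
       true_fwhm_um = 2 * sqrt(2 * log(2)) * ridge_sigma_um)
}

#' Write a generated point pattern to CSV and its truth to JSON
#'
#' @param pattern Output of [generate_point_pattern()].
#' @param dir Output directory (created if needed).
#' @param stem File stem for `<stem>_points.csv` and `<stem>_truth.json`.
#' @return Invisibly, the two paths written.
#' @export
write_point_pattern <- function(pattern, dir, stem = "pattern") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "_points.csv"))
  js <- file.path(dir, paste0(stem, "_truth.json"))
  utils::write.csv(pattern$points, csv, row.names = FALSE)
  tr <- pattern$truth
  jsonlite::write_json(
    list(mixture = as.list(unclass(tr$mixture)), n_pairs = tr$n_pairs,
         clutter_density = tr$clutter_density, field_size = tr$field_size,
         junction_path = if (is.null(tr$junction_path)) NULL else
           as.data.frame(tr$junction_path),
         junction_jitter_um = tr$junction_jitter_um, seed = tr$seed),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(points = csv, truth = js))
}
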