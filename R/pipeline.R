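#' Configuration for the proximity pipeline
#'
#' Describes one end-to-end proximity run: where the two channel images
#' come from (paths to TIFFs, or a [synth_truth] to simulate), the
#' detection parameters, the nearest-neighbour window, the histogram bin
#' width and the fit. All parameters are recorded in the run report.
#'
#' @param images `NULL`, or a named list `list(A = path, B = path)` of
#'   TIFFs (channel A is the query channel, e.g. PIEZO1; channel B the
#'   reference, e.g. PECAM1).
#' @param truth `NULL`, or a [synth_truth] to simulate instead of reading
#'   images.
#' @param render A [render_spec] used when simulating.
#' @param masks `NULL`, or a named list of [region_mask]s (e.g.
#'   `junctional`, `non_junctional`); a separate distance sample and fit is
#'   produced per mask in addition to the whole-field one.
#' @param blur_sigma_um Preprocessing Gaussian sigma (µm); default 0.015.
#' @param background_radius_px Rolling-ball radius (px); default 3.
#' @param min_area_um2,max_area_um2,circ_min,circ_max,threshold Particle
#'   filters, see [segment_particles()].
#' @param window_um Nearest-neighbour window (µm); default 0.5.
#' @param bin_width_um Histogram bin width (µm); default 0.01.
#' @param n_components Components of the distance model (1 or 2).
#' @param seed Integer seed governing simulation and any stochastic step.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @param force Overwrite existing outputs (default `FALSE`: idempotent).
#'
#' @return A list of class `proximity_config`.
#' @export
proximity_config <- function(images = NULL, truth = NULL,
                             render = render_spec(), masks = NULL,
                             blur_sigma_um = 0.015, background_radius_px = 3,
                             min_area_um2 = 0, max_area_um2 = 0.02,
                             circ_min = 0, circ_max = 1, threshold = "otsu",
                             window_um = 0.5, bin_width_um = 0.01,
                             n_components = 2, seed = 1L,
                             output_dir = NULL, force = FALSE) {
  if (is.null(images) == is.null(truth)) {
    stop("give exactly one of `images` (paths) or `truth` (simulation)",
         call. = FALSE)
  }
  if (!is.null(images)) {
    if (!all(c("A", "B") %in% names(images))) {
      stop("`images` must name channels A and B", call. = FALSE)
    }
    missing <- !vapply(images[c("A", "B")], file.exists, logical(1))
    if (any(missing)) {
      stop("image file(s) not found: ",
           paste(unlist(images[c("A", "B")])[missing], collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(truth) && !inherits(truth, "synth_truth")) {
    stop("`truth` must be a synth_truth", call. = FALSE)
  }
  if (!is.null(masks)) {
    ok <- vapply(masks, inherits, logical(1), what = "region_mask")
    if (!all(ok) || is.null(names(masks))) {
      stop("`masks` must be a named list of region_mask objects", call. = FALSE)
    }
  }
  structure(
    list(images = images, truth = truth, render = render, masks = masks,
         blur_sigma_um = blur_sigma_um,
         background_radius_px = background_radius_px,
         min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
         circ_min = circ_min, circ_max = circ_max, threshold = threshold,
         window_um = window_um, bin_width_um = bin_width_um,
         n_components = n_components, seed = as.integer(seed),
         output_dir = output_dir, force = force),
    class = "proximity_config"
  )
}

#' Run the two-channel proximity pipeline
#'
#' Executes the full analysis track on one image pair: preprocessing
#' (Gaussian blur, rolling-ball background subtraction), particle
#' segmentation with area/circularity filters and raw-image centres of
#' mass, optional region masking, windowed nearest-neighbour distances
#' from channel A to channel B, histogramming, and the two-component
#' distance-distribution fit with confidence intervals and the
#' degenerate-fit assessment. When the configuration carries a
#' [synth_truth], the image pair is simulated first and the truth is
#' echoed in the report.
#'
#' The run is deterministic given the configuration and seed; the report
#' embeds the configuration hash, the seed, every stage's parameters and
#' the package version.
#'
#' @param config A [proximity_config].
#' @return A list of class `proximity_report` with elements `particles`
#'   (tibble over both channels), `regions` (named list per region — whole
#'   field as `"all"` plus one per mask — each with `nn`, `histogram`,
#'   `fit`), `truth` (if simulated), `config`, `config_hash`, `seed`,
#'   `stages` (parameter log tibble), `warnings`, `package_version`.
#' @export
run_proximity_pipeline <- function(config) {
  stopifnot(inherits(config, "proximity_config"))
  warns <- character(0)
  if (!is.null(config$truth)) {
    truth <- config$truth
    pat <- generate_point_pattern(truth)
    # points displaced beyond the field are not acquired
    in_field <- pat$points$x_um >= 0 & pat$points$x_um <= truth$field_size[1] &
      pat$points$y_um >= 0 & pat$points$y_um <= truth$field_size[2]
    if (any(!in_field)) {
      warns <- c(warns, sprintf("%d point(s) fell outside the imaged field",
                                sum(!in_field)))
    }
    pts <- pat$points[in_field, ]
    spec_a <- config$render; spec_a$seed <- config$seed
    spec_b <- config$render; spec_b$seed <- config$seed + 1L
    img <- list(
      A = render_image(dplyr::filter(pts, .data$channel == "A"),
                       spec_a, truth$field_size, channel = "A"),
      B = render_image(dplyr::filter(pts, .data$channel == "B"),
                       spec_b, truth$field_size, channel = "B")
    )
  } else {
    truth <- NULL
    img <- list(A = read_image_tiff(config$images$A, channel = "A"),
                B = read_image_tiff(config$images$B, channel = "B"))
  }

  particles <- purrr::imap(img, function(im, ch) {
    pre <- gaussian_blur(im, config$blur_sigma_um)
    pre <- subtract_background(pre, config$background_radius_px)
    p <- segment_particles(pre, im,
                           min_area_um2 = config$min_area_um2,
                           max_area_um2 = config$max_area_um2,
                           circ_min = config$circ_min,
                           circ_max = config$circ_max,
                           threshold = config$threshold)
    p$channel <- ch
    p
  })

  regions <- list(all = NULL)
  if (!is.null(config$masks)) for (nm in names(config$masks)) regions[nm] <- list(NULL)
  regions <- purrr::imap(regions, function(., nm) {
    pa <- particles$A; pb <- particles$B
    if (nm != "all") {
      pa <- apply_region_mask(pa, config$masks[[nm]])
      pb <- apply_region_mask(pb, config$masks[[nm]])
    }
    nn <- nearest_neighbour_distances(pa, pb, window_um = config$window_um)
    if (nn$n_excluded > 0) {
      warns <<- c(warns, sprintf("region %s: %d quer%s had no neighbour in window",
                                 nm, nn$n_excluded,
                                 if (nn$n_excluded == 1) "y" else "ies"))
    }
    if (nrow(nn$distances) == 0) {
      warns <<- c(warns, sprintf("region %s: no distances; fit skipped", nm))
      return(list(nn = nn, histogram = NULL, fit = NULL))
    }
    hist <- build_histogram(nn, bin_width_um = config$bin_width_um)
    fit <- tryCatch(
      fit_distance_model(hist, n_components = config$n_components),
      error = function(e) {
        warns <<- c(warns, sprintf("region %s: fit failed (%s)", nm,
                                   conditionMessage(e)))
        NULL
      })
    if (!is.null(fit) && isTRUE(fit$degenerate)) {
      warns <<- c(warns, sprintf("region %s: degenerate fit (%s)", nm,
                                 paste(fit$offending$term, collapse = ", ")))
    }
    list(nn = nn, histogram = hist, fit = fit)
  })

  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  cfg_for_hash$force <- NULL
  stages <- tibble::tibble(
    stage = c("blur", "background", "segment", "nn", "histogram", "fit"),
    parameters = c(
      sprintf("sigma_um=%g", config$blur_sigma_um),
      sprintf("radius_px=%d", config$background_radius_px),
      sprintf("area_um2=[%g,%g], circ=[%g,%g], threshold=%s",
              config$min_area_um2, config$max_area_um2, config$circ_min,
              config$circ_max, paste(config$threshold, collapse = "")),
      sprintf("window_um=%g", config$window_um),
      sprintf("bin_width_um=%g", config$bin_width_um),
      sprintf("n_components=%d", config$n_components)
    )
  )
  report <- structure(
    list(particles = dplyr::bind_rows(particles), regions = regions,
         truth = truth, config = config,
         config_hash = rlang::hash(cfg_for_hash), seed = config$seed,
         stages = stages, warnings = warns,
         package_version = as.character(utils::packageVersion("punctaprox"))),
    class = "proximity_report"
  )
  if (!is.null(config$output_dir)) {
    write_proximity_outputs(report, config$output_dir, force = config$force)
  }
  report
}

write_proximity_outputs <- function(report, dir, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  put <- function(path, writer) {
    if (file.exists(path) && !force) return(invisible(NULL))
    writer(path)
  }
  put(file.path(dir, "particles.csv"),
      function(p) write_particles_csv(report$particles, p))
  for (nm in names(report$regions)) {
    reg <- report$regions[[nm]]
    put(file.path(dir, sprintf("distances_%s.csv", nm)), function(p) {
      utils::write.csv(reg$nn$distances["distance_um"], p, row.names = FALSE)
    })
    if (!is.null(reg$fit)) {
      put(file.path(dir, sprintf("fit_%s.json", nm)),
          function(p) write_fit_json(reg$fit, p))
    }
  }
  put(file.path(dir, "report.json"), function(p) {
    jsonlite::write_json(
      list(config_hash = report$config_hash, seed = report$seed,
           package_version = report$package_version,
           warnings = report$warnings,
           stages = report$stages),
      p, auto_unbox = TRUE, digits = NA)
  })
  invisible(dir)
}

#' @export
print.proximity_report <- function(x, ...) {
  cat(sprintf("<proximity_report> %d particles, %d region(s), seed %d\n",
              nrow(x$particles), length(x$regions), x$seed))
  for (nm in names(x$regions)) {
    fit <- x$regions[[nm]]$fit
    if (is.null(fit)) {
      cat(sprintf("  %s: no fit\n", nm))
    } else {
      cat(sprintf("  %s: mu1 = %.1f nm, mu2 = %.1f nm%s\n", nm,
                  1000 * fit$params["mu1"], 1000 * fit$params["mu2"],
                  if (fit$degenerate) " [degenerate]" else ""))
    }
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Configuration for the morphometry pipeline
#'
#' Describes a junction-morphometry run over groups of images: junction
#' width per line profile (Gaussian FWHM), organisation per trace
#' (coefficient of variance of the min-normalised profile) and
#' mask-normalised junctional intensity per image.
#'
#' @param images `NULL`, or a data frame with columns `path` (TIFF) and
#'   `group`.
#' @param junctions `NULL`, or a data frame describing synthetic junction
#'   groups with columns `group`, `ridge_sigma_um` and optionally
#'   `amplitude`, `baseline`, `noise_sd`, `n_images` (defaults 100, 10, 0,
#'   1); one straight-ridge image is generated per image with a distinct
#'   seed.
#' @param render A [render_spec] used when generating.
#' @param lines `NULL` for automatic horizontal scan lines across the field
#'   centre, or a list (one element per image) of segments
#'   `list(p0 = c(x, y), p1 = c(x, y))` in µm.
#' @param n_lines Automatic scan lines per image.
#' @param width_px Line width for profile extraction.
#' @param normalise CoV normalisation, `"min"` or `"none"`.
#' @param seed Integer seed.
#' @param output_dir Optional output directory.
#' @param force Overwrite existing outputs.
#' @return A list of class `morphometry_config`.
#' @export
morphometry_config <- function(images = NULL, junctions = NULL,
                               render = render_spec(), lines = NULL,
                               n_lines = 5, width_px = 1,
                               normalise = "min", seed = 1L,
                               output_dir = NULL, force = FALSE) {
  if (is.null(images) == is.null(junctions)) {
    stop("give exactly one of `images` or `junctions`", call. = FALSE)
  }
  if (!is.null(images)) {
    images <- tibble::as_tibble(images)
    stopifnot(all(c("path", "group") %in% names(images)))
    missing <- !file.exists(images$path)
    if (any(missing)) {
      stop("image file(s) not found: ",
           paste(images$path[missing], collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(junctions)) {
    junctions <- tibble::as_tibble(junctions)
    stopifnot(all(c("group", "ridge_sigma_um") %in% names(junctions)))
    if (!"amplitude" %in% names(junctions)) junctions$amplitude <- 100
    if (!"baseline" %in% names(junctions)) junctions$baseline <- 10
    if (!"noise_sd" %in% names(junctions)) junctions$noise_sd <- 0
    if (!"n_images" %in% names(junctions)) junctions$n_images <- 1L
  }
  structure(
    list(images = images, junctions = junctions, render = render,
         lines = lines, n_lines = n_lines, width_px = width_px,
         normalise = normalise, seed = as.integer(seed),
         output_dir = output_dir, force = force),
    class = "morphometry_config"
  )
}

#' Run the junction-morphometry pipeline
#'
#' For every image (read from disk, or generated straight-ridge junctions
#' with known width) and every scan line, extracts the line profile and
#' measures junction width as the Gaussian full width at half maximum and
#' organisation as the coefficient of variance of the min-normalised
#' trace; per image, computes the junctional intensity normalised to the
#' background outside the (dilated) junction mask.
#'
#' @param config A [morphometry_config].
#' @return A list of class `morphometry_report` with tibbles `widths`
#'   (`group`, `image_id`, `line_id`, `fwhm_um`, `true_fwhm_um` when
#'   known, `converged`), `covs` (`group`, `image_id`, `line_id`, `cov`)
#'   and `intensities` (`group`, `image_id`, `ratio`), plus provenance
#'   (`config`, `config_hash`, `seed`, `package_version`, `warnings`).
#' @export
run_morphometry_pipeline <- function(config) {
  stopifnot(inherits(config, "morphometry_config"))
  warns <- character(0)
  # assemble the image list with group labels and any known true widths
  items <- list()
  if (!is.null(config$junctions)) {
    img_counter <- 0L
    for (g in seq_len(nrow(config$junctions))) {
      row <- config$junctions[g, ]
      for (k in seq_len(row$n_images)) {
        img_counter <- img_counter + 1L
        spec <- config$render
        spec$seed <- config$seed + 1009L * img_counter
        jr <- generate_junction_image(
          ridge_sigma_um = row$ridge_sigma_um, amplitude = row$amplitude,
          baseline = row$baseline, noise_sd = row$noise_sd, spec = spec)
        items[[img_counter]] <- list(image = jr$image, group = row$group,
                                     image_id = img_counter,
                                     true_fwhm_um = jr$true_fwhm_um)
      }
    }
  } else {
    for (k in seq_len(nrow(config$images))) {
      items[[k]] <- list(image = read_image_tiff(config$images$path[k]),
                         group = config$images$group[k], image_id = k,
                         true_fwhm_um = NA_real_)
    }
  }

  widths <- list(); covs <- list(); intens <- list()
  for (it in items) {
    im <- it$image
    ext <- field_extent(im)
    segs <- if (!is.null(config$lines)) {
      config$lines[[it$image_id]]
    } else {
      # horizontal scan lines at evenly spaced heights, crossing the ridge
      ys <- ext[2] * seq_len(config$n_lines) / (config$n_lines + 1)
      lapply(ys, function(y) list(p0 = c(0, y), p1 = c(ext[1], y)))
    }
    for (li in seq_along(segs)) {
      prof <- extract_line_profile(im, segs[[li]]$p0, segs[[li]]$p1,
                                   width_px = config$width_px)
      gf <- tryCatch(gaussian_fwhm(prof), error = function(e) {
        warns <<- c(warns, sprintf("image %d line %d: %s", it$image_id, li,
                                   conditionMessage(e)))
        NULL
      })
      if (!is.null(gf)) {
        widths[[length(widths) + 1]] <- tibble::tibble(
          group = it$group, image_id = it$image_id, line_id = li,
          fwhm_um = gf$fwhm_um, true_fwhm_um = it$true_fwhm_um,
          converged = gf$converged)
      }
      cv <- tryCatch(profile_cov(prof, normalise = config$normalise),
                     error = function(e) {
                       warns <<- c(warns, sprintf("image %d line %d: %s",
                                                  it$image_id, li,
                                                  conditionMessage(e)))
                       NA_real_
                     })
      covs[[length(covs) + 1]] <- tibble::tibble(
        group = it$group, image_id = it$image_id, line_id = li, cov = cv)
    }
    ratio <- tryCatch({
      jm <- mask_from_channel(im)
      normalised_junctional_intensity(im, jm$raster, !jm$raster)
    }, error = function(e) {
      warns <<- c(warns, sprintf("image %d: %s", it$image_id,
                                 conditionMessage(e)))
      NA_real_
    })
    intens[[length(intens) + 1]] <- tibble::tibble(
      group = it$group, image_id = it$image_id, ratio = ratio)
  }

  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  cfg_for_hash$force <- NULL
  report <- structure(
    list(widths = dplyr::bind_rows(widths), covs = dplyr::bind_rows(covs),
         intensities = dplyr::bind_rows(intens), config = config,
         config_hash = rlang::hash(cfg_for_hash), seed = config$seed,
         warnings = warns,
         package_version = as.character(utils::packageVersion("punctaprox"))),
    class = "morphometry_report"
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("widths", "covs", "intensities")) {
      path <- file.path(config$output_dir, paste0(nm, ".csv"))
      if (!file.exists(path) || config$force) {
        utils::write.csv(report[[nm]], path, row.names = FALSE)
      }
    }
  }
  report
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("<morphometry_report> %d width fits, %d CoV traces, %d images\n",
              nrow(x$widths), nrow(x$covs), nrow(x$intensities)))
  if (nrow(x$widths)) {
    s <- dplyr::summarise(dplyr::group_by(x$widths, .data$group),
                          median_fwhm_um = stats::median(.data$fwhm_um))
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %s: median FWHM %.3f um\n", s$group[i],
                  s$median_fwhm_um[i]))
    }
  }
  invisible(x)
}

#' Read or write a pipeline configuration file
#'
#' Plain-list configurations round-trip to YAML or JSON (chosen by file
#' extension). Objects such as masks and synthetic truths are not
#' serialised; file-based runs are the intended use of on-disk configs.
#'
#' @param config A named list of configuration values.
#' @param path A `.yaml`/`.yml` or `.json` path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a named list.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  plain <- rapply(unclass(config), unclass, how = "replace")
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    stop("config files must be .yaml/.yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config files must be .yaml/.yml or .json", call. = FALSE)
  }
}
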