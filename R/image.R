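#' Two-dimensional fluorescence image with physical pixel size
#'
#' The basic raster container used throughout the package. Intensities are
#' stored as a plain numeric matrix (rows = y, columns = x) and every spatial
#' operator works in micrometres via the attached pixel size.
#'
#' The pixel at row `i`, column `j` (1-based) is centred at physical
#' coordinates `x = (j - 0.5) * pixel_size_um`, `y = (i - 0.5) * pixel_size_um`.
#'
#' @param data Numeric matrix of non-negative, finite intensities.
#' @param pixel_size_um Physical pixel size in micrometres per pixel (> 0).
#' @param channel Optional channel label (e.g. `"PIEZO1"`).
#'
#' @return An object of class `sr_image`.
#' @export
#' @examples
#' img <- sr_image(matrix(0, 64, 64), pixel_size_um = 0.02)
#' dim(img)
sr_image <- function(data, pixel_size_um, channel = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("image intensities must be finite", call. = FALSE)
  }
  if (any(data < 0)) {
    stop("image intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size_um = as.numeric(pixel_size_um),
         channel = as.character(channel)),
    class = "sr_image"
  )
}

#' @export
dim.sr_image <- function(x) dim(x$data)

#' @export
print.sr_image <- function(x, ...) {
  cat(sprintf(
    "<sr_image> %d x %d px @ %.4g um/px (%.3g x %.3g um)%s\n",
    nrow(x$data), ncol(x$data), x$pixel_size_um,
    ncol(x$data) * x$pixel_size_um, nrow(x$data) * x$pixel_size_um,
    if (is.na(x$channel)) "" else paste0(", channel ", x$channel)
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

is_sr_image <- function(x) inherits(x, "sr_image")

assert_sr_image <- function(x, arg = "image") {
  if (!is_sr_image(x)) stop(sprintf("`%s` must be an sr_image", arg), call. = FALSE)
  invisible(x)
}

#' Physical extent of an image
#'
#' @param image An [sr_image].
#' @return Named numeric vector `c(width_um, height_um)`.
#' @export
field_extent <- function(image) {
  assert_sr_image(image)
  c(width_um = ncol(image$data) * image$pixel_size_um,
    height_um = nrow(image$data) * image$pixel_size_um)
}

# physical x/y (um) of pixel centres, 1-based indices
px_centre_x <- function(j, pixel_size_um) (j - 0.5) * pixel_size_um
px_centre_y <- function(i, pixel_size_um) (i - 0.5) * pixel_size_um

#' Read a TIFF image with pixel-size metadata
#'
#' Reads a single-plane grayscale TIFF. The pixel size is taken, in order of
#' preference, from the `pixel_size_um` argument, from a JSON sidecar file
#' (`<path>.json` with a `pixel_size_um` field, as written by
#' [write_image_tiff()]), or from the TIFF x-resolution tag.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Optional explicit pixel size in micrometres per pixel.
#' @param channel Optional channel label.
#'
#' @return An [sr_image]. Integer sample values are preserved as counts.
#' @export
read_image_tiff <- function(path, pixel_size_um = NULL, channel = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  if (is.null(pixel_size_um)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      pixel_size_um <- meta$pixel_size_um
      if (is.na(channel) && !is.null(meta$channel)) channel <- meta$channel
    } else {
      xres <- attr(raw, "x.resolution")
      unit <- attr(raw, "resolution.unit")
      if (!is.null(xres) && is.finite(xres) && xres > 0) {
        per_um <- switch(as.character(unit %||% "inch"),
                         cm = xres / 1e4, inch = xres / 25400, xres / 1e4)
        pixel_size_um <- 1 / per_um
      }
    }
  }
  if (is.null(pixel_size_um)) {
    stop("pixel size not found in metadata; supply `pixel_size_um`", call. = FALSE)
  }
  sr_image(matrix(as.numeric(raw), nrow(raw), ncol(raw)),
           pixel_size_um = pixel_size_um, channel = channel)
}

#' Write an image to TIFF with a pixel-size sidecar
#'
#' Intensities are clipped to the bit depth and written as integer samples.
#' Because the TIFF writer used here exposes no resolution tags, the pixel
#' size (and channel label) are stored in a JSON sidecar `<path>.json`.
#'
#' @param image An [sr_image].
#' @param path Output TIFF path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, bit_depth = 16) {
  assert_sr_image(image)
  if (!bit_depth %in% c(8, 16)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  maxv <- 2^bit_depth - 1
  m <- pmin(pmax(round(image$data), 0), maxv) / maxv
  tiff::writeTIFF(m, path, bits.per.sample = bit_depth)
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um, channel = image$channel,
         bit_depth = bit_depth),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Plot an image with physical axes
#'
#' @param object An [sr_image].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sr_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$data)), col = seq_len(ncol(object$data))
  )
  df$intensity <- as.vector(t(object$data))[
    (df$row - 1) * ncol(object$data) + df$col]
  df$x_um <- px_centre_x(df$col, object$pixel_size_um)
  df$y_um <- px_centre_y(df$row, object$pixel_size_um)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  fill = "counts",
                  title = if (is.na(object$channel)) NULL else object$channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
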