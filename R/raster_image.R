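#' Raster image with physical pixel size
#'
#' The universal carrier for all measurements in exmetry: a 2D grayscale
#' intensity matrix (or a 3D stack, third dimension = plane) together with
#' the lateral pixel size in nanometres per pixel.
#'
#' Coordinate convention (used throughout the package): pixel indices are
#' 0-based with pixel centers at integers; `x` runs along columns
#' (rightward), `y` along rows (downward). A physical position in nm is
#' `index * pixel_size_nm`. The intensity at integer position `(x, y)` is
#' stored at `data[y + 1, x + 1]`.
#'
#' @param data numeric matrix (2D image) or 3D array (stack), finite and
#'   non-negative.
#' @param pixel_size_nm lateral pixel size, nm per pixel (> 0).
#' @param axial_step_nm optional plane spacing for stacks, nm.
#' @param channel optional channel label.
#' @return an object of class `raster_image`.
#' @export
raster_image <- function(data, pixel_size_nm, axial_step_nm = NULL,
                         channel = NULL) {
  if (!is.numeric(data) || !(length(dim(data)) %in% c(2L, 3L)))
    stop("`data` must be a 2D numeric matrix or a 3D array")
  if (anyNA(data) || any(!is.finite(data)))
    stop("image intensities must be finite")
  if (any(data < 0))
    stop("image intensities must be non-negative")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number")
  structure(
    list(data = data, pixel_size_nm = as.numeric(pixel_size_nm),
         axial_step_nm = axial_step_nm, channel = channel),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raster_image> %d x %d px%s, %.4g nm/px, range [%.4g, %.4g]\n",
              d[1], d[2],
              if (length(d) == 3L) sprintf(" x %d planes", d[3]) else "",
              x$pixel_size_nm, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$data)

is_raster <- function(x) inherits(x, "raster_image")

#' Number of planes of an image or stack
#' @param image a `raster_image`.
#' @return integer number of planes (1 for a plain 2D image).
#' @export
n_planes <- function(image) {
  d <- dim(image$data)
  if (length(d) == 3L) d[3] else 1L
}

as_matrix <- function(image) {
  if (is_raster(image)) {
    if (length(dim(image$data)) != 2L)
      stop("expected a single-plane image; got a stack (use preprocess(project = TRUE))")
    image$data
  } else if (is.matrix(image)) image
  else stop("expected a raster_image or matrix")
}

#' Read a grayscale TIFF image
#'
#' Reads a single- or multi-page grayscale TIFF. The pixel size is taken,
#' in order of preference, from (1) standard TIFF resolution tags, (2) an
#' ImageJ-style `description` tag, (3) a JSON sidecar written by
#' [write_image()], (4) the explicit `pixel_size_nm` argument. If none is
#' available an error is raised; there is no silent default.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_nm optional explicit pixel size (nm/px), used when the
#'   file carries no calibration.
#' @return a [raster_image()].
#' @export
read_image <- function(path, pixel_size_nm = NULL) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  pages <- tiff::readTIFF(path, info = TRUE, all = TRUE)
  if (length(pages) == 0L) stop("empty TIFF: ", path)
  if (length(dim(pages[[1]])) == 3L)
    stop("RGB/multi-sample TIFF not supported; expected grayscale: ", path)
  ps <- parse_pixel_size(attributes(pages[[1]]))
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$intensity_scale)) scale <- as.numeric(meta$intensity_scale)
    if (is.null(ps) && !is.null(meta$pixel_size_nm))
      ps <- as.numeric(meta$pixel_size_nm)
  }
  if (is.null(ps)) ps <- pixel_size_nm
  if (is.null(ps))
    stop("TIFF carries no pixel-size calibration and `pixel_size_nm` was not ",
         "supplied: ", path)
  data <- if (length(pages) == 1L) pages[[1]] else {
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
    arr
  }
  attributes(data) <- list(dim = dim(data))
  raster_image(data * scale, ps)
}

# Pixel size (nm/px) from TIFF page attributes; NULL when absent.
# Handles standard resolution tags (pixels per unit) and the ImageJ
# description dialect ("unit=..." plus resolution, or "pixelwidth=").
parse_pixel_size <- function(att) {
  desc <- att$description
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("pixel_?width=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2L) {
      unit <- regmatches(desc, regexec("unit=([a-zA-Z]+)", desc))[[1]]
      f <- if (length(unit) == 2L) unit_to_nm(unit[2]) else 1
      if (!is.null(f)) return(as.numeric(m[2]) * f)
    }
  }
  xres <- att$x.resolution
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    unit <- att$resolution.unit
    # ImageJ writes pixels-per-unit with the unit named in the description
    if (!is.null(desc) && grepl("ImageJ", desc)) {
      u <- regmatches(desc, regexec("unit=([a-zA-Z]+)", desc))[[1]]
      f <- if (length(u) == 2L) unit_to_nm(u[2]) else NULL
      if (!is.null(f)) return(f / xres)
    }
    if (!is.null(unit)) {
      f <- switch(unit, inch = 2.54e7, cm = 1e7, NULL)
      if (!is.null(f)) return(f / xres)
    }
  }
  NULL
}

unit_to_nm <- function(u) {
  switch(tolower(u),
         nm = 1, um = 1e3, micron = 1e3, micrometer = 1e3, mm = 1e6,
         cm = 1e7, inch = 2.54e7, NULL)
}

#' Write a grayscale TIFF image
#'
#' Writes 32-bit float TIFF (one page per plane). Because the linked TIFF
#' writer does not persist resolution tags, the pixel size is stored in a
#' JSON sidecar `<path>.json`, which [read_image()] picks up automatically.
#'
#' @param image a [raster_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is_raster(image))
  d <- image$data
  mx <- max(d, 1e-12)
  scaled <- d / mx  # writer requires [0,1]; scale recorded in sidecar
  pages <- if (length(dim(d)) == 3L)
    lapply(seq_len(dim(d)[3]), function(i) scaled[, , i]) else list(scaled)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(pixel_size_nm = image$pixel_size_nm, intensity_scale = mx,
         axial_step_nm = image$axial_step_nm, channel = image$channel),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
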