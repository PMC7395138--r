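#' Thick line profile
#'
#' Samples intensities along the segment `p0 -> p1` on a band
#' `thickness_px` wide, averaging across the band perpendicular to the
#' line (bilinear sampling, approximately one sample per pixel along the
#' line).
#'
#' @param image a [raster_image()] (single plane).
#' @param p0,p1 segment endpoints, `c(x, y)` in 0-based pixels.
#' @param thickness_px band thickness in pixels (>= 1); offsets are
#'   spaced 1 px apart, symmetric about the line.
#' @return a `line_profile` with `position_nm` (along-line physical
#'   positions) and `intensity`.
#' @export
thick_line_profile <- function(image, p0, p1, thickness_px = 10) {
  m <- as_matrix(image)
  if (thickness_px < 1) stop("thickness_px must be >= 1")
  pts <- rbind(p0, p1)
  if (any(pts[, 1] < 0 | pts[, 1] > ncol(m) - 1 |
          pts[, 2] < 0 | pts[, 2] > nrow(m) - 1))
    stop("profile endpoints must lie inside the image")
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len == 0) stop("degenerate profile: endpoints coincide")
  dir <- d / len
  nrm <- c(-dir[2], dir[1])
  n <- ceiling(len) + 1L
  s <- seq(0, len, length.out = n)
  offs <- seq(-(thickness_px - 1) / 2, (thickness_px - 1) / 2, by = 1)
  acc <- numeric(n)
  for (o in offs) {
    x <- p0[1] + s * dir[1] + o * nrm[1]
    y <- p0[2] + s * dir[2] + o * nrm[2]
    acc <- acc + bilinear_sample(m, x, y)
  }
  px <- if (is_raster(image)) image$pixel_size_nm else 1
  structure(list(position_nm = s * px, intensity = acc / length(offs),
                 endpoints = rbind(p0, p1), thickness_px = thickness_px,
                 pixel_size_nm = px),
            class = "line_profile")
}

#' Morphometric result summary
#'
#' @param kind measurement kind.
#' @param values_raw_nm raw (image-space) measurements, nm.
#' @param expansion_factor linear expansion factor used for correction.
#' @return a `morphometric_result` with `values_nm = values_raw_nm /
#'   expansion_factor` and summary statistics (mean, sd, median, IQR, n).
#' @export
morphometric_result <- function(kind, values_raw_nm, expansion_factor = 1) {
  v <- values_raw_nm / expansion_factor
  structure(list(kind = kind, values_raw_nm = values_raw_nm,
                 values_nm = v, expansion_factor = expansion_factor,
                 summary = list(mean = mean(v), sd = stats::sd(v),
                                median = stats::median(v),
                                iqr = stats::IQR(v), n = length(v))),
            class = "morphometric_result")
}

#' @export
print.morphometric_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<morphometric_result:%s> n = %d, mean %.1f +/- %.1f nm, median %.1f (IQR %.1f)\n",
              x$kind, s$n, s$mean, if (is.na(s$sd)) 0 else s$sd,
              s$median, s$iqr))
  invisible(x)
}

#' Peak-to-peak spacings from a line profile
#'
#' Detects local maxima with prominence at least `prominence_frac` of the
#' profile's dynamic range and a minimum separation of `min_separation`
#' samples; consecutive peak separations are divided by the expansion
#' factor and reported in nm.
#'
#' @param profile a [thick_line_profile()] result.
#' @param expansion_factor linear expansion factor.
#' @param kind label for the result (e.g. `"cristae_spacing"`).
#' @param prominence_frac peak prominence threshold as a fraction of the
#'   profile dynamic range.
#' @param min_separation minimum separation between accepted peaks, in
#'   samples.
#' @param smooth_sd Gaussian smoothing of the profile (in samples) before
#'   peak detection; symmetric, so it does not shift symmetric peaks, and
#'   it stabilises the apex position on noisy flat-topped ridges.
#' @return a [morphometric_result()].
#' @export
peak_spacing <- function(profile, expansion_factor = 1,
                         kind = "peak_spacing", prominence_frac = 0.1,
                         min_separation = 3L, smooth_sd = 1) {
  stopifnot(inherits(profile, "line_profile"))
  y <- smooth_profile(profile$intensity, smooth_sd)
  prom <- prominence_frac * diff(range(y))
  pk <- find_profile_peaks(y, prominence = prom,
                           min_separation = min_separation)
  if (length(pk) < 2L)
    stop("need at least 2 peaks to measure spacings; detected ",
         length(pk))
  pos <- refine_peaks(profile$position_nm, y, pk)
  morphometric_result(kind, diff(pos), expansion_factor)
}

# Zero-phase Gaussian smoothing of a 1D profile (reflected ends).
smooth_profile <- function(y, sd_samples) {
  if (sd_samples <= 0) return(y)
  r <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(seq(-r, r), sd = sd_samples)
  k <- k / sum(k)
  ypad <- c(rev(y[seq_len(r) + 1]), y, rev(y[length(y) - seq_len(r)]))
  as.numeric(stats::filter(ypad, k, sides = 2))[r + seq_along(y)]
}

# Parabolic sub-sample refinement of peak positions.
refine_peaks <- function(pos, y, pk) {
  step <- pos[2] - pos[1]
  vapply(pk, function(i) {
    if (i <= 1L || i >= length(y)) return(pos[i])
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom == 0) return(pos[i])
    pos[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * step
  }, numeric(1))
}

#' Euclidean two-point diameter
#'
#' Distance between two manually placed crest points (e.g. the two sides
#' of an ER tubule), converted to physical units and corrected by the
#' expansion factor.
#'
#' @param p_a,p_b points `c(x, y)` in pixels.
#' @param pixel_size_nm pixel size, nm/px.
#' @param expansion_factor linear expansion factor.
#' @return diameter in nm (specimen scale).
#' @export
two_point_diameter <- function(p_a, p_b, pixel_size_nm,
                               expansion_factor = 1) {
  if (all(p_a == p_b)) stop("coincident points")
  sqrt(sum((p_a - p_b)^2)) * pixel_size_nm / expansion_factor
}

#' Roundness of a single object
#'
#' Smooths the region, thresholds it, and computes the shape descriptor
#' roundness `4 * area / (pi * major_axis^2)` of the fitted ellipse (an
#' ellipse with the region's area and second-moment aspect ratio). For
#' an ellipse this equals the minor/major axis ratio; a circle and any
#' moment-isotropic shape (e.g. a filled square) give 1.
#'
#' @param image_region a [raster_image()] or matrix containing exactly
#'   one object.
#' @param blur_sigma_px Gaussian smoothing applied before thresholding.
#' @param threshold_method `"otsu"` (default), `"mean"`, or numeric.
#' @param descriptor `"roundness"` (default) or `"circularity"`
#'   (`4 * pi * area / perimeter^2`).
#' @return scalar descriptor value in (0, 1].
#' @export
roundness <- function(image_region, blur_sigma_px = 1,
                      threshold_method = "otsu",
                      descriptor = c("roundness", "circularity")) {
  descriptor <- match.arg(descriptor)
  m <- if (is_raster(image_region)) as_matrix(image_region)
  else image_region
  if (blur_sigma_px > 0) m <- conv_gaussian(m, blur_sigma_px, boundary = "normalized")
  mask <- binarize(m, threshold_method)
  lab <- EBImage::bwlabel(mask * 1)
  ncomp <- max(lab)
  if (ncomp == 0L) stop("no object after thresholding")
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    # tolerate threshold speckle: minor components < 2% of the largest
    if (sum(sizes > 0.02 * max(sizes)) > 1L)
      stop("expected exactly one object, found ", ncomp)
    mask <- lab == which.max(sizes)
  }
  xy <- mask_coords(mask)
  n <- nrow(xy)
  if (descriptor == "circularity") {
    per <- sum(mask_outline(mask))  # crude pixel-count perimeter
    return(4 * pi * n / per^2)
  }
  ctr <- colMeans(xy)
  d <- sweep(xy, 2, ctr)
  C <- crossprod(d) / n
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(ev[1], 0) / ev[2])
}

#' Centriole length-to-width ratio
#'
#' Each profile (pan-stain along the centriole length; specific stain
#' across its width) must show exactly two dominant peaks; the ratio of
#' the two peak-to-peak distances is the length-to-width ratio. The
#' expansion factor cancels.
#'
#' @param profile_length,profile_width [thick_line_profile()] results.
#' @param prominence_frac peak prominence threshold, fraction of dynamic
#'   range.
#' @param smooth_sd profile smoothing before peak detection, in samples
#'   (see [peak_spacing()]); the barrel walls are thick, so a broader
#'   default stabilises the apex on their flat-topped cross-sections.
#' @return scalar ratio.
#' @export
length_width_ratio <- function(profile_length, profile_width,
                               prominence_frac = 0.25, smooth_sd = 4) {
  span <- function(p, lab) {
    y <- smooth_profile(p$intensity, smooth_sd)
    pk <- find_profile_peaks(y, prominence = prominence_frac * diff(range(y)),
                             min_separation = 3L)
    if (length(pk) != 2L)
      stop("expected exactly 2 dominant peaks in the ", lab,
           " profile; detected ", length(pk))
    diff(refine_peaks(p$position_nm, y, pk))
  }
  span(profile_length, "length") / span(profile_width, "width")
}
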