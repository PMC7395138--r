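#' Segment nuclei and measure cross-sectional areas
#'
#' Otsu threshold, hole filling, connected-component labelling; components
#' below `min_area_um2` or touching the image border are discarded (border
#' exclusion avoids truncation bias).
#'
#' @param image a nuclear-stain [raster_image()].
#' @param min_area_um2 minimum accepted component area, um^2.
#' @return numeric vector of component areas in um^2.
#' @export
nuclear_areas <- function(image, min_area_um2 = 20) {
  m <- as_matrix(image)
  mask <- binarize(m, "otsu")
  mask <- EBImage::fillHull(mask * 1)
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) stop("no nuclei found after segmentation")
  px_area_um2 <- (image$pixel_size_nm / 1000)^2
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = n)
  areas <- sizes * px_area_um2
  keep <- areas >= min_area_um2 & !(seq_len(n) %in% border_labels)
  if (!any(keep))
    stop("no component survives min_area (", min_area_um2,
         " um^2) and border exclusion")
  areas[keep]
}

#' Linear expansion-factor estimate
#'
#' @param linear_factor estimated linear expansion factor.
#' @param method estimation method.
#' @param n_objects number of objects entering the estimate.
#' @param dispersion spread (sd) across objects, where available.
#' @return an `expansion_estimate`.
#' @export
expansion_estimate <- function(linear_factor,
                               method = c("nuclear_area", "landmark_crop",
                                          "registration_scale"),
                               n_objects = 1L, dispersion = NA_real_) {
  if (linear_factor <= 0) stop("linear_factor must be > 0")
  structure(list(linear_factor = linear_factor, method = match.arg(method),
                 n_objects = as.integer(n_objects), dispersion = dispersion),
            class = "expansion_estimate")
}

#' @export
print.expansion_estimate <- function(x, ...) {
  cat(sprintf("<expansion_estimate> %.3f (%s, n = %d%s)\n",
              x$linear_factor, x$method, x$n_objects,
              if (is.finite(x$dispersion))
                sprintf(", sd %.3f", x$dispersion) else ""))
  invisible(x)
}

#' Expansion factor from nuclear cross-sectional areas
#'
#' The mean post-expansion nuclear area is divided by the mean
#' non-expanded area; the square root of the ratio is the linear
#' expansion factor.
#'
#' @param pre_areas,post_areas nuclear areas (um^2) for the non-expanded
#'   and expanded samples.
#' @return an [expansion_estimate()]. `dispersion` is the sd of
#'   per-post-nucleus factors `sqrt(area / mean(pre_areas))`.
#' @export
expansion_factor <- function(pre_areas, post_areas) {
  if (length(pre_areas) == 0L || length(post_areas) == 0L)
    stop("both area lists must be nonempty")
  if (any(pre_areas <= 0) || any(post_areas <= 0))
    stop("areas must be positive")
  factor <- sqrt(mean(post_areas) / mean(pre_areas))
  per_obj <- sqrt(post_areas / mean(pre_areas))
  expansion_estimate(factor, "nuclear_area",
                     n_objects = length(pre_areas) + length(post_areas),
                     dispersion = stats::sd(per_obj))
}

#' Expansion factor from landmark crops
#'
#' The physical area of the post-expansion crop (rectangle spanned by
#' corresponding landmark features) is divided by the pre-expansion crop
#' area; the square root of the ratio is the linear expansion factor.
#'
#' @param pre_crop_px,post_crop_px crop sizes as `c(width_px, height_px)`.
#' @param pre_pixel_size_nm,post_pixel_size_nm pixel sizes of the two
#'   images.
#' @return an [expansion_estimate()].
#' @export
crop_factor <- function(pre_crop_px, post_crop_px,
                        pre_pixel_size_nm, post_pixel_size_nm) {
  if (any(pre_crop_px <= 0) || any(post_crop_px <= 0))
    stop("degenerate crop rectangle")
  a_pre <- prod(pre_crop_px) * pre_pixel_size_nm^2
  a_post <- prod(post_crop_px) * post_pixel_size_nm^2
  expansion_estimate(sqrt(a_post / a_pre), "landmark_crop", n_objects = 1L)
}

#' Convert between image-space and specimen-space quantities
#'
#' `image_to_specimen` divides a length measured in the expanded image by
#' the expansion factor (e.g. an optical PSF width to its
#' expansion-corrected effective size); `specimen_to_image` multiplies
#' (e.g. a molecular spacing to its post-expansion distance);
#' `volumetric` returns `factor^3`, the volumetric dilution (decrowding)
#' factor (`value` is ignored).
#'
#' @param value length (any unit); ignored for `"volumetric"`.
#' @param factor linear expansion factor (> 0).
#' @param direction `"image_to_specimen"`, `"specimen_to_image"` or
#'   `"volumetric"`.
#' @return converted value.
#' @export
scale_convert <- function(value, factor,
                          direction = c("image_to_specimen",
                                        "specimen_to_image", "volumetric")) {
  direction <- match.arg(direction)
  if (factor <= 0) stop("factor must be > 0")
  if (direction != "volumetric" && (is.na(value) || value < 0))
    stop("value must be >= 0")
  switch(direction,
         image_to_specimen = value / factor,
         specimen_to_image = value * factor,
         volumetric = factor^3)
}
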