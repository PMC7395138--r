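#' Background level from a structure-free region
#'
#' @param image a [raster_image()] or matrix.
#' @param roi logical/binary matrix selecting the background region.
#' @return mean intensity inside the ROI.
#' @export
background_level <- function(image, roi) {
  m <- if (is_raster(image)) as_matrix(image) else image
  if (!all(dim(roi) == dim(m))) stop("roi shape does not match image")
  sel <- roi > 0
  if (!any(sel)) stop("empty background roi")
  mean(m[sel])
}

#' Count nuclei in a nuclear-stain image
#'
#' Threshold, label connected components, keep those of at least
#' `min_size` pixels. With `split = TRUE`, touching nuclei are separated
#' by a watershed on the distance transform before counting (emulating
#' the manual merge correction applied to automatic object counts).
#'
#' @param image a [raster_image()] or matrix.
#' @param min_size minimum component size in pixels.
#' @param split watershed-split touching blobs.
#' @param threshold_method passed to the binarization.
#' @return integer count (0 allowed).
#' @export
count_nuclei <- function(image, min_size = 9L, split = FALSE,
                         threshold_method = "otsu") {
  m <- if (is_raster(image)) as_matrix(image) else image
  if (diff(range(m)) == 0) return(0L)
  mask <- binarize(m, threshold_method)
  if (!any(mask)) return(0L)
  lab <- if (split)
    EBImage::watershed(EBImage::distmap(mask * 1), tolerance = 1)
  else EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  sum(sizes >= min_size)
}

#' Background-corrected total fluorescence signal
#'
#' Computes the total fluorescence signal (TFS) of a field of view,
#' background-corrected pixelwise before totalling, exposure-corrected,
#' and normalised per cell, per ROI, or per mask area:
#' * `per_cell` — totals over the whole field and divides by the cell
#'   count;
#' * `per_roi` — the mean background-corrected signal inside the ROI
#'   multiplied by the ROI area (um^2), i.e. the ROI total expressed in
#'   physical area units;
#' * `per_mask_area` — the ROI total divided by the area (um^2) of a
#'   structure mask (e.g. a mitochondria mask from a companion channel).
#' All modes divide by the exposure time in ms.
#'
#' @param image a [raster_image()].
#' @param mode `"per_cell"`, `"per_roi"` or `"per_mask_area"`.
#' @param background background level (e.g. from [background_level()]).
#' @param n_cells cell count (`per_cell` mode).
#' @param roi binary matrix: region to total over (`per_roi` and
#'   `per_mask_area`; defaults to the whole field).
#' @param mask binary matrix: structure mask (`per_mask_area` mode).
#' @param exposure_ms camera exposure time, ms (> 0).
#' @return a `field_measurement` with `total_signal` (background
#'   corrected), `normalized_signal`, and the inputs used.
#' @export
total_signal <- function(image, mode = c("per_cell", "per_roi",
                                         "per_mask_area"),
                         background = 0, n_cells = NULL, roi = NULL,
                         mask = NULL, exposure_ms = 1) {
  mode <- match.arg(mode)
  stopifnot(is_raster(image))
  if (exposure_ms <= 0) stop("exposure_ms must be > 0")
  m <- as_matrix(image)
  px_area_um2 <- (image$pixel_size_nm / 1000)^2
  corr <- m - background
  if (mode == "per_cell") {
    if (is.null(n_cells) || n_cells < 1) stop("n_cells must be >= 1")
    total <- sum(corr)
    norm <- total / n_cells / exposure_ms
    denom <- list(n_cells = n_cells)
  } else {
    sel <- if (is.null(roi)) matrix(TRUE, nrow(m), ncol(m)) else roi > 0
    if (!any(sel)) stop("empty roi")
    total <- sum(corr[sel])
    if (mode == "per_roi") {
      roi_area <- sum(sel) * px_area_um2
      norm <- total / exposure_ms
      denom <- list(roi_area_um2 = roi_area)
    } else {
      if (is.null(mask)) stop("per_mask_area mode requires a mask")
      mask_area <- sum(mask > 0) * px_area_um2
      if (mask_area == 0) stop("empty mask")
      norm <- total / mask_area / exposure_ms
      denom <- list(mask_area_um2 = mask_area)
    }
  }
  structure(c(list(total_signal = total, background_level = background,
                   normalized_signal = norm, exposure_time_ms = exposure_ms,
                   mode = mode), denom),
            class = "field_measurement")
}

#' Subtract channel bleedthrough
#'
#' Removes the leakage of channel B into channel A by subtracting a
#' constant fraction of B; negative results are clipped to 0.
#'
#' @param channel_a,channel_b [raster_image()]s of the same shape.
#' @param fraction mixing fraction (>= 0).
#' @return corrected channel A as a [raster_image()].
#' @export
bleedthrough_subtract <- function(channel_a, channel_b, fraction) {
  stopifnot(is_raster(channel_a), is_raster(channel_b))
  if (fraction < 0) stop("fraction must be >= 0")
  a <- channel_a$data; b <- channel_b$data
  if (!all(dim(a) == dim(b))) stop("channel shapes do not match")
  raster_image(pmax(a - fraction * b, 0), channel_a$pixel_size_nm,
               channel = channel_a$channel)
}

#' Compare two measurement groups with an unpaired two-tailed t-test
#'
#' Classical unpaired two-tailed t-test, pooled variance by default
#' (Welch optional). Also reports the group means and their ratio, the
#' quantity of interest for retention statements.
#'
#' @param values_1,values_2 numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal variance) variant.
#' @return a list with `t`, `p`, `means`, `ratio` (mean1/mean2), `n`.
#' @export
compare_groups <- function(values_1, values_2, welch = FALSE) {
  if (length(values_1) < 2L || length(values_2) < 2L)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(values_1, values_2, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       means = c(mean(values_1), mean(values_2)),
       ratio = mean(values_1) / mean(values_2),
       n = c(length(values_1), length(values_2)))
}
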