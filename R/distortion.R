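#' Dense deformation field
#'
#' Per-pixel residual displacement vectors on the pre-expansion image
#' grid; the output of non-rigid registration and the ground truth of the
#' phantom simulator.
#'
#' @param ux,uy matrices of x/y displacement components.
#' @param pixel_size_nm pixel size of the carrying grid, nm/px.
#' @param units units of the displacement values, `"px"` (pre-image
#'   pixels, the default used by the registration output) or `"nm"`.
#' @return a `deformation_field`.
#' @export
deformation_field <- function(ux, uy, pixel_size_nm, units = "px") {
  stopifnot(is.matrix(ux), is.matrix(uy), all(dim(ux) == dim(uy)))
  if (anyNA(ux) || anyNA(uy) || any(!is.finite(ux)) || any(!is.finite(uy)))
    stop("deformation field must be finite everywhere")
  units <- match.arg(units, c("px", "nm"))
  structure(list(ux = ux, uy = uy, pixel_size_nm = pixel_size_nm,
                 units = units),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2)
  cat(sprintf("<deformation_field> %d x %d, RMS magnitude %.3g %s\n",
              nrow(x$ux), ncol(x$ux), sqrt(mean(mag^2)), x$units))
  invisible(x)
}

#' RMS magnitude of a deformation field
#' @param field a [deformation_field()].
#' @return scalar RMS of the displacement magnitudes, in the field's units.
#' @export
field_rms <- function(field)
  sqrt(mean(field$ux^2 + field$uy^2))

#' Point set for distortion metrology
#'
#' @param coords n x 2 matrix of (x, y) coordinates in pre-image pixels
#'   (0-based, pixel centers at integers).
#' @param pixel_size_nm pixel size, nm/px.
#' @param provenance `"outline"`, `"skeleton"` or `"ground_truth"`.
#' @return a `point_set`.
#' @export
point_set <- function(coords, pixel_size_nm,
                      provenance = c("outline", "skeleton", "ground_truth")) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("point set must be nonempty")
  stopifnot(ncol(coords) == 2L)
  structure(list(coords = unname(coords),
                 pixel_size_nm = pixel_size_nm,
                 provenance = match.arg(provenance)),
            class = "point_set")
}

#' Extract structural points from an image
#'
#' Binarizes the (preprocessed) image and returns either the one-pixel
#' boundary of the foreground (`"outline"`, used for nucleus images) or
#' its one-pixel-wide medial skeleton by morphological thinning
#' (`"skeleton"`, used for filamentous structures).
#'
#' @param image a [raster_image()] (single plane).
#' @param mode `"outline"` or `"skeleton"`.
#' @param threshold_method `"otsu"` (default), `"mean"`, or a numeric
#'   threshold.
#' @return a [point_set()].
#' @export
extract_points <- function(image, mode = c("outline", "skeleton"),
                           threshold_method = "otsu") {
  mode <- match.arg(mode)
  m <- as_matrix(image)
  mask <- binarize(m, threshold_method)
  if (!any(mask))
    stop("empty foreground after thresholding (method: ",
         if (is.numeric(threshold_method)) signif(threshold_method, 4)
         else threshold_method, ")")
  res <- if (mode == "outline") mask_outline(mask) else skeletonize(mask)
  if (!any(res)) stop("no ", mode, " points after extraction")
  point_set(mask_coords(res),
            pixel_size_nm = if (is_raster(image)) image$pixel_size_nm else NA,
            provenance = mode)
}

#' Displace a point set through a deformation field
#'
#' Applies `p -> p + u(p)` with bilinear interpolation of the field
#' between grid nodes. Field and points must share the pre-image pixel
#' frame; a field in nm is converted using its pixel size.
#'
#' @param points a [point_set()].
#' @param field a [deformation_field()].
#' @return a [point_set()] of displaced coordinates.
#' @export
displace_points <- function(points, field) {
  stopifnot(inherits(points, "point_set"),
            inherits(field, "deformation_field"))
  p <- points$coords
  if (any(p[, 1] < 0 | p[, 1] > ncol(field$ux) - 1 |
          p[, 2] < 0 | p[, 2] > nrow(field$ux) - 1))
    stop("point outside the deformation field domain")
  f <- if (field$units == "nm") 1 / field$pixel_size_nm else 1
  ux <- bilinear_sample(field$ux, p[, 1], p[, 2]) * f
  uy <- bilinear_sample(field$uy, p[, 1], p[, 2]) * f
  point_set(cbind(p[, 1] + ux, p[, 2] + uy), points$pixel_size_nm,
            provenance = points$provenance)
}

#' RMS error versus measurement length
#'
#' For every (optionally subsampled) unordered pair of points, computes
#' the pre-expansion pair distance `d_i` and the distance between the
#' corresponding displaced points `d_def`; the per-pair error is
#' `|d_def - d_i|`. Pairs are binned by `d_i` and summarised per bin.
#'
#' @param points,displaced matched [point_set()]s (same length, same
#'   order); `displaced` is typically [displace_points()] output.
#' @param max_length_um maximum measurement length, micrometres
#'   (pre-expansion scale).
#' @param bin_width_um bin width, micrometres.
#' @param max_pairs cap on the number of pairs; when exceeded, a seeded
#'   uniform subsample of pairs is used. `Inf` disables subsampling.
#' @param seed seed for the pair subsample.
#' @param aggregator `"mean_abs"` (mean of `|d_def - d_i|` per bin, the
#'   default) or `"rms"` (root mean square of the per-pair errors).
#' @return an `rms_curve` data frame with columns `bin_center_um`,
#'   `mean_error_nm`, `sd_nm`, `n_pairs`, `relative_pct`.
#' @export
rms_vs_length <- function(points, displaced, max_length_um,
                          bin_width_um = 0.5, max_pairs = 2e6, seed = 1L,
                          aggregator = c("mean_abs", "rms")) {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(points, "point_set"), inherits(displaced, "point_set"))
  if (bin_width_um <= 0) stop("bin_width_um must be > 0")
  p <- points$coords; q <- displaced$coords
  if (nrow(p) != nrow(q)) stop("point sets must have equal length")
  n <- nrow(p)
  if (n < 2L) stop("need at least 2 points")
  px_um <- points$pixel_size_nm / 1000
  np_total <- n * (n - 1) / 2
  if (np_total <= max_pairs) {
    di <- as.numeric(stats::dist(p)) * px_um
    dd <- as.numeric(stats::dist(q)) * px_um
  } else {
    k <- with_seed(seed, sample_pair_indices(np_total, max_pairs))
    ij <- decode_pair_index(k, n)
    di <- sqrt((p[ij$i, 1] - p[ij$j, 1])^2 +
                 (p[ij$i, 2] - p[ij$j, 2])^2) * px_um
    dd <- sqrt((q[ij$i, 1] - q[ij$j, 1])^2 +
                 (q[ij$i, 2] - q[ij$j, 2])^2) * px_um
  }
  # pairs closer than one pixel are below the sampling scale and dropped;
  # bin edges are fixed-width from zero so bin centers do not depend on
  # the coordinate unit
  keep <- di <= max_length_um & di >= px_um & di > 0
  di <- di[keep]; dd <- dd[keep]
  if (length(di) == 0L) stop("no point pairs within max_length_um")
  err_nm <- abs(dd - di) * 1000
  edges <- seq(0, max_length_um + bin_width_um, by = bin_width_um)
  bin <- findInterval(di, edges, rightmost.closed = FALSE)
  ok <- bin >= 1 & di <= max_length_um
  bin <- bin[ok]; err_nm <- err_nm[ok]
  agg_mean <- if (aggregator == "mean_abs")
    tapply(err_nm, bin, mean) else sqrt(tapply(err_nm^2, bin, mean))
  agg_sd <- tapply(err_nm, bin, stats::sd)
  agg_n <- tapply(err_nm, bin, length)
  b <- as.integer(names(agg_mean))
  centers <- (b - 0.5) * bin_width_um
  out <- data.frame(bin_center_um = centers,
                    mean_error_nm = as.numeric(agg_mean),
                    sd_nm = as.numeric(agg_sd),
                    n_pairs = as.integer(agg_n))
  out$relative_pct <- out$mean_error_nm / (out$bin_center_um * 1000) * 100
  out <- out[order(out$bin_center_um), ]
  rownames(out) <- NULL
  attr(out, "aggregator") <- aggregator
  attr(out, "subsampled") <- np_total > max_pairs
  class(out) <- c("rms_curve", "data.frame")
  out
}

# Uniform sample of pair indices 1..np (np may exceed .Machine$integer.max;
# indices kept in double precision).
sample_pair_indices <- function(np, max_pairs) {
  if (np <= 2^31 - 2) return(sample.int(np, max_pairs))
  k <- unique(ceiling(stats::runif(ceiling(max_pairs * 1.05)) * np))
  while (length(k) < max_pairs)
    k <- unique(c(k, ceiling(stats::runif(max_pairs) * np)))
  k[seq_len(max_pairs)]
}

# Decode condensed pair index k (1-based, ordered (i<j) lexicographically
# by i) into row/col indices for n points.
decode_pair_index <- function(k, n) {
  k0 <- k - 1
  i <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k0)) / 2)
  base <- i * n - i * (i + 1) / 2
  # guard against floating point at the boundaries
  too_big <- base > k0
  i[too_big] <- i[too_big] - 1
  base <- i * n - i * (i + 1) / 2
  j <- k0 - base + i + 1
  list(i = as.integer(i + 1), j = as.integer(j + 1))
}

#' Mean relative error of an RMS curve
#'
#' Pair-count-weighted mean of the per-bin relative errors (per-bin mean
#' error divided by the bin-center measurement length).
#'
#' @param curve an `rms_curve`.
#' @param min_length_um optionally restrict to bins at or above this length.
#' @return scalar percentage.
#' @export
mean_relative_error <- function(curve, min_length_um = 0) {
  cv <- curve[curve$bin_center_um >= min_length_um, ]
  sum(cv$relative_pct * cv$n_pairs) / sum(cv$n_pairs)
}

#' @export
print.rms_curve <- function(x, ...) {
  cat(sprintf("<rms_curve> %d bins, %.2f-%.2f um, mean relative error %.3f%%\n",
              nrow(x), min(x$bin_center_um), max(x$bin_center_um),
              mean_relative_error(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot an RMS-error-versus-length curve
#'
#' Mean per-bin error (line) with standard-deviation error bars.
#'
#' @param x an `rms_curve`.
#' @param ... passed to [plot()].
#' @export
plot.rms_curve <- function(x, ...) {
  graphics::plot(x$bin_center_um, x$mean_error_nm, type = "o", col = "orange",
                 pch = 16, xlab = "measurement length (um)",
                 ylab = "error (nm)", ...)
  graphics::arrows(x$bin_center_um, pmax(x$mean_error_nm - x$sd_nm, 0),
                   x$bin_center_um, x$mean_error_nm + x$sd_nm,
                   angle = 90, code = 3, length = 0.03, col = "blue")
  invisible(x)
}

structure_presets <- function(structure_class) {
  switch(structure_class,
         nuclei = list(mode = "outline", max_length_um = 20,
                       penalty_weight = 1e-1),
         mitochondria = list(mode = "skeleton", max_length_um = 10,
                             penalty_weight = 1e-2),
         microtubules = list(mode = "skeleton", max_length_um = 8,
                             penalty_weight = 1e-2),
         stop("unknown structure class: ", structure_class))
}

#' Full distortion pipeline on a pre/post image pair
#'
#' Runs the complete distortion metrology: preprocessing, linear
#' registration of the post- to the pre-expansion image, B-spline
#' non-rigid registration of the resampled post image, extraction of
#' outline/skeleton points from the pre image, displacement of the points
#' through the measured field, and the RMS-error-versus-length summary.
#' The whole chain is run twice, once with a similarity and once with an
#' affine pre-registration.
#'
#' @param pre,post pre- and post-expansion [raster_image()]s.
#' @param structure_class `"nuclei"` (outline points, 20 um range,
#'   penalty 1e-1), `"mitochondria"` (skeleton, 10 um, 1e-2) or
#'   `"microtubules"` (skeleton, 8 um, 1e-2).
#' @param config a [registration_config()]; the structure-class penalty
#'   default is applied when `penalty_weight` is `NULL`.
#' @param blur_sigma_px Gaussian preprocessing blur for the post image.
#' @param pre_blur_sigma_px Gaussian blur for the pre image. The default
#'   (1.5 px) brings the diffraction-limited pre image and the smoothed,
#'   expansion-sharpened post image to a comparable effective resolution,
#'   which keeps apparent structure-width differences out of the
#'   non-rigid stage.
#' @param despeckle apply a 3x3 median despeckle to the post image.
#' @param transforms which linear pre-registrations to run
#'   (`"similarity"`, `"affine"`, or both).
#' @param mask optional binary matrix marking the evaluation region.
#' @param max_points cap on the number of extracted points (seeded
#'   subsample above this).
#' @param max_pairs,bin_width_um,seed passed to [rms_vs_length()].
#' @return a list with per-transform results (`similarity`, `affine`),
#'   each holding `curve`, `field`, `linear` (the fitted transform) and
#'   `expansion_factor`, plus the shared `points`.
#' @export
distortion_report <- function(pre, post,
                              structure_class = c("nuclei", "mitochondria",
                                                  "microtubules"),
                              config = registration_config(),
                              blur_sigma_px = 2, pre_blur_sigma_px = 1.5,
                              despeckle = FALSE,
                              mask = NULL, max_points = 3000,
                              max_pairs = 2e6, bin_width_um = 0.5,
                              seed = 1L,
                              transforms = c("similarity", "affine")) {
  structure_class <- match.arg(structure_class)
  transforms <- match.arg(transforms, several.ok = TRUE)
  preset <- structure_presets(structure_class)
  if (is.null(config$penalty_weight))
    config$penalty_weight <- preset$penalty_weight
  pre_p <- preprocess(pre, blur_sigma_px = pre_blur_sigma_px, mask = mask)
  post_p <- preprocess(post, blur_sigma_px = blur_sigma_px,
                       despeckle = despeckle)
  pts <- extract_points(pre_p, mode = preset$mode)
  if (nrow(pts$coords) > max_points) {
    keep <- with_seed(seed, sort(sample.int(nrow(pts$coords), max_points)))
    pts <- point_set(pts$coords[keep, ], pts$pixel_size_nm, pts$provenance)
  }
  run_one <- function(kind) {
    lin <- fit_linear(pre_p, post_p, kind = kind, config = config)
    post_reg <- resample(post_p, lin, output_dim = dim(pre_p$data))
    bs <- fit_bspline(pre_p, post_reg, config = config, mask = mask)
    disp <- displace_points(pts, bs$field)
    curve <- rms_vs_length(pts, disp, max_length_um = preset$max_length_um,
                           bin_width_um = bin_width_um,
                           max_pairs = max_pairs, seed = seed)
    list(curve = curve, field = bs$field, linear = lin,
         expansion_factor = lin$expansion_scale)
  }
  out <- lapply(stats::setNames(transforms, transforms), run_one)
  c(out, list(points = pts, structure_class = structure_class))
}

#' Write a deformation field as a two-page 32-bit TIFF
#'
#' Page 1 holds the x component, page 2 the y component. Values are
#' affinely packed into `[0, 1]` for the writer; the offset/scale and
#' pixel size are recorded in a JSON sidecar so [read_field()] restores
#' them exactly (to float precision).
#'
#' @param field a [deformation_field()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "deformation_field"))
  lo <- min(field$ux, field$uy)
  hi <- max(field$ux, field$uy)
  sc <- max(hi - lo, 1e-12)
  tiff::writeTIFF(list((field$ux - lo) / sc, (field$uy - lo) / sc),
                  path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(offset = lo, scale = sc,
                            pixel_size_nm = field$pixel_size_nm,
                            units = field$units),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a deformation field written by [write_field()]
#' @param path TIFF path.
#' @return a [deformation_field()].
#' @export
read_field <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  restore <- function(m) m * meta$scale + meta$offset
  deformation_field(restore(pages[[1]]), restore(pages[[2]]),
                    pixel_size_nm = meta$pixel_size_nm,
                    units = meta$units)
}

#' Best-fit linear transform between matched point sets
#'
#' Closed-form least-squares fit of a similarity (Procrustes/Kabsch with
#' isotropic scale) or affine transform mapping `p` onto `q`.
#'
#' @param p,q n x 2 coordinate matrices (or [point_set()]s), matched rows.
#' @param kind `"similarity"` or `"affine"`.
#' @return a [transform_model()].
#' @export
fit_point_linear <- function(p, q, kind = c("similarity", "affine")) {
  kind <- match.arg(kind)
  if (inherits(p, "point_set")) p <- p$coords
  if (inherits(q, "point_set")) q <- q$coords
  stopifnot(nrow(p) == nrow(q), nrow(p) >= 3)
  pc <- colMeans(p); qc <- colMeans(q)
  X <- sweep(p, 2, pc); Y <- sweep(q, 2, qc)
  if (kind == "similarity") {
    H <- crossprod(X, Y)
    sv <- svd(H)
    S <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% S %*% t(sv$u)
    s <- sum(diag(S) * sv$d) / sum(X^2)
    A <- s * R
  } else {
    A <- t(solve(crossprod(X), crossprod(X, Y)))
  }
  transform_model(kind, A, qc - as.numeric(A %*% pc))
}

#' Residual displacement after removing the best-fit linear transform
#'
#' Given pre-expansion points and their images under the true (or
#' measured) total deformation, fits the best linear transform and pulls
#' the mapped points back through its inverse. The result is directly
#' comparable to [displace_points()] output from a registration-derived
#' field: `rms_vs_length(points, residual_points(...))` is the
#' ground-truth distortion curve of a simulated deformation.
#'
#' @param points a [point_set()] (pre frame).
#' @param mapped n x 2 matrix or [point_set()]: the same points after the
#'   total deformation (any frame, consistent units).
#' @param kind linear model to remove, `"similarity"` or `"affine"`.
#' @return a [point_set()] in the pre frame.
#' @export
residual_points <- function(points, mapped,
                            kind = c("similarity", "affine")) {
  kind <- match.arg(kind)
  m <- if (inherits(mapped, "point_set")) mapped$coords else mapped
  lin <- fit_point_linear(points$coords, m, kind)
  back <- apply_transform(invert_transform(lin), m)
  point_set(back, points$pixel_size_nm, provenance = "ground_truth")
}
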