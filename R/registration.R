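#' Registration configuration
#'
#' @param penalty_weight bending-energy regularization weight for the
#'   B-spline stage. `NULL` lets pipeline drivers apply a structure-class
#'   default (1e-1 for dense blob-like content, 1e-2 for filamentous
#'   content); when used directly, `NULL` falls back to 1e-2.
#' @param pyramid_levels number of multiresolution levels (>= 1).
#' @param grid_spacing_px B-spline control-point spacing at full
#'   resolution, px.
#' @param max_iterations optimizer iteration cap per level.
#' @param convergence_tol relative tolerance for the optimizer.
#' @param max_metric_px cap on pixels used for the linear-fit metric at
#'   the finest level (regular stride subsampling above this).
#' @return a `registration_config`.
#' @export
registration_config <- function(penalty_weight = NULL, pyramid_levels = 3L,
                                grid_spacing_px = 32, max_iterations = 80L,
                                convergence_tol = 1e-10,
                                max_metric_px = 150000L) {
  if (!is.null(penalty_weight) && penalty_weight < 0)
    stop("penalty_weight must be >= 0")
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  structure(list(penalty_weight = penalty_weight,
                 pyramid_levels = as.integer(pyramid_levels),
                 grid_spacing_px = grid_spacing_px,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 max_metric_px = as.integer(max_metric_px),
                 metric = "ssd"),
            class = "registration_config")
}

#' Preprocess an image for registration
#'
#' Applies, in order: maximum-intensity projection (stacks), 3x3 median
#' despeckle, Gaussian blur, and masking (outside-mask pixels set to 0).
#'
#' @param image a [raster_image()] (2D, or a stack with `project = TRUE`).
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 = none).
#' @param despeckle apply a 3x3 median filter.
#' @param project maximum-project a stack to 2D.
#' @param mask optional binary matrix of the same shape as the (projected)
#'   image.
#' @return a [raster_image()]; the mask, if any, is kept in attribute
#'   `"mask"`.
#' @export
preprocess <- function(image, blur_sigma_px = 2, despeckle = FALSE,
                       project = FALSE, mask = NULL) {
  stopifnot(is_raster(image))
  d <- image$data
  if (project) {
    if (length(dim(d)) != 3L) stop("project = TRUE requires a 3D stack")
    d <- apply(d, c(1, 2), max)
  }
  if (length(dim(d)) != 2L)
    stop("input is a stack; use project = TRUE")
  if (despeckle) {
    mx <- max(d)
    d <- if (mx > 0) EBImage::medianFilter(d / mx, 1L) * mx else d
  }
  if (blur_sigma_px > 0) d <- conv_gaussian(d, blur_sigma_px, boundary = "normalized")
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(d)))
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match image shape ", paste(dim(d), collapse = "x"))
    d <- d * (mask > 0)
  }
  out <- raster_image(pmax(d, 0), image$pixel_size_nm,
                      channel = image$channel)
  attr(out, "mask") <- mask
  out
}

#' Linear spatial transform
#'
#' A similarity (uniform scale, rotation, translation) or affine (2x2
#' matrix + translation) map acting on pre-image pixel coordinates,
#' `q = A p + t`, with `q` in post-image pixel coordinates.
#'
#' @param kind `"similarity"` or `"affine"`.
#' @param A 2x2 matrix (for similarity, `s * R(theta)`).
#' @param t length-2 translation.
#' @param ... additional metadata fields stored on the object.
#' @return a `transform_model`.
#' @export
transform_model <- function(kind, A, t, ...) {
  structure(c(list(kind = kind, A = matrix(A, 2, 2), t = as.numeric(t)),
              list(...)),
            class = "transform_model")
}

#' Apply a transform to coordinates
#' @param transform a `transform_model` (linear kinds) or a
#'   `bspline_transform`.
#' @param pts n x 2 matrix of (x, y) coordinates, 0-based pixels.
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_transform <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (inherits(transform, "bspline_transform")) {
    u <- eval_bspline_u(transform, pts)
    return(pts + u)
  }
  sweep(pts %*% t(transform$A), 2, transform$t, `+`)
}

#' Invert a linear transform
#' @param transform a linear `transform_model`.
#' @return the inverse `transform_model`.
#' @export
invert_transform <- function(transform) {
  Ai <- solve(transform$A)
  transform_model(transform$kind, Ai, -as.numeric(Ai %*% transform$t))
}

#' @export
print.transform_model <- function(x, ...) {
  s <- sqrt(abs(det(x$A)))
  cat(sprintf("<transform_model:%s> scale %.4f, t = (%.2f, %.2f)%s\n",
              x$kind, s, x$t[1], x$t[2],
              if (!is.null(x$expansion_scale))
                sprintf(", expansion %.3f", x$expansion_scale) else ""))
  invisible(x)
}

znorm <- function(m) {
  s <- stats::sd(m)
  if (s == 0) stop("featureless (constant) image; cannot register")
  (m - mean(m)) / s
}

# Intensity-moment summary (centroid + second-moment matrix) of the
# above-threshold part of an image; used to initialise the linear fit.
# Otsu weighting suppresses background and noise pedestal, which would
# otherwise bias the centroid and inflate the second moments.
image_moments <- function(m) {
  th <- tryCatch(otsu_threshold(m), error = function(e) stats::median(m))
  w <- pmax(m - th, 0)
  tot <- sum(w)
  if (tot <= 0) stop("featureless image; cannot compute moments")
  nr <- nrow(m); nc <- ncol(m)
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  cx <- sum(w * xs) / tot; cy <- sum(w * ys) / tot
  dx <- xs - cx; dy <- ys - cy
  C <- matrix(c(sum(w * dx * dx), sum(w * dx * dy),
                sum(w * dx * dy), sum(w * dy * dy)), 2, 2) / tot
  list(center = c(cx, cy), C = C)
}

# Metric-grid pixel coordinates (0-based), optionally strided to a cap.
metric_grid <- function(nr, nc, max_px) {
  stride <- max(1L, ceiling(sqrt(nr * nc / max_px)))
  xs <- seq(0, nc - 1, by = stride)
  ys <- seq(0, nr - 1, by = stride)
  list(x = rep(xs, each = length(ys)), y = rep(ys, times = length(xs)))
}

# Full-res linear transform -> its expression in coordinates of a
# pyramid level downscaled by f (block centers at f*p + (f-1)/2).
transform_to_level <- function(A, t, f) {
  cc <- (f - 1) / 2
  list(A = A, t = ((A - diag(2)) %*% c(cc, cc) + t) / f)
}
transform_from_level <- function(A, t_lvl, f) {
  cc <- (f - 1) / 2
  as.numeric(f * t_lvl - (A - diag(2)) %*% c(cc, cc))
}

par_to_At <- function(par, kind) {
  if (kind == "similarity") {
    s <- exp(par[1]); th <- par[2]
    list(A = s * rot2(th), t = par[3:4])
  } else list(A = matrix(par[1:4], 2, 2), t = par[5:6])
}
At_to_par <- function(A, t, kind) {
  if (kind == "similarity") {
    s <- sqrt(abs(det(A)))
    th <- atan2(A[2, 1], A[1, 1])
    c(log(s), th, t)
  } else c(as.vector(A), t)
}

#' Fit a linear (similarity or affine) transform between image pair
#'
#' Minimises the sum of squared differences between the z-normalised
#' pre-expansion (fixed) image and the resampled post-expansion (moving)
#' image over a multiresolution pyramid. The fit is initialised from
#' intensity moments (centroid, second-moment scale and principal-axis
#' orientation; both orientation branches are tried) and refined with
#' BFGS, so it is fully deterministic.
#'
#' @param pre,post [raster_image()]s (preprocessed, single plane).
#' @param kind `"similarity"` or `"affine"`.
#' @param config a [registration_config()].
#' @return a `transform_model` mapping pre-image pixel coordinates to
#'   post-image pixel coordinates, with fields `metric` (final mean SSD),
#'   `metric_trace` (best-so-far metric values across accepted
#'   evaluations), `converged`, and `expansion_scale` (physical linear
#'   expansion factor, accounting for the two pixel sizes).
#' @export
fit_linear <- function(pre, post, kind = c("similarity", "affine"),
                       config = registration_config()) {
  kind <- match.arg(kind)
  stopifnot(is_raster(pre), is_raster(post))
  F0 <- znorm(as_matrix(pre))
  M0 <- znorm(as_matrix(post))
  mf <- image_moments(as_matrix(pre))
  mm <- image_moments(as_matrix(post))
  s0 <- (det(mm$C) / det(mf$C))^(1 / 4)
  ef <- eigen(mf$C, symmetric = TRUE)
  em <- eigen(mm$C, symmetric = TRUE)
  th0 <- atan2(em$vectors[2, 1], em$vectors[1, 1]) -
    atan2(ef$vectors[2, 1], ef$vectors[1, 1])
  # candidate orientations: the principal-axis estimate (both branches)
  # plus a coarse deterministic sweep, scored by SSD at the coarsest
  # pyramid scale where the basin of attraction is widest
  thetas <- unique(c(th0, th0 + pi, seq(0, 2 * pi, by = pi / 12)))
  cand <- lapply(thetas, function(th) {
    A <- s0 * rot2(th)
    list(A = A, t = mm$center - as.numeric(A %*% mf$center))
  })
  ssd_at <- function(A, t, Ff, Mf, f) {
    lv <- transform_to_level(A, t, f)
    g <- metric_grid(nrow(Ff), ncol(Ff), config$max_metric_px)
    q1 <- lv$A[1, 1] * g$x + lv$A[1, 2] * g$y + lv$t[1]
    q2 <- lv$A[2, 1] * g$x + lv$A[2, 2] * g$y + lv$t[2]
    inside <- q1 >= 0 & q1 <= ncol(Mf) - 1 & q2 >= 0 & q2 <= nrow(Mf) - 1
    if (sum(inside) < 16) return(Inf)
    v <- bilinear_sample(Mf, q1[inside], q2[inside])
    fv <- Ff[g$y[inside] + 1 + nrow(Ff) * g$x[inside]]
    mean((v - fv)^2)
  }
  f_init <- 2^(config$pyramid_levels - 1) * 2
  Fc <- znorm(conv_gaussian(downsample_by(F0, f_init), 1))
  Mc <- znorm(conv_gaussian(downsample_by(M0, f_init), 1))
  init <- cand[[which.min(vapply(cand, function(cc)
    ssd_at(cc$A, cc$t, Fc, Mc, f_init), numeric(1)))]]
  A <- init$A; t <- init$t
  ssd_full <- function(A, t) ssd_at(A, t, F0, M0, 1)
  trace_env <- new.env(); trace_env$best <- numeric(0)
  levels <- rev(2^(seq_len(config$pyramid_levels) - 1))
  for (f in levels) {
    Fl <- znorm(downsample_by(F0, f))
    Ml <- znorm(downsample_by(M0, f))
    g <- metric_grid(nrow(Fl), ncol(Fl), config$max_metric_px)
    fidx <- g$y + 1 + nrow(Fl) * g$x
    fv <- Fl[fidx]
    lv <- transform_to_level(A, t, f)
    par0 <- At_to_par(lv$A, lv$t, kind)
    fn <- function(par) {
      at <- par_to_At(par, kind)
      q1 <- at$A[1, 1] * g$x + at$A[1, 2] * g$y + at$t[1]
      q2 <- at$A[2, 1] * g$x + at$A[2, 2] * g$y + at$t[2]
      inside <- q1 >= 0 & q1 <= ncol(Ml) - 1 & q2 >= 0 & q2 <= nrow(Ml) - 1
      if (sum(inside) < 16) return(1e6)
      v <- bilinear_sample(Ml, q1[inside], q2[inside])
      val <- mean((v - fv[inside])^2)
      b <- trace_env$best
      trace_env$best <- c(b, if (length(b)) min(b[length(b)], val) else val)
      val
    }
    parscale <- if (kind == "similarity") c(0.02, 0.02, 1, 1)
    else c(rep(0.01, 4), 1, 1)
    opt <- stats::optim(par0, fn, method = "BFGS",
                        control = list(maxit = config$max_iterations,
                                       reltol = config$convergence_tol,
                                       parscale = parscale))
    at <- par_to_At(opt$par, kind)
    A <- at$A
    t <- transform_from_level(A, at$t, f)
  }
  final_metric <- ssd_full(A, t)
  s_px <- sqrt(abs(det(A)))
  transform_model(kind, A, t,
                  metric = final_metric,
                  metric_trace = trace_env$best,
                  converged = opt$convergence == 0,
                  pre_pixel_size_nm = pre$pixel_size_nm,
                  post_pixel_size_nm = post$pixel_size_nm,
                  expansion_scale = s_px * post$pixel_size_nm /
                    pre$pixel_size_nm)
}

#' Resample an image through a transform
#'
#' Pulls intensities of `image` through the map: the output at pre-frame
#' pixel `p` is `image` sampled (bilinearly) at `T(p)`; out-of-domain
#' pixels are filled with 0.
#'
#' @param image the moving [raster_image()] (e.g. the post-expansion
#'   image).
#' @param transform a `transform_model` or `bspline_transform` mapping
#'   output coordinates into `image` coordinates.
#' @param output_dim dimensions (rows, cols) of the output; defaults to
#'   the input's.
#' @param pixel_size_nm pixel size of the output frame; defaults to the
#'   transform's recorded pre-frame pixel size, else the input's.
#' @return a [raster_image()].
#' @export
resample <- function(image, transform, output_dim = NULL,
                     pixel_size_nm = NULL) {
  stopifnot(is_raster(image))
  m <- as_matrix(image)
  if (is.null(output_dim)) output_dim <- dim(m)
  if (is.null(pixel_size_nm))
    pixel_size_nm <- transform$pre_pixel_size_nm %||% image$pixel_size_nm
  nr <- output_dim[1]; nc <- output_dim[2]
  p <- cbind(rep(0:(nc - 1), each = nr), rep(0:(nr - 1), times = nc))
  q <- apply_transform(transform, p)
  v <- bilinear_sample(m, q[, 1], q[, 2], fill = 0)
  raster_image(matrix(pmax(v, 0), nr, nc), pixel_size_nm)
}

# ---- B-spline free-form deformation --------------------------------------

bspline_weights <- function(u) {
  u2 <- u * u; u3 <- u2 * u
  cbind((1 - 3 * u + 3 * u2 - u3) / 6,
        (3 * u3 - 6 * u2 + 4) / 6,
        (-3 * u3 + 3 * u2 + 3 * u + 1) / 6,
        u3 / 6)
}

# Precompute per-pixel control indices and tensor weights for a pixel
# coordinate set (full-res px) on a control grid with spacing h whose
# array index (2, 2) corresponds to cell 0 (control point at x = 0).
bspline_support <- function(x, y, h, ncy, ncx) {
  tx <- x / h; ty <- y / h
  ix <- floor(tx); iy <- floor(ty)
  wx <- bspline_weights(tx - ix)
  wy <- bspline_weights(ty - iy)
  n <- length(x)
  W <- matrix(0, n, 16)
  I <- matrix(0L, n, 16)
  k <- 0L
  for (a in 0:3) {       # x / column offset
    col <- ix + a + 1    # array col = i + (a - 1) + 2
    for (b in 0:3) {     # y / row offset
      k <- k + 1L
      row <- iy + b + 1
      W[, k] <- wx[, a + 1] * wy[, b + 1]
      I[, k] <- as.integer((col - 1) * ncy + row)
    }
  }
  list(W = W, I = I)
}

eval_u_component <- function(phi, sup) {
  v <- phi[sup$I]
  dim(v) <- dim(sup$I)
  rowSums(sup$W * v)
}

# Discrete bending energy of one control-grid component and its gradient.
# Curvature is measured as plain second differences of the control
# displacements (grid-cell units), so the penalty weight is expressed
# relative to the control-grid scale; its absolute meaning is
# implementation-relative, as for any B-spline registration package.
bending <- function(phi, h) {
  d2x <- phi[, c(-1, -ncol(phi))] * -2 +
    phi[, -c(1, 2)] + phi[, -c(ncol(phi) - 1, ncol(phi))]
  d2y <- phi[c(-1, -nrow(phi)), ] * -2 +
    phi[-c(1, 2), ] + phi[-c(nrow(phi) - 1, nrow(phi)), ]
  dxy <- (phi[-1, -1] - phi[-1, -ncol(phi)] -
            phi[-nrow(phi), -1] + phi[-nrow(phi), -ncol(phi)])
  h4 <- 1
  val <- (sum(d2x^2) + sum(d2y^2) + 2 * sum(dxy^2)) / length(phi)
  g <- matrix(0, nrow(phi), ncol(phi))
  nc <- ncol(phi); nr <- nrow(phi)
  g[, 2:(nc - 1)] <- g[, 2:(nc - 1)] - 2 * d2x
  g[, 1:(nc - 2)] <- g[, 1:(nc - 2)] + d2x
  g[, 3:nc] <- g[, 3:nc] + d2x
  g[2:(nr - 1), ] <- g[2:(nr - 1), ] - 2 * d2y
  g[1:(nr - 2), ] <- g[1:(nr - 2), ] + d2y
  g[3:nr, ] <- g[3:nr, ] + d2y
  g[-1, -1] <- g[-1, -1] + 2 * dxy
  g[-nr, -nc] <- g[-nr, -nc] + 2 * dxy
  g[-1, -nc] <- g[-1, -nc] - 2 * dxy
  g[-nr, -1] <- g[-nr, -1] - 2 * dxy
  list(val = val, grad = 2 * g / h4 / length(phi))
}

#' Fit a B-spline non-rigid deformation between registered images
#'
#' Optimises a cubic B-spline free-form deformation of the moving image
#' (the linearly registered post-expansion image, already resampled into
#' the pre frame) against the fixed pre-expansion image, minimising mean
#' squared intensity difference plus `penalty_weight` times a discrete
#' bending energy, coarse-to-fine, with analytic gradients (L-BFGS-B).
#' The bending energy vanishes on affine fields, so residual linear
#' mismatch left by the similarity stage is absorbed into the measured
#' field rather than suppressed.
#'
#' @param pre fixed [raster_image()].
#' @param post_linear_registered moving [raster_image()], same shape.
#' @param config a [registration_config()].
#' @param mask optional binary matrix; the metric is evaluated only
#'   inside.
#' @return a list with `transform` (a `bspline_transform`), `field` (the
#'   dense [deformation_field()] `u(p)` on the pre grid, units px), and
#'   `metric_trace`.
#' @export
fit_bspline <- function(pre, post_linear_registered,
                        config = registration_config(), mask = NULL) {
  stopifnot(is_raster(pre), is_raster(post_linear_registered))
  F0 <- znorm(as_matrix(pre))
  M0 <- znorm(as_matrix(post_linear_registered))
  if (!all(dim(F0) == dim(M0)))
    stop("pre and registered post images must have the same shape")
  lambda <- config$penalty_weight %||% 1e-2
  h <- config$grid_spacing_px
  nr <- nrow(F0); nc <- ncol(F0)
  ncy <- floor((nr - 1) / h) + 4L
  ncx <- floor((nc - 1) / h) + 4L
  phix <- matrix(0, ncy, ncx)
  phiy <- matrix(0, ncy, ncx)
  trace_best <- numeric(0)
  levels <- rev(2^(seq_len(config$pyramid_levels) - 1))
  for (f in levels) {
    Fl <- downsample_by(F0, f)
    Ml <- downsample_by(M0, f)
    maskl <- if (!is.null(mask)) downsample_by(mask * 1, f) > 0.5 else NULL
    nrl <- nrow(Fl); ncl <- ncol(Fl)
    xs <- rep(0:(ncl - 1), each = nrl)
    ys <- rep(0:(nrl - 1), times = ncl)
    xf <- f * xs + (f - 1) / 2
    yf <- f * ys + (f - 1) / 2
    sup <- bspline_support(xf, yf, h, ncy, ncx)
    Gx <- (cbind(Ml[, -1], Ml[, ncl]) - cbind(Ml[, 1], Ml[, -ncl])) / 2
    Gy <- (rbind(Ml[-1, ], Ml[nrl, ]) - rbind(Ml[1, ], Ml[-nrl, ])) / 2
    fvec <- as.numeric(Fl)
    wmask <- if (!is.null(maskl)) as.numeric(maskl) else 1
    npar <- ncy * ncx
    cost_grad <- function(par, want_grad) {
      px <- matrix(par[seq_len(npar)], ncy, ncx)
      py <- matrix(par[npar + seq_len(npar)], ncy, ncx)
      ux <- eval_u_component(px, sup) / f
      uy <- eval_u_component(py, sup) / f
      qx <- xs + ux; qy <- ys + uy
      inside <- qx >= 0 & qx <= ncl - 1 & qy >= 0 & qy <= nrl - 1
      v <- bilinear_sample(Ml, qx, qy)
      r <- (v - fvec) * inside * wmask
      nv <- max(sum(inside * wmask), 1)
      bx <- bending(px, h); by <- bending(py, h)
      val <- sum(r^2) / nv + lambda * (bx$val + by$val)
      if (!want_grad) return(val)
      gxw <- bilinear_sample(Gx, qx, qy) * r * (2 / nv) / f
      gyw <- bilinear_sample(Gy, qx, qy) * r * (2 / nv) / f
      gx_phi <- matrix(0, ncy, ncx)
      gy_phi <- matrix(0, ncy, ncx)
      for (k in 1:16) {
        wk <- sup$W[, k]; ik <- sup$I[, k]
        ax <- rowsum(gxw * wk, group = ik)
        ay <- rowsum(gyw * wk, group = ik)
        ii <- as.integer(rownames(ax))
        gx_phi[ii] <- gx_phi[ii] + ax
        gy_phi[ii] <- gy_phi[ii] + ay
      }
      list(val = val,
           grad = c(as.numeric(gx_phi + lambda * bx$grad),
                    as.numeric(gy_phi + lambda * by$grad)))
    }
    fn <- function(par) {
      val <- cost_grad(par, FALSE)
      b <- trace_best
      trace_best <<- c(b, if (length(b)) min(b[length(b)], val) else val)
      val
    }
    gr <- function(par) cost_grad(par, TRUE)$grad
    opt <- stats::optim(c(as.numeric(phix), as.numeric(phiy)), fn, gr,
                        method = "L-BFGS-B",
                        control = list(maxit = config$max_iterations))
    phix <- matrix(opt$par[seq_len(npar)], ncy, ncx)
    phiy <- matrix(opt$par[npar + seq_len(npar)], ncy, ncx)
  }
  tr <- structure(list(kind = "bspline", phi_x = phix, phi_y = phiy,
                       grid_spacing_px = h, dims = c(nr, nc),
                       pre_pixel_size_nm = pre$pixel_size_nm),
                  class = c("bspline_transform", "transform_model"))
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  supf <- bspline_support(xs, ys, h, ncy, ncx)
  ux <- matrix(0, nr, nc); uy <- matrix(0, nr, nc)
  ux[ys + 1 + nr * xs] <- eval_u_component(phix, supf)
  uy[ys + 1 + nr * xs] <- eval_u_component(phiy, supf)
  field <- deformation_field(ux, uy, pre$pixel_size_nm, units = "px")
  list(transform = tr, field = field, metric_trace = trace_best,
       final_metric = opt$value)
}

# Evaluate the B-spline displacement at arbitrary pixel coordinates.
eval_bspline_u <- function(transform, pts) {
  ncy <- nrow(transform$phi_x); ncx <- ncol(transform$phi_x)
  sup <- bspline_support(pts[, 1], pts[, 2], transform$grid_spacing_px,
                         ncy, ncx)
  cbind(eval_u_component(transform$phi_x, sup),
        eval_u_component(transform$phi_y, sup))
}
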