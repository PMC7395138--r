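#' Imaging parameters for phantom rendering
#'
#' Models a confocal acquisition: Gaussian point-spread function, constant
#' background, Poisson shot noise followed by additive Gaussian read noise.
#' Rendered intensities scale linearly with `exposure_time_ms` relative to
#' a 100 ms reference exposure.
#'
#' @param pixel_size_nm lateral pixel size, nm/px (> 0).
#' @param psf_sigma_nm standard deviation of the Gaussian PSF, nm (>= 0).
#' @param background_level constant background, arbitrary units (>= 0).
#' @param poisson_scale photons per intensity unit; 0 disables shot noise.
#' @param gaussian_read_noise_sd read-noise standard deviation (>= 0).
#' @param exposure_time_ms exposure time, ms (> 0).
#' @return an `imaging_params` object.
#' @export
imaging_params <- function(pixel_size_nm = 100, psf_sigma_nm = 150,
                           background_level = 10, poisson_scale = 1,
                           gaussian_read_noise_sd = 2,
                           exposure_time_ms = 100) {
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  if (psf_sigma_nm < 0) stop("psf_sigma_nm must be >= 0")
  if (background_level < 0 || poisson_scale < 0 || gaussian_read_noise_sd < 0)
    stop("noise parameters must be >= 0")
  if (exposure_time_ms <= 0) stop("exposure_time_ms must be > 0")
  structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 background_level = background_level,
                 poisson_scale = poisson_scale,
                 gaussian_read_noise_sd = gaussian_read_noise_sd,
                 exposure_time_ms = exposure_time_ms),
            class = "imaging_params")
}

#' Deformation specification for simulated expansion
#'
#' Forward model of the expansion step: a global linear map (isotropic
#' scale `s` times a unimodular shear/anisotropy matrix `M`) plus a smooth
#' stationary random displacement field `u`, i.e. `x -> s * M x + u(x)`.
#' `u` is a band-limited Gaussian random field (seeded random cosine
#' components with wavenumbers below `2 * pi / correlation_length`),
#' rescaled so that the RMS of its magnitude over the pre-expansion grid
#' equals `nonrigid_amplitude_nm`.
#'
#' @param scale linear expansion factor `s` (> 0).
#' @param shear 2x2 unimodular matrix (det = 1 within 1e-9).
#' @param nonrigid_amplitude_nm RMS magnitude of the residual field, nm.
#' @param nonrigid_correlation_length_nm correlation length of the field, nm.
#' @param seed integer seed for the random field.
#' @return a `deformation_spec` object.
#' @export
deformation_spec <- function(scale = 1, shear = diag(2),
                             nonrigid_amplitude_nm = 0,
                             nonrigid_correlation_length_nm = 8000,
                             seed = 1L) {
  if (scale <= 0) stop("scale must be > 0")
  shear <- matrix(as.numeric(shear), 2, 2)
  if (abs(det(shear) - 1) > 1e-9)
    stop("shear matrix must be unimodular (det = 1)")
  if (nonrigid_amplitude_nm < 0) stop("nonrigid_amplitude_nm must be >= 0")
  if (nonrigid_correlation_length_nm <= 0)
    stop("nonrigid_correlation_length_nm must be > 0")
  structure(list(scale = scale, shear = shear,
                 nonrigid_amplitude_nm = nonrigid_amplitude_nm,
                 nonrigid_correlation_length_nm = nonrigid_correlation_length_nm,
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Generate a ground-truthed synthetic specimen scene
#'
#' Builds vector geometry (ellipses, curvilinear filaments, stripe
#' families, annuli/barrels) emulating the cellular structures used for
#' expansion validation: DNA-stained nuclei, microtubule filaments,
#' mitochondria (optionally with internal cristae striping), Golgi stacks
#' of parallel cisternae, and centrioles. Every requested structural
#' parameter is recorded in the scene's `truth` element.
#'
#' @param kind one of `"nuclei"`, `"filaments"`, `"mitochondria"`,
#'   `"golgi"`, `"centriole"`.
#' @param params named list overriding kind-specific defaults, see Details.
#' @param seed integer seed; scenes are deterministic per seed.
#' @details Geometry defaults (all specimen-scale, pre-expansion nm):
#'   nuclei: `n = 3`, semi-major 4000-6000, axis ratio 0.8-1;
#'   filaments: `n = 20`, width 25;
#'   mitochondria: `n = 12`, half-width 150-250, half-length 500-2000,
#'     optional `cristae = TRUE` stripes at `cristae_spacing_nm = 85`;
#'   golgi: `n_cisternae = 4` ribbons at `spacing_nm = 64`, length 1000,
#'     thickness 25;
#'   centriole: `view = "axial"` annulus (`outer_diameter_nm = 230`,
#'     `wall_nm = 60`, `axis_ratio = 1`) or `view = "lateral"` barrel
#'     (`length_nm = 450`, `width_nm = 230`).
#'   `field_size_nm` (default `c(51200, 51200)`) sets the field of view.
#' @return a `phantom_scene`.
#' @export
make_scene <- function(kind = c("nuclei", "filaments", "mitochondria",
                                "golgi", "centriole"),
                       params = list(), seed = 1L) {
  kind <- match.arg(kind)
  fs <- params$field_size_nm %||% c(51200, 51200)
  if (length(fs) == 1L) fs <- c(fs, fs)
  prim <- list()
  truth <- list(points_nm = NULL, spacings_nm = NULL, axis_ratio = NULL,
                region_areas_um2 = NULL)
  with_seed(seed, {
    if (kind == "nuclei") {
      n <- params$n %||% 3L
      density <- params$intensity_density %||% 0.02  # au per nm^2
      margin <- min(8000, min(fs) / 3)
      placed <- matrix(0, 0, 3)  # center x, y, radius
      for (i in seq_len(n)) {
        a <- params$radius_nm %||% stats::runif(1, 4000, 6000)
        b <- if (is.null(params$radius_nm)) a * stats::runif(1, 0.8, 1) else a
        ctr <- place_disjoint(fs, margin, a + 1500, placed)
        placed <- rbind(placed, c(ctr, a + 1500))
        ang <- stats::runif(1, 0, pi)
        prim[[i]] <- list(type = "ellipse", center = ctr,
                          semi_axes = c(a, b), angle = ang,
                          intensity = pi * a * b * density)
      }
      truth$region_areas_um2 <- vapply(prim, function(p)
        pi * p$semi_axes[1] * p$semi_axes[2] / 1e6, numeric(1))
      truth$points_nm <- do.call(rbind, lapply(prim, function(p)
        ellipse_boundary(p, 50)))
    } else if (kind == "filaments") {
      n <- params$n %||% 20L
      width <- params$width_nm %||% 25
      lin_density <- params$linear_density %||% 3  # au per nm of length
      for (i in seq_len(n)) {
        pts <- random_smooth_curve(fs, margin = 3000)
        prim[[i]] <- list(type = "curve", pts = pts, width_nm = width,
                          intensity = lin_density * polyline_length(pts))
      }
      truth$points_nm <- do.call(rbind, lapply(prim, function(p)
        resample_polyline(p$pts, 100)))
    } else if (kind == "mitochondria") {
      n <- params$n %||% 12L
      density <- params$intensity_density %||% 0.03
      cristae <- isTRUE(params$cristae)
      csp <- params$cristae_spacing_nm %||% 85
      margin <- min(4000, min(fs) / 3)
      k <- 0L
      placed <- matrix(0, 0, 3)
      for (i in seq_len(n)) {
        b <- params$half_width_nm %||% stats::runif(1, 150, 250)
        a <- params$half_length_nm %||% stats::runif(1, 500, 2000)
        if (cristae && csp >= 2 * b)
          stop("inconsistent geometry: cristae spacing (", csp,
               " nm) must be smaller than the mitochondrion width (",
               2 * b, " nm)")
        ctr <- place_disjoint(fs, margin, a + 500, placed)
        placed <- rbind(placed, c(ctr, a + 500))
        ang <- stats::runif(1, 0, pi)
        k <- k + 1L
        prim[[k]] <- list(type = "ellipse", center = ctr,
                          semi_axes = c(a, b), angle = ang,
                          intensity = pi * a * b * density)
        if (cristae) {
          for (xc in seq(-a + csp, a - csp / 2, by = csp)) {
            half <- b * sqrt(max(0, 1 - (xc / a)^2)) * 0.9
            p0 <- ctr + rot2(ang) %*% c(xc, -half)
            p1 <- ctr + rot2(ang) %*% c(xc, half)
            k <- k + 1L
            prim[[k]] <- list(type = "curve",
                              pts = rbind(c(p0), c(p1)), width_nm = 20,
                              intensity = 2 * half *
                                (params$cristae_density %||% 0.15),
                              spacing_nm = csp)
          }
        }
      }
      if (cristae) truth$spacings_nm <- csp
      truth$points_nm <- do.call(rbind, lapply(prim, function(p) {
        if (p$type == "ellipse")
          major_axis_points(p, 100) else NULL
      }))
    } else if (kind == "golgi") {
      ncis <- params$n_cisternae %||% 4L
      spacing <- params$spacing_nm %||% 64
      if (spacing <= 0) stop("inconsistent geometry: spacing_nm must be > 0")
      len <- params$length_nm %||% 1000
      thick <- params$thickness_nm %||% 25
      if (thick >= spacing)
        stop("inconsistent geometry: cisterna thickness (", thick,
             " nm) must be smaller than the inter-cisternal spacing (",
             spacing, " nm)")
      ang <- params$angle %||% stats::runif(1, 0, pi)
      ctr <- params$center_nm %||% (fs / 2)
      lin_density <- params$linear_density %||% 4
      R <- rot2(ang)
      offs <- (seq_len(ncis) - (ncis + 1) / 2) * spacing
      pts_list <- list()
      for (j in seq_len(ncis)) {
        p0 <- ctr + R %*% c(-len / 2, offs[j])
        p1 <- ctr + R %*% c(len / 2, offs[j])
        prim[[j]] <- list(type = "curve", pts = rbind(c(p0), c(p1)),
                          width_nm = thick, intensity = lin_density * len,
                          spacing_nm = spacing)
        pts_list[[j]] <- resample_polyline(rbind(c(p0), c(p1)), 100)
      }
      truth$spacings_nm <- rep(spacing, ncis - 1)
      truth$points_nm <- do.call(rbind, pts_list)
    } else if (kind == "centriole") {
      view <- params$view %||% "axial"
      ctr <- params$center_nm %||% (fs / 2)
      if (view == "axial") {
        dia <- params$outer_diameter_nm %||% 230
        wall <- params$wall_nm %||% 60
        ratio <- params$axis_ratio %||% 1
        if (ratio <= 0 || ratio > 1)
          stop("inconsistent geometry: axis_ratio must be in (0, 1]")
        if (wall >= dia / 2)
          stop("inconsistent geometry: wall thicker than radius")
        a <- dia / 2; b <- a * ratio
        prim[[1]] <- list(type = "annulus", center = ctr,
                          semi_axes = c(a, b), thickness_nm = wall,
                          angle = params$angle %||% 0,
                          intensity = params$intensity %||% 5e4)
        truth$axis_ratio <- ratio
      } else {
        len <- params$length_nm %||% 450
        wid <- params$width_nm %||% 230
        wall <- params$wall_nm %||% 60
        ang <- params$angle %||% 0
        R <- rot2(ang)
        corners <- list(c(-len / 2, -wid / 2), c(len / 2, -wid / 2),
                        c(len / 2, wid / 2), c(-len / 2, wid / 2))
        sides <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
        for (j in seq_along(sides)) {
          p0 <- ctr + R %*% corners[[sides[[j]][1]]]
          p1 <- ctr + R %*% corners[[sides[[j]][2]]]
          prim[[j]] <- list(type = "curve", pts = rbind(c(p0), c(p1)),
                            width_nm = wall,
                            intensity = (params$linear_density %||% 4) *
                              sqrt(sum((p1 - p0)^2)))
        }
        truth$length_width_ratio <- len / wid
      }
    }
  })
  bad <- vapply(prim, function(p) {
    xy <- primitive_bbox(p)
    any(xy[, 1] < 0 | xy[, 1] > fs[1] | xy[, 2] < 0 | xy[, 2] > fs[2])
  }, logical(1))
  if (any(bad))
    warning(sum(bad), " primitive(s) extend beyond the field of view")
  structure(list(kind = kind, primitives = prim, field_size_nm = fs,
                 seed = as.integer(seed), truth = truth),
            class = "phantom_scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rejection-sample a center whose clearance disk does not intersect the
# already placed ones (falls back to the best of the attempts).
place_disjoint <- function(fs, margin, radius, placed, attempts = 200L) {
  best <- NULL; best_gap <- -Inf
  for (i in seq_len(attempts)) {
    ctr <- c(stats::runif(1, margin, fs[1] - margin),
             stats::runif(1, margin, fs[2] - margin))
    gap <- if (nrow(placed) == 0) Inf else
      min(sqrt((placed[, 1] - ctr[1])^2 + (placed[, 2] - ctr[2])^2) -
            placed[, 3] - radius)
    if (gap >= 0) return(ctr)
    if (gap > best_gap) { best_gap <- gap; best <- ctr }
  }
  best
}

rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

polyline_length <- function(pts)
  sum(sqrt(rowSums(diff(pts)^2)))

# Resample a polyline at (approximately) equal arc-length spacing (nm).
resample_polyline <- function(pts, spacing_nm) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- seq(0, L, by = spacing_nm)
  cbind(stats::approx(cum, pts[, 1], xout = s)$y,
        stats::approx(cum, pts[, 2], xout = s)$y)
}

ellipse_boundary <- function(p, spacing_nm) {
  per <- pi * (3 * sum(p$semi_axes) -
                 sqrt((3 * p$semi_axes[1] + p$semi_axes[2]) *
                        (p$semi_axes[1] + 3 * p$semi_axes[2])))
  n <- max(16L, ceiling(per / spacing_nm))
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  xy <- cbind(p$semi_axes[1] * cos(t), p$semi_axes[2] * sin(t))
  sweep(xy %*% t(rot2(p$angle)), 2, p$center, `+`)
}

major_axis_points <- function(p, spacing_nm) {
  xs <- seq(-p$semi_axes[1] * 0.9, p$semi_axes[1] * 0.9, by = spacing_nm)
  xy <- cbind(xs, 0)
  sweep(xy %*% t(rot2(p$angle)), 2, p$center, `+`)
}

random_smooth_curve <- function(fs, margin, step_nm = 400,
                                turn_sd = 0.12) {
  p <- c(stats::runif(1, margin, fs[1] - margin),
         stats::runif(1, margin, fs[2] - margin))
  theta <- stats::runif(1, 0, 2 * pi)
  n_steps <- ceiling(1.2 * max(fs) / step_nm)
  pts <- matrix(0, n_steps + 1, 2)
  pts[1, ] <- p
  for (i in seq_len(n_steps)) {
    theta <- theta + stats::rnorm(1, 0, turn_sd)
    cand <- p + step_nm * c(cos(theta), sin(theta))
    # steer back into the field when approaching the margin
    if (cand[1] < margin || cand[1] > fs[1] - margin ||
        cand[2] < margin || cand[2] > fs[2] - margin) {
      to_ctr <- atan2(fs[2] / 2 - p[2], fs[1] / 2 - p[1])
      theta <- to_ctr + stats::rnorm(1, 0, 0.3)
      cand <- p + step_nm * c(cos(theta), sin(theta))
    }
    p <- cand
    pts[i + 1, ] <- p
  }
  pts
}

primitive_bbox <- function(p) {
  switch(p$type,
         ellipse = ,
         annulus = {
           r <- max(p$semi_axes)
           rbind(p$center - r, p$center + r)
         },
         curve = {
           w <- p$width_nm / 2
           rbind(apply(p$pts, 2, min) - w, apply(p$pts, 2, max) + w)
         })
}

# Sample points (nm) with weights summing to the primitive intensity.
sample_primitive <- function(p, spacing_nm) {
  if (p$type %in% c("ellipse", "annulus")) {
    a <- p$semi_axes[1]; b <- p$semi_axes[2]
    gx <- seq(-a, a, length.out = max(3L, ceiling(2 * a / spacing_nm) + 1L))
    gy <- seq(-b, b, length.out = max(3L, ceiling(2 * b / spacing_nm) + 1L))
    g <- expand.grid(x = gx, y = gy)
    r2 <- (g$x / a)^2 + (g$y / b)^2
    keep <- r2 <= 1
    if (p$type == "annulus") {
      ai <- max(a - p$thickness_nm, 0); bi <- max(b - p$thickness_nm, 0)
      keep <- keep & ((g$x / max(ai, 1e-9))^2 + (g$y / max(bi, 1e-9))^2 > 1)
    }
    g <- g[keep, , drop = FALSE]
    xy <- sweep(as.matrix(g) %*% t(rot2(p$angle)), 2, p$center, `+`)
  } else if (p$type == "curve") {
    ctr <- resample_polyline(p$pts, spacing_nm / 2)
    if (nrow(ctr) < 2) ctr <- p$pts
    tang <- rbind(ctr[2, ] - ctr[1, ], diff(ctr))
    tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
    nrm <- cbind(-tang[, 2], tang[, 1])
    offs <- if (p$width_nm > spacing_nm)
      seq(-p$width_nm / 2, p$width_nm / 2, by = spacing_nm / 2) else 0
    xy <- do.call(rbind, lapply(offs, function(o) ctr + o * nrm))
  } else stop("unknown primitive type: ", p$type)
  if (nrow(xy) == 0L) stop("primitive produced no sample points")
  list(xy = xy, w = rep(p$intensity / nrow(xy), nrow(xy)))
}

scene_points <- function(scene, spacing_nm) {
  samples <- lapply(scene$primitives, sample_primitive,
                    spacing_nm = spacing_nm)
  list(xy = do.call(rbind, lapply(samples, `[[`, "xy")),
       w = unlist(lapply(samples, `[[`, "w")))
}

#' Total intensity of a scene's primitives
#' @param scene a `phantom_scene`.
#' @return sum of primitive intensities (arbitrary units).
#' @export
scene_intensity <- function(scene)
  sum(vapply(scene$primitives, `[[`, numeric(1), "intensity"))

# Rasterize pre-positioned sample points into an image and push them
# through the acquisition model.
render_points <- function(xy_nm, w, imaging, dims_px, seed) {
  px <- imaging$pixel_size_nm
  raw <- bilinear_splat(dims_px[1], dims_px[2],
                        xy_nm[, 1] / px, xy_nm[, 2] / px, w)
  sigma_px <- imaging$psf_sigma_nm / px
  if (sigma_px > min(dims_px)) stop("PSF sigma exceeds the image extent")
  img <- conv_gaussian(raw, sigma_px)
  expo <- imaging$exposure_time_ms / 100
  img <- (img + imaging$background_level) * expo
  with_seed(seed, {
    if (imaging$poisson_scale > 0)
      img <- matrix(stats::rpois(length(img), img * imaging$poisson_scale) /
                      imaging$poisson_scale, dims_px[1], dims_px[2])
    if (imaging$gaussian_read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0,
                                       imaging$gaussian_read_noise_sd),
                          dims_px[1], dims_px[2])
  })
  raster_image(pmax(img, 0), px)
}

#' Render a phantom scene through the acquisition model
#'
#' Rasterizes the vector primitives (conservative bilinear splatting of
#' dense sample points), convolves with the Gaussian PSF (kernel
#' normalised to integrate to 1), adds background, scales by exposure,
#' then applies Poisson and Gaussian noise in that order.
#'
#' @param scene a `phantom_scene`.
#' @param imaging an [imaging_params()].
#' @param seed integer seed for the noise realisation.
#' @return a [raster_image()].
#' @export
render <- function(scene, imaging = imaging_params(), seed = 1L) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(imaging, "imaging_params"))
  dims <- rev(ceiling(scene$field_size_nm / imaging$pixel_size_nm))  # (rows, cols)
  if (any(dims < 64)) stop("field_size / pixel_size must give at least 64x64 px")
  sp <- scene_points(scene, imaging$pixel_size_nm / 2)
  render_points(sp$xy, sp$w, imaging, dims, seed)
}

# Band-limited Gaussian random displacement field as a closure u(xy_nm)
# -> n x 2 displacements (nm), plus its grid realisation used for the
# exact RMS normalisation.
make_random_field <- function(spec, grid_xy_nm) {
  if (spec$nonrigid_amplitude_nm == 0) {
    f <- function(xy) matrix(0, nrow(xy), 2)
    return(list(fun = f))
  }
  K <- 32L
  kmax <- 2 * pi / spec$nonrigid_correlation_length_nm
  comp <- with_seed(spec$seed, {
    lapply(1:2, function(cc) {
      r <- kmax * sqrt(stats::runif(K))
      th <- stats::runif(K, 0, 2 * pi)
      list(kx = r * cos(th), ky = r * sin(th),
           amp = stats::rnorm(K), phase = stats::runif(K, 0, 2 * pi))
    })
  })
  raw <- function(xy) {
    vapply(1:2, function(cc) {
      co <- comp[[cc]]
      ph <- outer(xy[, 1], co$kx) + outer(xy[, 2], co$ky) +
        rep(co$phase, each = nrow(xy))
      as.numeric(cos(ph) %*% co$amp)
    }, numeric(nrow(xy)))
  }
  u0 <- raw(grid_xy_nm)
  rms0 <- sqrt(mean(rowSums(u0^2)))
  sc <- spec$nonrigid_amplitude_nm / rms0
  list(fun = function(xy) raw(xy) * sc)
}

#' Simulate the expansion of a scene and image it post-expansion
#'
#' Maps every primitive sample point continuously through
#' `x -> s * M x + u(x)` (no image-space warping, so the ground truth is
#' interpolation-free) and renders the result with `imaging_post`.
#'
#' @param scene a `phantom_scene`.
#' @param spec a [deformation_spec()].
#' @param imaging_post an [imaging_params()] for the post-expansion
#'   acquisition. Its pixel size should be chosen so the expanded scene
#'   fits the image (e.g. roughly `scale` times the pre pixel size).
#' @param imaging_pre the pre-expansion [imaging_params()]; defines the
#'   pre grid on which the ground-truth fields are sampled.
#' @param seed seed for the post-acquisition noise realisation.
#' @return a list with elements
#'   `post` (the post-expansion [raster_image()]),
#'   `field` (the true non-rigid displacement `u` sampled on the pre
#'   grid, class `deformation_field`, units nm), and
#'   `truth` (ground truth: `map` — the exact coordinate map on nm
#'   coordinates; `residual_field` — the residual displacement
#'   `(s M)^{-1} u` on the pre grid in pre-image pixels, i.e. what an
#'   ideal non-rigid registration after a perfect linear registration
#'   would measure; `points_nm`, structural parameters, and `spec`).
#' @export
deform_scene <- function(scene, spec, imaging_post,
                         imaging_pre = imaging_params(), seed = 1L) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(spec, "deformation_spec"),
            inherits(imaging_post, "imaging_params"))
  s <- spec$scale; M <- spec$shear
  pre_px <- imaging_pre$pixel_size_nm
  pre_dims <- rev(ceiling(scene$field_size_nm / pre_px))
  gx <- (seq_len(pre_dims[2]) - 1) * pre_px
  gy <- (seq_len(pre_dims[1]) - 1) * pre_px
  grid <- cbind(rep(gx, each = pre_dims[1]), rep(gy, times = pre_dims[1]))
  fld <- make_random_field(spec, grid)
  u <- fld$fun
  A <- s * M
  map <- function(xy_nm) xy_nm %*% t(A) + u(xy_nm)
  post_field <- scene$field_size_nm * s
  post_dims <- rev(ceiling(post_field / imaging_post$pixel_size_nm))
  if (any(post_dims < 64))
    stop("post field_size / pixel_size must give at least 64x64 px")
  sp <- scene_points(scene, imaging_post$pixel_size_nm / (2 * s))
  xy_post <- map(sp$xy)
  post <- render_points(xy_post, sp$w, imaging_post, post_dims, seed)
  ug <- u(grid)
  dimg <- c(pre_dims[1], pre_dims[2])
  field_nm <- deformation_field(
    ux = matrix(ug[, 1], dimg[1], dimg[2]),
    uy = matrix(ug[, 2], dimg[1], dimg[2]),
    pixel_size_nm = pre_px, units = "nm")
  res <- t(solve(A) %*% t(ug)) / pre_px
  residual <- deformation_field(
    ux = matrix(res[, 1], dimg[1], dimg[2]),
    uy = matrix(res[, 2], dimg[1], dimg[2]),
    pixel_size_nm = pre_px, units = "px")
  truth <- c(scene$truth,
             list(map = map, residual_field = residual, spec = spec))
  list(post = post, field = field_nm, truth = truth)
}
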