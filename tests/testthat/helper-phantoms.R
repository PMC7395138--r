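# Shared fixture builders: small, fast phantom scenes and image pairs.

quiet_imaging <- function(pixel_size_nm = 100, ...)
  imaging_params(pixel_size_nm = pixel_size_nm, poisson_scale = 0,
                 gaussian_read_noise_sd = 0, ...)

# A single filled disk rendered on a dark field.
disk_image <- function(radius_nm = 5000, pixel_size_nm = 100,
                       field_nm = 30000, noise = FALSE, seed = 1) {
  sc <- make_scene("nuclei", params = list(field_size_nm = field_nm, n = 1,
                                           radius_nm = radius_nm),
                   seed = seed)
  ip <- if (noise) imaging_params(pixel_size_nm = pixel_size_nm)
  else quiet_imaging(pixel_size_nm)
  list(scene = sc, image = render(sc, ip, seed = seed))
}

# Small pre/post pair (256 px) for registration tests.
small_pair <- function(scale = 4, shear = diag(2), amplitude = 0,
                       seed = 5, kind = "mitochondria",
                       post_px = scale * 100 / 1.04) {
  sc <- make_scene(kind, params = list(field_size_nm = 25600), seed = seed)
  ip_pre <- imaging_params()
  pre <- render(sc, ip_pre, seed = 1)
  d <- deform_scene(sc,
                    deformation_spec(scale = scale, shear = shear,
                                     nonrigid_amplitude_nm = amplitude,
                                     seed = seed + 50),
                    imaging_params(pixel_size_nm = post_px),
                    imaging_pre = ip_pre, seed = 2)
  list(scene = sc, pre = pre, post = d$post, truth = d$truth)
}

# Hand-built scene holding arbitrary primitives (bypasses make_scene).
raw_scene <- function(primitives, field_size_nm = c(12800, 12800)) {
  structure(list(kind = "filaments", primitives = primitives,
                 field_size_nm = field_size_nm, seed = 0L,
                 truth = list()), class = "phantom_scene")
}

# Independent all-pairs brute-force distortion curve (the oracle for
# rms_vs_length): plain double loop, no shared code with the package.
brute_force_curve <- function(p, q, px_um, max_length_um, bin_width_um) {
  di <- c(); dd <- c()
  n <- nrow(p)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      di <- c(di, sqrt(sum((p[i, ] - p[j, ])^2)) * px_um)
      dd <- c(dd, sqrt(sum((q[i, ] - q[j, ])^2)) * px_um)
    }
  }
  keep <- di <= max_length_um & di >= px_um
  di <- di[keep]; dd <- dd[keep]
  bin <- floor(di / bin_width_um) + 1
  err <- abs(dd - di) * 1000
  data.frame(bin_center_um = (sort(unique(bin)) - 0.5) * bin_width_um,
             mean_error_nm = as.numeric(tapply(err, bin, mean)))
}
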