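test_that("scene generation is seeded-deterministic and records ground truth", {
  s1 <- make_scene("filaments", params = list(n = 20), seed = 7)
  s2 <- make_scene("filaments", params = list(n = 20), seed = 7)
  expect_identical(s1$primitives, s2$primitives)

  g <- make_scene("golgi", params = list(spacing_nm = 64, n_cisternae = 4,
                                         angle = 0), seed = 1)
  expect_equal(g$truth$spacings_nm, rep(64, 3))
  # consecutive centerline separations are exactly the requested spacing
  ys <- sort(vapply(g$primitives, function(p) p$pts[1, 2], numeric(1)))
  expect_equal(diff(ys), rep(64, 3), tolerance = 1e-12)

  cen <- make_scene("centriole", params = list(axis_ratio = 1), seed = 1)
  expect_equal(cen$primitives[[1]]$semi_axes[1],
               cen$primitives[[1]]$semi_axes[2])
  expect_equal(cen$truth$axis_ratio, 1)
})

test_that("geometrically inconsistent scene parameters are rejected by name", {
  expect_error(make_scene("golgi", params = list(spacing_nm = 30,
                                                 thickness_nm = 40)),
               "thickness")
  expect_error(make_scene("mitochondria",
                          params = list(cristae = TRUE,
                                        cristae_spacing_nm = 600,
                                        half_width_nm = 200)),
               "cristae spacing")
  expect_error(make_scene("centriole", params = list(axis_ratio = 1.7)),
               "axis_ratio")
})

test_that("rendering conserves intensity and realises the Gaussian PSF", {
  sc <- make_scene("nuclei", seed = 3)
  img <- render(sc, quiet_imaging(background_level = 10), seed = 1)
  total <- sum(img$data - 10)
  expect_lt(abs(total - scene_intensity(sc)) / scene_intensity(sc), 0.005)

  # near-point source renders as a Gaussian spot of the PSF sigma
  pt <- raw_scene(list(list(type = "ellipse", center = c(6400, 6400),
                            semi_axes = c(2, 2), angle = 0,
                            intensity = 1e4)))
  spot <- render(pt, quiet_imaging(psf_sigma_nm = 300, background_level = 0),
                 seed = 1)
  m <- spot$data
  xs <- rep(0:(ncol(m) - 1), each = nrow(m))
  ys <- rep(0:(nrow(m) - 1), times = ncol(m))
  w <- as.numeric(m) / sum(m)
  sx <- sqrt(sum(w * (xs - sum(w * xs))^2))
  sy <- sqrt(sum(w * (ys - sum(w * ys))^2))
  expect_lt(abs(sx - 3) / 3, 0.02)  # 300 nm at 100 nm/px
  expect_lt(abs(sy - 3) / 3, 0.02)

  expect_error(render(sc, imaging_params(psf_sigma_nm = 1e9)), "PSF")
})

test_that("noise model is Poisson shot noise then Gaussian read noise", {
  flat <- make_scene("filaments", params = list(n = 0), seed = 1)
  img <- render(flat, imaging_params(background_level = 50, poisson_scale = 4,
                                     gaussian_read_noise_sd = 0), seed = 3)
  v <- as.numeric(img$data)
  expect_lt(abs(var(v) - mean(v) / 4) / (mean(v) / 4), 0.05)

  i1 <- render(flat, imaging_params(), seed = 9)
  i2 <- render(flat, imaging_params(), seed = 9)
  i3 <- render(flat, imaging_params(), seed = 10)
  expect_identical(i1$data, i2$data)
  expect_false(identical(i1$data, i3$data))
})

test_that("identity deformation reproduces the pre rendering pixel-exactly", {
  sc <- make_scene("mitochondria", params = list(field_size_nm = 25600),
                   seed = 4)
  ip <- quiet_imaging()
  pre <- render(sc, ip, seed = 1)
  d <- deform_scene(sc, deformation_spec(scale = 1), ip,
                    imaging_pre = ip, seed = 1)
  expect_equal(d$post$data, pre$data, tolerance = 1e-12)
})

test_that("pure scaling multiplies every ground-truth pairwise distance", {
  sc <- make_scene("filaments", params = list(field_size_nm = 25600, n = 5),
                   seed = 2)
  d <- deform_scene(sc, deformation_spec(scale = 4),
                    imaging_params(pixel_size_nm = 400), seed = 1)
  pts <- sc$truth$points_nm[seq(1, nrow(sc$truth$points_nm), 40), ]
  mapped <- d$truth$map(pts)
  expect_equal(as.numeric(dist(mapped)), 4 * as.numeric(dist(pts)),
               tolerance = 1e-12)
})

test_that("scaling composes multiplicatively on ground-truth coordinates", {
  sc <- make_scene("filaments", params = list(field_size_nm = 25600, n = 3),
                   seed = 2)
  d1 <- deform_scene(sc, deformation_spec(scale = 2),
                     imaging_params(pixel_size_nm = 210), seed = 1)
  d2 <- deform_scene(sc, deformation_spec(scale = 3),
                     imaging_params(pixel_size_nm = 310), seed = 1)
  d6 <- deform_scene(sc, deformation_spec(scale = 6),
                     imaging_params(pixel_size_nm = 610), seed = 1)
  pts <- sc$truth$points_nm[seq(1, nrow(sc$truth$points_nm), 50), ]
  expect_equal(d2$truth$map(d1$truth$map(pts) / 2) * 2, d6$truth$map(pts),
               tolerance = 1e-9)
})

test_that("the non-rigid field realises the requested RMS amplitude", {
  sc <- make_scene("filaments", params = list(field_size_nm = 25600, n = 3),
                   seed = 2)
  d <- deform_scene(sc, deformation_spec(scale = 4,
                                         nonrigid_amplitude_nm = 200,
                                         seed = 9),
                    imaging_params(pixel_size_nm = 420), seed = 1)
  expect_lt(abs(field_rms(d$field) - 200) / 200, 0.01)
  # residual field is the linear pull-back of the imposed field
  expect_lt(abs(field_rms(d$truth$residual_field) - 200 / 4 / 100) /
              (200 / 4 / 100), 0.01)
})

test_that("true deformation fed to the distortion module closes the loop", {
  # analytic check without any registration: residual_points of a pure
  # linear map is the identity, so the curve is exactly zero
  sc <- make_scene("filaments", params = list(field_size_nm = 25600, n = 5),
                   seed = 2)
  d <- deform_scene(sc, deformation_spec(scale = 4),
                    imaging_params(pixel_size_nm = 420), seed = 1)
  pts_nm <- sc$truth$points_nm[seq(1, nrow(sc$truth$points_nm), 10), ]
  pts <- point_set(pts_nm / 100, 100, "ground_truth")
  res <- residual_points(pts, d$truth$map(pts_nm) / 100)
  curve <- rms_vs_length(pts, res, max_length_um = 10)
  expect_lt(max(curve$mean_error_nm), 1e-6)
})
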