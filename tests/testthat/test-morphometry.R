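stripe_image <- function(period_px = 10, n = 128, amplitude = 100,
                         noise_sd = 0, seed = 1) {
  xs <- matrix(rep(0:(n - 1), each = n), n, n)  # xs[r, c] = c - 1
  m <- amplitude * (1 + sin(2 * pi * xs / period_px)) / 2
  if (noise_sd > 0) {
    set.seed(seed)
    m <- m + matrix(rnorm(n * n, 0, noise_sd), n, n)
  }
  raster_image(pmax(m, 0), 1)
}

test_that("thick line profiles average across the band", {
  const <- raster_image(matrix(7, 64, 64), 100)
  pr <- thick_line_profile(const, c(5, 30), c(55, 30), 10)
  expect_true(all(abs(pr$intensity - 7) < 1e-9))

  img <- stripe_image(10)
  pr2 <- thick_line_profile(img, c(2, 60), c(120, 60), 10)
  sp <- peak_spacing(pr2, expansion_factor = 1, smooth_sd = 0)
  expect_equal(unname(sp$summary$mean), 10, tolerance = 0.02)

  expect_error(thick_line_profile(const, c(-5, 0), c(10, 10)), "inside")
  expect_error(thick_line_profile(const, c(5, 5), c(5, 5)), "degenerate")
})

test_that("thicker bands reduce profile variance without moving peaks", {
  img <- stripe_image(10, noise_sd = 15, seed = 4)
  p1 <- thick_line_profile(img, c(2, 60), c(120, 60), 1)
  p11 <- thick_line_profile(img, c(2, 60), c(120, 60), 11)
  s1 <- peak_spacing(p1, smooth_sd = 1)
  s11 <- peak_spacing(p11, smooth_sd = 1)
  expect_equal(unname(s11$summary$mean), 10, tolerance = 0.1)
  expect_equal(unname(s1$summary$mean), unname(s11$summary$mean),
               tolerance = 0.15)
  clean <- thick_line_profile(stripe_image(10), c(2, 60), c(120, 60), 1)
  expect_gt(var(p1$intensity - clean$intensity),
            4 * var(p11$intensity - clean$intensity))
})

test_that("peak spacings are corrected by the expansion factor", {
  # two Gaussians 1215 px apart at 1 nm/px, factor 14.3 -> 85.0 nm
  x <- 0:1500
  y <- exp(-(x - 100)^2 / (2 * 20^2)) + exp(-(x - 1315)^2 / (2 * 20^2))
  img <- raster_image(rbind(y, y, y, y, y), 1)
  pr <- thick_line_profile(img, c(0, 2), c(1500, 2), 3)
  sp <- peak_spacing(pr, expansion_factor = 14.3, min_separation = 50)
  expect_equal(unname(sp$summary$mean), 1215 / 14.3, tolerance = 0.01)
  expect_equal(unname(sp$summary$mean), 85.0, tolerance = 0.05)
  # correction is exactly linear in 1/factor
  sp1 <- peak_spacing(pr, expansion_factor = 1, min_separation = 50)
  expect_equal(sp$values_nm * 14.3, sp1$values_nm, tolerance = 1e-12)

  flatp <- thick_line_profile(raster_image(matrix(1, 8, 8), 1),
                              c(0, 4), c(7, 4), 3)
  expect_error(peak_spacing(flatp), "peaks")
})

test_that("two-point diameters convert px to corrected nm", {
  expect_equal(two_point_diameter(c(0, 0), c(3, 4), 100, 10), 50)
  expect_equal(two_point_diameter(c(0, 0), c(3, 4), 100, 1), 500)
  expect_error(two_point_diameter(c(1, 1), c(1, 1), 100), "oincident")
})

test_that("roundness matches the fitted-ellipse axis ratio", {
  disk <- disk_image(radius_nm = 4000, field_nm = 20000)$image
  expect_equal(roundness(disk), 1, tolerance = 0.02)

  ell <- make_scene("mitochondria",
                    params = list(field_size_nm = 30000, n = 1,
                                  half_length_nm = 4000, half_width_nm = 2000,
                                  intensity_density = 0.05), seed = 2)
  expect_equal(roundness(render(ell, quiet_imaging(), seed = 1)), 0.5,
               tolerance = 0.02)

  sq <- matrix(0, 100, 100)
  sq[30:70, 25:65] <- 1
  expect_equal(roundness(sq, blur_sigma_px = 0, threshold_method = 0.5), 1,
               tolerance = 0.02)
})

test_that("roundness is invariant under rotation and uniform scaling", {
  mk_ellipse_mask <- function(a, b, theta, n = 200) {
    xs <- rep(0:(n - 1), each = n) - (n - 1) / 2
    ys <- rep(0:(n - 1), times = n) - (n - 1) / 2
    xr <- cos(theta) * xs + sin(theta) * ys
    yr <- -sin(theta) * xs + cos(theta) * ys
    matrix(as.numeric((xr / a)^2 + (yr / b)^2 <= 1), n, n)
  }
  vals <- vapply(c(0, 0.4, 1.1), function(th)
    roundness(mk_ellipse_mask(60, 36, th), blur_sigma_px = 0,
              threshold_method = 0.5), numeric(1))
  expect_true(all(abs(vals - 0.6) < 0.02))
  scaled <- roundness(mk_ellipse_mask(30, 18, 0.4), blur_sigma_px = 0,
                      threshold_method = 0.5)
  expect_lt(abs(scaled - vals[2]), 0.02)
})

test_that("length-to-width ratio inverts when profiles are swapped", {
  x <- 0:199
  two_peaks <- function(sep) {
    y <- exp(-(x - 100 + sep / 2)^2 / 18) + exp(-(x - 100 - sep / 2)^2 / 18)
    img <- raster_image(rbind(y, y, y, y, y), 1)
    thick_line_profile(img, c(0, 2), c(199, 2), 3)
  }
  pl <- two_peaks(120); pw <- two_peaks(100)
  r <- length_width_ratio(pl, pw, smooth_sd = 1)
  expect_equal(r, 1.2, tolerance = 0.01)
  expect_equal(length_width_ratio(pw, pl, smooth_sd = 1), 1 / r,
               tolerance = 1e-9)
  expect_equal(length_width_ratio(pl, pl, smooth_sd = 1), 1, tolerance = 1e-9)
})

test_that("profile measurements are rotation invariant", {
  period <- 12
  n <- 256
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  th <- 0.5
  coord <- cos(th) * xs + sin(th) * ys
  img <- raster_image(100 * (1 + sin(2 * pi * coord / period)) / 2, 1)
  ctr <- c(128, 128)
  dirv <- c(cos(th), sin(th))
  p0 <- ctr - 60 * dirv; p1 <- ctr + 60 * dirv
  pr <- thick_line_profile(img, p0, p1, 10)
  sp <- peak_spacing(pr, smooth_sd = 0)
  expect_lt(abs(unname(sp$summary$mean) - period), 0.5)
})
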