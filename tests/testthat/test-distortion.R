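test_that("outline extraction traces the boundary of a disk", {
  img <- disk_image(radius_nm = 3000, field_nm = 12800)$image
  pts <- extract_points(img, "outline")
  ctr <- colMeans(pts$coords)
  r <- sqrt(rowSums(sweep(pts$coords, 2, ctr)^2))
  # radius in px, allowing the PSF-driven threshold bias
  expect_lt(diff(range(r)), 3)
  expect_equal(median(r), 30, tolerance = 0.1)
})

test_that("skeletonization thins a bar to its collinear medial axis", {
  m <- matrix(0, 64, 64)
  m[31:33, 10:54] <- 1  # 3 px wide horizontal bar
  pts <- extract_points(raster_image(m + 0.01, 100), "skeleton",
                        threshold_method = 0.5)
  expect_true(all(abs(pts$coords[, 2] - 31) <= 1))
  expect_gt(nrow(pts$coords), 35)
})

test_that("filament skeletons land on the true centerlines", {
  sc <- make_scene("filaments", params = list(field_size_nm = 25600, n = 6),
                   seed = 3)
  img <- render(sc, imaging_params(), seed = 1)
  pts <- extract_points(preprocess(img, blur_sigma_px = 1), "skeleton")
  truth_px <- do.call(rbind, lapply(sc$primitives, function(p)
    exmetry:::resample_polyline(p$pts, 20))) / 100
  d2 <- vapply(seq_len(nrow(pts$coords)), function(i) {
    min((truth_px[, 1] - pts$coords[i, 1])^2 +
          (truth_px[, 2] - pts$coords[i, 2])^2)
  }, numeric(1))
  # a unit-width discrete skeleton of a noisy ridge carries ~0.5 px
  # quantization; assess at the diagonal-pixel scale
  expect_gt(mean(sqrt(d2) <= 1.5), 0.9)
  expect_gt(mean(sqrt(d2) <= 1), 0.8)
})

test_that("empty foreground is reported with the threshold", {
  img <- raster_image(matrix(rep(c(1, 1.01), 50), 10, 10), 100)
  expect_error(extract_points(img, threshold_method = 99), "99")
})

test_that("point displacement applies the interpolated field exactly", {
  pts <- point_set(cbind(c(5, 10, 20.5), c(8, 16, 3.25)), 100)
  zero <- deformation_field(matrix(0, 32, 32), matrix(0, 32, 32), 100)
  expect_equal(displace_points(pts, zero)$coords, pts$coords)

  const <- deformation_field(matrix(2, 32, 32), matrix(-1, 32, 32), 100)
  expect_equal(displace_points(pts, const)$coords,
               pts$coords + rep(c(2, -1), each = 3))

  # linear field u(p) = eps * p scales all pairwise distances by 1 + eps
  xs <- matrix(rep(0:31, each = 32), 32, 32)   # xs[r, c] = c - 1
  ys <- matrix(rep(0:31, times = 32), 32, 32)  # ys[r, c] = r - 1
  lin <- deformation_field(0.05 * xs, 0.05 * ys, 100)
  disp <- displace_points(pts, lin)
  expect_equal(as.numeric(dist(disp$coords)),
               1.05 * as.numeric(dist(pts$coords)), tolerance = 1e-12)

  out <- point_set(cbind(40, 2), 100)
  expect_error(displace_points(out, zero), "outside")
})

test_that("a uniform residual scaling appears as a constant relative error", {
  set.seed(42)
  p <- cbind(runif(200, 0, 99), runif(200, 0, 99))
  pts <- point_set(p, 100)
  disp <- point_set(p * 1.03, 100)
  curve <- rms_vs_length(pts, disp, max_length_um = 10)
  # the bin-center denominator is exact only up to the within-bin spread
  # of pair distances, so restrict to bins of at least 1 um
  expect_true(all(abs(curve$relative_pct[curve$bin_center_um >= 1] - 3)
                  < 0.2))
  # per-pair relative error is exactly 3%
  expect_equal(as.numeric(dist(disp$coords)) / as.numeric(dist(pts$coords)),
               rep(1.03, 199 * 100), tolerance = 1e-12)
})

test_that("rms_vs_length equals an independent all-pairs brute force", {
  set.seed(7)
  p <- cbind(runif(100, 0, 99), runif(100, 0, 99))
  q <- p + matrix(rnorm(200, 0, 0.8), 100, 2)
  curve <- rms_vs_length(point_set(p, 100), point_set(q, 100),
                         max_length_um = 15, max_pairs = Inf)
  oracle <- brute_force_curve(p, q, 0.1, 15, 0.5)
  expect_equal(nrow(curve), nrow(oracle))
  expect_equal(curve$mean_error_nm, oracle$mean_error_nm, tolerance = 1e-12)
})

test_that("condensed pair indices decode to every unordered pair", {
  ij <- exmetry:::decode_pair_index(1:45, 10)
  expect_true(all(ij$i < ij$j))
  expect_equal(anyDuplicated(paste(ij$i, ij$j)), 0L)
  expect_equal(range(ij$i), c(1, 9))
  expect_equal(range(ij$j), c(2, 10))
})

test_that("relative error curves are invariant to the coordinate unit", {
  set.seed(3)
  p <- cbind(runif(150, 0, 99), runif(150, 0, 99))
  q <- p + matrix(rnorm(300, 0, 0.5), 150, 2)
  c1 <- rms_vs_length(point_set(p, 100), point_set(q, 100), 10)
  c2 <- rms_vs_length(point_set(p * 2, 50), point_set(q * 2, 50), 10)
  # the sub-pixel pair floor differs between units; bins above it match
  k1 <- c1$bin_center_um >= 1; k2 <- c2$bin_center_um >= 1
  expect_equal(c1$relative_pct[k1], c2$relative_pct[k2], tolerance = 1e-12)
  expect_equal(c1$n_pairs[k1], c2$n_pairs[k2])
})

test_that("seeded pair subsampling estimates the full-pair bin means", {
  set.seed(11)
  p <- cbind(runif(500, 0, 99), runif(500, 0, 99))
  q <- p + matrix(rnorm(1000, 0, 0.6), 500, 2)
  pts <- point_set(p, 100); dps <- point_set(q, 100)
  full <- rms_vs_length(pts, dps, 10, max_pairs = Inf)
  for (s in 1:3) {
    sub <- rms_vs_length(pts, dps, 10, max_pairs = 2e4, seed = s)
    expect_true(attr(sub, "subsampled"))
    m <- merge(full, sub, by = "bin_center_um")
    se <- m$sd_nm.y / sqrt(m$n_pairs.y)
    expect_true(all(abs(m$mean_error_nm.x - m$mean_error_nm.y) < 3.5 * se))
  }
})

test_that("distortion grows monotonically with the imposed amplitude", {
  sc <- make_scene("filaments", params = list(field_size_nm = 25600, n = 8),
                   seed = 3)
  pts_nm <- sc$truth$points_nm[seq(1, nrow(sc$truth$points_nm), 4), ]
  pts <- point_set(pts_nm / 100, 100, "ground_truth")
  auc <- vapply(c(500, 1500, 4000), function(amp) {
    d <- deform_scene(sc, deformation_spec(scale = 4,
                                           nonrigid_amplitude_nm = amp,
                                           nonrigid_correlation_length_nm = 8000,
                                           seed = 21),
                      imaging_params(pixel_size_nm = 420), seed = 1)
    cv <- rms_vs_length(pts, residual_points(pts, d$truth$map(pts_nm) / 100),
                        max_length_um = 10)
    sum(cv$mean_error_nm)
  }, numeric(1))
  expect_true(all(diff(auc) > 0))
})

test_that("closed-form point fits recover known linear transforms", {
  set.seed(5)
  p <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  A <- 1.7 * exmetry:::rot2(0.3)
  q <- sweep(p %*% t(A), 2, c(4, -2), `+`)
  fit <- fit_point_linear(p, q, "similarity")
  expect_equal(fit$A, A, tolerance = 1e-9)
  expect_equal(fit$t, c(4, -2), tolerance = 1e-9)

  Aa <- matrix(c(1.5, 0.1, -0.2, 1.3), 2, 2)
  qa <- sweep(p %*% t(Aa), 2, c(-1, 7), `+`)
  fa <- fit_point_linear(p, qa, "affine")
  expect_equal(fa$A, Aa, tolerance = 1e-9)
  res <- residual_points(point_set(p, 100), qa, "affine")
  expect_equal(res$coords, p, tolerance = 1e-9)
})
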