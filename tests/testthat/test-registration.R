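test_that("preprocess applies projection, despeckle, blur and mask in order", {
  const <- raster_image(matrix(5, 64, 64), 100)
  expect_equal(preprocess(const, blur_sigma_px = 3)$data, const$data,
               tolerance = 1e-12)

  imp <- matrix(1, 64, 64)
  imp[30, 30] <- 100
  out <- preprocess(raster_image(imp, 100), blur_sigma_px = 0,
                    despeckle = TRUE)
  expect_lt(max(out$data), 100)

  stack <- array(0, c(16, 16, 3))
  stack[, , 1] <- 1; stack[5, 5, 2] <- 7; stack[, , 3] <- 0.5
  proj <- preprocess(raster_image(stack, 100), blur_sigma_px = 0,
                     project = TRUE)
  expect_equal(proj$data[5, 5], 7)
  expect_equal(proj$data[1, 1], 1)

  expect_error(preprocess(const, mask = matrix(1, 10, 10)), "mask shape")
  msk <- matrix(0, 64, 64); msk[1:32, ] <- 1
  masked <- preprocess(raster_image(matrix(2, 64, 64), 100),
                       blur_sigma_px = 0, mask = msk)
  expect_equal(sum(masked$data[33:64, ]), 0)
})

test_that("resample reproduces inputs under identity and integer shifts", {
  img <- disk_image(radius_nm = 2000, field_nm = 12800)$image
  ident <- transform_model("similarity", diag(2), c(0, 0))
  expect_equal(resample(img, ident)$data, img$data, tolerance = 1e-12)

  sh <- transform_model("similarity", diag(2), c(3, 5))
  shifted <- resample(img, sh)$data
  expect_equal(shifted[1:(128 - 5), 1:(128 - 3)],
               img$data[6:128, 4:128], tolerance = 1e-12)
  expect_equal(sum(shifted[, (128 - 2):128]), 0)  # border fill
})

test_that("resample round-trip through a transform and its inverse is faithful", {
  img <- disk_image(radius_nm = 3000, field_nm = 12800)$image
  tr <- transform_model("affine", matrix(c(1.05, 0.02, -0.03, 0.97), 2, 2),
                        c(2.5, -1.5))
  back <- resample(resample(img, tr), invert_transform(tr))
  interior <- 20:109
  err <- img$data[interior, interior] - back$data[interior, interior]
  psnr <- 10 * log10(max(img$data)^2 / mean(err^2))
  expect_gt(psnr, 40)
})

test_that("linear fit of an image onto itself is the identity", {
  img <- preprocess(small_pair(scale = 1, post_px = 100)$pre,
                    blur_sigma_px = 1)
  fit <- fit_linear(img, img, "similarity")
  expect_lt(abs(sqrt(det(fit$A)) - 1), 0.01)
  expect_lt(max(abs(fit$t)), 0.1)
})

test_that("similarity fit recovers a pure expansion within 1%", {
  pair <- small_pair(scale = 4)
  fit <- fit_linear(preprocess(pair$pre, blur_sigma_px = 1.5),
                    preprocess(pair$post, blur_sigma_px = 2), "similarity")
  expect_lt(abs(fit$expansion_scale - 4) / 4, 0.01)
})

test_that("affine fit resolves shear that the similarity model cannot", {
  pair <- small_pair(scale = 4, shear = diag(c(1.03, 1 / 1.03)))
  pre_p <- preprocess(pair$pre, blur_sigma_px = 1.5)
  post_p <- preprocess(pair$post, blur_sigma_px = 2)
  sim <- fit_linear(pre_p, post_p, "similarity")
  aff <- fit_linear(pre_p, post_p, "affine")
  expect_lt(aff$metric, sim$metric)
  # normalise out the pixel-size ratio and the scale; compare to shear
  A_norm <- aff$A / sqrt(det(aff$A))
  expect_equal(A_norm, diag(c(1.03, 1 / 1.03)), tolerance = 0.005)
  # the similarity fit leaves ~3% residual anisotropy by construction
  expect_lt(abs(sqrt(det(sim$A)) * 4 / 1.04 / 4 - 1), 0.02)
})

test_that("reported metric is non-increasing across accepted steps", {
  pair <- small_pair(scale = 2, post_px = 195)
  fit <- fit_linear(preprocess(pair$pre, blur_sigma_px = 1.5),
                    preprocess(pair$post, blur_sigma_px = 2), "similarity")
  expect_true(all(diff(fit$metric_trace) <= 1e-12))
})

test_that("translating both images leaves the fitted linear part unchanged", {
  pair <- small_pair(scale = 1, post_px = 104)
  shift <- function(img, d) {
    m <- matrix(0, nrow(img$data), ncol(img$data))
    m[(d + 1):nrow(m), (d + 1):ncol(m)] <-
      img$data[1:(nrow(m) - d), 1:(ncol(m) - d)]
    raster_image(m, img$pixel_size_nm)
  }
  f0 <- fit_linear(preprocess(pair$pre, blur_sigma_px = 1.5),
                   preprocess(pair$post, blur_sigma_px = 2), "similarity")
  f1 <- fit_linear(preprocess(shift(pair$pre, 8), blur_sigma_px = 1.5),
                   preprocess(shift(pair$post, 8), blur_sigma_px = 2),
                   "similarity")
  expect_equal(f1$A, f0$A, tolerance = 0.01)
})

test_that("featureless images are rejected", {
  flat <- raster_image(matrix(3, 64, 64), 100)
  expect_error(fit_linear(flat, flat), "featureless")
})

test_that("B-spline registration of identical images returns a null field", {
  img <- preprocess(small_pair(scale = 1, post_px = 100)$pre,
                    blur_sigma_px = 1)
  bs <- fit_bspline(img, img, registration_config(penalty_weight = 1e-2))
  expect_lt(field_rms(bs$field), 0.1)
})

test_that("B-spline recovers an imposed sinusoidal field within 25%", {
  base <- disk_image(radius_nm = 4000, field_nm = 25600, noise = TRUE)$image
  pre <- preprocess(base, blur_sigma_px = 2)
  m <- pre$data
  xs <- rep(0:(ncol(m) - 1), each = nrow(m))
  ys <- rep(0:(nrow(m) - 1), times = ncol(m))
  u0x <- 3 * sin(2 * pi * xs / 100)
  u0y <- 3 * cos(2 * pi * ys / 100)
  warped <- matrix(exmetry:::bilinear_sample(m, xs - u0x, ys - u0y),
                   nrow(m), ncol(m))
  moving <- raster_image(warped, 100)
  bs <- fit_bspline(pre, moving, registration_config(penalty_weight = 1e-2))
  interior <- as.numeric(matrix(seq_along(m), nrow(m))[33:224, 33:224])
  rms_fit <- sqrt(mean(bs$field$ux[interior]^2 + bs$field$uy[interior]^2))
  rms_true <- sqrt(mean(u0x[interior]^2 + u0y[interior]^2))
  expect_lt(abs(rms_fit - rms_true) / rms_true, 0.25)
})

test_that("increasing the bending penalty monotonically shrinks the field", {
  pair <- small_pair(scale = 4, amplitude = 800)
  pre_p <- preprocess(pair$pre, blur_sigma_px = 1.5)
  post_p <- preprocess(pair$post, blur_sigma_px = 2)
  lin <- fit_linear(pre_p, post_p, "similarity")
  reg <- resample(post_p, lin, output_dim = dim(pre_p$data))
  rms <- vapply(c(1e-2, 1, 100), function(pw) {
    field_rms(fit_bspline(pre_p, reg,
                          registration_config(penalty_weight = pw))$field)
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
  expect_lt(rms[3], 0.35 * rms[1])
})
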