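# Internal numerical helpers shared across modules.
# Coordinates are 0-based with pixel centers at integers: x = column,
# y = row; value at (x, y) lives in m[y + 1, x + 1].

# Evaluate a block with a temporary, restorable RNG state seeded by `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible integer sub-seed (< 2^31) from a seed and a label.
sub_seed <- function(seed, label) {
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  bytes <- strtoi(substring(h, seq(1, 13, 2), seq(2, 14, 2)), 16L)
  s <- 0
  for (b in bytes) s <- (s * 31 + b) %% 2147483647
  as.integer(s)
}

# Bilinear interpolation of matrix m at continuous (x, y); out-of-domain
# points get `fill`.
bilinear_sample <- function(m, x, y, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  # clamp upper edge so points exactly on the last row/col are valid
  x1 <- pmin(pmax(x0 + 1, 0), nc - 1); y1 <- pmin(pmax(y0 + 1, 0), nr - 1)
  x0c <- pmin(pmax(x0, 0), nc - 1); y0c <- pmin(pmax(y0, 0), nr - 1)
  i00 <- y0c + 1 + nr * x0c
  i01 <- y0c + 1 + nr * x1
  i10 <- y1 + 1 + nr * x0c
  i11 <- y1 + 1 + nr * x1
  v <- (1 - fy) * ((1 - fx) * m[i00] + fx * m[i01]) +
    fy * ((1 - fx) * m[i10] + fx * m[i11])
  v[!inside] <- fill
  v
}

# Conservative bilinear splat of point weights into an nr x nc matrix.
# Each point deposits its full weight onto its 4 neighbouring pixel
# centers; weight falling outside the grid is dropped.
bilinear_splat <- function(nr, nc, x, y, w) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  xs <- c(x0, x0 + 1, x0, x0 + 1)
  ys <- c(y0, y0, y0 + 1, y0 + 1)
  ws <- c(w * (1 - fx) * (1 - fy), w * fx * (1 - fy),
          w * (1 - fx) * fy, w * fx * fy)
  keep <- xs >= 0 & xs <= nc - 1 & ys >= 0 & ys <= nr - 1 & ws != 0
  m <- matrix(0, nr, nc)
  if (!any(keep)) return(m)
  idx <- ys[keep] + 1 + nr * xs[keep]
  agg <- rowsum(ws[keep], group = idx)
  m[as.integer(rownames(agg))] <- agg
  m
}

# Separable Gaussian convolution, kernel normalised to integrate to 1.
# boundary "zero": zero-padded (conserves total intensity; used by the
# imaging model). boundary "normalized": renormalises by the convolved
# support so constants are preserved at the borders (used for
# preprocessing smoothing).
conv_gaussian <- function(m, sigma_px, boundary = c("zero", "normalized")) {
  boundary <- match.arg(boundary)
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  out <- conv_sep(m, k)
  if (boundary == "normalized")
    out <- out / conv_sep(matrix(1, nrow(m), ncol(m)), k)
  out
}

conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  Kr <- band_matrix(nr, k, r)
  Kc <- band_matrix(nc, k, r)
  Kr %*% m %*% t(Kc)
}

band_matrix <- function(n, k, r) {
  K <- matrix(0, n, n)
  d <- outer(seq_len(n), seq_len(n), `-`)
  sel <- abs(d) <= r
  K[sel] <- k[d[sel] + r + 1]
  K
}

# 2x block-mean downsample (odd trailing row/col dropped).
downsample2 <- function(m) {
  nr <- 2L * (nrow(m) %/% 2L); nc <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
     m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

downsample_by <- function(m, f) {
  while (f > 1) { m <- downsample2(m); f <- f / 2 }
  m
}

# Otsu threshold on a matrix with arbitrary intensity range.
otsu_threshold <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) stop("cannot threshold a constant image")
  EBImage::otsu(m, range = rng, levels = 256L)
}

binarize <- function(m, threshold_method = "otsu") {
  th <- if (is.numeric(threshold_method)) threshold_method
  else switch(threshold_method,
              otsu = otsu_threshold(m),
              mean = mean(m),
              stop("unknown threshold method: ", threshold_method))
  m > th
}

# Shift a matrix by (dy, dx) filling with `fill` (used by morphology).
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# One-pixel outer boundary of a binary mask (pixels of the mask with at
# least one 4-neighbour outside it).
mask_outline <- function(mask) {
  m <- mask * 1
  er <- shift_mat(m, 1, 0, 0) * shift_mat(m, -1, 0, 0) *
    shift_mat(m, 0, 1, 0) * shift_mat(m, 0, -1, 0) * m
  mask & !(er > 0)
}

# Zhang-Suen morphological thinning to a 1-px skeleton; vectorized over
# the whole image per subiteration.
skeletonize <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & b >= 2 & b <= 6 & a == 1
      if (step == 1)
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# (x, y) 0-based coordinates of TRUE pixels of a mask, as an n x 2 matrix.
mask_coords <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  cbind(x = (idx - 1) %/% nr, y = (idx - 1) %% nr)
}

# Local maxima of a 1D signal with prominence and minimum-separation
# filters. Returns indices into y.
find_profile_peaks <- function(y, prominence = 0, min_separation = 1L) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > y[i])
    base_l <- min(y[(if (length(higher_l)) max(higher_l) else 1):(i - 1)])
    right <- y[(i + 1):n]
    higher_r <- which(right > y[i])
    hi_r <- if (length(higher_r)) i + min(higher_r) else n
    base_r <- min(y[(i + 1):hi_r])
    y[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= prominence]
  promk <- prom[prom >= prominence]
  if (min_separation > 1L && length(keep) > 1L) {
    ord <- order(promk, decreasing = TRUE)
    sel <- logical(length(keep))
    taken <- integer(0)
    for (j in ord) {
      if (all(abs(keep[j] - taken) >= min_separation)) {
        sel[j] <- TRUE; taken <- c(taken, keep[j])
      }
    }
    keep <- sort(keep[sel])
  }
  keep
}
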