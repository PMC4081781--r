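# Oriented-gradient descriptors for palmprint ROIs.
#
# HOG: per-pixel gradients from the [-1, 0, 1] mask, magnitude-weighted
# orientation histograms over the full circle (gradient vector orientation,
# [0, 2*pi)).
# RIGO/RIHOG: gradients re-expressed in a local frame attached to sample
# points on a circle around each pixel, which makes the histogram invariant
# to rotations of the image about that pixel.
# RHOG: blockwise concatenation of per-block RIHOGs.
# WRHOG: RHOG with each block's histogram scaled by the block's differential
# box-counting fractal dimension.

#' Gradient magnitude and orientation map
#'
#' Horizontal/vertical gradients from the \[-1, 0, 1\] mask with mirrored
#' edges (so boundary gradients in the mirrored direction are zero).
#' Orientation is the gradient vector orientation: `atan2(Gy, Gx)` with
#' +x = increasing column, +y = increasing row, reduced to \[0, 2*pi).
#'
#' @param img Gray matrix, at least 3x3.
#' @return List with `mag` and `ang` matrices of the image's shape.
#' @export
gradient_map <- function(img) {
  check_image_matrix(img, min_side = 3L)
  h <- nrow(img); w <- ncol(img)
  right <- img[, c(2:w, w - 1L), drop = FALSE]
  left  <- img[, c(2L, 1:(w - 1L)), drop = FALSE]
  down  <- img[c(2:h, h - 1L), , drop = FALSE]
  up    <- img[c(2L, 1:(h - 1L)), , drop = FALSE]
  gx <- right - left
  gy <- down - up
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  ang <- ifelse(ang < 0, ang + 2 * pi, ang)
  ang[ang >= 2 * pi] <- 0
  list(mag = mag, ang = ang)
}

# Map angles in [0, 2*pi) to 0-based bin indices with half-open bins
# [2*pi*i/N, 2*pi*(i+1)/N); 2*pi wraps to bin 0.
angle_bin <- function(ang, n_bins) {
  idx <- floor(ang * n_bins / (2 * pi))
  idx[idx >= n_bins] <- 0
  idx[idx < 0] <- 0
  idx
}

#' Magnitude-weighted orientation histogram
#'
#' Each pixel votes its gradient magnitude into the bin containing its
#' orientation; the histogram is L1-normalized. An all-zero accumulation
#' (e.g. a constant image) is returned as zeros rather than NaN.
#'
#' @param omap Orientation map from [gradient_map()].
#' @param n_bins Number of orientation bins covering \[0, 2*pi) (>= 2).
#' @return Numeric vector of length `n_bins` summing to 1 (or all zero).
#' @export
hog <- function(omap, n_bins = 12L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("need at least 2 orientation bins", call. = FALSE)
  accumulate_hist(omap$mag, omap$ang, n_bins, normalize = TRUE)
}

accumulate_hist <- function(mag, ang, n_bins, normalize = TRUE) {
  idx <- angle_bin(ang, n_bins)
  hvec <- vapply(0:(n_bins - 1L),
                 function(b) sum(mag[idx == b]), numeric(1))
  if (normalize) {
    s <- sum(hvec)
    # vote mass below 1e-9 gray levels is interpolation round-off from a
    # flat patch, not signal: leave the histogram at zero
    if (s > 1e-9) hvec <- hvec / s else hvec[] <- 0
  }
  hvec
}

# Precomputed sampling geometry for the rotation-invariant gradient
# operator: K sample points p_k at angles 2*pi*k/K on the radius-r circle
# around the pixel, and for each a local frame with x along the outward
# ray. Gradients at p_k are central differences (step 1 px) of bilinearly
# interpolated gray values along the local axes. Offsets are (drow, dcol)
# relative to the center pixel.
rigo_offsets <- function(r = 2, K = 8L) {
  th <- 2 * pi * (seq_len(K) - 1L) / K
  ex_r <- sin(th); ex_c <- cos(th)     # local +x (outward ray), image coords
  ey_r <- cos(th); ey_c <- -sin(th)    # local +y = +x rotated +90deg (ccw)
  list(K = as.integer(K), r = r, theta = th,
       # probe points for Gx: p_k +/- local x; for Gy: p_k +/- local y
       xp_r = r * ex_r + ex_r, xp_c = r * ex_c + ex_c,
       xm_r = r * ex_r - ex_r, xm_c = r * ex_c - ex_c,
       yp_r = r * ex_r + ey_r, yp_c = r * ex_c + ey_c,
       ym_r = r * ex_r - ey_r, ym_c = r * ex_c - ey_c,
       margin = as.integer(ceiling(r + 1)))
}

#' Rotation-invariant gradient operator at one pixel
#'
#' For each of `K` sample points on the radius-`r` circle around the pixel,
#' returns the gradient at that point expressed in a local frame whose x
#' axis points along the ray from the pixel to the sample point. Rotating
#' the image about the pixel permutes the sample points but leaves the set
#' of (magnitude, local angle) pairs unchanged.
#'
#' @param img Gray matrix.
#' @param pixel `c(row, col)` (1-based), at least `r + 1` from every border.
#' @param r Circle radius in pixels.
#' @param K Number of sample points.
#' @return `K` x 2 matrix with columns `mag` and `ang` (local angle in
#'   \[0, 2*pi)).
#' @export
rigo_at <- function(img, pixel, r = 2, K = 8L) {
  geo <- rigo_offsets(r, K)
  i <- pixel[1L]; j <- pixel[2L]
  m <- geo$margin
  if (i <= m || j <= m || i > nrow(img) - m || j > ncol(img) - m)
    stop("pixel too close to the border for radius ", r, call. = FALSE)
  gx <- bilinear_sample(img, i + geo$xp_r, j + geo$xp_c) -
        bilinear_sample(img, i + geo$xm_r, j + geo$xm_c)
  gy <- bilinear_sample(img, i + geo$yp_r, j + geo$yp_c) -
        bilinear_sample(img, i + geo$ym_r, j + geo$ym_c)
  ang <- atan2(gy, gx)
  ang <- ifelse(ang < 0, ang + 2 * pi, ang)
  ang[ang >= 2 * pi] <- 0
  cbind(mag = sqrt(gx^2 + gy^2), ang = ang)
}

# Vectorized RIGO over every interior pixel of img. Returns, for each of
# the K sample directions, full-size matrices of magnitude and local angle
# (zero outside the margin-`m` interior).
rigo_maps <- function(img, r = 2, K = 8L) {
  geo <- rigo_offsets(r, K)
  m <- geo$margin
  h <- nrow(img); w <- ncol(img)
  if (h < 2L * m + 1L || w < 2L * m + 1L)
    stop("image too small for RIGO radius ", r, call. = FALSE)
  ri <- (m + 1L):(h - m); ci <- (m + 1L):(w - m)
  RI <- matrix(ri, length(ri), length(ci))
  CI <- matrix(ci, length(ri), length(ci), byrow = TRUE)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    gx <- bilinear_sample(img, RI + geo$xp_r[k], CI + geo$xp_c[k]) -
          bilinear_sample(img, RI + geo$xm_r[k], CI + geo$xm_c[k])
    gy <- bilinear_sample(img, RI + geo$yp_r[k], CI + geo$yp_c[k]) -
          bilinear_sample(img, RI + geo$ym_r[k], CI + geo$ym_c[k])
    ang <- atan2(gy, gx)
    ang <- ifelse(ang < 0, ang + 2 * pi, ang)
    ang[ang >= 2 * pi] <- 0
    magf <- matrix(0, h, w); angf <- matrix(0, h, w)
    magf[ri, ci] <- sqrt(gx^2 + gy^2)
    angf[ri, ci] <- ang
    out[[k]] <- list(mag = magf, ang = angf)
  }
  attr(out, "margin") <- m
  out
}

#' Rotation-invariant histogram of oriented gradients
#'
#' Accumulates the RIGO contributions of every interior pixel (each pixel
#' contributes `K` magnitude-weighted votes, one per sample direction) into
#' an L1-normalized orientation histogram.
#'
#' @param img Gray matrix.
#' @param n_bins Number of orientation bins.
#' @param r,K RIGO circle radius and sample count.
#' @return Numeric vector of length `n_bins`.
#' @export
rihog <- function(img, n_bins = 12L, r = 2, K = 8L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("need at least 2 orientation bins", call. = FALSE)
  maps <- rigo_maps(img, r, K)
  hvec <- numeric(n_bins)
  for (k in seq_along(maps))
    hvec <- hvec + accumulate_hist(maps[[k]]$mag, maps[[k]]$ang, n_bins,
                                   normalize = FALSE)
  s <- sum(hvec)
  if (s > 1e-9) hvec <- hvec / s else hvec[] <- 0
  hvec
}

# Per-block histograms shared by rhog/wrhog and the blockwise HOG arm.
# Each block's histogram is computed from the block sub-image alone (RIGO
# votes only from pixels at least `margin` inside the block), so blocks are
# independent: permuting input blocks permutes histogram segments.
block_histograms <- function(img, b, n_bins, r = 2, K = 8L,
                             use_rigo = TRUE) {
  b <- as.integer(b)
  if (b < 4L) stop("block size must be >= 4", call. = FALSE)
  if (b > min(dim(img)))
    stop("block size exceeds image dimensions", call. = FALSE)
  nbr <- nrow(img) %/% b
  nbc <- ncol(img) %/% b
  hist_mat <- matrix(0, nbr * nbc, n_bins)
  if (use_rigo) {
    maps <- rigo_maps(img, r, K)
    m <- attr(maps, "margin")
    # votes count only when the whole sampling neighborhood lies inside the
    # pixel's own block
    h <- nrow(img); w <- ncol(img)
    rloc <- (seq_len(h) - 1L) %% b + 1L
    cloc <- (seq_len(w) - 1L) %% b + 1L
    rok <- rloc > m & rloc <= b - m & seq_len(h) <= nbr * b
    cok <- cloc > m & cloc <= b - m & seq_len(w) <= nbc * b
    mask <- outer(rok, cok, `&`)
    blk <- outer((seq_len(h) - 1L) %/% b, (seq_len(w) - 1L) %/% b,
                 function(i, j) i * nbc + j)  # 0-based row-major block id
    blk_m <- blk[mask]
    acc <- numeric(nbr * nbc * n_bins)
    for (k in seq_along(maps)) {
      bins <- angle_bin(maps[[k]]$ang[mask], n_bins)
      g <- blk_m * n_bins + bins + 1L
      s <- rowsum(maps[[k]]$mag[mask], g)
      acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1L]
    }
    hist_mat <- matrix(acc, nbr * nbc, n_bins, byrow = TRUE)
  } else {
    for (i in seq_len(nbr)) {
      for (j in seq_len(nbc)) {
        rows <- ((i - 1L) * b + 1L):(i * b)
        cols <- ((j - 1L) * b + 1L):(j * b)
        om <- gradient_map(img[rows, cols, drop = FALSE])
        blk <- (i - 1L) * nbc + j
        hist_mat[blk, ] <- accumulate_hist(om$mag, om$ang, n_bins,
                                           normalize = FALSE)
      }
    }
  }
  sums <- rowSums(hist_mat)
  nz <- sums > 1e-9          # same round-off floor as accumulate_hist
  hist_mat[!nz, ] <- 0
  hist_mat[nz, ] <- hist_mat[nz, , drop = FALSE] / sums[nz]
  hist_mat
}

feature_from_hist <- function(hist_mat, b, n_bins, weighted, weights = NULL) {
  if (!is.null(weights)) hist_mat <- hist_mat * weights
  fv <- as.numeric(t(hist_mat))  # row-major block order, bins contiguous
  attr(fv, "block_size") <- as.integer(b)
  attr(fv, "n_bins") <- as.integer(n_bins)
  attr(fv, "weighted") <- weighted
  fv
}

#' Robust histogram of oriented gradients (blockwise RIHOG)
#'
#' Partitions the image into non-overlapping `b` x `b` blocks (trailing
#' remainder dropped) and concatenates the per-block RIHOGs row-major.
#'
#' @param img Gray matrix.
#' @param b Block side in pixels.
#' @param n_bins Orientation bins per block.
#' @param r,K RIGO parameters.
#' @return Numeric feature vector of length `floor(H/b)*floor(W/b)*n_bins`.
#' @export
rhog <- function(img, b = 16L, n_bins = 12L, r = 2, K = 8L) {
  check_image_matrix(img)
  hm <- block_histograms(img, b, n_bins, r, K, use_rigo = TRUE)
  feature_from_hist(hm, b, n_bins, weighted = FALSE)
}

#' Fractal-weighted robust histogram of oriented gradients
#'
#' The RHOG vector with each block's normalized histogram multiplied by
#' that block's differential box-counting fractal dimension, computed on
#' the same input image (the structure layer in the full pipeline).
#' Rough, texture-rich blocks (higher D) therefore carry more weight.
#'
#' @inheritParams rhog
#' @param scales Box-counting grid scales; `NULL` for the power-of-two
#'   divisors of `b` in \[2, b/2\].
#' @param gray_levels Gray-level count G for the box height.
#' @return Numeric feature vector, `weighted = TRUE`.
#' @export
wrhog <- function(img, b = 16L, n_bins = 12L, r = 2, K = 8L,
                  scales = NULL, gray_levels = 256L) {
  check_image_matrix(img)
  hm <- block_histograms(img, b, n_bins, r, K, use_rigo = TRUE)
  wts <- block_fractal_weights(img, b, scales, gray_levels)
  feature_from_hist(hm, b, n_bins, weighted = TRUE, weights = wts)
}

# Fractal dimension of every b-block, as a vector aligned with the
# row-major block order of block_histograms(). Computed for all blocks at
# once: since every scale divides the block side and blocks are anchored on
# the b-grid, the s-cells of all blocks form one global strided grid.
block_fractal_weights <- function(img, b, scales = NULL,
                                  gray_levels = 256L) {
  b <- as.integer(b)
  if (is.null(scales)) scales <- default_dbc_scales(b)
  scales <- as.integer(scales)
  if (any(b %% scales != 0L))
    stop("every scale must divide the block size", call. = FALSE)
  nbr <- nrow(img) %/% b
  nbc <- ncol(img) %/% b
  sub <- img[seq_len(nbr * b), seq_len(nbc * b), drop = FALSE]
  logx <- log(b / scales)
  logy <- matrix(0, nbr * nbc, length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    ncr <- nrow(sub) %/% s; ncc <- ncol(sub) %/% s
    cmin <- matrix(Inf, ncr, ncc); cmax <- matrix(-Inf, ncr, ncc)
    for (or in seq_len(s)) {
      for (oc in seq_len(s)) {
        v <- sub[seq(or, by = s, length.out = ncr),
                 seq(oc, by = s, length.out = ncc), drop = FALSE]
        cmin <- pmin(cmin, v); cmax <- pmax(cmax, v)
      }
    }
    sp <- s * gray_levels / b
    n_cell <- floor(cmax / sp) - floor(cmin / sp) + 1
    # sum cells into their parent blocks (row-major block id)
    cb <- b %/% s
    blk <- outer((seq_len(ncr) - 1L) %/% cb, (seq_len(ncc) - 1L) %/% cb,
                 function(i, j) i * nbc + j)
    ns <- rowsum(as.numeric(n_cell), as.integer(blk))
    logy[as.integer(rownames(ns)) + 1L, si] <- log(ns[, 1L])
  }
  xc <- logx - mean(logx)
  as.numeric(logy %*% xc) / sum(xc^2)
}

#' Blockwise plain HOG feature vector
#'
#' The non-rotation-invariant baseline: per-block magnitude-weighted
#' orientation histograms from the \[-1, 0, 1\] gradient mask, concatenated
#' row-major.
#'
#' @inheritParams rhog
#' @return Numeric feature vector.
#' @export
block_hog <- function(img, b = 16L, n_bins = 12L) {
  check_image_matrix(img)
  hm <- block_histograms(img, b, n_bins, use_rigo = FALSE)
  feature_from_hist(hm, b, n_bins, weighted = FALSE)
}

#' Rotate an image about its center
#'
#' Counter-clockwise rotation by bilinear resampling; target pixels whose
#' source falls outside the image take the nearest edge value.
#'
#' @param img Gray matrix.
#' @param degrees Rotation angle, counter-clockwise positive.
#' @return Rotated gray matrix of the same shape.
#' @export
rotate_image <- function(img, degrees) {
  th <- degrees * pi / 180
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  RI <- matrix(seq_len(h), h, w) - cy
  CI <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse map: rotate target coords by -theta
  src_r <- cy + RI * cos(th) - CI * sin(th)
  src_c <- cx + RI * sin(th) + CI * cos(th)
  src_r <- pmin(pmax(src_r, 1), h)
  src_c <- pmin(pmax(src_c, 1), w)
  matrix(bilinear_sample(img, src_r, src_c), h, w)
}
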