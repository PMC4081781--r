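# Independent brute-force oracles, written against the documented
# conventions only (never calling the implementation paths they check).

# luminance-free bilinear interpolation at a single point (1-based coords)
oracle_bilinear <- function(img, r, c) {
  r0 <- min(max(floor(r), 1), nrow(img) - 1)
  c0 <- min(max(floor(c), 1), ncol(img) - 1)
  fr <- r - r0; fc <- c - c0
  img[r0, c0] * (1 - fr) * (1 - fc) + img[r0 + 1, c0] * fr * (1 - fc) +
    img[r0, c0 + 1] * (1 - fr) * fc + img[r0 + 1, c0 + 1] * fr * fc
}

# magnitude-weighted orientation histogram by explicit double loop
oracle_hog <- function(mag, ang, n_bins) {
  h <- numeric(n_bins)
  for (i in seq_len(nrow(mag))) {
    for (j in seq_len(ncol(mag))) {
      b <- floor(ang[i, j] * n_bins / (2 * pi)) + 1
      if (b > n_bins) b <- 1
      h[b] <- h[b] + mag[i, j]
    }
  }
  if (sum(h) > 0) h <- h / sum(h)
  h
}

# RIGO pairs at one pixel by direct geometry
oracle_rigo_pairs <- function(img, i, j, r = 2, K = 8) {
  out <- matrix(0, K, 2)
  for (k in seq_len(K)) {
    th <- 2 * pi * (k - 1) / K
    ex <- c(sin(th), cos(th))        # (drow, dcol) of local +x
    ey <- c(cos(th), -sin(th))       # local +y
    pk <- c(i, j) + r * ex
    gx <- oracle_bilinear(img, pk[1] + ex[1], pk[2] + ex[2]) -
          oracle_bilinear(img, pk[1] - ex[1], pk[2] - ex[2])
    gy <- oracle_bilinear(img, pk[1] + ey[1], pk[2] + ey[2]) -
          oracle_bilinear(img, pk[1] - ey[1], pk[2] - ey[2])
    a <- atan2(gy, gx)
    if (a < 0) a <- a + 2 * pi
    if (a >= 2 * pi) a <- 0
    out[k, ] <- c(sqrt(gx^2 + gy^2), a)
  }
  out
}

# full RIHOG by double loop over interior pixels
oracle_rihog <- function(img, n_bins = 12, r = 2, K = 8) {
  m <- ceiling(r + 1)
  h <- numeric(n_bins)
  for (i in (m + 1):(nrow(img) - m)) {
    for (j in (m + 1):(ncol(img) - m)) {
      pr <- oracle_rigo_pairs(img, i, j, r, K)
      for (k in seq_len(K)) {
        b <- floor(pr[k, 2] * n_bins / (2 * pi)) + 1
        if (b > n_bins) b <- 1
        h[b] <- h[b] + pr[k, 1]
      }
    }
  }
  if (sum(h) > 0) h <- h / sum(h)
  h
}

# differential box count by per-cell loops
oracle_dbc <- function(block, s, G = 256) {
  M <- nrow(block)
  sp <- s * G / M
  total <- 0
  for (bi in seq_len(M / s)) {
    for (bj in seq_len(M / s)) {
      cell <- block[((bi - 1) * s + 1):(bi * s), ((bj - 1) * s + 1):(bj * s)]
      total <- total + floor(max(cell) / sp) - floor(min(cell) / sp) + 1
    }
  }
  total
}

# FAR/FRR at one threshold by counting
oracle_far_frr_at <- function(genuine, imposter, t) {
  c(far = sum(imposter >= t) / length(imposter),
    frr = sum(genuine < t) / length(genuine))
}

# EER by exhaustive sweep over all observed scores with sentinel
# thresholds, locating the FAR-FRR sign change and interpolating linearly
oracle_eer <- function(genuine, imposter) {
  ts <- c(Inf, sort(unique(c(genuine, imposter)), decreasing = TRUE), -Inf)
  far <- sapply(ts, function(t) mean(imposter >= t))
  frr <- sapply(ts, function(t) mean(genuine < t))
  d <- far - frr
  k <- which(d >= 0)[1]
  if (k == 1 || d[k] == 0) return((far[k] + frr[k]) / 2)
  al <- -d[k - 1] / (d[k] - d[k - 1])
  far[k - 1] + al * (far[k] - far[k - 1])
}

# dense 2-D convolution with symmetric (mirror) boundary, direct loops
oracle_conv2_reflect <- function(img, kernel) {
  rk <- (nrow(kernel) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  refl <- function(k, n) {
    k <- abs(k - 1) + 1
    if (k > n) k <- 2 * n - k
    min(max(k, 1), n)
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -rk:rk) for (dj in -rk:rk)
      acc <- acc + kernel[di + rk + 1, dj + rk + 1] *
        img[refl(i + di, h), refl(j + dj, w)]
    out[i, j] <- acc
  }
  out
}

# a small deterministic ridge-texture fixture (independent of the synth
# module): oriented sinusoid plus a dark diagonal line. Rotation-robustness
# tests use band-limited frequencies (well below Nyquist) so that bilinear
# resampling does not attenuate the texture itself.
ridge_fixture <- function(seed, size = 64, freq_range = c(0.1, 0.25)) {
  set.seed(seed)
  th <- runif(1, 0, pi)
  fr <- runif(1, freq_range[1], freq_range[2])
  y <- matrix(seq_len(size), size, size)
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  img <- 150 + 35 * cos(2 * pi * fr * (x * cos(th) + y * sin(th)))
  d <- abs((x - y) - runif(1, -10, 10)) / sqrt(2)
  img <- img - 60 * exp(-d^2 / (2 * 16))
  pmin(pmax(img, 0), 255)
}

# isotropic band-limited texture: low-pass filtered white noise, rescaled
# to the gray range; its gradient-angle distribution is smooth, which is
# the regime where the rotation-invariance claims of relative-angle
# histograms apply
band_limited_fixture <- function(seed, size = 80) {
  set.seed(seed)
  img <- vowrhog:::gaussian_blur(matrix(rnorm(size^2), size, size), 2)
  128 + 100 * img / max(abs(img))
}

# exact 90-degree counter-clockwise grid rotation
rot90_grid <- function(m) t(m)[, nrow(m):1, drop = FALSE]
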