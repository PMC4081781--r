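# Gaussian defocus simulation and the Roberts-gradient sharpness measure.
#
# Defocus on a non-contact capture device is modeled as convolution of the
# sharp image with an isotropic Gaussian point-spread function of width
# sigma, optionally followed by additive Gaussian noise:
#   g = h_sigma (*) f + n
# Larger sigma means a more defocused image.

#' Gaussian point-spread function
#'
#' Samples the isotropic 2-D Gaussian on an odd square grid and normalizes
#' it to unit sum. The default support radius is `ceiling(3*sigma)`, which
#' keeps the truncated mass below 0.3\% before renormalization.
#'
#' @param sigma Positive width of the Gaussian, in pixels.
#' @param radius Integer half-width of the kernel; `NULL` for automatic.
#' @return List with `taps` ((2r+1) x (2r+1) matrix summing to 1), `sigma`,
#'   `radius`.
#' @export
gaussian_psf <- function(sigma, radius = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a positive number", call. = FALSE)
  if (is.null(radius)) radius <- ceiling(3 * sigma)
  radius <- as.integer(radius)
  if (radius < 1L) radius <- 1L
  x <- seq(-radius, radius)
  g1 <- exp(-x^2 / (2 * sigma^2))
  taps <- outer(g1, g1)
  taps <- taps / sum(taps)
  list(taps = taps, sigma = sigma, radius = radius)
}

# 1-D correlation pass along rows (dim = 1) or columns (dim = 2) with
# symmetric (reflect) boundary handling. Kernel must be odd-length and
# symmetric, so correlation equals convolution.
sep_filter_reflect <- function(img, taps, dim) {
  r <- (length(taps) - 1L) %/% 2L
  n <- if (dim == 1L) nrow(img) else ncol(img)
  # reflect indices: 1 2 ... n with edge mirroring (no repeated edge sample
  # beyond what symmetric extension gives: 2-x style reflection)
  idx <- function(k) {
    k <- abs(k - 1L) + 1L              # reflect below 1
    k <- ifelse(k > n, 2L * n - k, k)  # reflect above n
    pmin(pmax(k, 1L), n)
  }
  out <- matrix(0, nrow(img), ncol(img))
  base <- seq_len(n)
  for (t in seq_along(taps)) {
    off <- t - r - 1L
    src <- idx(base + off)
    if (dim == 1L) out <- out + taps[t] * img[src, , drop = FALSE]
    else out <- out + taps[t] * img[, src, drop = FALSE]
  }
  out
}

# Convolve with the separable Gaussian PSF (reflect boundaries).
gaussian_blur <- function(img, sigma, radius = NULL) {
  if (is.null(radius)) radius <- ceiling(3 * sigma)
  radius <- max(1L, as.integer(radius))
  x <- seq(-radius, radius)
  g1 <- exp(-x^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  sep_filter_reflect(sep_filter_reflect(img, g1, 1L), g1, 2L)
}

#' Simulate Gaussian defocus degradation
#'
#' Applies `output = clip(h_sigma (*) img + n, 0, 255)` where `h_sigma` is the
#' Gaussian PSF and `n` is optional additive Gaussian noise. Deterministic
#' given `seed`.
#'
#' @param img Gray matrix in \[0, 255\].
#' @param sigma Positive blur width.
#' @param noise_std Standard deviation of additive Gaussian noise (gray
#'   levels); 0 disables noise.
#' @param seed Integer seed for the noise draw.
#' @return Degraded gray matrix, clipped to \[0, 255\].
#' @export
apply_gddm <- function(img, sigma, noise_std = 0, seed = 1L) {
  check_image_matrix(img)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (noise_std < 0) stop("noise_std must be non-negative", call. = FALSE)
  out <- gaussian_blur(img, sigma)
  if (noise_std > 0) {
    out <- out + with_seed(seed, matrix(stats::rnorm(length(img),
                                                     sd = noise_std),
                                        nrow(img), ncol(img)))
  }
  clip255(out)
}

#' Roberts gradient energy
#'
#' Sharpness measure: the sum over all 2x2 neighborhoods of the squared
#' Roberts cross differences,
#' `(f[i,j] - f[i+1,j+1])^2 + (f[i+1,j] - f[i,j+1])^2`.
#' It decreases as defocus blur increases and plateaus for heavy blur.
#'
#' @param img Gray matrix, at least 2x2.
#' @return Non-negative scalar.
#' @export
rge <- function(img) {
  check_image_matrix(img, min_side = 2L)
  h <- nrow(img); w <- ncol(img)
  a <- img[-h, -w]; d <- img[-1, -1]
  b <- img[-1, -w]; c <- img[-h, -1]
  sum((a - d)^2) + sum((b - c)^2)
}
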