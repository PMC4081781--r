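# Synthetic palmprint-like ROI generator.
#
# An identity is a ridge-texture template: a quasi-periodic ridge pattern
# cos(2*pi * freq * psi) whose phase field psi is a base direction plus a
# smooth identity-specific warp (so ridge orientation bends gently across
# the ROI, without singularities), darkened by 2-3 principal lines drawn as
# quadratic Bezier curves with Gaussian cross-profiles. Samples of an
# identity differ by small rotation/translation, Gaussian defocus blur and
# optional noise, mimicking a pre-cropped two-session capture protocol.
# Templates are rendered on a padded canvas so rotation never imports
# border artifacts into the cropped ROI.

SYNTH_PAD <- 16L

#' Create a synthetic palm identity template
#'
#' Deterministic given `seed`. Ridge frequency is drawn from
#' \[0.1, 0.25\] cycles/pixel, ridge amplitude from \[25, 45\] gray levels,
#' and 2-3 principal lines with depth 40-80 and width 3-5 px.
#'
#' @param seed Integer identity seed.
#' @param size ROI side in pixels (canvas adds padding for rotation).
#' @return Template list with the rendered `canvas`, the `orientation`
#'   field (radians), and the drawn parameters.
#' @export
make_identity <- function(seed, size = 128L) {
  size <- as.integer(size)
  cs <- size + 2L * SYNTH_PAD
  with_seed(seed, {
    theta0 <- stats::runif(1, 0, pi)
    freq <- stats::runif(1, 0.10, 0.25)
    amp <- stats::runif(1, 25, 45)
    base_level <- stats::runif(1, 130, 170)
    phase0 <- stats::runif(1, 0, 2 * pi)
    # smooth identity-specific phase warp: low-pass white noise, scaled to
    # a few pixels of phase displacement
    warp_amp <- stats::runif(1, 1.5, 3.0)
    raw <- matrix(stats::rnorm(cs * cs), cs, cs)
    warp <- gaussian_blur(raw, 12)
    warp <- warp_amp * warp / stats::sd(warp)
    n_lines <- sample(2:3, 1)
    lines <- lapply(seq_len(n_lines), function(i) {
      list(p0 = stats::runif(2, 0.05, 0.95) * cs,
           p1 = stats::runif(2, 0.05, 0.95) * cs,
           p2 = stats::runif(2, 0.05, 0.95) * cs,
           width = stats::runif(1, 3, 5),
           depth = stats::runif(1, 40, 80))
    })
    y <- matrix(seq_len(cs), cs, cs) - (cs + 1) / 2
    x <- matrix(seq_len(cs), cs, cs, byrow = TRUE) - (cs + 1) / 2
    psi <- x * cos(theta0) + y * sin(theta0) + warp
    ridges <- amp * cos(2 * pi * freq * psi + phase0)
    dark <- matrix(0, cs, cs)
    for (ln in lines) dark <- dark + bezier_darkening(ln, cs)
    canvas <- clip255(base_level + ridges - dark)
    # local ridge orientation = direction of the phase gradient
    gpsi_x <- cbind(psi[, -1] - psi[, -cs], rep(cos(theta0), cs))
    gpsi_y <- rbind(psi[-1, ] - psi[-cs, ], rep(sin(theta0), cs))
    list(seed = as.integer(seed), size = size, canvas_size = cs,
         canvas = canvas, orientation = atan2(gpsi_y, gpsi_x),
         ridge_frequency = freq, ridge_amplitude = amp,
         base_level = base_level, principal_lines = lines)
  })
}

# Gaussian-profile darkening field of one quadratic Bezier principal line.
bezier_darkening <- function(ln, cs, n_samples = 150L) {
  t <- seq(0, 1, length.out = n_samples)
  bx <- (1 - t)^2 * ln$p0[1] + 2 * (1 - t) * t * ln$p1[1] + t^2 * ln$p2[1]
  by <- (1 - t)^2 * ln$p0[2] + 2 * (1 - t) * t * ln$p1[2] + t^2 * ln$p2[2]
  y <- matrix(seq_len(cs), cs, cs)
  x <- matrix(seq_len(cs), cs, cs, byrow = TRUE)
  d2 <- matrix(Inf, cs, cs)
  for (k in seq_len(n_samples))
    d2 <- pmin(d2, (x - bx[k])^2 + (y - by[k])^2)
  ln$depth * exp(-d2 / (2 * ln$width^2))
}

#' Specification of one degraded sample
#'
#' Residual misalignment after ROI preprocessing is small: rotation within
#' \[-3, 3\] degrees and integer shifts within \[-2, 2\] pixels.
#'
#' @param rotation_deg Rotation in degrees.
#' @param shift_px Integer `c(row, col)` shift.
#' @param blur_sigma Gaussian defocus width (0 = sharp).
#' @param noise_std Additive Gaussian noise std (gray levels).
#' @param seed Integer seed for the noise draw.
#' @return Validated spec list.
#' @export
sample_spec <- function(rotation_deg = 0, shift_px = c(0L, 0L),
                        blur_sigma = 0, noise_std = 0, seed = 1L) {
  stopifnot(abs(rotation_deg) <= 3 + 1e-9,
            length(shift_px) == 2L, all(abs(shift_px) <= 2),
            blur_sigma >= 0, noise_std >= 0)
  list(rotation_deg = rotation_deg,
       shift_px = as.integer(round(shift_px)),
       blur_sigma = blur_sigma, noise_std = noise_std,
       seed = as.integer(seed))
}

#' Central crop of a template (its undegraded base image)
#'
#' @param tpl Template from [make_identity()].
#' @param size ROI side.
#' @return Gray matrix `size` x `size`.
#' @export
base_image <- function(tpl, size = tpl$size) {
  cs <- tpl$canvas_size
  off <- (cs - size) %/% 2L
  tpl$canvas[(off + 1L):(off + size), (off + 1L):(off + size)]
}

#' Render one degraded sample of an identity
#'
#' Rotates the padded canvas about its center by bilinear resampling, crops
#' the shifted ROI window, then applies Gaussian defocus blur and additive
#' noise. Deterministic given the spec's seed.
#'
#' @param tpl Template from [make_identity()].
#' @param spec [sample_spec()] list.
#' @param size ROI side.
#' @return Gray matrix in \[0, 255\].
#' @export
render_sample <- function(tpl, spec, size = tpl$size) {
  cs <- tpl$canvas_size
  img <- tpl$canvas
  if (spec$rotation_deg != 0) img <- rotate_image(img, spec$rotation_deg)
  off <- (cs - size) %/% 2L
  r0 <- off + spec$shift_px[1L]
  c0 <- off + spec$shift_px[2L]
  out <- img[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size)]
  if (spec$blur_sigma > 0 || spec$noise_std > 0) {
    sig <- max(spec$blur_sigma, 1e-6)
    out <- apply_gddm(out, sig, spec$noise_std, spec$seed)
  }
  clip255(out)
}

#' Generate a labeled gallery/probe database
#'
#' Mirrors a two-session protocol: gallery samples are mildly degraded
#' (blur sigma U\[0.5, 1.5\], rotation U\[-1.5, 1.5\] deg, shifts in
#' \[-1, 1\]); probe samples carry the test degradation (blur sigma
#' U\[`blur_range`\], rotation U\[-3, 3\] deg, shifts in \[-2, 2\]).
#' Fully reproducible from `master_seed`.
#'
#' @param n_identities Number of distinct palms.
#' @param n_gallery_per,n_probe_per Samples per palm per set.
#' @param blur_range `c(lo, hi)` for probe blur sigma.
#' @param master_seed Integer master seed.
#' @param size ROI side.
#' @param noise_std Additive noise std applied to every sample.
#' @return List with `gallery`, `probe` (lists of gray matrices),
#'   `gallery_id`, `probe_id` (integer identity labels), and `meta`
#'   (data.frame of per-sample degradation parameters).
#' @export
make_database <- function(n_identities, n_gallery_per, n_probe_per,
                          blur_range = c(1, 7), master_seed = 1L,
                          size = 128L, noise_std = 0) {
  stopifnot(n_identities >= 1, n_gallery_per >= 1, n_probe_per >= 1,
            blur_range[1] >= 0, blur_range[1] <= blur_range[2])
  plan <- with_seed(master_seed, {
    id_seeds <- sample.int(2^31 - 2, n_identities)
    n_g <- n_identities * n_gallery_per
    n_p <- n_identities * n_probe_per
    list(
      id_seeds = id_seeds,
      g = data.frame(
        id = rep(seq_len(n_identities), each = n_gallery_per),
        rot = stats::runif(n_g, -1.5, 1.5),
        sr = sample(-1:1, n_g, replace = TRUE),
        sc = sample(-1:1, n_g, replace = TRUE),
        sigma = stats::runif(n_g, 0.5, 1.5),
        seed = sample.int(2^31 - 2, n_g)),
      p = data.frame(
        id = rep(seq_len(n_identities), each = n_probe_per),
        rot = stats::runif(n_p, -3, 3),
        sr = sample(-2:2, n_p, replace = TRUE),
        sc = sample(-2:2, n_p, replace = TRUE),
        sigma = stats::runif(n_p, blur_range[1], blur_range[2]),
        seed = sample.int(2^31 - 2, n_p)))
  })
  tpls <- lapply(plan$id_seeds, make_identity, size = size)
  render_set <- function(df) {
    lapply(seq_len(nrow(df)), function(k) {
      sp <- sample_spec(df$rot[k], c(df$sr[k], df$sc[k]), df$sigma[k],
                        noise_std, df$seed[k])
      render_sample(tpls[[df$id[k]]], sp, size)
    })
  }
  meta <- rbind(cbind(plan$g, session = 1L), cbind(plan$p, session = 2L))
  list(gallery = render_set(plan$g), probe = render_set(plan$p),
       gallery_id = plan$g$id, probe_id = plan$p$id, meta = meta)
}
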