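# NCC matching and biometric verification metrics.
#
# A probe-gallery comparison is genuine when both images come from the same
# palm and imposter otherwise. Accepting a comparison when its score is at
# least the threshold t gives, per threshold,
#   FRR(t) = NFR / NEA  (genuine comparisons scoring below t)
#   FAR(t) = NFA / NIA  (imposter comparisons scoring at or above t).
# The equal error rate is the common value where the two curves cross.

#' Normalized correlation coefficient
#'
#' Pearson correlation with population (divide-by-n) standard deviations:
#' `sum((A - mean(A)) * (B - mean(B))) / (n * sd_pop(A) * sd_pop(B))`.
#' Invariant to positive affine rescaling of either argument; a
#' zero-variance input yields 0 with a warning (degenerate feature).
#'
#' @param a,b Equal-length numeric vectors, length >= 2.
#' @return Score in \[-1, 1\].
#' @export
ncc <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("vectors must have length >= 2", call. = FALSE)
  da <- a - mean(a); db <- b - mean(b)
  sa <- sqrt(sum(da^2) / n); sb <- sqrt(sum(db^2) / n)
  if (sa == 0 || sb == 0) {
    warning("zero-variance feature vector; NCC defined as 0")
    return(0)
  }
  sum(da * db) / (n * sa * sb)
}

# All-pairs NCC between the rows of two feature matrices. Zero-variance
# rows score 0 against everything.
ncc_matrix <- function(A, B) {
  stand <- function(M) {
    M <- M - rowMeans(M)
    s <- sqrt(rowSums(M^2))
    bad <- s == 0
    if (any(bad)) {
      warning("zero-variance feature vector(s); NCC defined as 0")
      s[bad] <- 1
    }
    M / s
  }
  tcrossprod(stand(A), stand(B))
}

#' Verification protocol match counts
#'
#' Every probe image is matched against every gallery image:
#' `total = (n_palms * n_probe_per) * (n_palms * n_gallery_per)`; a match is
#' genuine when probe and gallery share the palm.
#'
#' @param n_palms Number of distinct palms.
#' @param n_gallery_per,n_probe_per Images per palm in gallery / probe set.
#' @return List with `total`, `genuine`, `imposter` (numeric).
#' @export
match_counts <- function(n_palms, n_gallery_per, n_probe_per) {
  stopifnot(n_palms >= 1, n_gallery_per >= 1, n_probe_per >= 1)
  total <- (n_palms * n_probe_per) * (n_palms * n_gallery_per)
  genuine <- n_palms * n_probe_per * n_gallery_per
  list(total = total, genuine = genuine, imposter = total - genuine)
}

#' Genuine/imposter score container
#'
#' @param genuine,imposter Numeric score vectors in \[-1, 1\].
#' @return Validated list.
#' @export
score_set <- function(genuine, imposter) {
  if (length(genuine) == 0L || length(imposter) == 0L)
    stop("both score lists must be non-empty", call. = FALSE)
  tol <- 1e-9
  if (any(genuine < -1 - tol | genuine > 1 + tol) ||
      any(imposter < -1 - tol | imposter > 1 + tol))
    stop("scores must lie in [-1, 1]", call. = FALSE)
  list(genuine = as.numeric(genuine), imposter = as.numeric(imposter))
}

#' FAR/FRR curves over a threshold sweep
#'
#' Accept iff score >= threshold (ties accept). The default threshold grid
#' is every distinct observed score plus -Inf/+Inf sentinels, in decreasing
#' order, so every attainable operating point appears.
#'
#' @param scores [score_set()] list.
#' @param thresholds Optional decreasing threshold vector.
#' @return List with `thresholds` (decreasing), `far`, `frr`.
#' @export
far_frr <- function(scores, thresholds = NULL) {
  g <- scores$genuine; im <- scores$imposter
  if (length(g) == 0L || length(im) == 0L)
    stop("both score lists must be non-empty", call. = FALSE)
  if (is.null(thresholds))
    thresholds <- c(Inf, sort(unique(c(g, im)), decreasing = TRUE), -Inf)
  else
    thresholds <- sort(thresholds, decreasing = TRUE)
  frr <- vapply(thresholds, function(t) mean(g < t), numeric(1))
  far <- vapply(thresholds, function(t) mean(im >= t), numeric(1))
  list(thresholds = thresholds, far = far, frr = frr)
}

#' Equal error rate of a FAR/FRR curve
#'
#' Locates the crossing of FAR and FRR by linear interpolation between the
#' two adjacent thresholds where `FAR - FRR` changes sign, and returns the
#' common error value together with the interpolated threshold.
#'
#' @param curve Result of [far_frr()].
#' @return List with `eer` and `threshold`.
#' @export
eer <- function(curve) {
  d <- curve$far - curve$frr
  k <- which(d >= 0)[1L]
  if (is.na(k)) stop("FAR/FRR curves do not cross", call. = FALSE)
  if (k == 1L || d[k] == 0)
    return(list(eer = (curve$far[k] + curve$frr[k]) / 2,
                threshold = curve$thresholds[k]))
  d0 <- d[k - 1L]; d1 <- d[k]
  alpha <- if (d1 - d0 > 0) -d0 / (d1 - d0) else 0
  e <- curve$far[k - 1L] + alpha * (curve$far[k] - curve$far[k - 1L])
  t0 <- curve$thresholds[k - 1L]; t1 <- curve$thresholds[k]
  thr <- if (is.finite(t0) && is.finite(t1)) t0 + alpha * (t1 - t0) else t1
  list(eer = e, threshold = thr)
}

#' Decidability index between genuine and imposter scores
#'
#' `d = |mu_g - mu_i| / sqrt((sd_g^2 + sd_i^2) / 2)` with population
#' (divide-by-n) standard deviations, matching the NCC convention. Larger
#' values mean better-separated score distributions.
#'
#' @param scores [score_set()] list, each side with >= 2 scores.
#' @return Non-negative float.
#' @export
decidability <- function(scores) {
  g <- scores$genuine; im <- scores$imposter
  if (length(g) < 2L || length(im) < 2L)
    stop("need at least two scores on each side", call. = FALSE)
  vg <- mean((g - mean(g))^2)
  vi <- mean((im - mean(im))^2)
  if (vg == 0 && vi == 0)
    stop("both score distributions are degenerate", call. = FALSE)
  abs(mean(g) - mean(im)) / sqrt((vg + vi) / 2)
}

#' Summarize a score set into verification metrics
#'
#' @param scores [score_set()] list.
#' @return List with `eer`, `eer_threshold`, `decidability`, `n_genuine`,
#'   `n_imposter`, and the ROC `curve`.
#' @export
evaluate_scores <- function(scores) {
  curve <- far_frr(scores)
  e <- eer(curve)
  list(eer = e$eer, eer_threshold = e$threshold,
       decidability = decidability(scores),
       n_genuine = length(scores$genuine),
       n_imposter = length(scores$imposter),
       curve = curve)
}
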