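# End-to-end verification pipeline: (optional) structure-layer extraction,
# descriptor computation, NCC scoring and FAR/FRR/EER summarization.
#
# The three descriptor switches select the ablation arms:
#   use_rigo = FALSE, use_weights = FALSE  -> blockwise HOG
#   use_rigo = TRUE,  use_weights = FALSE  -> RHOG
#   use_rigo = TRUE,  use_weights = TRUE   -> WRHOG
# crossed with use_vo (descriptor on the raw image vs the structure layer),
# the full method being VO + WRHOG.

#' Pipeline configuration
#'
#' @param vo [vo_params()] list for the structure-layer decomposition.
#' @param block_size Descriptor block side (default 16).
#' @param n_bins Orientation bins per block (default 12).
#' @param rigo_r,rigo_k RIGO circle radius and sample count.
#' @param dbc_scales Box-counting scales (`NULL` = power-of-two divisors).
#' @param use_vo Run the descriptor on the structure layer.
#' @param use_rigo Use the rotation-invariant gradient operator.
#' @param use_weights Apply fractal-dimension block weights.
#' @param decision_threshold Accept threshold for [verify()].
#' @return Config list.
#' @export
pipeline_config <- function(vo = vo_params(), block_size = 16L,
                            n_bins = 12L, rigo_r = 2, rigo_k = 8L,
                            dbc_scales = NULL, use_vo = TRUE,
                            use_rigo = TRUE, use_weights = TRUE,
                            decision_threshold = 0.5) {
  stopifnot(block_size >= 4L, n_bins >= 2L, rigo_r > 0, rigo_k >= 2L)
  list(vo = vo, block_size = as.integer(block_size),
       n_bins = as.integer(n_bins), rigo_r = rigo_r,
       rigo_k = as.integer(rigo_k), dbc_scales = dbc_scales,
       use_vo = isTRUE(use_vo), use_rigo = isTRUE(use_rigo),
       use_weights = isTRUE(use_weights),
       decision_threshold = decision_threshold)
}

#' Extract the configured feature vector from an image
#'
#' @param img Gray matrix in \[0, 255\].
#' @param cfg [pipeline_config()] list.
#' @return Numeric feature vector of length
#'   `floor(H/b) * floor(W/b) * n_bins`.
#' @export
extract_features <- function(img, cfg = pipeline_config()) {
  layer <- if (cfg$use_vo) structure_layer(img, cfg$vo) else img
  hm <- block_histograms(layer, cfg$block_size, cfg$n_bins,
                         cfg$rigo_r, cfg$rigo_k, use_rigo = cfg$use_rigo)
  wts <- if (cfg$use_weights)
    block_fractal_weights(layer, cfg$block_size, cfg$dbc_scales)
  else NULL
  feature_from_hist(hm, cfg$block_size, cfg$n_bins,
                    weighted = cfg$use_weights, weights = wts)
}

#' Extract all six ablation-arm features at once
#'
#' Shares the VO decomposition and RIGO maps across arms, which is much
#' cheaper than six independent [extract_features()] calls.
#'
#' @param img Gray matrix.
#' @param cfg [pipeline_config()] list (the use_* switches are ignored).
#' @return Named list of feature vectors: `hog`, `rhog`, `wrhog`,
#'   `vo_hog`, `vo_rhog`, `vo_wrhog`.
#' @export
extract_feature_arms <- function(img, cfg = pipeline_config()) {
  arms_for <- function(layer, prefix) {
    hm_h <- block_histograms(layer, cfg$block_size, cfg$n_bins,
                             use_rigo = FALSE)
    hm_r <- block_histograms(layer, cfg$block_size, cfg$n_bins,
                             cfg$rigo_r, cfg$rigo_k, use_rigo = TRUE)
    wts <- block_fractal_weights(layer, cfg$block_size, cfg$dbc_scales)
    out <- list(
      feature_from_hist(hm_h, cfg$block_size, cfg$n_bins, FALSE),
      feature_from_hist(hm_r, cfg$block_size, cfg$n_bins, FALSE),
      feature_from_hist(hm_r, cfg$block_size, cfg$n_bins, TRUE, wts))
    names(out) <- paste0(prefix, c("hog", "rhog", "wrhog"))
    out
  }
  u <- structure_layer(img, cfg$vo)
  c(arms_for(img, ""), arms_for(u, "vo_"))
}

#' Verify a claimed identity
#'
#' Scores the probe feature vector against every gallery entry of the
#' claimed identity and accepts when the best NCC reaches the threshold.
#'
#' @param probe Feature vector.
#' @param gallery List or matrix (rows) of gallery feature vectors.
#' @param gallery_id Identity label per gallery entry.
#' @param claimed_id The claimed identity.
#' @param threshold Accept threshold.
#' @return List with `accept`, `score`, `n_compared`.
#' @export
verify <- function(probe, gallery, gallery_id, claimed_id,
                   threshold = 0.5) {
  if (is.list(gallery)) gallery <- do.call(rbind, gallery)
  if (ncol(gallery) != length(probe))
    stop("feature length mismatch", call. = FALSE)
  sel <- which(gallery_id == claimed_id)
  if (length(sel) == 0L)
    stop("no gallery entries for claimed identity", call. = FALSE)
  sc <- as.numeric(ncc_matrix(matrix(probe, nrow = 1L),
                              gallery[sel, , drop = FALSE]))
  best <- max(sc)
  list(accept = best >= threshold, score = best, n_compared = length(sel))
}

#' Run the all-vs-all verification experiment
#'
#' Extracts features for every gallery and probe image, scores every
#' probe-gallery pair with NCC, splits scores genuine/imposter by identity
#' label and summarizes FAR/FRR/EER and decidability.
#'
#' @param db Database from [make_database()] (or a list with the same
#'   `gallery`/`probe`/`gallery_id`/`probe_id` fields).
#' @param cfg [pipeline_config()] list.
#' @return List with `summary` (eer, eer_threshold, decidability, counts),
#'   `curve`, and `scores` ([score_set()]).
#' @export
run_experiment <- function(db, cfg = pipeline_config()) {
  gal <- t(vapply(db$gallery, extract_features,
                  numeric(feature_length(db$gallery[[1L]], cfg)), cfg))
  pro <- t(vapply(db$probe, extract_features,
                  numeric(feature_length(db$probe[[1L]], cfg)), cfg))
  summarize_scores(score_matrix_split(pro, gal, db$probe_id,
                                      db$gallery_id))
}

feature_length <- function(img, cfg) {
  (nrow(img) %/% cfg$block_size) * (ncol(img) %/% cfg$block_size) *
    cfg$n_bins
}

# Split an all-vs-all probe x gallery NCC score matrix by label match.
score_matrix_split <- function(pro, gal, probe_id, gallery_id) {
  S <- ncc_matrix(pro, gal)
  same <- outer(probe_id, gallery_id, `==`)
  score_set(S[same], S[!same])
}

summarize_scores <- function(scores) {
  ev <- evaluate_scores(scores)
  list(summary = ev[c("eer", "eer_threshold", "decidability",
                      "n_genuine", "n_imposter")],
       curve = ev$curve, scores = scores)
}

#' Run all six ablation arms on one database
#'
#' @param db Database from [make_database()].
#' @param cfg [pipeline_config()] list.
#' @return Named list (per arm) of experiment results as in
#'   [run_experiment()].
#' @export
run_ablation <- function(db, cfg = pipeline_config()) {
  arm_names <- c("hog", "rhog", "wrhog", "vo_hog", "vo_rhog", "vo_wrhog")
  gal <- lapply(db$gallery, extract_feature_arms, cfg = cfg)
  pro <- lapply(db$probe, extract_feature_arms, cfg = cfg)
  out <- lapply(arm_names, function(a) {
    G <- do.call(rbind, lapply(gal, `[[`, a))
    P <- do.call(rbind, lapply(pro, `[[`, a))
    summarize_scores(score_matrix_split(P, G, db$probe_id, db$gallery_id))
  })
  names(out) <- arm_names
  out
}
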