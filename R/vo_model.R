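# Vese-Osher (TV-G, p = 1) structure/texture decomposition.
#
# An image f is split as f ~ u + v where u is a cartoon-like structure
# layer of bounded variation and v = div(g1, g2) is an oscillatory texture
# layer expressed through an auxiliary vector field g. The model minimized
# here is
#   E(u, g) = TV_eps(u) + lam * ||f - u - div g||_2^2
#           + mu * sum sqrt(g1^2 + g2^2 + eps^2)
# with TV_eps the eps-regularized discrete total variation (forward
# differences, replicated edges). The structure layer is what survives
# defocus blur, which is why the descriptor pipeline runs on u by default.

#' Parameters for the Vese-Osher decomposition
#'
#' @param lam Positive fidelity penalty on `f - u - div g` (applied on the
#'   internal \[0, 1\] gray scale).
#' @param mu Positive penalty on the magnitude of the auxiliary field `g`;
#'   smaller values let more oscillation into the texture layer.
#' @param eps Regularizer inside the square roots of the TV and `|g|` terms.
#' @param max_outer Maximum number of alternating outer iterations.
#' @param tol Relative L2 change of `u` below which iteration stops.
#' @return List of validated parameters (p is fixed at 1).
#' @export
vo_params <- function(lam = 5, mu = 0.01, eps = 1e-4,
                      max_outer = 100L, tol = 1e-3) {
  stopifnot(lam > 0, mu > 0, eps > 0, tol > 0, max_outer >= 1)
  list(lam = lam, mu = mu, eps = eps,
       max_outer = as.integer(max_outer), tol = tol, p = 1L)
}

#' Vese-Osher energy of a candidate decomposition
#'
#' Evaluates the objective at the given layers on whatever gray scale they
#' are supplied in. Uses the same stencils as the solver: forward
#' differences for the gradient of `u`, backward differences for `div g`.
#'
#' @param f,u Image and structure layer (same-shape matrices).
#' @param g1,g2 Auxiliary vector-field components (same shape).
#' @param params `vo_params()` list.
#' @return Finite scalar energy.
#' @export
vo_energy <- function(f, u, g1, g2, params = vo_params()) {
  if (!all(dim(f) == dim(u)) || !all(dim(f) == dim(g1)) ||
      !all(dim(f) == dim(g2)))
    stop("all layers must share the image's shape", call. = FALSE)
  h <- nrow(f); w <- ncol(f)
  ux <- cbind(u[, -1, drop = FALSE] - u[, -w, drop = FALSE], rep(0, h))
  uy <- rbind(u[-1, , drop = FALSE] - u[-h, , drop = FALSE], rep(0, w))
  tv <- sum(sqrt(ux^2 + uy^2 + params$eps^2))
  v <- div_backward(g1, g2)
  fid <- params$lam * sum((f - u - v)^2)
  gnorm <- params$mu * sum(sqrt(g1^2 + g2^2 + params$eps^2))
  tv + fid + gnorm
}

# Backward-difference divergence with zero inflow at the first row/column,
# matching the solver's stencil exactly.
div_backward <- function(g1, g2) {
  h <- nrow(g1); w <- ncol(g1)
  dx <- g1 - cbind(rep(0, h), g1[, -w, drop = FALSE])
  dy <- g2 - rbind(rep(0, w), g2[-h, , drop = FALSE])
  dx + dy
}

#' Decompose an image into structure and texture layers
#'
#' Alternating half-quadratic minimization: a Gauss-Seidel sweep for `u`
#' with the TV diffusivity lagged, then coordinate-descent sweeps for `g1`
#' and `g2` with the `|g|` weight lagged, one each per outer iteration. The
#' image is normalized to \[0, 1\] internally for parameter stability; the
#' returned layers are rescaled to the input's gray range. The energy trace
#' is reported on the internal scale.
#'
#' @param f Gray matrix in \[0, 255\].
#' @param params `vo_params()` list.
#' @return List with `u`, `v`, `g1`, `g2` (input scale), `energy_trace`
#'   (initial energy followed by one value per outer iteration),
#'   `iterations`, and `converged` (FALSE means `max_outer` was hit).
#' @export
vo_decompose <- function(f, params = vo_params()) {
  check_image_matrix(f, min_side = 2L)
  fn <- f / 255
  res <- vo_solve_cpp(fn, params$lam, params$mu, params$eps,
                      params$max_outer, params$tol)
  list(u = res$u * 255, v = res$v * 255,
       g1 = res$g1 * 255, g2 = res$g2 * 255,
       energy_trace = res$energy_trace,
       iterations = res$iterations,
       converged = res$converged)
}

#' Structure layer of an image
#'
#' Convenience wrapper around [vo_decompose()] returning only the structure
#' layer `u`, clipped back to the \[0, 255\] gray range.
#'
#' @inheritParams vo_decompose
#' @return Gray matrix, same shape as `f`.
#' @export
structure_layer <- function(f, params = vo_params()) {
  clip255(vo_decompose(f, params)$u)
}
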