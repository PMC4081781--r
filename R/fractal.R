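# Differential box counting (DBC) fractal dimension.
#
# The gray surface z = f(x, y) over an M x M block is covered, at each grid
# scale s, by boxes of height s' = s * G / M stacked over s x s cells. The
# cell's box count is floor(l_max/s') - floor(l_min/s') + 1, where l_max and
# l_min are the cell's extreme gray values. The fractal dimension is the
# least-squares slope of log N_s against log(M/s); it ranges from 2 (flat)
# towards 3 (rough) and serves as the block weight in the WRHOG descriptor.

#' Differential box count at one scale
#'
#' @param block Square gray matrix of side M.
#' @param s Grid scale; must divide M.
#' @param gray_levels Gray-level count G (box height is `s * G / M`).
#' @return Integer total box count `N_s >= (M/s)^2`.
#' @export
dbc_box_count <- function(block, s, gray_levels = 256L) {
  check_image_matrix(block)
  M <- nrow(block)
  if (ncol(block) != M) stop("block must be square", call. = FALSE)
  s <- as.integer(s)
  if (s < 1L || M %% s != 0L)
    stop("scale s must divide the block side", call. = FALSE)
  n_cells <- M %/% s
  sp <- s * gray_levels / M
  a <- array(block, dim = c(s, n_cells, s, n_cells))
  lmin <- apply(a, c(2L, 4L), min)
  lmax <- apply(a, c(2L, 4L), max)
  sum(floor(lmax / sp) - floor(lmin / sp) + 1)
}

# Power-of-two divisors of M in [2, M/2]: at least two grid cells per side
# and at least two pixels per cell.
default_dbc_scales <- function(M) {
  s <- 2L^(1:30)
  s[s >= 2L & s <= M %/% 2L & M %% s == 0L]
}

#' Fractal dimension by differential box counting
#'
#' Ordinary least-squares slope of `log N_s` versus `log(M/s)` over the
#' scale set. A constant block gives exactly 2; i.i.d. noise approaches 3.
#'
#' @param block Square gray matrix.
#' @param scales Grid scales (>= 2 of them, each dividing the block side);
#'   `NULL` for the power-of-two divisors in \[2, M/2\].
#' @param gray_levels Gray-level count G.
#' @return Estimated fractal dimension (float).
#' @export
fractal_dimension <- function(block, scales = NULL, gray_levels = 256L) {
  check_image_matrix(block)
  M <- nrow(block)
  if (ncol(block) != M) stop("block must be square", call. = FALSE)
  if (is.null(scales)) scales <- default_dbc_scales(M)
  scales <- as.integer(scales)
  if (length(scales) < 2L)
    stop("need at least two scales for the regression", call. = FALSE)
  ns <- vapply(scales, function(s) dbc_box_count(block, s, gray_levels),
               numeric(1))
  x <- log(M / scales)
  y <- log(ns)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
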