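# Loss terms and composite objectives.
#
# The similarity term is the negative mean squared local normalized
# cross-correlation (the standard realization for unsupervised registration):
# per voxel, over a centred window of `window` voxels per axis,
#   cc2 = (sum (a - abar)(b - bbar))^2 /
#         ((sum (a - abar)^2)(sum (b - bbar)^2) + epsilon)
# and L_sim = -mean(cc2) in [-1, 0].  Windows are truncated at the image
# border (local sums use the actual number of in-bounds voxels), so border
# windows are genuine statistics rather than zero-padded ones.
#
# All reductions are means rather than sums so that the balancing weights
# alpha, beta and lambda are resolution-independent.

lcc_stats <- function(a, b, window, epsilon) {
  dims <- dim(a)
  n <- cpp_boxsum(array(1, dims), dims, window)
  Sa <- cpp_boxsum(a, dims, window)
  Sb <- cpp_boxsum(b, dims, window)
  Saa <- cpp_boxsum(a * a, dims, window)
  Sbb <- cpp_boxsum(b * b, dims, window)
  Sab <- cpp_boxsum(a * b, dims, window)
  abar <- Sa / n
  bbar <- Sb / n
  cross <- Sab - n * abar * bbar
  A <- pmax(Saa - n * abar^2, 0)
  B <- pmax(Sbb - n * bbar^2, 0)
  den <- A * B + epsilon
  list(n = n, abar = abar, bbar = bbar, cross = cross, A = A, B = B,
       den = den, cc2 = cross^2 / den)
}

#' Local normalized cross-correlation loss
#'
#' Negative mean squared local NCC between two images; a value in
#' \[-1, 0\], with -1 meaning perfect local (affine) intensity agreement.
#'
#' @param a,b `scalar_image`s or numeric arrays of identical shape.
#' @param window Odd per-axis window size.
#' @param epsilon Positive stabilizer in the denominator.
#' @return A single number in \[-1, 0\].
#' @export
local_cross_correlation <- function(a, b, window = 9L, epsilon = 1e-5) {
  a <- grid_values(a); b <- grid_values(b)
  check_same_shape(a, b, "images")
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 1L)
    stop("window must be odd", call. = FALSE)
  if (window > min(dim(a)))
    stop("window (", window, ") larger than the smallest image axis (",
         min(dim(a)), ")", call. = FALSE)
  st <- lcc_stats(a, b, window, epsilon)
  -mean(st$cc2)
}

# Gradient of local_cross_correlation with respect to its second argument.
local_cross_correlation_grad <- function(a, b, window = 9L, epsilon = 1e-5) {
  a <- grid_values(a); b <- grid_values(b)
  st <- lcc_stats(a, b, window, epsilon)
  dims <- dim(a)
  c1 <- 2 * st$cross / st$den
  c2 <- 2 * st$cross^2 * st$A / st$den^2
  g <- a * cpp_boxsum(c1, dims, window) -
    cpp_boxsum(c1 * st$abar, dims, window) -
    b * cpp_boxsum(c2, dims, window) +
    cpp_boxsum(c2 * st$bbar, dims, window)
  -g / length(a)
}

# Forward difference along a spatial axis of a (d, n1..nd) field array with
# a zero difference at the trailing edge (Neumann/replicate boundary).
axis_forward_diff <- function(x, axis) {
  dm <- dim(x)
  idx <- lapply(dm, seq_len)
  n <- dm[axis]
  idx[[axis]] <- c(seq_len(n - 1L) + 1L, n)
  do.call(`[`, c(list(x), idx, list(drop = FALSE))) - x
}

# Adjoint-ish helper: shift D forward along axis, zero-filling the first slice.
axis_shift_down <- function(x, axis) {
  dm <- dim(x)
  idx <- lapply(dm, seq_len)
  n <- dm[axis]
  idx[[axis]] <- c(1L, seq_len(n - 1L))
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  first <- lapply(dm, seq_len)
  first[[axis]] <- 1L
  out <- do.call(`[<-`, c(list(out), first, list(value = 0)))
  out
}

#' Smoothness penalty on a deformation field
#'
#' Mean over voxels, axes and components of squared forward finite
#' differences; the final difference at each axis end is zero (Neumann
#' boundary).  Zero iff the field is constant per component.
#'
#' @param field A `deformation_field` or `(d, n1..nd)` array.
#' @return A single nonnegative number.
#' @export
smoothness_penalty <- function(field) {
  u <- field_values(field)
  d <- length(dim(u)) - 1L
  total <- 0
  for (a in seq_len(d)) total <- total + sum(axis_forward_diff(u, a + 1L)^2)
  total / (length(u) * d)
}

# Gradient of smoothness_penalty with respect to the field.
smoothness_penalty_grad <- function(field) {
  u <- field_values(field)
  d <- length(dim(u)) - 1L
  g <- array(0, dim = dim(u))
  for (a in seq_len(d)) {
    D <- axis_forward_diff(u, a + 1L)
    g <- g - 2 * D + 2 * axis_shift_down(D, a + 1L)
  }
  g / (length(u) * d)
}

#' Coupling penalty between two fields
#'
#' Mean squared difference over all components and voxels; zero iff `u = v`.
#'
#' @param u,v `deformation_field`s or arrays of identical shape.
#' @return A single nonnegative number.
#' @export
coupling_penalty <- function(u, v) {
  u <- field_values(u); v <- field_values(v)
  check_same_shape(u, v, "fields")
  mean((u - v)^2)
}

#' Similarity sub-problem loss
#'
#' `L_sim(fixed, warp(moving, u)) + alpha * mean((u - v)^2)`, the objective
#' minimized in `u` while the auxiliary field `v` is held constant.
#'
#' @param fixed,moving Images of identical shape.
#' @param u Field being optimized.
#' @param v Auxiliary (smoothed) field, treated as a constant.
#' @param alpha Coupling weight.
#' @param window,epsilon LCC parameters.
#' @return A single number.
#' @export
similarity_subproblem_loss <- function(fixed, moving, u, v, alpha = 0.1,
                                       window = 9L, epsilon = 1e-5) {
  warped <- warp_image(moving, u, "linear")
  local_cross_correlation(fixed, warped, window, epsilon) +
    alpha * coupling_penalty(u, v)
}

#' Smoothing (denoiser) sub-problem loss
#'
#' `mean((v - u)^2) + beta * smoothness_penalty(v)`, the strictly convex
#' quadratic minimized in `v` while `u` is held constant.
#'
#' @param u Field from the similarity step (constant here).
#' @param v Candidate smoothed field.
#' @param beta Smoothness weight.
#' @return A single nonnegative number.
#' @export
denoiser_subproblem_loss <- function(u, v, beta = 1) {
  coupling_penalty(v, u) + beta * smoothness_penalty(v)
}

# Gradient of denoiser_subproblem_loss with respect to v.
denoiser_subproblem_grad <- function(u, v, beta = 1) {
  u <- field_values(u); v <- field_values(v)
  2 * (v - u) / length(v) + beta * smoothness_penalty_grad(v)
}

#' Joint registration objective
#'
#' `L_sim(fixed, warp(moving, phi)) + lambda_ * smoothness_penalty(phi)`,
#' used for monitoring the alternating scheme and as the loss of the
#' in-loss-smoothing baseline.
#'
#' @param fixed,moving Images of identical shape.
#' @param phi Deformation field.
#' @param lambda_ Smoothness weight.
#' @param window,epsilon LCC parameters.
#' @return A single number.
#' @export
joint_objective <- function(fixed, moving, phi, lambda_ = 1,
                            window = 9L, epsilon = 1e-5) {
  warped <- warp_image(moving, phi, "linear")
  local_cross_correlation(fixed, warped, window, epsilon) +
    lambda_ * smoothness_penalty(phi)
}
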