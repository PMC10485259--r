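# Exact and iterative solvers for the decoupled sub-problems, used as a
# network-free "classical mode" and as the reference the learned denoiser is
# tested against.
#
# The smoothing sub-problem
#   min_v  mean((v - u)^2) + beta * smoothness_penalty(v)
# is a strictly convex quadratic whose unique minimizer solves, per
# component, the discrete screened-Poisson system
#   (I + beta' * L) v = u,    beta' = beta / d,
# where L is the Neumann (replicate-boundary) graph Laplacian assembled from
# the same forward differences the penalty uses, and beta' = beta/d because
# the coupling term averages over d*N entries while the smoothness term
# averages over d*d*N axis-component differences.  L is diagonalized by the
# type-II discrete cosine basis, so the solve is exact: per axis eigenvalues
# are 4*sin^2(pi*k/(2*n)), k = 0..n-1.

dct_matrix <- function(n) {
  k <- 0:(n - 1)
  i <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, i + 0.5) / n)
  C[1, ] <- sqrt(1 / n)
  C
}

# Apply matrix M (n x n) along a given axis of array x.
apply_axis <- function(x, M, axis) {
  dm <- dim(x)
  nd <- length(dm)
  perm <- c(axis, seq_len(nd)[-axis])
  xp <- aperm(x, perm)
  dim(xp) <- c(dm[axis], prod(dm[-axis]))
  yp <- M %*% xp
  dim(yp) <- dm[perm]
  aperm(yp, order(perm))
}

neumann_eigenvalues <- function(n) 4 * sin(pi * (0:(n - 1)) / (2 * n))^2

#' Closed-form minimizer of the smoothing sub-problem
#'
#' Returns the unique minimizer of
#' `coupling_penalty(v, u) + beta * smoothness_penalty(v)`, computed exactly
#' per component in the Neumann cosine eigenbasis (`method = "dct"`) or by a
#' sparse direct solve (`method = "sparse"`, the cross-check path for small
#' grids).
#'
#' @param u A `deformation_field` or `(d, n1..nd)` array.
#' @param beta Smoothness weight (>= 0).
#' @param method `"dct"` (default, exact and O(n log n)-ish via separable
#'   dense transforms) or `"sparse"` (direct solve of the same system).
#' @return Same type as `u`.
#' @export
closed_form_smooth <- function(u, beta, method = c("dct", "sparse")) {
  method <- match.arg(method)
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  uv <- field_values(u)
  dm <- dim(uv)
  d <- dm[1L]
  shape <- dm[-1L]
  bprime <- beta / length(shape)
  if (beta == 0) return(u)

  out <- array(0, dim = dm)
  if (method == "dct") {
    Cs <- lapply(shape, dct_matrix)
    lams <- lapply(shape, neumann_eigenvalues)
    denom <- array(1, dim = shape)
    for (a in seq_along(shape)) {
      lam_a <- array(rep(lams[[a]],
                         each = prod(shape[seq_len(a - 1L)]),
                         times = prod(shape[-seq_len(a)])),
                     dim = shape)
      denom <- denom + bprime * lam_a
    }
    for (c in seq_len(d)) {
      comp <- get_comp(uv, c)
      for (a in seq_along(shape)) comp <- apply_axis(comp, Cs[[a]], a)
      comp <- comp / denom
      for (a in seq_along(shape)) comp <- apply_axis(comp, t(Cs[[a]]), a)
      out <- set_comp(out, c, comp)
    }
  } else {
    A <- screened_poisson_matrix(shape, bprime)
    for (c in seq_len(d)) {
      comp <- get_comp(uv, c)
      sol <- Matrix::solve(A, as.vector(comp))
      out <- set_comp(out, c, array(as.numeric(sol), dim = shape))
    }
  }
  if (inherits(u, "deformation_field")) deformation_field(out) else out
}

# Sparse (I + bprime * L) with L the Neumann Laplacian as a Kronecker sum.
screened_poisson_matrix <- function(shape, bprime) {
  lap1 <- function(n) {
    if (n == 1L) return(Matrix::Matrix(0, 1, 1, sparse = TRUE))
    Matrix::bandSparse(n, n,
                       k = c(-1L, 0L, 1L),
                       diagonals = list(rep(-1, n - 1),
                                        c(1, rep(2, n - 2), 1),
                                        rep(-1, n - 1)))
  }
  eye <- function(n) Matrix::Diagonal(n)
  L <- NULL
  nd <- length(shape)
  for (a in seq_len(nd)) {
    term <- NULL
    for (q in seq_len(nd)) {
      blk <- if (q == a) lap1(shape[q]) else eye(shape[q])
      term <- if (is.null(term)) blk else Matrix::kronecker(blk, term)
    }
    L <- if (is.null(L)) term else L + term
  }
  Matrix::Diagonal(prod(shape)) + bprime * L
}

#' Network-free alternating solver for the decoupled objective
#'
#' Realizes the variable-splitting scheme without networks: alternates
#' `n_inner` gradient-descent steps on the similarity sub-problem in `u`
#' (with `v` fixed) with the exact closed-form update
#' `v <- closed_form_smooth(u, beta)`.
#'
#' @param fixed,moving `scalar_image`s or arrays of identical shape.
#' @param hp A [hyperparams()] object (alpha, beta, lcc_window, epsilon;
#'   lambda_ is used only for the recorded joint objective).
#' @param n_outer Number of outer alternations.
#' @param n_inner Gradient-descent steps on `u` per alternation.
#' @param step Gradient-descent step size.
#' @return A list with `u`, `v` (as `deformation_field`s) and `history`, a
#'   data frame of the joint objective per outer iteration.
#' @export
alternate_variational_solve <- function(fixed, moving, hp = hyperparams(),
                                        n_outer = 10L, n_inner = 20L,
                                        step = 20) {
  f <- grid_values(fixed); m <- grid_values(moving)
  check_same_shape(f, m, "images")
  shape <- dim(f)
  d <- length(shape)
  u <- array(0, dim = c(d, shape))
  v <- u
  m <- as.double(m); dim(m) <- shape
  nelem <- length(u)
  history <- data.frame(outer = integer(0), joint_objective = numeric(0))
  for (it in seq_len(n_outer)) {
    for (j in seq_len(n_inner)) {
      warped <- cpp_warp(m, shape, u, 0L)
      dlcc <- local_cross_correlation_grad(f, warped, hp$lcc_window,
                                           hp$epsilon)
      g <- cpp_warp_bwd_field(m, shape, u, dlcc) +
        2 * hp$alpha * (u - v) / nelem
      u <- u - step * g
    }
    v <- closed_form_smooth(u, hp$beta)
    jo <- joint_objective(f, m, u, hp$lambda_, hp$lcc_window, hp$epsilon)
    if (!is.finite(jo))
      stop("alternating solve diverged at outer iteration ", it,
           call. = FALSE)
    history <- rbind(history,
                     data.frame(outer = it, joint_objective = jo))
  }
  list(u = deformation_field(u), v = deformation_field(v),
       history = history)
}
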