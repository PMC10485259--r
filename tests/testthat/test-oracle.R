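test_that("the closed-form smoother handles the degenerate cases exactly", {
  set.seed(30)
  u <- array(rnorm(2 * 12 * 12), c(2, 12, 12))
  expect_identical(closed_form_smooth(u, 0), u)

  cst <- array(0, c(2, 10, 10))
  cst[1, , ] <- 2.5; cst[2, , ] <- -1
  expect_equal(closed_form_smooth(cst, 7), cst, tolerance = 1e-12)
})

test_that("cosine-transform and sparse solves agree", {
  set.seed(31)
  u <- array(rnorm(2 * 11 * 13), c(2, 11, 13))
  expect_equal(closed_form_smooth(u, 2, "dct"),
               closed_form_smooth(u, 2, "sparse"), tolerance = 1e-10)
  u3 <- array(rnorm(3 * 6 * 7 * 8), c(3, 6, 7, 8))
  expect_equal(closed_form_smooth(u3, 0.5, "dct"),
               closed_form_smooth(u3, 0.5, "sparse"), tolerance = 1e-10)
})

test_that("smoothing is linear and preserves per-component means", {
  set.seed(32)
  u1 <- array(rnorm(2 * 16 * 16), c(2, 16, 16))
  u2 <- array(rnorm(2 * 16 * 16), c(2, 16, 16))
  s <- function(u) closed_form_smooth(u, 3)
  expect_equal(s(2 * u1 - 0.5 * u2), 2 * s(u1) - 0.5 * s(u2),
               tolerance = 1e-8)
  v <- s(u1)
  for (c in 1:2)
    expect_equal(mean(v[c, , ]), mean(u1[c, , ]), tolerance = 1e-8)
})

test_that("stronger smoothing weights give smoother fields", {
  set.seed(33)
  u <- array(rnorm(2 * 20 * 20), c(2, 20, 20))
  pen <- vapply(c(0, 0.1, 1, 10),
                function(b) smoothness_penalty(closed_form_smooth(u, b)),
                numeric(1))
  expect_true(all(diff(pen) <= 0))
})

test_that("the smoother is the exact minimizer of the quadratic objective", {
  set.seed(34)
  u <- array(rnorm(2 * 16 * 16), c(2, 16, 16))
  beta <- 1.7
  v <- closed_form_smooth(u, beta)
  obj <- denoiser_subproblem_loss(u, v, beta)
  # analytic gradient vanishes at the minimizer
  g <- splitreg:::denoiser_subproblem_grad(u, v, beta)
  expect_lt(max(abs(g)), 1e-12)
  # and any perturbation increases the objective
  for (i in 1:25) {
    pert <- v + array(rnorm(length(v), sd = 0.05), dim(v))
    expect_gt(denoiser_subproblem_loss(u, pert, beta), obj)
  }
})

test_that("network-free alternation stays near identity on matched pairs", {
  spec <- tiny_synth_spec(seed = 3L)
  pair <- make_pair(spec)
  res <- alternate_variational_solve(pair$fixed, pair$fixed,
                                     hyperparams(lcc_window = 5),
                                     n_outer = 2, n_inner = 5, step = 20)
  mag <- sqrt(colSums(matrix(res$u$displacements^2, nrow = 2)))
  expect_lt(mean(mag), 0.05)
  expect_equal(nrow(res$history), 2)
})

test_that("one outer pass with alpha = 0 is plain gradient descent on LCC", {
  spec <- tiny_synth_spec(seed = 4L)
  pair <- make_pair(spec)
  hp <- hyperparams(alpha = 0, beta = 1, lcc_window = 9)
  res <- alternate_variational_solve(pair$fixed, pair$moving, hp,
                                     n_outer = 1, n_inner = 8, step = 15)
  # replicate manually
  f <- pair$fixed$values; m <- pair$moving$values
  u <- array(0, c(2, dim(f)))
  for (j in 1:8) {
    w <- warp_image(m, u)
    g <- splitreg:::warp_image_grad_field(
      m, u, splitreg:::local_cross_correlation_grad(f, w, 9, 1e-5))
    u <- u - 15 * g
  }
  expect_equal(res$u$displacements, u, tolerance = 1e-12)
})

test_that("divergent alternation reports the failing outer iteration", {
  spec <- tiny_synth_spec(seed = 5L)
  pair <- make_pair(spec)
  expect_error(
    alternate_variational_solve(pair$fixed, pair$moving, hyperparams(),
                                n_outer = 3, n_inner = 30, step = 1e9),
    "outer iteration")
})
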