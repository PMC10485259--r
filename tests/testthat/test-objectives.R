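test_that("local NCC is -1 for identical and affinely related images", {
  set.seed(7)
  a <- matrix(runif(16 * 16), 16, 16)
  expect_equal(local_cross_correlation(a, a, 9, 1e-10), -1,
               tolerance = 1e-3)
  expect_equal(local_cross_correlation(a, 2 * a + 3, 9, 1e-10), -1,
               tolerance = 1e-3)
})

test_that("local NCC matches the sliding-window oracle", {
  set.seed(8)
  a <- matrix(rnorm(12 * 12), 12, 12)
  b <- matrix(rnorm(12 * 12), 12, 12)
  expect_equal(local_cross_correlation(a, b, 5, 1e-5),
               ref_lcc(a, b, 5, 1e-5), tolerance = 1e-10)

  a3 <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  b3 <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  expect_equal(local_cross_correlation(a3, b3, 3, 1e-5),
               ref_lcc(a3, b3, 3, 1e-5), tolerance = 1e-10)

  val <- local_cross_correlation(a, b, 5)
  expect_gte(val, -1); expect_lte(val, 0)
})

test_that("local NCC rejects bad windows and mismatched shapes", {
  a <- matrix(0, 8, 8)
  expect_error(local_cross_correlation(a, matrix(0, 8, 9)), "identical shapes")
  expect_error(local_cross_correlation(a, a, window = 9), "larger than")
  expect_error(local_cross_correlation(a, a, window = 4), "odd")
})

test_that("LCC gradient matches central finite differences", {
  set.seed(9)
  a <- matrix(runif(10 * 10), 10, 10)
  b <- matrix(runif(10 * 10), 10, 10)
  g <- splitreg:::local_cross_correlation_grad(a, b, 5, 1e-5)
  h <- 1e-6
  worst <- 0
  for (i in sample(100, 25)) {
    bp <- b; bp[i] <- bp[i] + h
    bm <- b; bm[i] <- bm[i] - h
    fd <- (local_cross_correlation(a, bp, 5, 1e-5) -
             local_cross_correlation(a, bm, 5, 1e-5)) / (2 * h)
    worst <- max(worst, abs(fd - g[i]) / max(abs(fd), 1e-8))
  }
  expect_lt(worst, 1e-4)
})

test_that("smoothness penalty follows the forward-difference definition", {
  expect_identical(smoothness_penalty(array(3.7, c(2, 6, 6))), 0)
  expect_equal(smoothness_penalty(array(c(0, 1, 2, 3), c(1, 4))), 0.75)

  set.seed(10)
  u <- array(rnorm(2 * 5 * 6), c(2, 5, 6))
  expect_equal(smoothness_penalty(u), ref_smoothness(u), tolerance = 1e-12)
  u3 <- array(rnorm(3 * 4 * 4 * 5), c(3, 4, 4, 5))
  expect_equal(smoothness_penalty(u3), ref_smoothness(u3),
               tolerance = 1e-12)
  expect_gte(smoothness_penalty(u), 0)
})

test_that("smoothness gradient matches finite differences", {
  set.seed(11)
  u <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  g <- splitreg:::smoothness_penalty_grad(u)
  h <- 1e-6
  for (i in sample(length(u), 20)) {
    up <- u; up[i] <- up[i] + h
    um <- u; um[i] <- um[i] - h
    fd <- (smoothness_penalty(up) - smoothness_penalty(um)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("coupling penalty is the mean squared field difference", {
  u <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  expect_identical(coupling_penalty(u, u), 0)
  expect_equal(coupling_penalty(u, u - 0.3), 0.09)
  v <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  expect_equal(coupling_penalty(u, v), mean((u - v)^2))
  expect_error(coupling_penalty(u, array(0, c(2, 4, 4))), "identical shapes")
})

test_that("composite losses equal the sum of their terms", {
  set.seed(12)
  fixed <- matrix(runif(16 * 16), 16, 16)
  moving <- matrix(runif(16 * 16), 16, 16)
  u <- array(rnorm(2 * 256, sd = 0.5), c(2, 16, 16))
  v <- array(rnorm(2 * 256, sd = 0.5), c(2, 16, 16))

  lcc_term <- local_cross_correlation(fixed, warp_image(moving, u), 5, 1e-5)
  expect_equal(similarity_subproblem_loss(fixed, moving, u, v, alpha = 0,
                                          window = 5),
               lcc_term)
  expect_equal(similarity_subproblem_loss(fixed, moving, u, v, alpha = 0.7,
                                          window = 5),
               lcc_term + 0.7 * coupling_penalty(u, v))

  z <- array(0, c(2, 16, 16))
  expect_equal(similarity_subproblem_loss(fixed, fixed, z, z, alpha = 1,
                                          window = 5, epsilon = 1e-10),
               -1, tolerance = 1e-3)

  expect_identical(denoiser_subproblem_loss(u, u, beta = 0), 0)
  expect_identical(denoiser_subproblem_loss(array(1.5, c(2, 8, 8)),
                                            array(1.5, c(2, 8, 8)),
                                            beta = 3), 0)
  expect_equal(denoiser_subproblem_loss(u, v, beta = 2),
               coupling_penalty(v, u) + 2 * smoothness_penalty(v))

  expect_equal(joint_objective(fixed, moving, u, lambda_ = 0, window = 5),
               lcc_term)
  expect_equal(joint_objective(fixed, moving, u, lambda_ = 1.3, window = 5),
               lcc_term + 1.3 * smoothness_penalty(u))
  expect_equal(joint_objective(fixed, fixed, z, lambda_ = 1, window = 5,
                               epsilon = 1e-10), -1, tolerance = 1e-3)

  # constant field: zero smoothness, similarity equals the shifted-image LCC
  cst <- array(0, c(2, 16, 16)); cst[1, , ] <- 1
  expect_equal(joint_objective(fixed, moving, cst, lambda_ = 5, window = 5),
               local_cross_correlation(fixed, warp_image(moving, cst), 5,
                                       1e-5))
})
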