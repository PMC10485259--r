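test_that("identity grid holds voxel coordinates", {
  g <- identity_grid(c(2, 2))
  expect_equal(g[1, , ], matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(g[2, , ], matrix(c(0, 0, 1, 1), 2, 2))

  expect_equal(as.vector(identity_grid(3)), c(0, 1, 2))

  g3 <- identity_grid(c(4, 5, 6))
  expect_equal(apply(g3, 1, max), c(3, 4, 5))
})

test_that("warping with a zero field is the identity", {
  set.seed(2)
  img <- matrix(runif(15 * 17), 15, 17)
  z <- array(0, c(2, 15, 17))
  expect_equal(warp_image(img, z, "linear"), img, tolerance = 1e-6)
  expect_identical(warp_image(img, z, "nearest"), img)

  lab <- label_map(matrix(sample(0:3, 16 * 16, TRUE), 16, 16))
  expect_identical(warp_labels(lab, array(0, c(2, 16, 16)))$labels,
                   lab$labels)
})

test_that("integer shifts sample grid points exactly, with border clamping", {
  v <- c(0, 10, 20, 30); dim(v) <- 4
  shifted <- warp_image(v, array(1, c(1, 4)), "linear")
  expect_equal(as.vector(shifted), c(10, 20, 30, 30))

  lab <- c(1L, 1L, 2L, 2L); dim(lab) <- 4
  expect_equal(as.vector(warp_labels(lab, array(1, c(1, 4)))),
               c(1, 2, 2, 2))
})

test_that("linear warp matches the per-voxel interpolation oracle", {
  set.seed(3)
  for (case in 1:8) {
    img <- matrix(rnorm(16 * 16), 16, 16)
    field <- array(rnorm(2 * 16 * 16, sd = 2), c(2, 16, 16))
    expect_equal(warp_image(img, field, "linear"),
                 ref_warp_linear_2d(img, field), tolerance = 1e-6)
  }
})

test_that("linear warp is exact on affine images for in-bounds samples", {
  set.seed(4)
  a <- c(0.7, -0.3); b <- 1.2
  g <- identity_grid(c(12, 12))
  img <- a[1] * g[1, , ] + a[2] * g[2, , ] + b
  field <- array(runif(2 * 144, -1.5, 1.5), c(2, 12, 12))
  # keep all samples strictly inside the grid
  for (c in 1:2) {
    s <- g[c, , ] + field[c, , ]
    field[c, , ] <- pmin(pmax(s, 0), 11) - g[c, , ]
  }
  expected <- a[1] * (g[1, , ] + field[1, , ]) +
    a[2] * (g[2, , ] + field[2, , ]) + b
  expect_equal(warp_image(img, field, "linear"), expected,
               tolerance = 1e-12)
})

test_that("warp gradient w.r.t. the field matches central differences", {
  set.seed(5)
  n <- 8
  img <- matrix(rnorm(n * n), n, n)
  dout <- matrix(rnorm(n * n), n, n)
  g <- identity_grid(c(n, n))
  field <- array(runif(2 * n * n, -0.9, 0.9), c(2, n, n))
  for (c in 1:2) {  # keep samples away from the clamped border
    s <- g[c, , ] + field[c, , ]
    field[c, , ] <- pmin(pmax(s, 0.05), n - 1.05) - g[c, , ]
  }
  an <- splitreg:::warp_image_grad_field(img, field, dout)
  h <- 1e-5
  worst <- 0
  for (i in sample(length(field), 40)) {
    fp <- field; fp[i] <- fp[i] + h
    fm <- field; fm[i] <- fm[i] - h
    fd <- (sum(dout * warp_image(img, fp)) -
             sum(dout * warp_image(img, fm))) / (2 * h)
    if (abs(fd) > 1e-8 || abs(an[i]) > 1e-8)
      worst <- max(worst, abs(fd - an[i]) / max(abs(fd), abs(an[i])))
  }
  expect_lt(worst, 1e-3)
})

test_that("label warping equals nearest-neighbour warping per indicator", {
  set.seed(6)
  lab <- matrix(sample(0:3, 20 * 20, TRUE), 20, 20)
  field <- array(rnorm(2 * 400, sd = 1.5), c(2, 20, 20))
  warped <- warp_labels(lab, field)
  for (id in 0:3) {
    ind <- (lab == id) * 1
    dim(ind) <- dim(lab)
    expect_equal((warped == id) * 1,
                 warp_image(ind, field, "nearest"))
  }
  lm <- label_map(matrix(sample(0:3, 16 * 16, TRUE), 16, 16))
  wl <- warp_labels(lm, array(rnorm(2 * 256), c(2, 16, 16)))
  expect_true(all(wl$label_ids %in% lm$label_ids))
})

test_that("shape mismatches are rejected", {
  img <- matrix(0, 8, 8)
  expect_error(warp_image(img, array(0, c(2, 8, 9))), "does not match")
  expect_error(warp_labels(matrix(0L, 8, 8), array(0, c(2, 4, 4))),
               "does not match")
})
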