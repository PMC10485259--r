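test_that("Dice follows its defining identities", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_identical(dice(a, a), 1)

  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_identical(dice(a, b), 0)

  # |A| = 4, |B| = 4, |A intersect B| = 2
  c1 <- matrix(FALSE, 4, 4); c1[1, 1:4] <- TRUE
  c2 <- matrix(FALSE, 4, 4); c2[1, 3:4] <- TRUE; c2[2, 1:2] <- TRUE
  expect_identical(dice(c1, c2), 0.5)

  empty <- matrix(FALSE, 4, 4)
  expect_true(is.na(dice(empty, empty)))
  expect_error(dice(a, matrix(FALSE, 4, 5)), "identical shapes")
})

test_that("Dice is symmetric", {
  set.seed(40)
  for (i in 1:10) {
    a <- matrix(runif(64) < 0.4, 8, 8)
    b <- matrix(runif(64) < 0.4, 8, 8)
    expect_identical(dice(a, b), dice(b, a))
  }
})

test_that("multi-label Dice matches the per-indicator oracle", {
  set.seed(41)
  a <- matrix(sample(0:3, 32 * 32, TRUE), 32, 32)
  b <- matrix(sample(0:3, 32 * 32, TRUE), 32, 32)
  res <- multi_label_dice(a, b)
  expect_identical(res$per_label$label, 1:3)
  for (id in 1:3)
    expect_identical(res$per_label$dice[id], dice(a == id, b == id))
  expect_equal(res$mean, mean(res$per_label$dice))
  expect_gte(res$mean, 0); expect_lte(res$mean, 1)

  expect_identical(multi_label_dice(a, a)$mean, 1)
  allbg <- matrix(0L, 32, 32)
  expect_identical(multi_label_dice(a, allbg)$mean, 0)
})

test_that("labels absent from both maps are excluded, undefined dropped", {
  a <- matrix(0L, 8, 8); a[1:2, ] <- 5L
  b <- matrix(0L, 8, 8); b[1:2, ] <- 5L; b[5, 5] <- 9L
  res <- multi_label_dice(a, b)
  expect_identical(res$per_label$label, c(5L, 9L))
  expect_identical(res$per_label$dice, c(1, 0))
  expect_equal(res$mean, 0.5)

  # adding a perfectly overlapping label never decreases the mean
  a2 <- a; a2[8, 8] <- 7L
  b2 <- b; b2[8, 8] <- 7L
  expect_gte(multi_label_dice(a2, b2)$mean, res$mean)
})

test_that("endpoint error is the per-voxel Euclidean displacement gap", {
  u <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  expect_identical(endpoint_error(u, u), list(mean = 0, max = 0))

  t <- u; t[1, , ] <- t[1, , ] - 3; t[2, , ] <- t[2, , ] + 4
  expect_equal(endpoint_error(u, t), list(mean = 5, max = 5))

  set.seed(42)
  v <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  ref <- mean(sqrt(colSums(matrix((u - v)^2, nrow = 2))))
  expect_equal(endpoint_error(u, v)$mean, ref)
})

test_that("residual maps use the registered-minus-template convention", {
  set.seed(43)
  f <- scalar_image(matrix(runif(64), 8, 8))
  expect_identical(residual_map(f, f)$mar, 0)

  g <- f; g$values <- f$values + 0.1
  r <- residual_map(f, g)
  expect_equal(r$map$values, matrix(0.1, 8, 8))
  expect_equal(r$mar, 0.1)

  h <- matrix(rnorm(64), 8, 8)
  expect_equal(residual_map(f$values, h), list(map = h - f$values,
                                               mar = mean(abs(h - f$values))))
})

test_that("on synthetic pairs the inverse-truth warp beats no registration", {
  for (seed in 1:8) {
    spec <- tiny_synth_spec(seed = seed)
    p <- make_pair(spec)
    aligned <- warp_labels(p$moving_labels, p$inv_truth_field)
    expect_gte(multi_label_dice(p$fixed_labels, aligned)$mean,
               multi_label_dice(p$fixed_labels, p$moving_labels)$mean)
  }
})

test_that("the per-region Dice table round-trips through CSV", {
  a <- matrix(sample(0:2, 256, TRUE), 16, 16)
  b <- matrix(sample(0:2, 256, TRUE), 16, 16)
  res <- multi_label_dice(a, b)
  path <- tempfile(fileext = ".csv")
  write_dice_table(res, path)
  got <- read.csv(path)
  expect_equal(got$dice, res$per_label$dice)
})
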