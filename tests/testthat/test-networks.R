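test_that("1D dilated convolution follows its defining sum", {
  expect_equal(dilated_conv_1d(c(1, 2, 3, 4), c(1, 1), r = 1), c(3, 5, 7))
  expect_equal(dilated_conv_1d(c(1, 2, 3, 4, 5), c(1, 1), r = 2), c(4, 6, 8))
  expect_error(dilated_conv_1d(c(1, 2, 3), c(1, 1, 1), r = 2),
               "shorter than the dilated filter")
})

test_that("network specs enforce their structural invariants", {
  expect_error(similarity_net_spec(2, encoder_channels = c(8, 8, 8)),
               "4 encoder stages")
  expect_error(similarity_net_spec(2, head_channels = c(16, 3)),
               "must output d = 2")
  expect_error(denoiser_net_spec(2, dilation_rates = c(2)), "distinct")
  expect_error(denoiser_net_spec(2, dilation_rates = c(2, 2)), "distinct")
  spec <- similarity_net_spec(3)
  expect_identical(spec$head_channels[2], 3L)
})

test_that("similarity net output matches the input grid and d channels", {
  set.seed(20)
  spec2 <- tiny_sim_spec(2)
  p2 <- init_similarity_net(spec2)
  f <- matrix(runif(64 * 64), 64, 64)
  u <- similarity_net_forward(p2, f, f, spec2)
  expect_s3_class(u, "deformation_field")
  expect_equal(dim(u$displacements), c(2, 64, 64))

  spec3 <- tiny_sim_spec(3)
  p3 <- init_similarity_net(spec3)
  f3 <- array(runif(32 * 48 * 64), c(32, 48, 64))
  u3 <- similarity_net_forward(p3, f3, f3, spec3)
  expect_equal(dim(u3$displacements), c(3, 32, 48, 64))

  expect_error(similarity_net_forward(p2, matrix(0, 24, 64),
                                      matrix(0, 24, 64), spec2),
               "axis 1 \\(size 24\\)")
})

test_that("zero head weights give the exactly zero field", {
  set.seed(21)
  spec <- tiny_sim_spec(2)
  p <- init_similarity_net(spec)
  p$head2$W[] <- 0; p$head2$b[] <- 0
  f <- matrix(runif(32 * 32), 32, 32)
  m <- matrix(runif(32 * 32), 32, 32)
  u <- similarity_net_forward(p, f, m, spec)
  expect_identical(max(abs(u$displacements)), 0)
})

test_that("parameter count matches a layer-by-layer hand count", {
  spec <- similarity_net_spec(2)
  p <- init_similarity_net(spec)
  k2 <- 9  # 3x3 kernels
  # encoder: 2->16->32->32->32; decoder inputs concatenate the skip features
  # (f4,f3,f2,f1); head: 16 then d = 2
  # the first head convolution also sees the 2-channel raw input pair
  hand <- (2 * 16 + 16 * 32 + 32 * 32 + 32 * 32) * k2 + 16 + 32 + 32 + 32 +
    ((32 + 32) * 32 + (32 + 32) * 32 + (32 + 32) * 16 + (16 + 16) * 16) * k2 +
    32 + 32 + 16 + 16 +
    ((16 + 2) * 16 + 16 * 2) * k2 + 16 + 2
  expect_identical(count_params(p), hand)

  dspec <- denoiser_net_spec(2)
  dp <- init_denoiser_net(dspec)
  hand_d <- (2 * 16) * k2 + 16 +
    4 * ((16 * 8) * k2 + 8) +
    (32 * 16) * k2 + 16 +
    (16 * 2) * k2 + 2
  expect_identical(count_params(dp), hand_d)
})

test_that("a zeroed residual branch makes the denoiser the exact identity", {
  set.seed(22)
  spec <- tiny_den_spec(2)
  p <- init_denoiser_net(spec)
  p$out$W[] <- 0; p$out$b[] <- 0
  u <- deformation_field(array(rnorm(2 * 24 * 24), c(2, 24, 24)))
  v <- denoiser_net_forward(p, u, spec)
  expect_identical(v$displacements, u$displacements)
})

test_that("denoiser output shape is preserved for any dilation rates", {
  set.seed(23)
  for (rates in list(c(1L, 2L), c(2L, 5L), c(1L, 3L, 7L))) {
    spec <- denoiser_net_spec(2, stem_channels = 3L, dilation_rates = rates,
                              branch_channels = 2L, fusion_channels = 3L)
    p <- init_denoiser_net(spec)
    u <- array(rnorm(2 * 20 * 28), c(2, 20, 28))
    v <- denoiser_net_forward(p, u, spec)
    expect_equal(dim(v$displacements), dim(u))
  }
})

test_that("a dilated branch reduces to the 1D operation on separable input", {
  # a kernel supported on one row, applied to an image constant along the
  # other axis, must reproduce the zero-padded 1D dilated convolution
  set.seed(24)
  n <- 40
  x1 <- rnorm(n)
  img <- array(rep(x1, times = n), c(1, n, n, 1))
  for (r in c(1L, 2L, 4L)) {
    w <- rnorm(3)
    W <- matrix(0, 1, 9)
    W[1, 4:6] <- w    # kernel column t2 = centre, taps varying along axis 1
    pad <- r
    out <- splitreg:::nn_conv_fwd(img, list(W = W, b = 0), 3L,
                                  dilation = r, pad = pad,
                                  keep_col = FALSE)$y
    xpad <- c(numeric(pad), x1, numeric(pad))
    expect_equal(out[1, , n %/% 2, 1], ref_dilated_conv(xpad, w, r),
                 tolerance = 1e-5)
  }
})

test_that("wider dilation rates spread a point perturbation further", {
  set.seed(25)
  width_for_rates <- function(rates) {
    spec <- denoiser_net_spec(2, stem_channels = 2L, dilation_rates = rates,
                              branch_channels = 2L, fusion_channels = 2L)
    p <- init_denoiser_net(spec)
    # make the residual branch non-trivial
    p$out$W <- matrix(rnorm(length(p$out$W), sd = 0.1), nrow(p$out$W))
    u <- array(0, c(2, 33, 33, 1))
    base <- splitreg:::dennet_fwd(p, spec, u)$v
    u2 <- u; u2[1, 17, 17, 1] <- 1
    pert <- splitreg:::dennet_fwd(p, spec, u2)$v
    moved <- apply(abs(pert - base) > 1e-7, 2, any)
    diff(range(which(moved)))
  }
  expect_gt(width_for_rates(c(4L, 8L)), width_for_rates(c(1L, 2L)))
})

test_that("network forwards are deterministic", {
  set.seed(26)
  spec <- tiny_sim_spec(2)
  p <- init_similarity_net(spec)
  f <- matrix(runif(32 * 32), 32, 32)
  m <- matrix(runif(32 * 32), 32, 32)
  u1 <- similarity_net_forward(p, f, m, spec)
  u2 <- similarity_net_forward(p, f, m, spec)
  expect_identical(u1$displacements, u2$displacements)

  dspec <- tiny_den_spec(2)
  dp <- init_denoiser_net(dspec)
  v1 <- denoiser_net_forward(dp, u1, dspec)
  v2 <- denoiser_net_forward(dp, u1, dspec)
  expect_identical(v1$displacements, v2$displacements)
})
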