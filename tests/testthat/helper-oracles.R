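# Independent reference implementations used as test oracles.  These are
# deliberately written as plain loops, separate from the package's compiled
# and vectorized code paths.

# Valid-mode dilated convolution, double loop.
ref_dilated_conv <- function(x, w, r) {
  n <- length(x); m <- length(w)
  L <- n - r * (m - 1L)
  y <- numeric(L)
  for (i in seq_len(L)) {
    acc <- 0
    for (k in seq_len(m)) acc <- acc + x[i + r * (k - 1L)] * w[k]
    y[i] <- acc
  }
  y
}

# Per-voxel bilinear interpolation with border clamping, 2D.
ref_warp_linear_2d <- function(img, field) {
  n <- dim(img)
  out <- matrix(0, n[1], n[2])
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) {
    s1 <- min(max((i - 1) + field[1, i, j], 0), n[1] - 1)
    s2 <- min(max((j - 1) + field[2, i, j], 0), n[2] - 1)
    f1 <- min(floor(s1), n[1] - 2); f2 <- min(floor(s2), n[2] - 2)
    w1 <- s1 - f1; w2 <- s2 - f2
    out[i, j] <-
      (1 - w1) * (1 - w2) * img[f1 + 1, f2 + 1] +
      w1 * (1 - w2) * img[f1 + 2, f2 + 1] +
      (1 - w1) * w2 * img[f1 + 1, f2 + 2] +
      w1 * w2 * img[f1 + 2, f2 + 2]
  }
  out
}

# Sliding-window squared local NCC, truncated windows, explicit loops.
ref_lcc <- function(a, b, window, epsilon) {
  h <- window %/% 2
  n <- dim(a)
  total <- 0
  nd <- length(n)
  idx <- arrayInd(seq_along(a), .dim = n)
  for (v in seq_along(a)) {
    rng <- lapply(seq_len(nd), function(ax)
      max(1, idx[v, ax] - h):min(n[ax], idx[v, ax] + h))
    sel <- as.matrix(expand.grid(rng))
    aw <- a[sel]; bw <- b[sel]
    cross <- sum((aw - mean(aw)) * (bw - mean(bw)))
    A <- sum((aw - mean(aw))^2); B <- sum((bw - mean(bw))^2)
    total <- total + cross^2 / (A * B + epsilon)
  }
  -total / length(a)
}

# Loop-based forward-difference smoothness penalty (zero at trailing edge).
ref_smoothness <- function(u) {
  dm <- dim(u)
  d <- dm[1]
  shape <- dm[-1]
  nd <- length(shape)
  total <- 0
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape)
  for (c in seq_len(d)) for (v in seq_len(prod(shape))) for (ax in seq_len(nd)) {
    here <- idx[v, ]
    there <- here; there[ax] <- there[ax] + 1L
    if (there[ax] <= shape[ax]) {
      diffv <- u[matrix(c(c, there), 1)] - u[matrix(c(c, here), 1)]
      total <- total + diffv^2
    }
  }
  total / (prod(shape) * d * nd)
}

# Norm-wise relative error between a finite-difference gradient and an
# analytic one, for one layer's weight matrix.
fd_layer_grad <- function(lossf, params, nm, fld, h = 1e-5) {
  arr <- params[[nm]][[fld]]
  fd <- numeric(length(arr))
  for (i in seq_along(fd)) {
    pp <- params; pp[[nm]][[fld]][i] <- pp[[nm]][[fld]][i] + h
    pm <- params; pm[[nm]][[fld]][i] <- pm[[nm]][[fld]][i] - h
    fd[i] <- (lossf(pp) - lossf(pm)) / (2 * h)
  }
  fd
}

normwise_err <- function(fd, an) {
  sqrt(sum((fd - an)^2)) / max(sqrt(sum(an^2)), 1e-12)
}

# Small, fast synthetic spec for unit tests.
tiny_synth_spec <- function(seed = 0L, shape = c(32L, 32L), ...) {
  synthetic_spec(shape = shape, n_pairs = 2L, max_displacement = 3,
                 smoothness_sigma = 3, n_regions = 4L, seed = seed, ...)
}

tiny_sim_spec <- function(d = 2L) {
  similarity_net_spec(d, encoder_channels = c(1L, 1L, 2L, 2L),
                      decoder_channels = c(2L, 2L, 1L, 1L),
                      head_channels = c(2L, d))
}

tiny_den_spec <- function(d = 2L) {
  denoiser_net_spec(d, stem_channels = 3L, dilation_rates = c(1L, 2L),
                    branch_channels = 2L, fusion_channels = 3L)
}
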