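# The two learnable operators.
#
# Similarity-Net: a light encoder-decoder that maps a (fixed, moving) image
# pair to a displacement field.  Four stride-2 convolutions encode (saving
# each stage's features); the decoder restores resolution with
# nearest-neighbour upsampling, concatenating the saved encoder features at
# the matching scale before each upsample; two final convolutions produce
# the d-channel field.
#
# Denoiser-Net: a residual smoother v = u + R(u), where R is a stem
# convolution, parallel dilated convolutions with multiple rates (zero
# padding r*(k-1)/2 preserves shape), channel concatenation, and fusion
# convolutions down to d channels.
#
# Both are implemented with explicit forward/backward passes over compiled
# im2col convolutions; every convolution except the field-producing heads is
# followed by leaky rectification.  The field head is initialized near zero
# (sd 1e-5, zero bias) so registration starts near the identity.

#' Similarity network specification
#'
#' @param d Spatial dimensionality (2 or 3).
#' @param encoder_channels Four positive integers, output channels of the
#'   four stride-2 encoder convolutions.
#' @param decoder_channels Four positive integers for the decoder stages.
#' @param head_channels Two positive integers for the two final
#'   convolutions; the second must equal `d` (the field has one channel per
#'   spatial axis).
#' @param kernel_size Odd convolution kernel size.
#' @param negative_slope Slope of the leaky rectification for negative
#'   inputs.
#' @return An object of class `similarity_net_spec`.
#' @export
similarity_net_spec <- function(d = 2L,
                                encoder_channels = c(16L, 32L, 32L, 32L),
                                decoder_channels = c(32L, 32L, 16L, 16L),
                                head_channels = c(16L, d),
                                kernel_size = 3L,
                                negative_slope = 0.2) {
  d <- as.integer(d)
  stopifnot(d %in% 2:3)
  if (length(encoder_channels) != 4L)
    stop("exactly 4 encoder stages are required", call. = FALSE)
  if (length(decoder_channels) != 4L)
    stop("exactly 4 decoder stages are required", call. = FALSE)
  if (length(head_channels) != 2L)
    stop("exactly 2 head convolutions are required", call. = FALSE)
  if (head_channels[2L] != d)
    stop("the final head layer must output d = ", d, " channels",
         call. = FALSE)
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd", call. = FALSE)
  stopifnot(all(encoder_channels >= 1L), all(decoder_channels >= 1L),
            all(head_channels >= 1L))
  structure(list(d = d,
                 encoder_channels = as.integer(encoder_channels),
                 decoder_channels = as.integer(decoder_channels),
                 head_channels = as.integer(head_channels),
                 kernel_size = as.integer(kernel_size),
                 negative_slope = negative_slope),
            class = "similarity_net_spec")
}

#' Denoiser network specification
#'
#' @param d Spatial dimensionality (2 or 3).
#' @param stem_channels Channels of the stem convolution.
#' @param dilation_rates At least two distinct positive dilation rates for
#'   the parallel branches.
#' @param branch_channels Channels of each dilated branch.
#' @param fusion_channels Channels of the fusion convolution.
#' @param kernel_size Odd convolution kernel size.
#' @param negative_slope Leaky rectification slope.
#' @return An object of class `denoiser_net_spec`.
#' @export
denoiser_net_spec <- function(d = 2L,
                              stem_channels = 16L,
                              dilation_rates = c(1L, 2L, 4L, 8L),
                              branch_channels = 8L,
                              fusion_channels = 16L,
                              kernel_size = 3L,
                              negative_slope = 0.2) {
  d <- as.integer(d)
  stopifnot(d %in% 2:3)
  dilation_rates <- as.integer(dilation_rates)
  if (length(dilation_rates) < 2L || anyDuplicated(dilation_rates) ||
      any(dilation_rates < 1L))
    stop("dilation_rates must be >= 2 distinct positive integers",
         call. = FALSE)
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd", call. = FALSE)
  stopifnot(stem_channels >= 1L, branch_channels >= 1L, fusion_channels >= 1L)
  structure(list(d = d,
                 stem_channels = as.integer(stem_channels),
                 dilation_rates = dilation_rates,
                 branch_channels = as.integer(branch_channels),
                 fusion_channels = as.integer(fusion_channels),
                 kernel_size = as.integer(kernel_size),
                 negative_slope = negative_slope),
            class = "denoiser_net_spec")
}

# ---- primitive layers on batched (C, n1..nd, B) tensors ----

new_conv_layer <- function(c_in, c_out, k, d, w_sd = NULL) {
  fan_in <- c_in * k^d
  if (is.null(w_sd)) w_sd <- sqrt(2 / fan_in)
  list(W = matrix(rnorm(c_out * fan_in, sd = w_sd), c_out, fan_in),
       b = numeric(c_out))
}

# Convolutions run in single precision by default (ample for registration
# and twice the throughput); options(splitreg.conv_double = TRUE) switches
# the whole path to double, used by the numerical verification tests.
nn_conv_fwd <- function(x, layer, k, stride = 1L, dilation = 1L,
                        pad = NULL, keep_col = TRUE) {
  if (is.null(pad)) pad <- dilation * (k - 1L) %/% 2L
  cpp_conv_fwd(x, dim(x), layer$W, layer$b, k, stride, dilation, pad,
               keep_col, isTRUE(getOption("splitreg.conv_double")))
}

nn_conv_bwd <- function(fw, xdim, layer, dy, k, stride = 1L, dilation = 1L,
                        pad = NULL, need_dx = TRUE) {
  if (is.null(pad)) pad <- dilation * (k - 1L) %/% 2L
  cpp_conv_bwd(fw$col, fw$ncols, xdim, layer$W, dy, k, stride, dilation,
               pad, need_dx, isTRUE(fw$dbl))
}

lrelu_fwd <- function(x, slope) cpp_lrelu_fwd(x, slope)

# the sign of the activation output recovers the local slope (slope > 0)
lrelu_bwd <- function(dy, act, slope) cpp_lrelu_bwd(dy, act, slope)

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  m <- prod(da[-1L])
  dim(a) <- c(da[1L], m); dim(b) <- c(db[1L], m)
  out <- rbind(a, b)
  dim(out) <- c(da[1L] + db[1L], da[-1L])
  out
}

split_ch <- function(x, c1) {
  dm <- dim(x)
  m <- prod(dm[-1L])
  dim(x) <- c(dm[1L], m)
  a <- x[seq_len(c1), , drop = FALSE]
  b <- x[-seq_len(c1), , drop = FALSE]
  dim(a) <- c(c1, dm[-1L])
  dim(b) <- c(dm[1L] - c1, dm[-1L])
  list(a, b)
}

# ---- parameter initialization ----

#' Initialize Similarity-Net parameters
#'
#' The final head convolution gets near-zero weights (sd 1e-5) and zero bias
#' so that the initial predicted field is approximately zero.
#'
#' @param spec A `similarity_net_spec`.
#' @return A named list of `(W, b)` layers.
#' @export
init_similarity_net <- function(spec) {
  k <- spec$kernel_size; d <- spec$d
  ec <- spec$encoder_channels; dc <- spec$decoder_channels
  hc <- spec$head_channels
  p <- list()
  cin <- 2L
  for (i in 1:4) {
    p[[paste0("enc", i)]] <- new_conv_layer(cin, ec[i], k, d)
    cin <- ec[i]
  }
  skips <- c(ec[4], ec[3], ec[2], ec[1])
  h <- ec[4]
  for (i in 1:4) {
    p[[paste0("dec", i)]] <- new_conv_layer(h + skips[i], dc[i], k, d)
    h <- dc[i]
  }
  # the head sees the raw image pair at full resolution alongside the
  # decoded features (sub-voxel matching needs full-resolution intensities)
  p[["head1"]] <- new_conv_layer(h + 2L, hc[1], k, d)
  p[["head2"]] <- new_conv_layer(hc[1], hc[2], k, d, w_sd = 1e-5)
  p
}

#' Initialize Denoiser-Net parameters
#'
#' The residual output convolution gets near-zero weights so the initial
#' denoiser is approximately the identity (v = u).
#'
#' @param spec A `denoiser_net_spec`.
#' @return A named list of `(W, b)` layers.
#' @export
init_denoiser_net <- function(spec) {
  k <- spec$kernel_size; d <- spec$d
  p <- list()
  p[["stem"]] <- new_conv_layer(d, spec$stem_channels, k, d)
  for (i in seq_along(spec$dilation_rates))
    p[[paste0("branch", i)]] <-
      new_conv_layer(spec$stem_channels, spec$branch_channels, k, d)
  p[["fusion"]] <- new_conv_layer(
    spec$branch_channels * length(spec$dilation_rates),
    spec$fusion_channels, k, d)
  p[["out"]] <- new_conv_layer(spec$fusion_channels, d, k, d, w_sd = 1e-5)
  p
}

#' Number of parameters in a network
#' @param params A named list of `(W, b)` layers.
#' @return Integer total count.
#' @export
count_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

# ---- Similarity-Net forward / backward ----

check_div16 <- function(shape) {
  bad <- which(shape %% 16L != 0L)
  if (length(bad) > 0L)
    stop("axis ", bad[1L], " (size ", shape[bad[1L]],
         ") is not divisible by 16 (four stride-2 stages)", call. = FALSE)
  invisible(TRUE)
}

# Batched forward.  fixed/moving: arrays (n1..nd, B).  Returns the field
# tensor (d, n1..nd, B) and, if want_cache, everything backward needs.
simnet_fwd <- function(params, spec, fixed, moving, want_cache = FALSE) {
  dmf <- dim(fixed)
  nd <- length(dmf) - 1L
  shape <- dmf[seq_len(nd)]
  B <- dmf[nd + 1L]
  check_div16(shape)
  k <- spec$kernel_size; slope <- spec$negative_slope

  x <- rbind(as.vector(fixed), as.vector(moving))
  dim(x) <- c(2L, shape, B)

  caches <- list()
  feats <- vector("list", 4L)
  h <- x
  for (i in 1:4) {
    nm <- paste0("enc", i)
    fw <- nn_conv_fwd(h, params[[nm]], k, stride = 2L, pad = k %/% 2L,
                      keep_col = want_cache)
    act <- lrelu_fwd(fw$y, slope)
    if (want_cache)
      caches[[nm]] <- list(col = fw$col, ncols = fw$ncols, dbl = fw$dbl,
                           xdim = dim(h), act = act)
    h <- act
    feats[[i]] <- h
  }
  skips <- list(feats[[4]], feats[[3]], feats[[2]], feats[[1]])
  for (i in 1:4) {
    nm <- paste0("dec", i)
    cc <- concat_ch(h, skips[[i]])
    up <- cpp_upsample2_fwd(cc, dim(cc))
    fw <- nn_conv_fwd(up, params[[nm]], k, pad = k %/% 2L,
                      keep_col = want_cache)
    act <- lrelu_fwd(fw$y, slope)
    if (want_cache)
      caches[[nm]] <- list(col = fw$col, ncols = fw$ncols, dbl = fw$dbl,
                           xdim = dim(up), updim = dim(up),
                           ccdim = dim(cc), act = act,
                           h_ch = dim(cc)[1L] - dim(skips[[i]])[1L])
    h <- act
  }
  h <- concat_ch(h, x)
  fw1 <- nn_conv_fwd(h, params$head1, k, pad = k %/% 2L, keep_col = want_cache)
  act1 <- lrelu_fwd(fw1$y, slope)
  fw2 <- nn_conv_fwd(act1, params$head2, k, pad = k %/% 2L,
                     keep_col = want_cache)
  if (want_cache) {
    caches$head1 <- list(col = fw1$col, ncols = fw1$ncols, dbl = fw1$dbl,
                         xdim = dim(h), act = act1)
    caches$head2 <- list(col = fw2$col, ncols = fw2$ncols, dbl = fw2$dbl,
                         xdim = dim(act1))
  }
  list(field = fw2$y, cache = if (want_cache) caches else NULL)
}

# Backward pass: gradients of sum(dfield * field) w.r.t. all parameters.
simnet_bwd <- function(params, spec, cache, dfield) {
  k <- spec$kernel_size; slope <- spec$negative_slope
  grads <- list()

  bw <- nn_conv_bwd(cache$head2, cache$head2$xdim, params$head2, dfield, k,
                    pad = k %/% 2L)
  grads$head2 <- list(W = bw$dW, b = bw$db)
  dy <- lrelu_bwd(bw$dx, cache$head1$act, slope)
  bw <- nn_conv_bwd(cache$head1, cache$head1$xdim, params$head1, dy, k,
                    pad = k %/% 2L)
  grads$head1 <- list(W = bw$dW, b = bw$db)
  dh <- split_ch(bw$dx, cache$head1$xdim[1L] - 2L)[[1L]]

  dskips <- vector("list", 4L)
  for (i in 4:1) {
    nm <- paste0("dec", i)
    cc <- cache[[nm]]
    dy <- lrelu_bwd(dh, cc$act, slope)
    bw <- nn_conv_bwd(cc, cc$xdim, params[[nm]], dy, k, pad = k %/% 2L)
    grads[[nm]] <- list(W = bw$dW, b = bw$db)
    dcc <- cpp_upsample2_bwd(bw$dx, cc$updim)
    dim(dcc) <- cc$ccdim
    parts <- split_ch(dcc, cc$h_ch)
    dh <- parts[[1L]]
    dskips[[i]] <- parts[[2L]]
  }
  # skips were (f4, f3, f2, f1); dec1's incoming h was also f4
  denc <- list(dskips[[4L]], dskips[[3L]], dskips[[2L]],
               dskips[[1L]] + dh)
  dgrad <- NULL
  for (i in 4:1) {
    nm <- paste0("enc", i)
    cc <- cache[[nm]]
    dy <- denc[[i]]
    if (!is.null(dgrad)) dy <- dy + dgrad
    dy <- lrelu_bwd(dy, cc$act, slope)
    bw <- nn_conv_bwd(cc, cc$xdim, params[[nm]], dy, k, stride = 2L,
                      pad = k %/% 2L, need_dx = i > 1L)
    grads[[nm]] <- list(W = bw$dW, b = bw$db)
    dgrad <- if (i > 1L) bw$dx else NULL
  }
  grads
}

#' Similarity-Net forward pass
#'
#' Predicts the displacement field registering `moving` to `fixed`.  Every
#' image axis must be divisible by 16 (four stride-2 encoder stages).
#'
#' @param params Parameters from [init_similarity_net()].
#' @param fixed,moving `scalar_image`s or arrays of identical shape.
#' @param spec The `similarity_net_spec` used to create `params`.
#' @return A `deformation_field` at the full input resolution.
#' @export
similarity_net_forward <- function(params, fixed, moving, spec) {
  f <- grid_values(fixed); m <- grid_values(moving)
  check_same_shape(f, m, "images")
  fb <- array(f, dim = c(dim(f), 1L))
  mb <- array(m, dim = c(dim(m), 1L))
  out <- simnet_fwd(params, spec, fb, mb)
  u <- out$field
  dm <- dim(u)
  dim(u) <- dm[-length(dm)]
  deformation_field(u)
}

# ---- Denoiser-Net forward / backward ----

# u: batched field tensor (d, n1..nd, B).
dennet_fwd <- function(params, spec, u, want_cache = FALSE) {
  k <- spec$kernel_size; slope <- spec$negative_slope
  rates <- spec$dilation_rates
  caches <- list()

  fw <- nn_conv_fwd(u, params$stem, k, pad = k %/% 2L, keep_col = want_cache)
  act <- lrelu_fwd(fw$y, slope)
  if (want_cache) caches$stem <- list(col = fw$col, ncols = fw$ncols,
                                      dbl = fw$dbl, xdim = dim(u),
                                      act = act)
  s <- act

  branches <- vector("list", length(rates))
  for (i in seq_along(rates)) {
    nm <- paste0("branch", i)
    r <- rates[i]
    fw <- nn_conv_fwd(s, params[[nm]], k, dilation = r,
                      pad = r * (k - 1L) %/% 2L, keep_col = want_cache)
    act <- lrelu_fwd(fw$y, slope)
    if (want_cache) caches[[nm]] <- list(col = fw$col, ncols = fw$ncols,
                                         dbl = fw$dbl, xdim = dim(s),
                                         act = act)
    branches[[i]] <- act
  }
  cat_b <- Reduce(concat_ch, branches)
  fw <- nn_conv_fwd(cat_b, params$fusion, k, pad = k %/% 2L,
                    keep_col = want_cache)
  act <- lrelu_fwd(fw$y, slope)
  if (want_cache) caches$fusion <- list(col = fw$col, ncols = fw$ncols, dbl = fw$dbl,
                                        xdim = dim(cat_b), act = act)
  g <- act
  fw <- nn_conv_fwd(g, params$out, k, pad = k %/% 2L, keep_col = want_cache)
  if (want_cache) caches$out <- list(col = fw$col, ncols = fw$ncols, dbl = fw$dbl,
                                     xdim = dim(g))
  v <- u + fw$y
  list(v = v, cache = if (want_cache) caches else NULL)
}

dennet_bwd <- function(params, spec, cache, dv) {
  k <- spec$kernel_size; slope <- spec$negative_slope
  rates <- spec$dilation_rates
  grads <- list()

  bw <- nn_conv_bwd(cache$out, cache$out$xdim, params$out, dv, k,
                    pad = k %/% 2L)
  grads$out <- list(W = bw$dW, b = bw$db)
  dy <- lrelu_bwd(bw$dx, cache$fusion$act, slope)
  bw <- nn_conv_bwd(cache$fusion, cache$fusion$xdim, params$fusion, dy, k,
                    pad = k %/% 2L)
  grads$fusion <- list(W = bw$dW, b = bw$db)
  dcat <- bw$dx

  bc <- spec$branch_channels
  ds <- NULL
  rest <- dcat
  for (i in seq_along(rates)) {
    nm <- paste0("branch", i)
    if (i < length(rates)) {
      parts <- split_ch(rest, bc)
      dbi <- parts[[1L]]
      rest <- parts[[2L]]
    } else dbi <- rest
    dy <- lrelu_bwd(dbi, cache[[nm]]$act, slope)
    r <- rates[i]
    bw <- nn_conv_bwd(cache[[nm]], cache[[nm]]$xdim, params[[nm]], dy, k,
                      dilation = r, pad = r * (k - 1L) %/% 2L)
    grads[[nm]] <- list(W = bw$dW, b = bw$db)
    ds <- if (is.null(ds)) bw$dx else ds + bw$dx
  }
  dy <- lrelu_bwd(ds, cache$stem$act, slope)
  bw <- nn_conv_bwd(cache$stem, cache$stem$xdim, params$stem, dy, k,
                    pad = k %/% 2L, need_dx = FALSE)
  grads$stem <- list(W = bw$dW, b = bw$db)
  grads
}

#' Denoiser-Net forward pass
#'
#' Residual smoothing of a displacement field: `v = u + R(u)`.
#'
#' @param params Parameters from [init_denoiser_net()].
#' @param u A `deformation_field` or `(d, n1..nd)` array.
#' @param spec The `denoiser_net_spec` used to create `params`.
#' @return A `deformation_field` of the same shape.
#' @export
denoiser_net_forward <- function(params, u, spec) {
  uv <- field_values(u)
  ub <- array(uv, dim = c(dim(uv), 1L))
  out <- dennet_fwd(params, spec, ub)
  v <- out$v
  dm <- dim(v)
  dim(v) <- dm[-length(dm)]
  deformation_field(v)
}

#' One-dimensional dilated convolution
#'
#' Valid-mode dilated (atrous) convolution of a sequence:
#' `y[i] = sum_k x[i + r*k] * w[k]` (0-based), of length
#' `length(x) - r*(length(w)-1)`.
#'
#' @param x Numeric input sequence.
#' @param w Numeric filter.
#' @param r Positive integer dilation rate.
#' @return Numeric output sequence.
#' @export
dilated_conv_1d <- function(x, w, r = 1L) {
  r <- as.integer(r)
  stopifnot(r >= 1L)
  n <- length(x); m <- length(w)
  L <- n - r * (m - 1L)
  if (L < 1L)
    stop("input of length ", n, " is shorter than the dilated filter ",
         "footprint ", r * (m - 1L) + 1L, call. = FALSE)
  y <- numeric(L)
  for (k in seq_len(m))
    y <- y + x[seq_len(L) + r * (k - 1L)] * w[k]
  y
}
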