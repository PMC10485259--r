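# Alternating training of the two operators, following the algorithm box:
# per iteration, draw one batch; (a) freeze the denoiser, compute u and v,
# take one optimizer step on the similarity sub-problem loss; (b) freeze the
# similarity network, recompute u (detached) and v, take one optimizer step
# on the smoothing sub-problem loss.  The auxiliary field v is a constant
# target in step (a): no gradient flows into the (frozen) denoiser's input
# path.  Baseline modes: s_net (similarity loss only) and ss_net (similarity
# loss + lambda * smoothness on u), neither of which instantiates the
# denoiser.  Optimization uses adaptive moment estimation with separate
# states per network; batches are drawn uniformly at random with
# replacement (no epoch structure).

#' Training configuration
#'
#' @param mode One of `"decoupled"`, `"s_net"`, `"ss_net"`.  In `s_net` mode
#'   alpha, beta and lambda_ are ignored; in `ss_net` mode only lambda_ is
#'   used.
#' @param iterations Number of outer iterations k.
#' @param learning_rate Optimizer learning rate (default 5e-4).
#' @param batch_size Pairs drawn per iteration.
#' @param seed Integer seed; training is fully reproducible given it.
#' @param hp A [hyperparams()] object.
#' @param checkpoint_every History recording interval in iterations.
#' @return An object of class `training_config`.
#' @export
training_config <- function(mode = c("decoupled", "s_net", "ss_net"),
                            iterations = 1500L, learning_rate = 5e-4,
                            batch_size = 4L, seed = 0L,
                            hp = hyperparams(), checkpoint_every = 50L) {
  mode <- match.arg(mode)
  stopifnot(iterations >= 0L, learning_rate > 0, batch_size >= 1L,
            checkpoint_every >= 1L, inherits(hp, "hyperparams"))
  structure(list(mode = mode, iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), hp = hp,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "training_config")
}

# ---- adaptive moment estimation over named layer lists ----

adam_init <- function(params) {
  list(m = lapply(params, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(params, function(l) list(W = l$W * 0, b = l$b * 0)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (fld in c("W", "b")) {
      g <- grads[[nm]][[fld]]
      state$m[[nm]][[fld]] <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * g
      state$v[[nm]][[fld]] <- beta2 * state$v[[nm]][[fld]] +
        (1 - beta2) * g^2
      mhat <- state$m[[nm]][[fld]] / bc1
      vhat <- state$v[[nm]][[fld]] / bc2
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# ---- batched loss helpers on (sp, B) image stacks and (d, sp, B) fields ----

# Mean LCC over the batch plus gradient w.r.t. the batched field tensor.
batch_lcc_grad <- function(fixed_b, moving_b, u_b, window, epsilon) {
  dm <- dim(fixed_b)
  nd <- length(dm) - 1L
  shape <- dm[seq_len(nd)]
  B <- dm[nd + 1L]
  npix <- prod(shape)
  d <- dim(u_b)[1L]
  loss <- 0
  dfield <- array(0, dim = dim(u_b))
  warped_b <- array(0, dim = dm)
  fm <- fixed_b; dim(fm) <- c(npix, B)
  mm <- moving_b; dim(mm) <- c(npix, B)
  um <- u_b; dim(um) <- c(d * npix, B)
  dfm <- dfield; dim(dfm) <- c(d * npix, B)
  wm <- warped_b; dim(wm) <- c(npix, B)
  for (b in seq_len(B)) {
    f <- array(fm[, b], dim = shape)
    m <- array(mm[, b], dim = shape)
    u <- array(um[, b], dim = c(d, shape))
    w <- cpp_warp(m, shape, u, 0L)
    wm[, b] <- w
    st <- lcc_stats(f, w, window, epsilon)
    loss <- loss - mean(st$cc2)
    dlcc <- local_cross_correlation_grad(f, w, window, epsilon)
    dfm[, b] <- cpp_warp_bwd_field(m, shape, u, dlcc)
  }
  dim(wm) <- dm
  dim(dfm) <- c(d, shape, B)
  list(loss = loss / B, dfield = dfm / B, warped = wm)
}

# Per-batch means of the field penalties (each sample's penalty is averaged,
# then the batch mean is taken; for equal-shape samples this equals pooling).
batch_smoothness <- function(u_b) {
  dm <- dim(u_b)
  B <- dm[length(dm)]
  total <- 0
  for (b in seq_len(B))
    total <- total + smoothness_penalty(batch_slice(u_b, b))
  total / B
}

batch_smoothness_grad <- function(u_b) {
  dm <- dim(u_b)
  B <- dm[length(dm)]
  g <- array(0, dim = dm)
  npix <- prod(dm[-length(dm)])
  gm <- g; dim(gm) <- c(npix, B)
  for (b in seq_len(B))
    gm[, b] <- smoothness_penalty_grad(batch_slice(u_b, b)) / B
  dim(gm) <- dm
  gm
}

batch_slice <- function(x, b) {
  dm <- dim(x)
  npix <- prod(dm[-length(dm)])
  dim(x) <- c(npix, dm[length(dm)])
  out <- x[, b]
  dim(out) <- dm[-length(dm)]
  out
}

stack_batch <- function(lst) {
  shape <- dim(lst[[1L]])
  out <- array(unlist(lst, use.names = FALSE), dim = c(shape, length(lst)))
  out
}

# ---- the alternating training loop ----

#' Train registration networks
#'
#' @param dataset A list of pairs; each element is a list with elements
#'   `fixed` and `moving` (`scalar_image`s or arrays of one common shape,
#'   every axis divisible by 16).  [make_pair()] outputs can be passed
#'   directly.
#' @param config A [training_config()].
#' @param sim_spec A `similarity_net_spec` (defaults to the standard spec for
#'   the data dimensionality).
#' @param den_spec A `denoiser_net_spec` (decoupled mode only).
#' @param trace_params If `TRUE`, snapshot both networks' parameters after
#'   each half-step (decoupled mode); used to verify that the similarity
#'   update never touches the denoiser and vice versa.  Meant for small runs.
#' @return An object of class `train_state` with the network parameters,
#'   optimizer states, config and a `history` data frame (iteration,
#'   sim_loss, denoise_loss, joint_objective).
#' @export
train <- function(dataset, config = training_config(),
                  sim_spec = NULL, den_spec = NULL, trace_params = FALSE) {
  if (length(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  pairs <- lapply(dataset, function(p)
    list(fixed = grid_values(p$fixed), moving = grid_values(p$moving)))
  shape <- dim(pairs[[1L]]$fixed)
  for (p in pairs) {
    check_same_shape(p$fixed, pairs[[1L]]$fixed, "dataset images")
    check_same_shape(p$moving, pairs[[1L]]$fixed, "dataset images")
  }
  check_div16(shape)
  d <- length(shape)
  if (is.null(sim_spec)) sim_spec <- similarity_net_spec(d)
  stopifnot(sim_spec$d == d)
  hp <- config$hp
  decoupled <- config$mode == "decoupled"

  set.seed(config$seed)
  sim_params <- init_similarity_net(sim_spec)
  sim_opt <- adam_init(sim_params)
  den_params <- NULL; den_opt <- NULL
  if (decoupled) {
    if (is.null(den_spec)) den_spec <- denoiser_net_spec(d)
    stopifnot(den_spec$d == d)
    den_params <- init_denoiser_net(den_spec)
    den_opt <- adam_init(den_params)
  } else den_spec <- NULL

  history <- data.frame(iteration = integer(0), sim_loss = numeric(0),
                        denoise_loss = numeric(0),
                        joint_objective = numeric(0))
  trace <- if (trace_params) vector("list", config$iterations) else NULL
  n <- length(pairs)
  lr <- config$learning_rate

  for (it in seq_len(config$iterations)) {
    idx <- sample.int(n, config$batch_size, replace = TRUE)
    fixed_b <- stack_batch(lapply(idx, function(i) pairs[[i]]$fixed))
    moving_b <- stack_batch(lapply(idx, function(i) pairs[[i]]$moving))

    # -- step (a): update the similarity network --
    fw <- simnet_fwd(sim_params, sim_spec, fixed_b, moving_b,
                     want_cache = TRUE)
    u_b <- fw$field
    lcc <- batch_lcc_grad(fixed_b, moving_b, u_b, hp$lcc_window, hp$epsilon)
    sim_loss <- lcc$loss
    dfield <- lcc$dfield
    if (decoupled) {
      v_b <- dennet_fwd(den_params, den_spec, u_b)$v   # frozen, detached
      sim_loss <- sim_loss + hp$alpha * mean((u_b - v_b)^2)
      dfield <- dfield + 2 * hp$alpha * (u_b - v_b) / length(u_b)
    } else if (config$mode == "ss_net") {
      sim_loss <- sim_loss + hp$lambda_ * batch_smoothness(u_b)
      dfield <- dfield + hp$lambda_ * batch_smoothness_grad(u_b)
    }
    if (!is.finite(sim_loss))
      stop("non-finite similarity loss at iteration ", it, call. = FALSE)
    grads <- simnet_bwd(sim_params, sim_spec, fw$cache, dfield)
    upd <- adam_step(sim_params, grads, sim_opt, lr)
    sim_params <- upd$params; sim_opt <- upd$state
    if (trace_params)
      trace[[it]] <- list(sim_after_a = sim_params,
                          den_after_a = den_params)

    # -- step (b): update the denoiser on the recomputed, detached u --
    den_loss <- NA_real_
    if (decoupled) {
      u_b <- simnet_fwd(sim_params, sim_spec, fixed_b, moving_b)$field
      dfw <- dennet_fwd(den_params, den_spec, u_b, want_cache = TRUE)
      v_b <- dfw$v
      den_loss <- mean((v_b - u_b)^2) + hp$beta * batch_smoothness(v_b)
      if (!is.finite(den_loss))
        stop("non-finite denoiser loss at iteration ", it, call. = FALSE)
      dv <- 2 * (v_b - u_b) / length(v_b) +
        hp$beta * batch_smoothness_grad(v_b)
      dgrads <- dennet_bwd(den_params, den_spec, dfw$cache, dv)
      dupd <- adam_step(den_params, dgrads, den_opt, lr)
      den_params <- dupd$params; den_opt <- dupd$state
    }
    if (trace_params) {
      trace[[it]]$sim_after_b <- sim_params
      trace[[it]]$den_after_b <- den_params
    }

    if (it %% config$checkpoint_every == 0L || it == config$iterations) {
      if (!decoupled)
        u_b <- simnet_fwd(sim_params, sim_spec, fixed_b, moving_b)$field
      jo <- batch_joint_objective(fixed_b, moving_b, u_b, hp)
      history <- rbind(history, data.frame(
        iteration = it, sim_loss = sim_loss, denoise_loss = den_loss,
        joint_objective = jo))
    }
  }

  structure(list(mode = config$mode, sim_params = sim_params,
                 sim_spec = sim_spec, den_params = den_params,
                 den_spec = den_spec, sim_opt = sim_opt, den_opt = den_opt,
                 config = config, history = history, trace = trace),
            class = "train_state")
}

batch_joint_objective <- function(fixed_b, moving_b, u_b, hp) {
  dm <- dim(fixed_b)
  B <- dm[length(dm)]
  total <- 0
  for (b in seq_len(B)) {
    f <- batch_slice(fixed_b, b)
    m <- batch_slice(moving_b, b)
    u <- batch_slice_field(u_b, b)
    total <- total + joint_objective(f, m, u, hp$lambda_, hp$lcc_window,
                                     hp$epsilon)
  }
  total / B
}

batch_slice_field <- function(u_b, b) {
  dm <- dim(u_b)
  npix <- prod(dm[-length(dm)])
  dim(u_b) <- c(npix, dm[length(dm)])
  out <- u_b[, b]
  dim(out) <- dm[-length(dm)]
  out
}

#' @export
print.train_state <- function(x, ...) {
  cat("<train_state> mode =", x$mode, "after",
      if (nrow(x$history)) max(x$history$iteration) else 0L, "iterations\n")
  invisible(x)
}

#' Register a moving image to a fixed image with trained networks
#'
#' @param state A `train_state` from [train()].
#' @param fixed,moving `scalar_image`s or arrays of identical shape.
#' @return A list with `u` (predicted field), `warped`
#'   (`warp_image(moving, u)`) and `v` (the denoised field, `NULL` for
#'   baseline modes).
#' @export
register_pair <- function(state, fixed, moving) {
  stopifnot(inherits(state, "train_state"))
  u <- similarity_net_forward(state$sim_params, fixed, moving,
                              state$sim_spec)
  v <- if (!is.null(state$den_params))
    denoiser_net_forward(state$den_params, u, state$den_spec) else NULL
  warped <- warp_image(moving, u, "linear")
  list(u = u, warped = warped, v = v)
}

#' Write a training history to CSV
#' @param state A `train_state`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(state, path) {
  write.csv(state$history, path, row.names = FALSE)
  invisible(path)
}
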