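# Shared desk-scale benchmark used by the end-to-end recovery tests:
# 64x64 phantoms, peak displacement 4 voxels, field smoothness scale 4,
# 20 training and 5 held-out pairs.  Trained states are cached per
# (mode, seed, iterations) so several tests can evaluate the same runs.

bench_cache <- new.env(parent = emptyenv())

bench_spec <- function(seed = 0L) {
  synthetic_spec(shape = c(64L, 64L), n_pairs = 20L, max_displacement = 4,
                 smoothness_sigma = 4, seed = seed)
}

bench_data <- function(seed = 0L) {
  key <- paste0("data", seed)
  if (is.null(bench_cache[[key]])) {
    spec <- bench_spec(seed)
    bench_cache[[key]] <- list(
      train = make_dataset(spec),
      heldout = make_dataset(spec, n = 5L, offset = 100L))
  }
  bench_cache[[key]]
}

bench_train <- function(mode, seed = 0L, iterations = 1500L,
                        learning_rate = 1e-3) {
  key <- paste(mode, seed, iterations, sep = "_")
  if (is.null(bench_cache[[key]])) {
    data <- bench_data(seed)
    cfg <- training_config(mode, iterations = iterations,
                           learning_rate = learning_rate, batch_size = 4L,
                           seed = seed)
    bench_cache[[key]] <- train(data$train, cfg)
  }
  bench_cache[[key]]
}

# Held-out metrics for a trained state: per-pair Dice before/after
# registration, endpoint error of the predicted field against the inverted
# truth, the zero-field baseline error, the joint objective (lambda = 1) and
# the smoothness of u (and of v where a denoiser exists).
bench_eval <- function(state, heldout) {
  rows <- lapply(heldout, function(p) {
    r <- register_pair(state, p$fixed, p$moving)
    warped_lab <- warp_labels(p$moving_labels, r$u)
    c(dsc_before = multi_label_dice(p$fixed_labels, p$moving_labels)$mean,
      dsc_after = multi_label_dice(p$fixed_labels, warped_lab)$mean,
      epe = endpoint_error(r$u, p$inv_truth_field)$mean,
      epe_zero = endpoint_error(zero_field(dim(p$fixed$values)),
                                p$inv_truth_field)$mean,
      joint = joint_objective(p$fixed, p$moving, r$u, lambda_ = 1),
      smooth_u = smoothness_penalty(r$u),
      smooth_v = if (!is.null(r$v)) smoothness_penalty(r$v) else NA_real_)
  })
  do.call(rbind, rows)
}
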