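# Desk-scale registration problems with known ground truth: smooth random
# displacement fields (Gaussian-filtered white noise, rescaled to a target
# peak magnitude) applied to piecewise-structured "head-like" phantoms with
# multi-region label maps.
#
# A dataset emulates an inter-subject study: all pairs share one base
# anatomy (determined by the spec seed), each pair's fixed image is the base
# warped by a per-pair random smooth "subject" deformation plus per-pair
# noise, and the moving image is synthesized FROM the fixed image via the
# ground-truth field.  The registration target is therefore the truth
# field's numerical inverse; both are returned with every pair.

#' Synthetic problem specification
#'
#' @param shape Grid shape, each axis divisible by 16.
#' @param n_pairs Number of pairs a dataset should contain.
#' @param max_displacement Peak displacement magnitude in voxels; must stay
#'   below `min(shape)/4` so fields stay well inside the grid.
#' @param smoothness_sigma Gaussian scale (voxels, >= 1) of the random field.
#' @param n_regions Number of foreground regions (>= 2).
#' @param noise_sigma Gaussian intensity noise level.
#' @param image_sigma Gaussian scale for smoothing the piecewise-constant
#'   phantom intensities (0 keeps them piecewise constant).
#' @param subject_displacement Peak magnitude (voxels) of the per-pair
#'   subject deformation relating each fixed image to the shared base
#'   anatomy.  Defaults to half `max_displacement`: the emulated data class
#'   is affine-prealigned, so residual inter-subject variability is smaller
#'   than the deformations being estimated.
#' @param texture_sigma Gaussian scale of the smooth anatomy-linked
#'   intensity modulation added to the base phantom (gives local matching
#'   signal inside regions, as tissue texture does).
#' @param texture_amp Amplitude of that modulation (0 disables it).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(64L, 64L), n_pairs = 20L,
                           max_displacement = 4, smoothness_sigma = 4,
                           n_regions = 8L, noise_sigma = 0.02,
                           image_sigma = 1,
                           subject_displacement = max_displacement / 2,
                           texture_sigma = 3, texture_amp = 0.25,
                           seed = 0L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% 2:3, all(shape >= 16L))
  if (max_displacement < 0 || max_displacement >= min(shape) / 4)
    stop("max_displacement must be in [0, min(shape)/4)", call. = FALSE)
  if (smoothness_sigma < 1)
    stop("smoothness_sigma must be >= 1", call. = FALSE)
  stopifnot(n_regions >= 2L, noise_sigma >= 0, image_sigma >= 0,
            n_pairs >= 1L, subject_displacement >= 0, texture_sigma > 0,
            texture_amp >= 0)
  if (subject_displacement >= min(shape) / 4)
    stop("subject_displacement must stay below min(shape)/4", call. = FALSE)
  structure(list(shape = shape, n_pairs = as.integer(n_pairs),
                 max_displacement = max_displacement,
                 smoothness_sigma = smoothness_sigma,
                 n_regions = as.integer(n_regions),
                 noise_sigma = noise_sigma, image_sigma = image_sigma,
                 subject_displacement = subject_displacement,
                 texture_sigma = texture_sigma, texture_amp = texture_amp,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  cpp_sepconv_replicate(arr, dim(arr), gauss_kernel(sigma))
}

#' Random smooth displacement field
#'
#' Per component: white noise convolved with a Gaussian of scale
#' `smoothness_sigma`, then rescaled so the maximum voxelwise magnitude
#' equals `max_displacement` exactly.
#'
#' @param spec A [synthetic_spec()].  Uses the current RNG state; seed with
#'   `set.seed()` (or use [make_pair()], which seeds from the spec).
#' @return A `deformation_field`.
#' @export
random_smooth_field <- function(spec) {
  shape <- spec$shape
  d <- length(shape)
  u <- array(0, dim = c(d, shape))
  if (spec$max_displacement == 0) return(deformation_field(u))
  for (c in seq_len(d)) {
    w <- array(rnorm(prod(shape)), dim = shape)
    u <- set_comp(u, c, gauss_smooth(w, spec$smoothness_sigma))
  }
  mag <- array(0, dim = shape)
  for (c in seq_len(d)) mag <- mag + get_comp(u, c)^2
  mag <- sqrt(mag)
  u <- u * (spec$max_displacement / max(mag))
  deformation_field(u)
}

#' Head-like phantom image and label map
#'
#' An ellipsoidal foreground partitioned into `n_regions` contiguous regions
#' (Voronoi cells of seed points drawn inside the foreground; each cell is
#' the intersection of two convex sets, hence connected), each region given
#' a distinct mean intensity, optionally smoothed, plus Gaussian noise; the
#' result is min-max normalized.  Labels are region IDs with 0 outside.
#'
#' @param spec A [synthetic_spec()].  Uses the current RNG state.
#' @param noise If `FALSE`, skip the additive noise (used when building the
#'   shared base anatomy of a dataset, which receives per-pair noise later).
#' @return A list with `image` (`scalar_image`) and `labels` (`label_map`).
#' @export
make_phantom <- function(spec, noise = TRUE) {
  shape <- spec$shape
  d <- length(shape)
  coords <- arrayInd(seq_len(prod(shape)), .dim = shape) - 1L
  centre <- (shape - 1) / 2
  semi <- shape * runif(d, 0.42, 0.48)
  q <- rep(0, nrow(coords))
  for (a in seq_len(d)) q <- q + ((coords[, a] - centre[a]) / semi[a])^2
  fg <- q <= 1

  # Voronoi partition of the foreground from seeds inside it
  fg_idx <- which(fg)
  seeds <- fg_idx[sample.int(length(fg_idx), spec$n_regions)]
  seed_xy <- coords[seeds, , drop = FALSE]
  best <- rep(Inf, length(fg_idx)); lab_fg <- rep(1L, length(fg_idx))
  for (r in seq_len(spec$n_regions)) {
    d2 <- rep(0, length(fg_idx))
    for (a in seq_len(d))
      d2 <- d2 + (coords[fg_idx, a] - seed_xy[r, a])^2
    better <- d2 < best
    best[better] <- d2[better]
    lab_fg[better] <- r
  }
  labels <- array(0L, dim = shape)
  labels[fg_idx] <- lab_fg

  means <- sample(seq(0.3, 1, length.out = spec$n_regions))
  img <- array(0, dim = shape)
  img[fg_idx] <- means[lab_fg]
  if (spec$texture_amp > 0) {
    tex <- gauss_smooth(array(rnorm(prod(shape)), dim = shape),
                        spec$texture_sigma)
    tex <- tex / max(abs(tex))
    img[fg_idx] <- img[fg_idx] + spec$texture_amp * tex[fg_idx]
  }
  img <- gauss_smooth(img, spec$image_sigma)
  if (noise && spec$noise_sigma > 0)
    img <- img + array(rnorm(prod(shape), sd = spec$noise_sigma),
                       dim = shape)
  list(image = normalize_image(img), labels = label_map(labels))
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `inv(x) = -u(x + inv(x))` so that backward-warping by `inv`
#' undoes the synthesis `moving(y) = fixed(y + u(y))`.
#'
#' @param field A `deformation_field` or `(d, n1..nd)` array.
#' @param n_iter Number of fixed-point iterations.
#' @return A list with `inverse` (same type as `field`) and `residual`,
#'   the maximum voxelwise norm of `u(x + inv(x)) + inv(x)`.
#' @export
invert_field <- function(field, n_iter = 20L) {
  u <- field_values(field)
  inv <- array(0, dim = dim(u))
  for (i in seq_len(n_iter)) inv <- -sample_field(u, inv)
  comp <- sample_field(u, inv) + inv
  mag <- sqrt(apply(comp^2, seq_along(dim(u))[-1L], sum))
  res <- list(inverse = inv, residual = max(mag))
  if (inherits(field, "deformation_field"))
    res$inverse <- deformation_field(inv)
  res
}

#' Generate one synthetic registration pair
#'
#' The fixed image is a subject drawn from the dataset's population: the
#' shared base anatomy (seeded by `spec$seed`) warped by a per-pair random
#' smooth subject deformation, plus per-pair noise.  The moving image and
#' labels are then synthesized by warping the fixed ones with a smooth
#' ground-truth field.  Returns the forward truth field plus its numerical
#' inverse (the target for registering moving to fixed); draws whose
#' inversion residual exceeds 0.5 voxels are redrawn (bounded retries).
#'
#' @param spec A [synthetic_spec()].
#' @param pair_seed Seed for this pair's subject deformation, noise and
#'   truth field; defaults to `spec$seed`.  The base anatomy always comes
#'   from `spec$seed`, so pairs with different `pair_seed` are different
#'   subjects of one population.
#' @return An object of class `synthetic_pair`: a list with `fixed`,
#'   `moving` (`scalar_image`s), `fixed_labels`, `moving_labels`
#'   (`label_map`s), `truth_field`, `inv_truth_field`
#'   (`deformation_field`s), `inversion_residual` and `seed`.
#' @export
make_pair <- function(spec, pair_seed = spec$seed) {
  set.seed(spec$seed)
  base <- make_phantom(spec, noise = FALSE)

  set.seed(pair_seed)
  sub_spec <- spec
  sub_spec$max_displacement <- spec$subject_displacement
  subject <- random_smooth_field(sub_spec)
  img <- warp_image(base$image, subject, "linear")$values
  if (spec$noise_sigma > 0)
    img <- img + array(rnorm(length(img), sd = spec$noise_sigma),
                       dim = dim(img))
  fixed <- normalize_image(img)
  fixed_labels <- warp_labels(base$labels, subject)

  for (attempt in 1:5) {
    truth <- random_smooth_field(spec)
    inv <- invert_field(truth)
    if (inv$residual <= 0.5) {
      moving <- warp_image(fixed, truth, "linear")
      moving_labels <- warp_labels(fixed_labels, truth)
      return(structure(
        list(fixed = fixed, moving = moving,
             fixed_labels = fixed_labels, moving_labels = moving_labels,
             truth_field = truth, inv_truth_field = inv$inverse,
             inversion_residual = inv$residual, seed = pair_seed),
        class = "synthetic_pair"))
    }
  }
  stop("field inversion residual stayed above 0.5 voxels after 5 draws",
       call. = FALSE)
}

#' Generate a dataset of synthetic pairs
#'
#' Pair i is generated with seed `spec$seed + i - 1`, so datasets are fully
#' deterministic given the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of pairs (defaults to `spec$n_pairs`).
#' @param offset Added to the per-pair seeds; use to draw disjoint held-out
#'   sets.
#' @return A list of `synthetic_pair`s.
#' @export
make_dataset <- function(spec, n = spec$n_pairs, offset = 0L) {
  lapply(seq_len(n), function(i) make_pair(spec, spec$seed + offset + i - 1L))
}
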