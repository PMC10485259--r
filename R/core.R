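# Domain types: scalar images, displacement fields, label maps and the
# balancing hyper-parameters.  All are light S3 wrappers around plain R
# arrays; displacement fields are stored in voxel units with layout
# (component, n1..nd), and spacing is metadata only.

#' Scalar image
#'
#' A d-dimensional (d in 2:3) grid of real intensities with voxel spacing
#' metadata.  Values must be finite; every axis must have at least 4 voxels.
#'
#' @param values Numeric array (matrix for 2D) of intensities.
#' @param spacing Positive numeric vector of mm per axis (recycled to d).
#' @return An object of class `scalar_image` with fields `values`, `spacing`
#'   and `intensity_range`.
#' @export
scalar_image <- function(values, spacing = 1) {
  values <- as_grid(values, "values")
  d <- length(dim(values))
  spacing <- rep_len(as.numeric(spacing), d)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive and finite", call. = FALSE)
  structure(
    list(values = values, spacing = spacing,
         intensity_range = range(values)),
    class = "scalar_image")
}

#' @export
print.scalar_image <- function(x, ...) {
  cat("<scalar_image> ", paste(dim(x$values), collapse = "x"),
      " spacing [", paste(format(x$spacing), collapse = ", "), "] range [",
      paste(format(signif(x$intensity_range, 4)), collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Deformation field
#'
#' A d-vector-valued grid of voxel-unit displacements with layout
#' `(d, n1..nd)`.  A field maps output voxel `x` to sampling location
#' `x + u(x)` in the moving image (backward warping, 0-based voxel-centred
#' coordinates).
#'
#' @param displacements Numeric array of shape `(d, n1..nd)`.
#' @return An object of class `deformation_field` with fields
#'   `displacements` and `grid_shape`.
#' @export
deformation_field <- function(displacements) {
  if (is.null(dim(displacements)))
    stop("displacements must be an array of shape (d, n1..nd)", call. = FALSE)
  dm <- dim(displacements)
  d <- dm[1L]
  if (length(dm) != d + 1L)
    stop("component count (", d, ") must equal spatial dimensionality (",
         length(dm) - 1L, ")", call. = FALSE)
  if (!(d %in% 2:3) && !(d == 1L && length(dm) == 2L))
    stop("dimensionality must be 2 or 3", call. = FALSE)
  nbad <- sum(!is.finite(displacements))
  if (nbad > 0L)
    stop("displacements contain ", nbad, " non-finite entries", call. = FALSE)
  structure(
    list(displacements = displacements, grid_shape = dm[-1L]),
    class = "deformation_field")
}

#' Zero deformation field for a grid shape
#' @param shape Integer vector of spatial grid sizes.
#' @return A `deformation_field` of zeros.
#' @export
zero_field <- function(shape) {
  d <- length(shape)
  deformation_field(array(0, dim = c(d, shape)))
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(apply(x$displacements^2, seq_along(x$grid_shape) + 1L, sum))
  cat("<deformation_field> ", paste(x$grid_shape, collapse = "x"),
      " max |u| = ", format(signif(max(mag), 4)), " voxels\n", sep = "")
  invisible(x)
}

#' Label map
#'
#' Non-negative integer grid of region IDs; label 0 is reserved for
#' background.
#'
#' @param labels Integer-valued array of region IDs.
#' @return An object of class `label_map` with fields `labels` and
#'   `label_ids` (sorted nonzero IDs present).
#' @export
label_map <- function(labels) {
  labels <- as_grid(labels, "labels")
  if (any(labels != round(labels)) || any(labels < 0))
    stop("labels must be non-negative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels != 0L]))
  structure(list(labels = labels, label_ids = ids), class = "label_map")
}

#' Balancing hyper-parameters
#'
#' @param alpha Coupling weight (>= 0) tying the similarity field `u` to the
#'   auxiliary field `v`.
#' @param beta Smoothness weight (>= 0) on `v` in the smoothing sub-problem.
#' @param lambda_ Smoothness weight (>= 0) in the joint objective, used for
#'   monitoring and for the single-network baseline with in-loss smoothing.
#' @param lcc_window Odd per-axis window size (>= 3) for local normalized
#'   cross-correlation.
#' @param epsilon Positive stabilizer added to the LCC denominator.
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(alpha = 0.1, beta = 1, lambda_ = 1,
                        lcc_window = 9L, epsilon = 1e-5) {
  lcc_window <- as.integer(lcc_window)
  if (lcc_window < 3L || lcc_window %% 2L == 0L)
    stop("lcc_window must be odd and >= 3", call. = FALSE)
  for (nm in c("alpha", "beta", "lambda_")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val < 0)
      stop(nm, " must be a single finite value >= 0", call. = FALSE)
  }
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, lambda_ = lambda_,
                 lcc_window = lcc_window, epsilon = epsilon),
            class = "hyperparams")
}

#' Min-max normalize a raw intensity grid
#'
#' Maps a raw grid affinely onto \[0, 1\]; a constant grid maps to all zeros
#' (synthetic fixtures legitimately contain constant backgrounds).
#'
#' @param raw Numeric array of raw intensities.
#' @param spacing Voxel spacing passed through to the result.
#' @return A `scalar_image` with values in \[0, 1\].
#' @export
normalize_image <- function(raw, spacing = 1) {
  if (inherits(raw, "scalar_image")) {
    spacing <- raw$spacing
    raw <- raw$values
  }
  raw <- as_grid(raw, "raw")
  rng <- range(raw)
  vals <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
          else array(0, dim = dim(raw))
  scalar_image(vals, spacing)
}

# ---- internal validation helpers ----

as_grid <- function(x, what) {
  if (is.null(dim(x))) stop(what, " must have a dim attribute", call. = FALSE)
  nbad <- sum(!is.finite(x))
  if (nbad > 0L)
    stop(what, " contains ", nbad, " non-finite entries", call. = FALSE)
  d <- length(dim(x))
  if (!(d %in% 2:3))
    stop(what, " must be 2- or 3-dimensional, got ", d, "D", call. = FALSE)
  if (any(dim(x) < 2L))
    stop("every axis must have at least 2 voxels", call. = FALSE)
  storage.mode(x) <- if (is.integer(x)) "integer" else "double"
  x
}

# Accept a scalar_image or plain array and return the values array.
grid_values <- function(x) {
  if (inherits(x, "scalar_image")) x$values
  else if (inherits(x, "label_map")) x$labels
  else x
}

# Accept a deformation_field or plain (d, n1..nd) array.
field_values <- function(u) {
  if (inherits(u, "deformation_field")) u$displacements else u
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(what, " must have identical shapes: ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

check_field_matches <- function(field, shape) {
  u <- field_values(field)
  fs <- dim(u)[-1L]
  if (!identical(as.integer(fs), as.integer(shape)))
    stop("field grid shape (", paste(fs, collapse = "x"),
         ") does not match image shape (", paste(shape, collapse = "x"), ")",
         call. = FALSE)
  invisible(TRUE)
}
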