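# Spatial transformation: backward warping of images and label maps by a
# displacement field, differentiable with respect to the field in linear
# mode.  Out-of-bounds samples use border clamping (replicate edge) so that
# local cross-correlation windows near the boundary are not polluted by
# artificial zeros.

#' Identity coordinate grid
#'
#' Returns the 0-based voxel-centred coordinate grid for a shape:
#' `grid[c, x] = x_c` for every voxel `x` and component `c`.
#'
#' @param shape Integer vector of spatial sizes (length 1 to 3).
#' @return Numeric array of shape `(d, shape)`.
#' @export
identity_grid <- function(shape) {
  shape <- as.integer(shape)
  d <- length(shape)
  stopifnot(d >= 1L, d <= 3L, all(shape >= 1L))
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape) - 1L
  g <- t(idx)
  storage.mode(g) <- "double"
  dim(g) <- c(d, shape)
  g
}

# Fast first-axis component access for (d, n1..nd) arrays.
get_comp <- function(u, c) {
  dm <- dim(u)
  dim(u) <- c(dm[1L], prod(dm[-1L]))
  comp <- u[c, ]
  dim(comp) <- dm[-1L]
  comp
}

set_comp <- function(u, c, value) {
  dm <- dim(u)
  dim(u) <- c(dm[1L], prod(dm[-1L]))
  u[c, ] <- value
  dim(u) <- dm
  u
}

#' Warp an image by a displacement field
#'
#' Backward warping: `out[x] = moving(x + u(x))`, sampled with linear or
#' nearest-neighbour interpolation and border clamping.  Linear mode is
#' differentiable with respect to the field.
#'
#' @param moving A `scalar_image` or plain numeric array.
#' @param field A `deformation_field` or `(d, n1..nd)` array matching the
#'   image shape.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return Same type as `moving` (a `scalar_image` in, `scalar_image` out).
#' @export
warp_image <- function(moving, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  vals <- grid_values(moving)
  if (is.null(dim(vals))) dim(vals) <- length(vals)  # allow 1-D vectors
  check_field_matches(field, dim(vals))
  u <- field_values(field)
  out <- cpp_warp(as.double(vals), dim(vals), as.double(u),
                  if (interpolation == "nearest") 1L else 0L)
  if (inherits(moving, "scalar_image")) {
    res <- moving
    res$values <- out
    res$intensity_range <- range(out)
    res
  } else out
}

#' Warp a label map by a displacement field
#'
#' Nearest-neighbour sampling of region IDs; the output ID set is a subset of
#' the input ID set.
#'
#' @param labels A `label_map` or integer-valued array.
#' @param field A `deformation_field` or `(d, n1..nd)` array.
#' @return Same type as `labels`.
#' @export
warp_labels <- function(labels, field) {
  vals <- grid_values(labels)
  if (is.null(dim(vals))) dim(vals) <- length(vals)
  check_field_matches(field, dim(vals))
  u <- field_values(field)
  out <- cpp_warp(as.double(vals), dim(vals), as.double(u), 1L)
  out <- array(as.integer(round(out)), dim = dim(vals))
  if (inherits(labels, "label_map")) label_map(out) else out
}

# Gradient of sum(dout * warp_image(moving, u, "linear")) with respect to u.
warp_image_grad_field <- function(moving, field, dout) {
  vals <- grid_values(moving)
  u <- field_values(field)
  cpp_warp_bwd_field(as.double(vals), dim(vals), as.double(u),
                     as.double(dout))
}

# Sample each component of a vector field at displaced positions; used by
# fixed-point field inversion.
sample_field <- function(field, at) {
  u <- field_values(field)
  d <- dim(u)[1L]
  shape <- dim(u)[-1L]
  out <- array(0, dim = dim(u))
  for (c in seq_len(d)) {
    comp <- get_comp(u, c)
    out <- set_comp(out, c,
                    cpp_warp(as.double(comp), shape, as.double(at), 0L))
  }
  out
}
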