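# Quantitative evaluation: Dice similarity coefficient per region and
# averaged, endpoint error against a ground-truth field, and residual maps.

#' Dice similarity coefficient between two binary masks
#'
#' `DSC(A, B) = 2|A intersect B| / (|A| + |B|)`.  When both masks are empty
#' the coefficient is undefined and `NA` is returned (excluded from
#' aggregation by [multi_label_dice()]).
#'
#' @param a,b Logical (or 0/1) arrays of identical shape.
#' @return A number in \[0, 1\], or `NA` if both masks are empty.
#' @export
dice <- function(a, b) {
  check_same_shape(a, b, "masks")
  a <- as.logical(a); b <- as.logical(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

#' Per-label and mean Dice between two label maps
#'
#' Computes the Dice coefficient of the indicator masks of every nonzero
#' label present in either map; labels absent from both are excluded.  The
#' mean is unweighted over defined per-label values.
#'
#' @param template_labels,registered_labels `label_map`s or integer arrays
#'   of identical shape.
#' @return A list with `per_label` (data frame: label, dice) and `mean`.
#' @export
multi_label_dice <- function(template_labels, registered_labels) {
  a <- grid_values(template_labels)
  b <- grid_values(registered_labels)
  check_same_shape(a, b, "label maps")
  ids <- sort(union(unique(a[a != 0L]), unique(b[b != 0L])))
  per <- vapply(ids, function(id) dice(a == id, b == id), numeric(1))
  list(per_label = data.frame(label = as.integer(ids), dice = per),
       mean = mean(per, na.rm = TRUE))
}

#' Endpoint error between two displacement fields
#'
#' Per-voxel Euclidean norm of the displacement difference, in voxels.
#'
#' @param estimated,truth `deformation_field`s or `(d, n1..nd)` arrays of
#'   identical shape.
#' @return A list with `mean` and `max`.
#' @export
endpoint_error <- function(estimated, truth) {
  e <- field_values(estimated); t <- field_values(truth)
  check_same_shape(e, t, "fields")
  diff2 <- (e - t)^2
  nrm <- sqrt(apply(diff2, seq_along(dim(e))[-1L], sum))
  list(mean = mean(nrm), max = max(nrm))
}

#' Residual map between a registered image and the template
#'
#' Signed voxelwise difference, sign convention `image - fixed`
#' (registered minus template), plus the mean absolute residual.
#'
#' @param fixed,image `scalar_image`s or arrays of identical shape.
#' @return A list with `map` (same type as `fixed`) and `mar` (mean absolute
#'   residual).
#' @export
residual_map <- function(fixed, image) {
  f <- grid_values(fixed); g <- grid_values(image)
  check_same_shape(f, g, "images")
  resid <- g - f
  out <- if (inherits(fixed, "scalar_image"))
    scalar_image(resid, fixed$spacing) else resid
  list(map = out, mar = mean(abs(resid)))
}

#' Write a per-region Dice table to CSV
#' @param dsc Output of [multi_label_dice()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dice_table <- function(dsc, path) {
  write.csv(dsc$per_label, path, row.names = FALSE)
  invisible(path)
}
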