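# File formats: NIfTI-1 for scalar images, label maps and vector-valued
# displacement fields (2D grids are stored as degenerate NIfTI volumes,
# which NIfTI-1 supports natively); plain CSV as an alternative for 2D
# scalar grids; JSON run manifests.  Fields are stored with the component
# axis last and voxel units noted in the header description.

nifti_ext <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Write a scalar image or label map to disk
#'
#' `.nii`/`.nii.gz` writes NIfTI-1 (float for images, int32 for labels,
#' spacing in the header); `.csv` writes a plain matrix (2D only, spacing
#' not stored).
#'
#' @param image A `scalar_image`, `label_map`, or plain array.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  is_labels <- inherits(image, "label_map")
  vals <- grid_values(image)
  spacing <- if (inherits(image, "scalar_image")) image$spacing
             else rep(1, length(dim(vals)))
  if (nifti_ext(path)) {
    hdr <- RNifti::asNifti(vals)
    RNifti::pixdim(hdr) <- spacing
    RNifti::writeNifti(hdr, path,
                       datatype = if (is_labels) "int32" else "double")
  } else if (grepl("\\.csv$", path)) {
    if (length(dim(vals)) != 2L)
      stop("CSV image output supports 2D grids only", call. = FALSE)
    utils::write.table(vals, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported image extension: ", path, call. = FALSE)
  invisible(path)
}

#' Read a scalar image or label map from disk
#'
#' @param path `.nii`, `.nii.gz` or `.csv` file.
#' @param labels If `TRUE`, validate integer values and return a
#'   `label_map`.
#' @return A `scalar_image` or `label_map`.
#' @export
read_image <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  if (nifti_ext(path)) {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    nd <- length(dim(vals))
    if (!(nd %in% 2:3))
      stop(path, " has ", nd, " dimensions; only 2D/3D grids are supported",
           call. = FALSE)
    spacing <- RNifti::pixdim(img)[seq_len(nd)]
  } else if (grepl("\\.csv$", path)) {
    vals <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(vals) <- NULL
    spacing <- rep(1, 2L)
  } else stop("unsupported image extension: ", path, call. = FALSE)
  if (labels) {
    if (any(vals != round(vals)))
      stop(path, " contains non-integer values; not a label map",
           call. = FALSE)
    label_map(array(as.integer(vals), dim = dim(vals)))
  } else scalar_image(array(as.double(vals), dim = dim(vals)), spacing)
}

#' Write a deformation field to NIfTI
#'
#' Stored with the component axis last (shape `n1..nd x d`), displacement
#' units recorded as voxels in the header description.
#'
#' @param field A `deformation_field`.
#' @param path `.nii` or `.nii.gz` destination.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  if (!nifti_ext(path))
    stop("fields are stored as NIfTI (.nii/.nii.gz)", call. = FALSE)
  u <- field_values(field)
  d <- dim(u)[1L]
  arr <- aperm(u, c(seq_len(d) + 1L, 1L))
  hdr <- RNifti::asNifti(arr, descrip =
    "displacement field, voxel units, component axis last")
  RNifti::writeNifti(hdr, path, datatype = "double")
  invisible(path)
}

#' Read a deformation field from NIfTI
#'
#' @param path `.nii` or `.nii.gz` file written by [write_field()].
#' @return A `deformation_field`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  dm <- dim(arr)
  nd <- length(dm) - 1L
  if (dm[length(dm)] != nd)
    stop("field file has ", dm[length(dm)], " components for ", nd,
         " spatial dimensions", call. = FALSE)
  deformation_field(aperm(arr, c(nd + 1L, seq_len(nd))))
}

#' Write a JSON run manifest
#'
#' Captures the configuration, seed, package version and MD5 hashes of the
#' input files so that runs are auditable and repeatable.
#'
#' @param path Destination `.json` path.
#' @param config A list of configuration values (serialized as-is).
#' @param seed The seed used.
#' @param inputs Character vector of input file paths to hash.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NA_integer_,
                           inputs = character(0)) {
  hashes <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "splitreg",
    version = as.character(utils::packageVersion("splitreg")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_hashes = hashes)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
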