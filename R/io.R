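#' Read a volume from NIfTI
#'
#' Reads a NIfTI-1/2 file into a [vvol]. Volumes are reoriented to RAS (the
#' scanner convention used throughout the package) when stored otherwise; the
#' applied permutation is recorded in the `"orientation_from"` attribute and a
#' message is emitted. A JSON units sidecar (`<stem>.units.json`) written by
#' [write_volume()] is honoured; without one the volume is tagged
#' dimensionless.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return a [vvol]; attributes `orientation_from` (original orientation code)
#'   and `affine` carry provenance.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  orig <- RNifti::orientation(img)
  if (!identical(orig, "RAS")) {
    RNifti::orientation(img) <- "RAS"
    message(sprintf("read_volume: reoriented %s -> RAS (%s)", orig,
                    basename(path)))
  }
  arr <- array(as.numeric(img), dim = dim(img))
  if (all(is.na(arr))) stop("volume is NaN-only: ", path)
  vox <- RNifti::pixdim(img)[1:3]
  units <- "1"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$units)) units <- meta$units
  }
  v <- vvol(arr, vox, units)
  attr(v, "orientation_from") <- orig
  attr(v, "affine") <- RNifti::xform(img)
  v
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".units.json")
}

#' Write a volume to NIfTI with a units sidecar
#'
#' Writes the array with an axis-aligned RAS affine whose origin is the centre
#' voxel, plus a JSON sidecar recording the units tag (NIfTI itself has no
#' field-map unit slot).
#'
#' @param v a [vvol].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "vvol"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$vox
  dims <- dim(v$data)
  aff <- diag(c(v$vox, 1))
  aff[1:3, 4] <- -(dims %/% 2L) * v$vox
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(units = v$units), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}
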