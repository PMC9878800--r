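# NIfTI layout of a flow dataset on disk:
#   vel_x.nii.gz, vel_y.nii.gz, vel_z.nii.gz  4D velocity (mm/s, float)
#   mag.nii.gz                                4D magnitude
#   mask.nii.gz                               3D aorta segmentation
#   sidecar.json                              dt_ms, venc_cms, seed, spec echo

write_nifti_volume <- function(arr, spacing_mm, path, dt_s = NULL) {
  img <- RNifti::asNifti(arr * 1)         # coerce logical/int to numeric
  pd <- if (length(dim(arr)) == 4) c(spacing_mm, dt_s %||% 1) else spacing_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a flow dataset as NIfTI volumes plus a JSON sidecar
#'
#' Writes the three 4D velocity component volumes (mm/s, float), the 4D
#' magnitude volume and the 3D segmentation mask as NIfTI with the voxel
#' spacing in the header, and a `sidecar.json` carrying the temporal
#' resolution, venc, seed and -- for phantoms -- an echo of the generating
#' spec. Ground truth is not serialized.
#'
#' @param ds a [flow_dataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_flow_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- ds$field$spacing_mm
  dt_s <- ds$field$dt_ms / 1000
  write_nifti_volume(ds$field$vx, sp, file.path(dir, "vel_x.nii.gz"), dt_s)
  write_nifti_volume(ds$field$vy, sp, file.path(dir, "vel_y.nii.gz"), dt_s)
  write_nifti_volume(ds$field$vz, sp, file.path(dir, "vel_z.nii.gz"), dt_s)
  write_nifti_volume(ds$magnitude, sp, file.path(dir, "mag.nii.gz"), dt_s)
  write_nifti_volume(ds$mask, sp, file.path(dir, "mask.nii.gz"))
  side <- list(dt_ms = ds$field$dt_ms, venc_cms = ds$field$venc_cms,
               spacing_mm = sp)
  if (!is.null(ds$spec)) {
    side$seed <- ds$spec$seed
    spec_echo <- unclass(ds$spec)
    spec_echo$eddy_coeffs <- as.vector(spec_echo$eddy_coeffs)
    side$spec <- spec_echo
  }
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a flow dataset from its NIfTI + JSON layout
#'
#' Counterpart of [write_flow_dataset()]. Spacing is taken from the NIfTI
#' headers; temporal resolution and venc from the sidecar.
#'
#' @param dir directory written by [write_flow_dataset()].
#' @return A [flow_dataset()] (without ground truth).
#' @export
read_flow_dataset <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  rd <- function(f) {
    img <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(img), dim(img))
  }
  vx <- rd("vel_x.nii.gz")
  spacing <- as.numeric(side$spacing_mm)
  field <- velocity_field(vx, rd("vel_y.nii.gz"), rd("vel_z.nii.gz"),
                          spacing, side$dt_ms, side$venc_cms)
  mask <- rd("mask.nii.gz") > 0.5
  flow_dataset(field, rd("mag.nii.gz"), array(mask, dim(mask)))
}
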