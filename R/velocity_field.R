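#' Time-resolved three-component velocity field
#'
#' Container for a 4D flow velocity dataset: one 4D array (x, y, z, frame) per
#' velocity component, in mm/s, on a regular grid with known voxel spacing,
#' temporal resolution and velocity-encoding limit (venc).
#'
#' @param vx,vy,vz 4D numeric arrays of identical dimensions, velocity along
#'   the three grid axes in mm/s.
#' @param spacing_mm positive numeric triple, voxel spacing in mm.
#' @param dt_ms temporal resolution in ms.
#' @param venc_cms velocity-encoding limit in cm/s; velocities beyond
#'   \eqn{\pm}venc alias by multiples of 2 venc in the raw data.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(vx, vy, vz, spacing_mm, dt_ms, venc_cms) {
  d <- dim(vx)
  if (length(d) != 4) stop("velocity components must be 4D arrays (x,y,z,t)")
  if (!identical(d, dim(vy)) || !identical(d, dim(vz)))
    stop("velocity components must share dimensions")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("'spacing_mm' must be a positive triple")
  stopifnot_scalar(dt_ms, "dt_ms")
  stopifnot_scalar(venc_cms, "venc_cms")
  structure(
    list(vx = vx, vy = vy, vz = vz,
         spacing_mm = as.numeric(spacing_mm),
         dt_ms = as.numeric(dt_ms),
         venc_cms = as.numeric(venc_cms)),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$vx)
  cat(sprintf(
    "<velocity_field> %d x %d x %d voxels, %d frames\n  spacing %s mm, dt %.1f ms, venc %.0f cm/s\n",
    d[1], d[2], d[3], d[4],
    paste(format(x$spacing_mm, digits = 3), collapse = " x "),
    x$dt_ms, x$venc_cms))
  invisible(x)
}

#' @export
dim.velocity_field <- function(x) dim(x$vx)

# number of frames
n_frames <- function(field) dim(field$vx)[4]

# venc in the working unit (mm/s)
venc_mms <- function(field) field$venc_cms * 10

# extract an n_voxels x n_frames matrix of one component at linear voxel
# indices `idx` (into a single 3D frame)
component_matrix <- function(comp, idx) {
  d <- dim(comp)
  nvol <- prod(d[1:3])
  nt <- d[4]
  m <- matrix(0, length(idx), nt)
  for (t in seq_len(nt)) m[, t] <- comp[idx + (t - 1) * nvol]
  m
}

# write an n_voxels x n_frames matrix back into a 4D array at voxel indices
`component_matrix<-` <- function(comp, idx, value) {
  d <- dim(comp)
  nvol <- prod(d[1:3])
  for (t in seq_len(d[4])) comp[idx + (t - 1) * nvol] <- value[, t]
  comp
}

#' Bundle of co-registered 4D flow inputs
#'
#' Groups the velocity field with its magnitude series and binary aorta
#' segmentation mask, plus optional phantom ground truth.
#'
#' @param field a [velocity_field].
#' @param magnitude 4D numeric array, signal magnitude per voxel and frame.
#' @param mask 3D logical array, the aorta segmentation.
#' @param spec optional `phantom_spec` the data were generated from.
#' @param ground_truth optional analytic ground truth (phantom only).
#' @return An object of class `flow_dataset`.
#' @export
flow_dataset <- function(field, magnitude, mask, spec = NULL,
                         ground_truth = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  if (!identical(dim(magnitude), dim(field$vx)))
    stop("magnitude must match the velocity field dimensions")
  if (!identical(dim(mask), dim(field$vx)[1:3]))
    stop("mask must match one velocity frame")
  structure(list(field = field, magnitude = magnitude,
                 mask = array(as.logical(mask), dim(mask)),
                 spec = spec, ground_truth = ground_truth),
            class = "flow_dataset")
}

#' @export
print.flow_dataset <- function(x, ...) {
  print(x$field)
  cat(sprintf("  mask: %d voxels; ground truth: %s\n",
              sum(x$mask), if (is.null(x$ground_truth)) "none" else "analytic"))
  invisible(x)
}
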