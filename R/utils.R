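# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# world-frame coordinate (mm) of voxel centres along one axis, 1-based indices
axis_world <- function(n, spacing) (seq_len(n) - 1) * spacing

# world coordinates (n x 3, mm) of 1-based linear voxel indices in a 3D grid
voxel_world_coords <- function(idx, dim3, spacing_mm) {
  idx0 <- as.numeric(idx) - 1
  i <- idx0 %% dim3[1]
  j <- (idx0 %/% dim3[1]) %% dim3[2]
  k <- idx0 %/% (dim3[1] * dim3[2])
  cbind(i * spacing_mm[1], j * spacing_mm[2], k * spacing_mm[3])
}

# centred moving average of width 3; ends keep the original samples
moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- x
  y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y
}

# mean voxel face area (mm^2); exact on an isotropic grid, which is the
# analysis grid after resampling. Anisotropic inputs should be resampled first.
voxel_face_area <- function(spacing_mm) prod(spacing_mm)^(2 / 3)

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (positive && x <= 0)) {
    stop(sprintf("'%s' must be a single finite %snumber", name,
                 if (positive) "positive " else ""), call. = FALSE)
  }
  invisible(x)
}
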