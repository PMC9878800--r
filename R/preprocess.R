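#' Detect static tissue from magnitude and velocity
#'
#' Static tissue is identified as voxels with high signal (time-averaged
#' magnitude above the `mag_quantile` threshold of the whole-image histogram)
#' whose velocity magnitude is temporally stable (standard deviation over
#' frames below `std_threshold_mms`). The result supports the eddy-current /
#' phase-offset fit.
#'
#' @param magnitude 4D magnitude array.
#' @param field a [velocity_field] co-registered with `magnitude`.
#' @param mag_quantile quantile of time-averaged magnitude above which a
#'   voxel counts as signal (default 0.6).
#' @param std_threshold_mms maximum temporal SD of the speed, mm/s
#'   (default 20).
#' @param exclude_mask optional 3D logical array (e.g. the aorta
#'   segmentation) removed from the result, keeping the static-tissue mask
#'   disjoint from the vessel.
#' @return 3D logical array (the static-tissue mask). Warns if empty.
#' @export
detect_static_tissue <- function(magnitude, field, mag_quantile = 0.6,
                                 std_threshold_mms = 20,
                                 exclude_mask = NULL) {
  nt <- dim(magnitude)[4]
  d3 <- dim(magnitude)[1:3]
  tmag <- rowMeans(matrix(magnitude, prod(d3), nt))
  speed <- sqrt(field$vx^2 + field$vy^2 + field$vz^2)
  sp <- matrix(speed, prod(d3), nt)
  mu <- rowMeans(sp)
  sdv <- sqrt(pmax(0, rowMeans(sp^2) - mu^2) * nt / (nt - 1))
  mask <- tmag >= stats::quantile(tmag, mag_quantile) & sdv < std_threshold_mms
  mask <- array(mask, d3)
  if (!is.null(exclude_mask)) mask <- mask & !exclude_mask
  if (!any(mask)) warning("static-tissue mask is empty")
  mask
}

#' Correct spatially smooth phase offsets (eddy currents, Maxwell terms)
#'
#' Fits, per velocity component, a polynomial of degree `order` in world
#' coordinates (x, y, z) to the time-averaged velocity over static tissue by
#' least squares, and subtracts the fitted surface from every frame. Phase
#' offsets are modelled as temporally static, so the time-averaged fit is
#' used. With an empty static mask the field is returned unchanged with a
#' warning; a rank-deficient first-order fit falls back to order 0.
#'
#' @param field a [velocity_field].
#' @param static_mask 3D logical array from [detect_static_tissue()].
#' @param order polynomial order, 0 (constant) or 1 (linear).
#' @return The corrected [velocity_field], with the fitted coefficients in
#'   attribute `eddy_fit` (3 x 4 matrix, c0/cx/cy/cz per component).
#' @export
correct_eddy_currents <- function(field, static_mask, order = 1) {
  stopifnot(order %in% c(0, 1))
  d3 <- dim(field$vx)[1:3]
  if (!any(static_mask)) {
    warning("empty static-tissue mask; skipping eddy-current correction")
    attr(field, "eddy_fit") <- matrix(0, 3, 4)
    return(field)
  }
  idx <- which(static_mask)
  W <- voxel_world_coords(idx, d3, field$spacing_mm)
  X <- if (order == 1) cbind(1, W) else cbind(rep(1, length(idx)))
  if (order == 1 && qr(X)$rank < 4) {
    warning("rank-deficient eddy-current fit; falling back to order 0")
    return(correct_eddy_currents(field, static_mask, order = 0))
  }
  nt <- n_frames(field)
  coefs <- matrix(0, 3, 4)
  comps <- c("vx", "vy", "vz")
  xs <- axis_world(d3[1], field$spacing_mm[1])
  ys <- axis_world(d3[2], field$spacing_mm[2])
  zs <- axis_world(d3[3], field$spacing_mm[3])
  for (ci in 1:3) {
    v <- field[[comps[ci]]]
    tavg <- rowMeans(matrix(v, prod(d3), nt))
    beta <- qr.coef(qr(X), tavg[idx])
    cf <- c(beta, rep(0, 4 - length(beta)))
    coefs[ci, ] <- cf
    surf <- cf[1] +
      array(rep(cf[2] * xs, times = d3[2] * d3[3]), d3) +
      array(rep(rep(cf[3] * ys, each = d3[1]), times = d3[3]), d3) +
      array(rep(cf[4] * zs, each = d3[1] * d3[2]), d3)
    field[[comps[ci]]] <- v - array(rep(surf, nt), c(d3, nt))
  }
  attr(field, "eddy_fit") <- coefs
  field
}

#' Unwrap velocity aliasing (venc antialiasing)
#'
#' Sequential temporal phase unwrapping per voxel and component: the first
#' frame is trusted, and whenever the jump between consecutive frames exceeds
#' the venc (in mm/s) a multiple of 2 venc is added or subtracted to minimize
#' the jump. Unwrapped values may legitimately exceed the venc. Voxels whose
#' series required more than one wrap at a single step are counted in
#' attribute `multi_wrap_voxels` rather than silently accepted.
#'
#' @param field a [velocity_field].
#' @return The unwrapped [velocity_field].
#' @export
unwrap_aliasing <- function(field) {
  venc <- venc_mms(field)
  d <- dim(field$vx)
  nvox <- prod(d[1:3])
  nt <- d[4]
  multi <- 0L
  for (cc in c("vx", "vy", "vz")) {
    v <- matrix(field[[cc]], nvox, nt)
    if (nt > 1) {
      dj <- v[, 2:nt, drop = FALSE] - v[, 1:(nt - 1), drop = FALSE]
      k <- round(dj / (2 * venc))
      multi <- multi + sum(abs(k) > 1)
      dj <- dj - 2 * venc * k
      for (t in 2:nt) v[, t] <- v[, t - 1] + dj[, t - 1]
    }
    field[[cc]] <- array(v, d)
  }
  attr(field, "multi_wrap_voxels") <- multi
  field
}

#' Flag low-signal (noise) voxels
#'
#' Voxels whose time-averaged magnitude falls strictly below the given
#' quantile of the image histogram are flagged as noise and should be
#' excluded from downstream statistics.
#'
#' @param magnitude 4D magnitude array.
#' @param quantile noise quantile in (0, 1), default 0.1.
#' @return 3D logical array, `TRUE` = noise.
#' @export
noise_mask <- function(magnitude, quantile = 0.1) {
  stopifnot(quantile > 0, quantile < 1)
  d3 <- dim(magnitude)[1:3]
  tmag <- rowMeans(matrix(magnitude, prod(d3), dim(magnitude)[4]))
  array(tmag < stats::quantile(tmag, quantile), d3)
}

#' Run the full classical preprocessing stack
#'
#' Applies, in order: velocity antialiasing ([unwrap_aliasing()]),
#' static-tissue detection ([detect_static_tissue()]), eddy-current /
#' phase-offset correction ([correct_eddy_currents()]) and noise masking
#' ([noise_mask()]). Unwrapping runs first because the phase offsets are
#' temporally static and do not disturb the temporal jumps it corrects.
#'
#' @param ds a [flow_dataset()].
#' @param eddy_order polynomial order for the offset fit (0 or 1).
#' @param mag_quantile,std_threshold_mms passed to [detect_static_tissue()].
#' @param noise_quantile passed to [noise_mask()].
#' @return The dataset with corrected `field` and additional elements
#'   `static_mask`, `noise` and `eddy_fit`.
#' @export
preprocess_flow <- function(ds, eddy_order = 1, mag_quantile = 0.6,
                            std_threshold_mms = 20, noise_quantile = 0.1) {
  field <- unwrap_aliasing(ds$field)
  stat <- detect_static_tissue(ds$magnitude, field, mag_quantile,
                               std_threshold_mms, exclude_mask = ds$mask)
  field <- correct_eddy_currents(field, stat, order = eddy_order)
  ds$field <- field
  ds$static_mask <- stat
  ds$noise <- noise_mask(ds$magnitude, noise_quantile)
  ds$eddy_fit <- attr(field, "eddy_fit")
  ds
}
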