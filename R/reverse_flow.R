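#' Project voxel velocities onto their analysis-plane normals
#'
#' For every mask voxel i assigned to plane k, computes the signed
#' along-track velocity \eqn{s_i(t) = v_i(t) \cdot \hat n_k} (mm/s), positive
#' away from the aortic valve (forward) and negative towards it (reverse).
#'
#' @param field a [velocity_field].
#' @param assignment an `assignment_map` from [assign_voxels()].
#' @param planes a `plane_set` from [build_planes()].
#' @return An object of class `along_track`: list with `s` (n_voxels x
#'   n_frames matrix, mm/s), `voxels` (linear indices), `dim` (grid shape),
#'   `spacing_mm`, `dt_ms`.
#' @export
project_velocities <- function(field, assignment, planes) {
  idx <- which(assignment > 0)
  nrm <- planes$normals[assignment[idx], , drop = FALSE]
  s <- component_matrix(field$vx, idx) * nrm[, 1] +
    component_matrix(field$vy, idx) * nrm[, 2] +
    component_matrix(field$vz, idx) * nrm[, 3]
  structure(list(s = s, voxels = idx, dim = dim(field$vx)[1:3],
                 spacing_mm = field$spacing_mm, dt_ms = field$dt_ms),
            class = "along_track")
}

#' Mean net-flow curve over the segmentation
#'
#' \eqn{Q(t)}: the mean over all segmented voxels of the along-track velocity
#' times the voxel face area (mm^3/s). Used to locate peak systole and end
#' systole for the whole aorta.
#'
#' @param at an `along_track` from [project_velocities()].
#' @param voxels optional subset of linear voxel indices to average over
#'   (e.g. the ascending aorta only); default all projected voxels.
#' @return Numeric vector, one value per frame, mm^3/s.
#' @export
net_flow_curve <- function(at, voxels = NULL) {
  s <- at$s
  if (!is.null(voxels)) {
    keep <- at$voxels %in% voxels
    if (!any(keep)) stop("empty voxel subset for the net flow curve")
    s <- s[keep, , drop = FALSE]
  }
  if (nrow(s) == 0) stop("empty mask: cannot compute the net flow curve")
  colMeans(s) * voxel_face_area(at$spacing_mm)
}

#' Detect end systole from the mean net-flow curve
#'
#' Lightly smooths Q with a centred moving average of width 3, finds peak
#' systole (earliest maximum) and returns the first frame after the peak at
#' which the discrete second difference
#' \eqn{\Delta^2 Q(k) = Q(k+1) - 2Q(k) + Q(k-1)} changes sign from negative
#' to non-negative -- the discrete inflection point. If no sign change exists
#' after the peak, the frame of the post-peak minimum is returned with a
#' warning. The returned index (1-based) is the first diastolic frame:
#' systole spans frames `1:(k_es - 1)`.
#'
#' @param Q numeric net-flow curve (>= 5 frames, interior maximum).
#' @param smooth apply the width-3 moving average first (default `TRUE`).
#' @return Integer end-systole frame index.
#' @export
detect_end_systole <- function(Q, smooth = TRUE) {
  n <- length(Q)
  if (n < 5) stop("need at least 5 frames to detect end systole")
  Qs <- if (smooth) moving_average3(Q) else Q
  k_peak <- which.max(Qs)                      # earliest on ties
  if (k_peak >= n - 1)
    stop("timing error: peak net flow at the final frames; cannot split phases")
  d2 <- c(NA, Qs[3:n] - 2 * Qs[2:(n - 1)] + Qs[1:(n - 2)], NA)
  prev_neg <- FALSE
  for (k in seq(min(k_peak + 1, n - 1), n - 1)) {
    if (is.na(d2[k])) next
    if (prev_neg && d2[k] >= 0) return(as.integer(k))
    prev_neg <- d2[k] < 0
  }
  warning("no inflection after peak systole; using the post-peak minimum")
  as.integer(k_peak + which.min(Qs[(k_peak + 1):n]))
}

#' Truncate the cardiac cycle to the common acquisition window
#'
#' Keeps only the frames fully contained in the first `window_ms` of the
#' cardiac cycle: \eqn{n_{inc} = \min(n_{frames}, \lfloor window /
#' \Delta t \rfloor)}. This mirrors restricting all subjects to the shortest
#' commonly acquired RR interval (600 ms).
#'
#' @param n_frames acquired frame count.
#' @param dt_ms temporal resolution, ms.
#' @param window_ms common window, default 600 ms.
#' @return List with `n_inc`, `dt_ms`, `window_ms`. Errors if fewer than 5
#'   frames remain.
#' @export
truncate_window <- function(n_frames, dt_ms, window_ms = 600) {
  stopifnot_scalar(dt_ms, "dt_ms")
  n_inc <- min(n_frames, floor(window_ms / dt_ms))
  if (n_inc < 5)
    stop("window too coarse: fewer than 5 frames in the common window")
  list(n_inc = as.integer(n_inc), dt_ms = dt_ms, window_ms = window_ms)
}

#' Cardiac window with end-systole split
#'
#' @param k_es end-systole frame (1-based first diastolic frame).
#' @param n_inc included frame count.
#' @param dt_ms temporal resolution, ms.
#' @return An object of class `cardiac_window`.
#' @export
cardiac_window <- function(k_es, n_inc, dt_ms) {
  if (!(k_es > 1 && k_es <= n_inc))
    stop("invalid cardiac window: need 1 < k_es <= n_inc")
  structure(list(k_es = as.integer(k_es), n_inc = as.integer(n_inc),
                 dt_ms = dt_ms),
            class = "cardiac_window")
}

#' Integrate per-voxel forward and reverse flow
#'
#' For each voxel, integrates the positive (forward) and negative (reverse)
#' parts of the along-track velocity over the systolic window (frames
#' `1:(k_es - 1)`), the diastolic window (frames `k_es:n_inc`) and the whole
#' included cycle: \eqn{R = \sum_t \max(0, -s_i(t))\, a\, \Delta t}, in mL
#' per window per voxel (voxel face area a, 1 mm^2 on the isotropic grid).
#' Whole-cycle maps are the elementwise sum of the two windows.
#'
#' @param at an `along_track` from [project_velocities()].
#' @param window a `cardiac_window`.
#' @return Object of class `reverse_flow_map`: list with per-voxel vectors
#'   `reverse_systolic`, `reverse_diastolic`, `reverse_whole`,
#'   `forward_systolic`, `forward_diastolic`, `forward_whole` (mL), plus
#'   `voxels`, `dim`, `window`.
#' @export
integrate_flow <- function(at, window) {
  stopifnot(inherits(window, "cardiac_window"))
  a <- voxel_face_area(at$spacing_mm)
  dt_s <- at$dt_ms / 1000
  scale <- a * dt_s / 1000                       # mm^3 -> mL
  sys_f <- seq_len(window$k_es - 1)
  dia_f <- seq(window$k_es, window$n_inc)
  s <- at$s
  rev_part <- pmax(-s, 0)
  fwd_part <- pmax(s, 0)
  sum_over <- function(m, frames)
    rowSums(m[, frames, drop = FALSE]) * scale
  out <- list(
    reverse_systolic = sum_over(rev_part, sys_f),
    reverse_diastolic = sum_over(rev_part, dia_f),
    forward_systolic = sum_over(fwd_part, sys_f),
    forward_diastolic = sum_over(fwd_part, dia_f))
  out$reverse_whole <- out$reverse_systolic + out$reverse_diastolic
  out$forward_whole <- out$forward_systolic + out$forward_diastolic
  structure(c(out, list(voxels = at$voxels, dim = at$dim, window = window,
                        spacing_mm = at$spacing_mm)),
            class = "reverse_flow_map")
}

#' Render one per-voxel map as a 3D volume
#'
#' @param rfmap a `reverse_flow_map`.
#' @param which one of `"reverse_systolic"`, `"reverse_diastolic"`,
#'   `"reverse_whole"`, `"forward_systolic"`, `"forward_diastolic"`,
#'   `"forward_whole"`.
#' @return 3D numeric array, `NA` outside the segmentation.
#' @export
map_volume <- function(rfmap, which = "reverse_systolic") {
  stopifnot(which %in% c("reverse_systolic", "reverse_diastolic",
                         "reverse_whole", "forward_systolic",
                         "forward_diastolic", "forward_whole"))
  vol <- array(NA_real_, rfmap$dim)
  vol[rfmap$voxels] <- rfmap[[which]]
  vol
}

#' Per-segment mean and SD of a flow map
#'
#' Arithmetic mean and SD of the per-voxel values over each aortic segment
#' (AAo, arch, DAo), for every window and flow direction. Empty segments are
#' reported as missing (`NA`), never as zero.
#'
#' @param rfmap a `reverse_flow_map`.
#' @param labels a `segment_labels` array from [label_segments()].
#' @return Data frame with columns `segment`, `direction`, `window`,
#'   `mean_mL`, `sd_mL`, `n_voxels`.
#' @export
segment_means <- function(rfmap, labels) {
  lab <- labels[rfmap$voxels]
  levs <- attr(labels, "levels")
  maps <- expand.grid(direction = c("reverse", "forward"),
                      window = c("systolic", "diastolic", "whole"),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (si in seq_along(levs)) {
    in_seg <- lab == si
    for (r in seq_len(nrow(maps))) {
      key <- paste(maps$direction[r], maps$window[r], sep = "_")
      vals <- rfmap[[key]][in_seg]
      rows[[length(rows) + 1]] <- data.frame(
        segment = levs[si], direction = maps$direction[r],
        window = maps$window[r],
        mean_mL = if (length(vals)) mean(vals) else NA_real_,
        sd_mL = if (length(vals) > 1) stats::sd(vals) else NA_real_,
        n_voxels = length(vals), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
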