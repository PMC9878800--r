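#' Specification of a synthetic candy-cane aorta phantom
#'
#' Parameterizes a curved-tube ("candy-cane") aorta phantom: a straight
#' ascending limb, a semicircular arch and a straight descending limb, carrying
#' a pulsatile axial velocity field with optional reverse-flow components and
#' injectable acquisition artifacts. All stochastic draws derive from the
#' single integer `seed`, so identical specs give bit-identical data.
#'
#' The forward waveform is a raised-cosine ejection
#' \eqn{U(t) = P/2\,(1 - \cos(2\pi t / T_{es}))} for \eqn{t < T_{es}} and zero
#' afterwards, sampled at frame times \eqn{t_k = (k-1)\,\Delta t}. Two reverse
#' components can be superimposed on the axial velocity:
#' \itemize{
#'   \item a near-wall retrograde ring (stenosis-like systolic reversal):
#'     \eqn{-A_{ring}} for radii \eqn{\rho/R \ge \rho_0} during
#'     `reverse_ring$frame_range`;
#'   \item a uniform regurgitant plug (regurgitation-like diastolic reversal):
#'     \eqn{-A_{reg}} across the whole lumen during `regurgitant$frame_range`.
#' }
#' Frame ranges are 1-based inclusive `c(first, last)`.
#'
#' @param grid_shape integer triple, grid size in voxels.
#' @param spacing_mm positive triple, voxel spacing in mm.
#' @param n_frames number of cardiac frames (>= 8).
#' @param dt_ms temporal resolution in ms.
#' @param venc_cms velocity-encoding limit in cm/s.
#' @param tube_radius_mm lumen radius.
#' @param ascending_len_mm,arch_radius_mm,descending_len_mm geometry of the
#'   straight-semicircle-straight centerline.
#' @param peak_velocity_mms systolic peak of the forward waveform, mm/s.
#' @param t_end_systole_ms duration of the raised-cosine ejection, ms.
#' @param profile radial velocity profile, `"parabolic"` (default,
#'   \eqn{U(t)(1-(\rho/R)^2)}) or `"plug"`.
#' @param reverse_ring list with `inner_fraction` (\eqn{\rho_0 \in [0,1)}),
#'   `amplitude_mms` (>= 0) and `frame_range` (default: early-systolic
#'   frames `c(3, min(6, n_frames - 1))`).
#' @param regurgitant list with `amplitude_mms` (>= 0) and `frame_range`
#'   (default: the last six frames, `c(max(2, n_frames - 5), n_frames)`).
#' @param noise_sigma_mms i.i.d. Gaussian noise SD added per component, mm/s.
#' @param eddy_coeffs 3 x 4 matrix of per-component linear phase-offset
#'   coefficients (c0, cx, cy, cz) in mm/s and mm/s per mm; rows = x/y/z
#'   velocity component.
#' @param alias_enabled if `TRUE`, stored velocities wrap into (-venc, venc].
#' @param seed integer RNG seed for all stochastic draws.
#' @return An object of class `phantom_spec`.
#' @seealso [synthesize_phantom()], [generate_phantom()],
#'   [analytic_reverse_flow()]
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 96),
                         spacing_mm = c(1, 1, 1),
                         n_frames = 15,
                         dt_ms = 40,
                         venc_cms = 150,
                         tube_radius_mm = 9,
                         ascending_len_mm = 40,
                         arch_radius_mm = 16,
                         descending_len_mm = 50,
                         peak_velocity_mms = 1000,
                         t_end_systole_ms = 360,
                         profile = c("parabolic", "plug"),
                         reverse_ring = list(inner_fraction = 0.6,
                                             amplitude_mms = 0,
                                             frame_range = NULL),
                         regurgitant = list(amplitude_mms = 0,
                                            frame_range = NULL),
                         noise_sigma_mms = 0,
                         eddy_coeffs = matrix(0, 3, 4),
                         alias_enabled = FALSE,
                         seed = 1L) {
  profile <- match.arg(profile)
  # default reverse windows: ring in early systole, regurgitation in the last
  # frames (diastole), scaled to the frame count
  if (is.null(reverse_ring$inner_fraction)) reverse_ring$inner_fraction <- 0.6
  if (is.null(reverse_ring$frame_range))
    reverse_ring$frame_range <- c(3, min(6, n_frames - 1))
  if (is.null(regurgitant$frame_range))
    regurgitant$frame_range <- c(max(2, n_frames - 5), n_frames)
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    n_frames = as.integer(n_frames), dt_ms = dt_ms, venc_cms = venc_cms,
    tube_radius_mm = tube_radius_mm, ascending_len_mm = ascending_len_mm,
    arch_radius_mm = arch_radius_mm, descending_len_mm = descending_len_mm,
    peak_velocity_mms = peak_velocity_mms, t_end_systole_ms = t_end_systole_ms,
    profile = profile, reverse_ring = reverse_ring, regurgitant = regurgitant,
    noise_sigma_mms = noise_sigma_mms, eddy_coeffs = eddy_coeffs,
    alias_enabled = isTRUE(alias_enabled), seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3 || any(grid_shape < 8))
      stop("grid_shape must be a triple of at least 8 voxels", call. = FALSE)
    if (any(spacing_mm <= 0)) stop("spacing must be positive", call. = FALSE)
    if (n_frames < 8) stop("n_frames must be >= 8", call. = FALSE)
    for (nm in c("dt_ms", "venc_cms", "tube_radius_mm", "ascending_len_mm",
                 "arch_radius_mm", "descending_len_mm", "t_end_systole_ms"))
      stopifnot_scalar(spec[[nm]], nm)
    for (nm in c("peak_velocity_mms", "noise_sigma_mms"))
      stopifnot_scalar(spec[[nm]], nm, positive = FALSE)
    if (peak_velocity_mms < 0 || noise_sigma_mms < 0)
      stop("amplitudes and noise must be non-negative", call. = FALSE)
    if (reverse_ring$inner_fraction < 0 || reverse_ring$inner_fraction >= 1)
      stop("reverse_ring$inner_fraction must lie in [0, 1)", call. = FALSE)
    if (reverse_ring$amplitude_mms < 0 || regurgitant$amplitude_mms < 0)
      stop("reverse amplitudes must be >= 0", call. = FALSE)
    for (fr in list(reverse_ring$frame_range, regurgitant$frame_range)) {
      if (length(fr) != 2 || fr[1] > fr[2] || fr[1] < 1 || fr[2] > n_frames)
        stop("frame_range must be 1-based inclusive within 1..n_frames",
             call. = FALSE)
    }
    if (!identical(dim(eddy_coeffs), c(3L, 4L)))
      stop("eddy_coeffs must be a 3 x 4 matrix", call. = FALSE)
  })
  candycane_geometry(spec)  # errors if the tube does not fit the grid
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  geo <- candycane_geometry(x)
  cat(sprintf(
    paste0("<phantom_spec> %d x %d x %d voxels @ %s mm, %d frames @ %.0f ms\n",
           "  tube radius %.1f mm, arc length %.1f mm, venc %.0f cm/s\n",
           "  peak %.0f mm/s (%s), ring %.0f mm/s, regurgitant %.0f mm/s, ",
           "noise %.0f mm/s\n"),
    x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
    paste(format(x$spacing_mm, digits = 3), collapse = "x"),
    x$n_frames, x$dt_ms, x$tube_radius_mm, geo$total_len, x$venc_cms,
    x$peak_velocity_mms, x$profile, x$reverse_ring$amplitude_mms,
    x$regurgitant$amplitude_mms, x$noise_sigma_mms))
  invisible(x)
}

# anchor points and segment breaks of the candy-cane centerline, world mm.
# The cane lies in the x-z plane: ascending limb along +z, semicircular arch,
# descending limb along -z. Errors if the tube (with a 2-voxel margin) does
# not fit the grid.
candycane_geometry <- function(spec) {
  La <- spec$ascending_len_mm
  Ra <- spec$arch_radius_mm
  Ld <- spec$descending_len_mm
  r <- spec$tube_radius_mm
  ext <- (spec$grid_shape - 1) * spec$spacing_mm  # world extent per axis

  width <- 2 * Ra + 2 * r
  zlow_rel <- min(0, La - Ld) - r
  zhigh_rel <- La + Ra + r
  height <- zhigh_rel - zlow_rel
  margin <- 2 * spec$spacing_mm

  if (width + 2 * margin[1] > ext[1] || 2 * r + 2 * margin[2] > ext[2] ||
      height + 2 * margin[3] > ext[3])
    stop("phantom geometry exceeds grid bounds (needs a 2-voxel margin)",
         call. = FALSE)

  x0 <- (ext[1] - width) / 2 + r          # ascending limb x position
  y0 <- ext[2] / 2
  z0 <- (ext[3] - height) / 2 - zlow_rel  # ascending limb base z
  list(origin = c(x0, y0, z0), La = La, Ra = Ra, Ld = Ld,
       total_len = La + pi * Ra + Ld,
       s_arch = La, s_desc = La + pi * Ra)
}

# analytic centerline point + unit tangent at arc lengths s (vector), world mm
candycane_point <- function(geo, s) {
  n <- length(s)
  p <- matrix(0, n, 3)
  tg <- matrix(0, n, 3)
  x0 <- geo$origin[1]; y0 <- geo$origin[2]; z0 <- geo$origin[3]
  p[, 2] <- y0

  asc <- s <= geo$s_arch
  arch <- s > geo$s_arch & s <= geo$s_desc
  des <- s > geo$s_desc

  p[asc, 1] <- x0
  p[asc, 3] <- z0 + s[asc]
  tg[asc, 3] <- 1

  th <- (s[arch] - geo$s_arch) / geo$Ra          # 0..pi over the arch
  cx <- x0 + geo$Ra                               # arch centre
  cz <- z0 + geo$La
  p[arch, 1] <- cx - geo$Ra * cos(th)
  p[arch, 3] <- cz + geo$Ra * sin(th)
  tg[arch, 1] <- sin(th)
  tg[arch, 3] <- cos(th)

  sd <- s[des] - geo$s_desc
  p[des, 1] <- x0 + 2 * geo$Ra
  p[des, 3] <- z0 + geo$La - sd
  tg[des, 3] <- -1
  list(points = p, tangents = tg)
}

#' Analytic centerline of the candy-cane phantom
#'
#' Builds the exact straight-semicircle-straight centerline of the phantom at
#' 1 mm arc-length spacing, oriented from the valve end towards the descending
#' end, with exact unit tangents.
#'
#' @param spec a [phantom_spec()].
#' @return A `centerline` object (see [new_centerline()]).
#' @export
build_candycane_centerline <- function(spec) {
  geo <- candycane_geometry(spec)
  s <- seq(0, floor(geo$total_len), by = 1)
  pt <- candycane_point(geo, s)
  new_centerline(pt$points, pt$tangents, s)
}

# waveform sampled at frame times t_k = (k-1) dt; returns n_frames vector, mm/s
forward_waveform <- function(spec) {
  t <- (seq_len(spec$n_frames) - 1) * spec$dt_ms
  u <- ifelse(t < spec$t_end_systole_ms,
              spec$peak_velocity_mms / 2 *
                (1 - cos(2 * pi * t / spec$t_end_systole_ms)),
              0)
  u
}

frame_flags <- function(frame_range, n_frames) {
  f <- rep(FALSE, n_frames)
  f[frame_range[1]:frame_range[2]] <- TRUE
  f
}

radial_profile <- function(x, profile) {
  if (profile == "parabolic") 1 - pmin(x, 1)^2 else rep(1, length(x))
}

# ---------------------------------------------------------------------------
# closed-form cross-section means
# ---------------------------------------------------------------------------

# Area-averaged reverse velocity contribution of the radial zone
# x in [xa, xb] (x = rho/R) with forward amplitude U and reverse offset A,
# relative to the FULL disk (divide by total area pi R^2 == x-measure 1).
# Parabolic: u(x) = U (1 - x^2) - A, reverse where u < 0;
#   2 * integral x (A - U(1-x^2)) dx has antiderivative (A-U) x^2 + U x^4 / 2.
# Plug: u = U - A uniform over the zone.
zone_reverse_mean <- function(U, A, xa, xb, profile) {
  if (A <= 0) return(0)
  if (profile == "plug") return(max(0, A - U) * (xb^2 - xa^2))
  if (U <= 0) return(A * (xb^2 - xa^2))
  if (A >= U) {
    xlo <- xa
  } else {
    xc <- sqrt(1 - A / U)
    if (xc >= xb) return(0)
    xlo <- max(xa, xc)
  }
  F <- function(x) (A - U) * x^2 + U * x^4 / 2
  F(xb) - F(xlo)
}

# per-frame cross-section mean reverse velocity (mm/s), closed form
frame_reverse_mean <- function(spec) {
  U <- forward_waveform(spec)
  ring_on <- frame_flags(spec$reverse_ring$frame_range, spec$n_frames)
  reg_on <- frame_flags(spec$regurgitant$frame_range, spec$n_frames)
  rho0 <- spec$reverse_ring$inner_fraction
  vapply(seq_len(spec$n_frames), function(k) {
    A_in <- if (reg_on[k]) spec$regurgitant$amplitude_mms else 0
    A_out <- A_in + if (ring_on[k]) spec$reverse_ring$amplitude_mms else 0
    zone_reverse_mean(U[k], A_in, 0, rho0, spec$profile) +
      zone_reverse_mean(U[k], A_out, rho0, 1, spec$profile)
  }, numeric(1))
}

# analytic cross-section mean net (signed) velocity per frame, mm/s
analytic_net_curve <- function(spec) {
  U <- forward_waveform(spec)
  pmean <- if (spec$profile == "parabolic") 0.5 else 1
  ring_on <- frame_flags(spec$reverse_ring$frame_range, spec$n_frames)
  reg_on <- frame_flags(spec$regurgitant$frame_range, spec$n_frames)
  rho0 <- spec$reverse_ring$inner_fraction
  U * pmean -
    ring_on * spec$reverse_ring$amplitude_mms * (1 - rho0^2) -
    reg_on * spec$regurgitant$amplitude_mms
}

#' Analytic ground-truth reverse flow of the phantom
#'
#' Closed-form per-voxel reverse flow expected over the lumen cross-section,
#' \eqn{\sum_t \max(0, -u(\rho, t))\, a\, \Delta t} averaged over the disk,
#' reported per segment (AAo, arch, DAo) and cardiac window (systolic,
#' diastolic, whole cycle) in mL per window per voxel. Because the phantom's
#' flow components are uniform along the tube, all three segments share the
#' same expectation. The systole/diastole split uses the ground-truth
#' end-systole frame: the same discrete inflection rule as
#' [detect_end_systole()], applied to the analytic noise-free mean net-flow
#' curve. Frames beyond the common acquisition window (600 ms by default) are
#' excluded, mirroring the analysis pipeline.
#'
#' @param spec a [phantom_spec()].
#' @param window_ms common cardiac window in ms (default 600).
#' @return A data frame with columns `segment`, `window`, `mean_mL`, with the
#'   ground-truth end-systole frame (`k_es`, 1-based first diastolic frame)
#'   and included frame count (`n_inc`) as attributes.
#' @export
analytic_reverse_flow <- function(spec, window_ms = 600) {
  rv <- frame_reverse_mean(spec)                # mm/s per frame
  n_inc <- min(spec$n_frames, floor(window_ms / spec$dt_ms))
  k_es <- detect_end_systole(analytic_net_curve(spec)[seq_len(n_inc)])
  a <- voxel_face_area(spec$spacing_mm)
  dt_s <- spec$dt_ms / 1000
  per_frame_mL <- rv * a * dt_s / 1000          # mm^3 -> mL
  sys <- sum(per_frame_mL[seq_len(k_es - 1)])
  dia <- sum(per_frame_mL[k_es:n_inc])
  out <- data.frame(
    segment = rep(c("AAo", "Arch", "DAo"), each = 3),
    window = rep(c("systolic", "diastolic", "whole"), 3),
    mean_mL = rep(c(sys, dia, sys + dia), 3),
    stringsAsFactors = FALSE)
  attr(out, "k_es") <- k_es
  attr(out, "n_inc") <- n_inc
  out
}

# ---------------------------------------------------------------------------
# synthesis
# ---------------------------------------------------------------------------

#' Synthesize a noise- and artifact-free phantom dataset
#'
#' Builds the candy-cane lumen on the voxel grid and fills it with the
#' prescribed axial velocity along the local centerline tangent. Voxels within
#' `tube_radius_mm` of the centerline form the lumen; a hollow static-tissue
#' shell (2-3 radii from the centerline) carries high magnitude and zero true
#' velocity, giving the eddy-current fit realistic support. Ground truth
#' (per-voxel along-track series, segment expectations, end-systole frame) is
#' recorded from the analytic construction before any artifact is applied.
#'
#' @param spec a [phantom_spec()].
#' @return A [flow_dataset()] whose `ground_truth` holds: `u` (lumen voxels x
#'   frames true along-track velocity, mm/s), `voxels` (their linear indices),
#'   `rho` (radial distance, mm), `assignment` (true nearest centerline point
#'   per lumen voxel), `tangents` (per-lumen-voxel unit flow direction),
#'   `shell` (static-tissue shell mask), `k_es`, `segments` (the
#'   [analytic_reverse_flow()] table), and `centerline` (the analytic one).
#' @export
synthesize_phantom <- function(spec) {
  geo <- candycane_geometry(spec)
  cl <- build_candycane_centerline(spec)
  d3 <- spec$grid_shape
  nvol <- prod(d3)
  nt <- spec$n_frames

  # nearest centerline point and distance for every grid voxel
  xs <- axis_world(d3[1], spec$spacing_mm[1])
  ys <- axis_world(d3[2], spec$spacing_mm[2])
  zs <- axis_world(d3[3], spec$spacing_mm[3])
  X <- array(rep(xs, times = d3[2] * d3[3]), d3)
  Y <- array(rep(rep(ys, each = d3[1]), times = d3[3]), d3)
  Z <- array(rep(zs, each = d3[1] * d3[2]), d3)
  nn <- nearest_point_index(cbind(as.vector(X), as.vector(Y), as.vector(Z)),
                            cl$points)
  best_d <- sqrt(nn$d2)
  r <- spec$tube_radius_mm
  mask <- array(best_d <= r, d3)
  shell <- array(best_d >= 2 * r & best_d <= 3 * r, d3)

  lumen <- which(mask)
  rho <- best_d[lumen]
  assign_true <- nn$index[lumen]
  tg <- cl$tangents[assign_true, , drop = FALSE]

  # true along-track velocity series for lumen voxels
  U <- forward_waveform(spec)
  ring_on <- frame_flags(spec$reverse_ring$frame_range, nt)
  reg_on <- frame_flags(spec$regurgitant$frame_range, nt)
  x <- pmin(rho / r, 1)
  u <- outer(radial_profile(x, spec$profile), U)
  if (spec$reverse_ring$amplitude_mms > 0) {
    in_ring <- x >= spec$reverse_ring$inner_fraction
    u[in_ring, ring_on] <- u[in_ring, ring_on] - spec$reverse_ring$amplitude_mms
  }
  if (spec$regurgitant$amplitude_mms > 0)
    u[, reg_on] <- u[, reg_on] - spec$regurgitant$amplitude_mms

  vx <- array(0, c(d3, nt)); vy <- vx; vz <- vx
  for (t in seq_len(nt)) {
    off <- (t - 1) * nvol
    vx[lumen + off] <- u[, t] * tg[, 1]
    vy[lumen + off] <- u[, t] * tg[, 2]
    vz[lumen + off] <- u[, t] * tg[, 3]
  }

  mag3 <- array(50, d3)
  mag3[shell] <- 800
  mag3[mask] <- 1000
  magnitude <- array(rep(mag3, nt), c(d3, nt))

  field <- velocity_field(vx, vy, vz, spec$spacing_mm, spec$dt_ms,
                          spec$venc_cms)
  segments <- analytic_reverse_flow(spec)
  gt <- list(u = u, voxels = lumen, rho = rho, assignment = assign_true,
             tangents = tg, shell = shell,
             k_es = attr(segments, "k_es"),
             n_inc = attr(segments, "n_inc"),
             segments = segments, centerline = cl,
             net_curve_mms = analytic_net_curve(spec))
  flow_dataset(field, magnitude, mask, spec = spec, ground_truth = gt)
}

# nearest point in `pts` (m x 3) for each row of `V` (n x 3); strict-min
# update keeps the LOWEST index on exact ties. Loops over the (few hundred)
# points so the n-sized arrays stay vectorized.
nearest_point_index <- function(V, pts) {
  n <- nrow(V)
  best_d2 <- rep(Inf, n)
  best_idx <- rep(1L, n)
  for (k in seq_len(nrow(pts))) {
    d2 <- (V[, 1] - pts[k, 1])^2 + (V[, 2] - pts[k, 2])^2 +
      (V[, 3] - pts[k, 3])^2
    better <- d2 < best_d2
    best_d2[better] <- d2[better]
    best_idx[better] <- k
  }
  list(index = best_idx, d2 = best_d2)
}

# wrap velocities into (-venc, venc]: v -> ((v + venc) mod 2 venc) - venc
wrap_velocity <- function(v, venc) ((v + venc) %% (2 * venc)) - venc

#' Inject acquisition artifacts into a velocity field
#'
#' Applies, in order: a spatially linear phase offset
#' \eqn{c_0 + c_x x + c_y y + c_z z} per velocity component (everywhere,
#' static tissue included), i.i.d. Gaussian noise of SD `noise_sigma_mms`,
#' and -- if `alias_enabled` -- venc wrapping
#' \eqn{v \mapsto ((v + venc) \bmod 2\,venc) - venc}. The RNG is seeded from
#' `spec$seed` so the call is deterministic.
#'
#' @param field a [velocity_field].
#' @param spec the [phantom_spec()] carrying `eddy_coeffs`, `noise_sigma_mms`,
#'   `alias_enabled` and `seed`.
#' @return The corrupted [velocity_field].
#' @export
inject_artifacts <- function(field, spec) {
  d3 <- dim(field$vx)[1:3]
  nt <- n_frames(field)
  set.seed(spec$seed)
  comps <- c("vx", "vy", "vz")
  xs <- axis_world(d3[1], field$spacing_mm[1])
  ys <- axis_world(d3[2], field$spacing_mm[2])
  zs <- axis_world(d3[3], field$spacing_mm[3])
  venc <- venc_mms(field)
  for (ci in 1:3) {
    cf <- spec$eddy_coeffs[ci, ]
    v <- field[[comps[ci]]]
    if (any(cf != 0)) {
      off3 <- cf[1] +
        array(rep(cf[2] * xs, times = d3[2] * d3[3]), d3) +
        array(rep(rep(cf[3] * ys, each = d3[1]), times = d3[3]), d3) +
        array(rep(cf[4] * zs, each = d3[1] * d3[2]), d3)
      v <- v + array(rep(off3, nt), c(d3, nt))
    }
    if (spec$noise_sigma_mms > 0)
      v <- v + array(stats::rnorm(length(v), 0, spec$noise_sigma_mms), dim(v))
    if (spec$alias_enabled) v <- wrap_velocity(v, venc)
    field[[comps[ci]]] <- v
  }
  field
}

#' Generate a complete synthetic 4D flow dataset
#'
#' Convenience wrapper: [synthesize_phantom()] followed by
#' [inject_artifacts()]. Ground truth always reflects the artifact-free
#' construction.
#'
#' @inheritParams synthesize_phantom
#' @return A [flow_dataset()].
#' @export
generate_phantom <- function(spec) {
  ds <- synthesize_phantom(spec)
  ds$field <- inject_artifacts(ds$field, spec)
  ds
}

#' Default landmark arc lengths for the phantom
#'
#' Analysis-plane positions (mm of arc length from the valve end) marking the
#' sinotubular junction, the plane proximal to the first supra-aortic branch
#' (start of the arch), the plane distal to the left subclavian artery (end of
#' the arch) and the plane proximal to the celiac artery. The first and last
#' exclude the tube's end caps, mirroring the exclusion of the left
#' ventricular outflow tract and the distal descending aorta.
#'
#' @param spec a [phantom_spec()].
#' @return Named numeric vector `c(stj, branch, subclavian, celiac)`.
#' @export
phantom_landmarks <- function(spec) {
  geo <- candycane_geometry(spec)
  c(stj = min(10, geo$La / 2), branch = geo$s_arch,
    subclavian = geo$s_desc, celiac = geo$total_len - 6)
}

#' Voxel seeds at the phantom's centerline endpoints
#'
#' Returns the 1-based voxel index triples of the lumen voxels nearest the
#' valve end and the descending end of the true centerline, for seeding
#' [extract_centerline()].
#'
#' @param ds a phantom [flow_dataset()] with ground truth.
#' @return List with `valve` and `distal` integer voxel triples.
#' @export
phantom_seeds <- function(ds) {
  cl <- ds$ground_truth$centerline
  d <- dim(ds$mask)
  lum <- which(ds$mask)
  W <- voxel_world_coords(lum, d, ds$spec$spacing_mm)
  near <- function(p) {
    i <- which.min((W[, 1] - p[1])^2 + (W[, 2] - p[2])^2 + (W[, 3] - p[3])^2)
    as.integer(arrayInd(lum[i], d)[1, ])
  }
  list(valve = near(cl$points[1, ]),
       distal = near(cl$points[nrow(cl$points), ]))
}
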