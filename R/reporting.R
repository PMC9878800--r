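#' Mean-intensity projection of a flow map
#'
#' Averages a per-voxel 3D flow map along the sagittal axis over the
#' non-excluded segmentation voxels in each projection column, producing the
#' 2D mean-intensity-projection (MIP) reverse-flow map. Columns containing no
#' mask voxel are flagged empty (`NA`), never zero; the per-pixel count of
#' contributing voxels is recorded.
#'
#' @param rfmap a `reverse_flow_map`.
#' @param which map to project (see [map_volume()]).
#' @param labels optional `segment_labels`; when given, only voxels labelled
#'   AAo/arch/DAo contribute.
#' @param axis projection (sagittal) axis: 1, 2 or 3. There is no default
#'   guess -- the caller states the axis explicitly (for the phantom the cane
#'   lies in the x-z plane, so `axis = 2`).
#' @return Object of class `mip_image`: list with `values` (2D, mL per
#'   voxel, `NA` where empty), `counts` (2D integer) and `axis`.
#' @export
mip_sagittal <- function(rfmap, which = "reverse_systolic", labels = NULL,
                         axis = 2) {
  stopifnot(axis %in% 1:3)
  vol <- map_volume(rfmap, which)
  keep <- !is.na(vol)
  if (!is.null(labels)) keep <- keep & labels > 0
  vol[!keep] <- 0
  counts <- apply(keep, setdiff(1:3, axis), sum)
  sums <- apply(vol, setdiff(1:3, axis), sum)
  values <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  structure(list(values = values, counts = counts, axis = axis,
                 map = which),
            class = "mip_image")
}

#' @export
print.mip_image <- function(x, ...) {
  cat(sprintf("<mip_image> %s, %d x %d pixels (%d non-empty), axis %d\n",
              x$map, nrow(x$values), ncol(x$values), sum(x$counts > 0),
              x$axis))
  invisible(x)
}

#' Estimate total reverse flow through a circular 2D ROI
#'
#' Clinical-context estimate: assumes every voxel of a circular
#' cross-section of the given diameter (e.g. the mid-ascending aorta)
#' experiences the measured mean per-voxel systolic reverse flow, so the
#' total is \eqn{\pi (d/2)^2 \times \bar R} with the continuous circle area
#' counting 1 mm^2 voxels. Conventionally reported to 0.1 mL; the exact
#' value is returned so the quantity stays linear in its inputs.
#'
#' @param mean_per_voxel_mL mean per-voxel reverse flow, mL per cycle.
#' @param diameter_mm vessel diameter, mm (>= 0).
#' @return Total reverse flow estimate, mL.
#' @examples
#' round(estimate_plane_total(0.019, 42.8), 1)  # 27.3
#' @export
estimate_plane_total <- function(mean_per_voxel_mL, diameter_mm) {
  stopifnot(diameter_mm >= 0)
  pi * (diameter_mm / 2)^2 * mean_per_voxel_mL
}

#' Bland-Altman agreement between repeated measurements
#'
#' For paired observations (e.g. two observers measuring the same scans):
#' differences d = obs1 - obs2, bias = mean(d), limits of agreement
#' LOA = 1.96 x SD(d) (half-width), coefficient of variation
#' CoV = 100 x SD(d) / grand mean of all measurements, Pearson correlation
#' of the pairs, and a paired two-sided t-test of bias = 0.
#'
#' @param obs1,obs2 numeric vectors of paired measurements (>= 3 pairs).
#' @return Object of class `agreement`: list with `bias`, `loa`, `cov_pct`,
#'   `r`, `p_value`, `n`. CoV is `NA` when the grand mean is zero.
#' @export
bland_altman <- function(obs1, obs2) {
  stopifnot(length(obs1) == length(obs2))
  if (length(obs1) < 3) stop("need at least 3 pairs")
  d <- obs1 - obs2
  sdd <- stats::sd(d)
  gm <- mean(c(obs1, obs2))
  cov_pct <- if (abs(gm) < .Machine$double.eps^0.5) NA_real_ else
    100 * sdd / gm
  r <- suppressWarnings(stats::cor(obs1, obs2))
  p <- if (sdd <= .Machine$double.eps * (abs(mean(d)) + 1)) NA_real_ else
    stats::t.test(obs1, obs2, paired = TRUE)$p.value
  structure(list(bias = mean(d), loa = 1.96 * sdd, cov_pct = cov_pct,
                 r = r, p_value = p, n = length(obs1)),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf(
    "<agreement> n = %d pairs\n  bias %.3g, LOA (1.96 SD) %.3g, CoV %.2f%%, r = %.3f, p = %.3g\n",
    x$n, x$bias, x$loa, x$cov_pct, x$r, x$p_value))
  invisible(x)
}

#' Export a pipeline run to disk
#'
#' Writes, deterministically (no timestamps): per-segment statistics and the
#' centerline as CSV, the six per-voxel flow maps as NIfTI volumes, MIP maps
#' as PNG images on a shared colour scale (0 to the 99th percentile across
#' the systolic and diastolic reverse maps), and a JSON manifest echoing all
#' parameters.
#'
#' @param run a `revflow_run` from [reverse_flow_run()].
#' @param dir output directory (created if missing).
#' @param mip_axis sagittal axis for the MIP images.
#' @return Invisibly, the manifest list.
#' @export
export_results <- function(run, dir, mip_axis = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$segment_stats, file.path(dir, "segment_stats.csv"),
                   row.names = FALSE)
  cl <- run$centerline
  utils::write.csv(
    data.frame(index = seq_len(nrow(cl$points)),
               x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
               tx = cl$tangents[, 1], ty = cl$tangents[, 2],
               tz = cl$tangents[, 3], arc_length = cl$arc_length),
    file.path(dir, "centerline.csv"), row.names = FALSE)

  maps <- c("reverse_systolic", "reverse_diastolic", "reverse_whole",
            "forward_systolic", "forward_diastolic", "forward_whole")
  for (m in maps) {
    vol <- map_volume(run$maps, m)
    vol[is.na(vol)] <- 0
    write_nifti_volume(vol, run$maps$spacing_mm,
                       file.path(dir, paste0(m, ".nii.gz")))
  }

  mips <- lapply(c("reverse_systolic", "reverse_diastolic"), function(m)
    mip_sagittal(run$maps, m, labels = run$labels, axis = mip_axis))
  vmax <- stats::quantile(unlist(lapply(mips, function(m)
    m$values[!is.na(m$values)])), 0.99)
  for (i in seq_along(mips)) {
    img <- mips[[i]]$values
    scaled <- pmin(pmax(img / max(vmax, .Machine$double.eps), 0), 1)
    scaled[is.na(scaled)] <- 0
    png::writePNG(t(scaled)[rev(seq_len(ncol(scaled))), , drop = FALSE],
                  file.path(dir, paste0("mip_", mips[[i]]$map, ".png")))
  }

  manifest <- list(
    parameters = run$parameters,
    k_es = run$window$k_es, n_inc = run$window$n_inc,
    dt_ms = run$window$dt_ms,
    n_voxels = length(run$maps$voxels),
    color_scale_max_mL = as.numeric(vmax),
    files = c("segment_stats.csv", "centerline.csv",
              paste0(maps, ".nii.gz"),
              paste0("mip_", c("reverse_systolic", "reverse_diastolic"),
                     ".png")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
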