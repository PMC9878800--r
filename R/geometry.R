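#' Centerline container
#'
#' Ordered centerline points at (nominally) 1 mm arc-length spacing with unit
#' tangents, oriented from the aortic-valve end towards the descending end.
#'
#' @param points n x 3 matrix of world coordinates, mm.
#' @param tangents n x 3 matrix of unit tangent vectors.
#' @param arc_length cumulative arc length from the valve end, mm.
#' @return An object of class `centerline`.
#' @export
new_centerline <- function(points, tangents, arc_length) {
  stopifnot(nrow(points) == nrow(tangents),
            nrow(points) == length(arc_length))
  nrm <- sqrt(rowSums(tangents^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("tangents must be unit vectors")
  structure(list(points = points, tangents = tangents,
                 arc_length = as.numeric(arc_length)),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.1f mm\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

#' Resample a volume to isotropic resolution
#'
#' Resamples a 3D volume (or every frame/component of a 4D volume or
#' [velocity_field]) to an isotropic grid, preserving world coordinates
#' (voxel-centre convention, origin at the first voxel). Continuous data are
#' interpolated trilinearly -- which reproduces affine functions exactly --
#' and masks/labels by nearest neighbour.
#'
#' @param x 3D/4D numeric or logical array, or a [velocity_field].
#' @param spacing_mm source voxel spacing (taken from the field if `x` is
#'   one).
#' @param target_mm target isotropic spacing, default 1 mm.
#' @param method `"trilinear"` or `"nearest"`; default chosen by data type.
#' @return The resampled object; arrays gain a `spacing_mm` attribute.
#' @export
resample_isotropic <- function(x, spacing_mm = NULL, target_mm = 1.0,
                               method = NULL) {
  if (inherits(x, "velocity_field")) {
    out <- x
    for (cc in c("vx", "vy", "vz"))
      out[[cc]] <- resample_isotropic(x[[cc]], x$spacing_mm, target_mm,
                                      method = "trilinear")
    out$spacing_mm <- rep(target_mm, 3)
    return(out)
  }
  stopifnot(!is.null(spacing_mm))
  if (is.null(method))
    method <- if (is.logical(x) || is.integer(x)) "nearest" else "trilinear"
  d <- dim(x)
  if (length(d) == 4) {
    first <- resample_isotropic(x[, , , 1], spacing_mm, target_mm, method)
    out <- array(if (is.logical(x)) NA else 0, c(dim(first), d[4]))
    out[, , , 1] <- first
    for (t in seq_len(d[4])[-1])
      out[, , , t] <- resample_isotropic(x[, , , t], spacing_mm, target_mm,
                                         method)
    attr(out, "spacing_mm") <- rep(target_mm, 3)
    return(out)
  }
  stopifnot(length(d) == 3)
  new_n <- floor((d - 1) * spacing_mm / target_mm) + 1
  pos <- lapply(1:3, function(a) axis_world(new_n[a], target_mm) / spacing_mm[a])
  if (method == "nearest") {
    ix <- lapply(1:3, function(a) pmax(1, pmin(round(pos[[a]]) + 1, d[a])))
    out <- x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  } else {
    i0 <- lapply(1:3, function(a) pmax(1, pmin(floor(pos[[a]]) + 1, d[a] - 1)))
    fr <- lapply(1:3, function(a) pmin(pmax(pos[[a]] + 1 - i0[[a]], 0), 1))
    # separable trilinear interpolation, one axis at a time
    g <- x[i0[[1]], , , drop = FALSE] * (1 - fr[[1]]) +
      x[i0[[1]] + 1, , , drop = FALSE] * fr[[1]]
    g <- g[, i0[[2]], , drop = FALSE] * rep(1 - fr[[2]], each = new_n[1]) +
      g[, i0[[2]] + 1, , drop = FALSE] * rep(fr[[2]], each = new_n[1])
    out <- g[, , i0[[3]], drop = FALSE] *
      rep(1 - fr[[3]], each = new_n[1] * new_n[2]) +
      g[, , i0[[3]] + 1, drop = FALSE] *
      rep(fr[[3]], each = new_n[1] * new_n[2])
  }
  out <- array(out, new_n)
  attr(out, "spacing_mm") <- rep(target_mm, 3)
  out
}

#' Resample a whole flow dataset to isotropic resolution
#'
#' @param ds a [flow_dataset()].
#' @param target_mm target isotropic spacing in mm.
#' @return The resampled [flow_dataset()] (ground truth, if any, is dropped:
#'   it refers to the acquisition grid).
#' @export
resample_dataset <- function(ds, target_mm = 1.0) {
  sp <- ds$field$spacing_mm
  if (all(abs(sp - target_mm) < 1e-9)) return(ds)
  field <- resample_isotropic(ds$field, target_mm = target_mm)
  mag <- resample_isotropic(ds$magnitude, sp, target_mm, "trilinear")
  mask <- resample_isotropic(ds$mask, sp, target_mm, "nearest")
  flow_dataset(field, mag, array(as.logical(mask), dim(mask)), spec = ds$spec)
}

# city-block distance to background by iterative 6-connected erosion; array
# borders count as background. Distances in voxel steps.
distance_to_boundary <- function(mask) {
  d <- array(0, dim(mask))
  cur <- mask
  while (any(cur)) {
    d[cur] <- d[cur] + 1
    cur <- erode6(cur)
  }
  d
}

shift_array <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# 3^3 box blur; zero fill at borders. Used to smooth the integer erosion
# distance into a field with a well-defined ridge along the lumen axis.
box_blur3 <- function(a, passes = 1) {
  for (p in seq_len(passes)) {
    acc <- array(0, dim(a))
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
      acc <- acc + shift_array(a, dx, dy, dz, fill = 0)
    a <- acc / 27
  }
  a
}

erode6 <- function(mask) {
  out <- mask
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    out <- out & shift_array(mask, o[1], o[2], o[3], fill = FALSE)
  out
}

#' Extract a vessel centerline from a binary mask
#'
#' Finds the distance-transform-weighted shortest path between two seed
#' voxels through the mask (26-connected graph; step cost is the Euclidean
#' step length divided by the cubed distance-to-boundary, which pulls the
#' path onto the lumen axis), smooths it with a Gaussian kernel along arc
#' length, resamples it at 1 mm arc-length spacing, and computes unit
#' tangents by central differences. Tangents are oriented from `seed_valve`
#' towards `seed_distal`.
#'
#' @param mask 3D logical array (single connected lumen).
#' @param seed_valve,seed_distal integer voxel triples (1-based) at the valve
#'   and descending ends; must lie inside the mask.
#' @param spacing_mm voxel spacing of `mask`.
#' @param smooth_sigma_mm Gaussian smoothing bandwidth along the path, mm.
#' @return A `centerline` (see [new_centerline()]).
#' @export
extract_centerline <- function(mask, seed_valve, seed_distal,
                               spacing_mm = c(1, 1, 1),
                               smooth_sigma_mm = 1.5) {
  d <- dim(mask)
  lin <- function(v) (v[3] - 1) * d[1] * d[2] + (v[2] - 1) * d[1] + v[1]
  for (s in list(seed_valve, seed_distal))
    if (any(s < 1) || any(s > d) || !mask[s[1], s[2], s[3]])
      stop("centerline geometry error: seed outside the mask", call. = FALSE)

  # integer erosion distance, blurred so its ridge follows the lumen axis
  # without the plateaus of the raw transform
  dtb <- box_blur3(distance_to_boundary(mask), passes = 2)
  idx <- which(mask)                      # linear indices of mask voxels
  id_of <- array(0L, d)
  id_of[idx] <- seq_along(idx)
  w <- 1 / (dtb[idx] + 0.5)^3             # per-voxel traversal cost factor

  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  # the 13 lexicographically positive offsets of the 26-neighbourhood
  offsets <- offsets[offsets$dz > 0 |
                       (offsets$dz == 0 & offsets$dy > 0) |
                       (offsets$dz == 0 & offsets$dy == 0 & offsets$dx > 0), ]
  edges <- vector("list", nrow(offsets))
  weights <- vector("list", nrow(offsets))
  for (r in seq_len(nrow(offsets))) {
    o <- as.integer(unlist(offsets[r, ]))
    nb <- shift_array(id_of, o[1], o[2], o[3], fill = 0L)
    a <- id_of[idx]
    b <- nb[idx]
    keep <- b > 0L
    a <- a[keep]; b <- b[keep]
    step <- sqrt(sum((o * spacing_mm)^2))
    edges[[r]] <- rbind(a, b)
    weights[[r]] <- step * (w[a] + w[b]) / 2
  }
  g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                          n = length(idx), directed = FALSE)
  sv <- id_of[lin(seed_valve)]
  sd_ <- id_of[lin(seed_distal)]
  path <- suppressWarnings(
    igraph::shortest_paths(g, from = sv, to = sd_,
                           weights = unlist(weights), output = "vpath"))
  vp <- as.integer(path$vpath[[1]])
  if (length(vp) < 2)
    stop("centerline geometry error: seeds are not connected in the mask",
         call. = FALSE)

  pts <- voxel_world_coords(idx[vp], d, spacing_mm)
  pts <- smooth_path(pts, smooth_sigma_mm)
  rs <- resample_path(pts, spacing_out = 1)
  new_centerline(rs$points, rs$tangents, rs$arc_length)
}

# Gaussian kernel smoothing of a polyline, parameterized by arc length.
# The path is padded by reflection at both ends so the kernel does not pull
# the endpoints towards the interior.
smooth_path <- function(pts, sigma) {
  n <- nrow(pts)
  if (sigma <= 0 || n < 3) return(pts)
  npad <- min(n - 1, 10)
  head_ref <- 2 * matrix(pts[1, ], npad, 3, byrow = TRUE) -
    pts[(npad + 1):2, , drop = FALSE]
  tail_ref <- 2 * matrix(pts[n, ], npad, 3, byrow = TRUE) -
    pts[(n - 1):(n - npad), , drop = FALSE]
  ext <- rbind(head_ref, pts, tail_ref)
  s <- c(0, cumsum(sqrt(rowSums(diff(ext)^2))))
  out <- pts
  for (i in seq_len(n)) {
    wgt <- exp(-0.5 * ((s - s[i + npad]) / sigma)^2)
    wgt <- wgt / sum(wgt)
    out[i, ] <- colSums(ext * wgt)
  }
  out
}

# resample a polyline at fixed arc-length spacing; tangents by central
# differences of the resampled points, renormalized
resample_path <- function(pts, spacing_out = 1) {
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- s[length(s)]
  snew <- seq(0, floor(total / spacing_out) * spacing_out, by = spacing_out)
  p <- sapply(1:3, function(a) stats::approx(s, pts[, a], xout = snew)$y)
  p <- matrix(p, ncol = 3)
  n <- nrow(p)
  tg <- matrix(0, n, 3)
  if (n >= 3) {
    tg[2:(n - 1), ] <- p[3:n, ] - p[1:(n - 2), ]
  }
  tg[1, ] <- p[2, ] - p[1, ]
  tg[n, ] <- p[n, ] - p[n - 1, ]
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = p, tangents = tg, arc_length = snew)
}

#' Build orthogonal analysis planes along a centerline
#'
#' One plane per centerline point (every millimetre along the vessel): origin
#' at the point, unit normal equal to the local tangent, so the normal points
#' away from the aortic valve (forward flow) and its negation towards the
#' valve (reverse flow). If the tangents' net projection onto the
#' valve-to-distal chord is negative the set is flipped with a warning.
#'
#' @param centerline a `centerline`.
#' @return An object of class `plane_set` with `origins`, `normals`,
#'   `arc_length` and `n`.
#' @export
build_planes <- function(centerline) {
  chord <- centerline$points[nrow(centerline$points), ] - centerline$points[1, ]
  normals <- centerline$tangents
  if (sum(normals %*% chord) < 0) {
    warning("plane normals pointed towards the valve; flipping orientation")
    normals <- -normals
  }
  structure(list(origins = centerline$points, normals = normals,
                 arc_length = centerline$arc_length,
                 n = nrow(centerline$points)),
            class = "plane_set")
}

#' @export
print.plane_set <- function(x, ...) {
  cat(sprintf("<plane_set> %d planes, arc length %.1f mm\n",
              x$n, max(x$arc_length)))
  invisible(x)
}

#' Assign every mask voxel to its nearest analysis plane
#'
#' Maps each voxel of the segmentation to the index of the Euclidean-nearest
#' centerline point (world frame); exact ties go to the lowest index. The
#' assigned plane defines the voxel's local forward/reverse flow direction.
#'
#' @param mask 3D logical array.
#' @param centerline a `centerline` in the same world frame.
#' @param spacing_mm voxel spacing of `mask`.
#' @return Integer 3D array of class `assignment_map`: plane index per mask
#'   voxel, 0 outside the mask.
#' @export
assign_voxels <- function(mask, centerline, spacing_mm = c(1, 1, 1)) {
  idx <- which(mask)
  V <- voxel_world_coords(idx, dim(mask), spacing_mm)
  nn <- nearest_point_index(V, centerline$points)
  out <- array(0L, dim(mask))
  out[idx] <- nn$index
  structure(out, class = "assignment_map",
            n_planes = nrow(centerline$points))
}

#' Remove branch vessels from a segmentation
#'
#' Subtracts a region of exclusion -- supplied either as a binary 3D array or
#' as a list of axis-aligned voxel-index boxes
#' `list(c(x1, x2), c(y1, y2), c(z1, z2))` -- from the mask, emulating the
#' manually drawn exclusion of supra-aortic branches.
#'
#' @param mask 3D logical array.
#' @param exclusion_roi binary array of the same shape, or a list of boxes,
#'   or `NULL` (no-op).
#' @return The pruned mask. Warns if more than half the mask is removed.
#' @export
exclude_branches <- function(mask, exclusion_roi = NULL) {
  if (is.null(exclusion_roi)) return(mask)
  roi <- array(FALSE, dim(mask))
  if (is.array(exclusion_roi)) {
    stopifnot(identical(dim(exclusion_roi), dim(mask)))
    roi <- exclusion_roi > 0
  } else {
    for (box in exclusion_roi) {
      stopifnot(length(box) == 3)
      roi[box[[1]][1]:box[[1]][2], box[[2]][1]:box[[2]][2],
          box[[3]][1]:box[[3]][2]] <- TRUE
    }
  }
  out <- mask & !roi
  if (sum(out) < 0.5 * sum(mask))
    warning("exclusion ROI removed more than 50% of the segmentation")
  out
}

#' Label aortic segments from landmark planes
#'
#' Given four landmark arc-length positions -- sinotubular junction (STJ),
#' proximal to the first supra-aortic branch, distal to the left subclavian
#' artery, proximal to the celiac artery -- labels every assigned voxel:
#' AAo for planes in `[stj, branch)`, arch for `[branch, subclavian)`, DAo
#' for `[subclavian, celiac]` (celiac plane inclusive). Voxels assigned to
#' planes before the STJ (left ventricular outflow tract) or beyond the
#' celiac plane are excluded.
#'
#' @param assignment an `assignment_map` from [assign_voxels()].
#' @param landmarks numeric length-4 vector
#'   `c(stj, branch, subclavian, celiac)` of arc lengths in mm, strictly
#'   increasing and within the centerline range.
#' @param arc_length per-plane arc lengths (mm), e.g. `planes$arc_length`.
#' @return Integer 3D array of class `segment_labels`: 1 = AAo, 2 = Arch,
#'   3 = DAo, 0 = excluded/background, with a `levels` attribute.
#' @export
label_segments <- function(assignment, landmarks, arc_length) {
  if (length(landmarks) != 4 || any(diff(landmarks) <= 0))
    stop("configuration error: landmarks must be 4 strictly increasing arc lengths",
         call. = FALSE)
  if (landmarks[1] < 0 || landmarks[4] > max(arc_length))
    stop("configuration error: landmark outside the centerline range",
         call. = FALSE)
  plane_lab <- integer(length(arc_length))        # 0 = excluded
  plane_lab[arc_length >= landmarks[1] & arc_length < landmarks[2]] <- 1L
  plane_lab[arc_length >= landmarks[2] & arc_length < landmarks[3]] <- 2L
  plane_lab[arc_length >= landmarks[3] & arc_length <= landmarks[4]] <- 3L
  out <- array(0L, dim(assignment))
  inside <- assignment > 0
  out[inside] <- plane_lab[assignment[inside]]
  structure(out, class = "segment_labels",
            levels = c("AAo", "Arch", "DAo"), landmarks = landmarks)
}
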