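# straight cylinder mask along z, axis on the voxel grid
cylinder_mask <- function(d3, axis_xy, radius, spacing = c(1, 1, 1)) {
  xs <- (seq_len(d3[1]) - 1) * spacing[1]
  ys <- (seq_len(d3[2]) - 1) * spacing[2]
  D2 <- outer((xs - axis_xy[1])^2, (ys - axis_xy[2])^2, "+")
  m <- array(FALSE, d3)
  for (k in seq_len(d3[3])) m[, , k] <- D2 <= radius^2
  m
}

straight_centerline <- function(axis_xy, z_range) {
  z <- seq(z_range[1], z_range[2], by = 1)
  n <- length(z)
  new_centerline(cbind(axis_xy[1], axis_xy[2], z),
                 matrix(rep(c(0, 0, 1), each = n), n, 3),
                 z - z[1])
}

test_that("trilinear resampling reproduces constant and affine fields exactly", {
  const <- array(3.7, c(6, 5, 4))
  out <- resample_isotropic(const, spacing_mm = c(2, 2, 2), target_mm = 1)
  expect_equal(dim(out), c(11, 9, 7))
  expect_true(all(abs(out - 3.7) < 1e-12))
  # field linear in world x, anisotropic source
  d <- c(7, 5, 4); sp <- c(2, 1.5, 3)
  lin <- array(rep((seq_len(d[1]) - 1) * sp[1], times = d[2] * d[3]), d)
  out2 <- resample_isotropic(lin, spacing_mm = sp, target_mm = 1)
  expected_x <- (seq_len(dim(out2)[1]) - 1) * 1
  expect_equal(out2[, 2, 2], expected_x, tolerance = 1e-12)
})

test_that("nearest-neighbour mask resampling conserves volume within 5%", {
  m <- cylinder_mask(c(16, 16, 12), c(15, 15), radius = 8,
                     spacing = c(2, 2, 2))
  out <- resample_isotropic(m, spacing_mm = c(2, 2, 2), target_mm = 1,
                            method = "nearest")
  vol_src <- sum(m) * 8                      # voxels x 8 mm^3
  vol_out <- sum(out) * 1
  expect_lt(abs(vol_out / vol_src - 1), 0.05)
})

test_that("centerline of a straight tube tracks the true axis", {
  m <- cylinder_mask(c(25, 25, 60), c(12, 12), radius = 10)
  cl <- extract_centerline(m, c(13, 13, 3), c(13, 13, 58))
  dev <- sqrt((cl$points[, 1] - 12)^2 + (cl$points[, 2] - 12)^2)
  expect_lt(max(dev), 0.5)
  expect_true(all(abs(sqrt(rowSums(cl$tangents^2)) - 1) < 1e-9))
  # endpoints land within one voxel of the seeds
  expect_lt(sqrt(sum((cl$points[1, ] - c(12, 12, 2))^2)), sqrt(3))
  expect_lt(sqrt(sum((cl$points[nrow(cl$points), ] - c(12, 12, 57))^2)),
            sqrt(3))
  # arc-length increments 1 mm +/- 0.05 mm
  expect_true(all(abs(diff(cl$arc_length) - 1) < 0.05))
})

test_that("candy-cane centerline recovers the analytic arc length within 2%", {
  spec <- study_spec()
  ds <- synthesize_phantom(spec)
  seeds <- phantom_seeds(ds)
  cl <- extract_centerline(ds$mask, seeds$valve, seeds$distal)
  true_len <- 40 + 16 * pi + 50
  expect_lt(abs(max(cl$arc_length) / true_len - 1), 0.02)
})

test_that("bad seeds and disconnected masks raise geometry errors", {
  m <- cylinder_mask(c(20, 20, 30), c(9, 9), radius = 6)
  expect_error(extract_centerline(m, c(1, 1, 1), c(10, 10, 28)),
               "seed outside")
  m2 <- m
  m2[, , 15] <- FALSE                        # split the tube
  expect_error(extract_centerline(m2, c(10, 10, 3), c(10, 10, 28)),
               "not connected")
})

test_that("voxel assignment matches a brute-force nearest-point search", {
  m <- cylinder_mask(c(15, 15, 40), c(7, 7), radius = 5)
  cl <- straight_centerline(c(7, 7), c(2, 37))
  am <- assign_voxels(m, cl)
  idx <- which(m)
  W <- revflow:::voxel_world_coords(idx, dim(m), c(1, 1, 1))
  brute <- vapply(seq_along(idx), function(i)
    which.min(colSums((t(cl$points) - W[i, ])^2)), integer(1))
  expect_identical(as.integer(am[idx]), as.integer(brute))
  # for an axis-aligned tube, assignment is the nearest axial station
  expect_identical(as.integer(am[idx]),
                   as.integer(pmin(pmax(round(W[, 3]) - 2, 0) + 1, 36)))
})

test_that("equidistant voxels are assigned the lowest plane index", {
  cl <- straight_centerline(c(3, 3), c(0, 10))
  m <- array(FALSE, c(7, 7, 12))
  m[4, 4, 6] <- TRUE                         # z = 5: coincides with point 6
  m[4, 4, 7] <- TRUE                         # z = 6: coincides with point 7
  m[4, 5, 6] <- TRUE
  am <- assign_voxels(m, cl)
  expect_equal(am[4, 4, 6], 6L)
  expect_equal(am[4, 4, 7], 7L)
  # voxel midway between two planes (constructed at z = 5.0 using coarser
  # centerline): tie must go to the lower index
  cl2 <- new_centerline(cbind(3, 3, c(4.5, 5.5)),
                        matrix(rep(c(0, 0, 1), each = 2), 2, 3), c(0, 1))
  m2 <- array(FALSE, c(7, 7, 12))
  m2[4, 4, 6] <- TRUE                        # z = 5, equidistant to both
  expect_equal(assign_voxels(m2, cl2)[4, 4, 6], 1L)
})

test_that("plane construction follows the tangent/orientation contract", {
  spec <- tiny_spec()
  cl <- build_candycane_centerline(spec)
  pl <- build_planes(cl)
  expect_equal(pl$n, floor(20 + 8 * pi + 24) + 1)
  expect_identical(pl$normals, cl$tangents)
  # reversing the point order flips every normal
  n <- nrow(cl$points)
  cl_rev <- new_centerline(cl$points[n:1, ], -cl$tangents[n:1, ],
                           cl$arc_length)
  pl_rev <- build_planes(cl_rev)
  expect_equal(pl_rev$normals[n:1, ], -pl$normals, tolerance = 1e-12)
})

test_that("branch exclusion removes exactly the ROI", {
  tube <- cylinder_mask(c(20, 20, 30), c(9, 9), radius = 5)
  branch <- array(FALSE, dim(tube))
  branch[16:19, 8:11, 10:14] <- TRUE         # disjoint side blob
  grafted <- tube | branch
  expect_identical(exclude_branches(grafted, NULL), grafted)
  pruned <- exclude_branches(grafted,
                             list(list(c(16, 19), c(8, 11), c(10, 14))))
  expect_identical(pruned, tube)
  expect_true(all(pruned <= grafted))        # always a subset
  expect_warning(exclude_branches(tube, tube), "50%")
})

test_that("segment labelling partitions the tube by landmark arc length", {
  d3 <- c(28, 28, 260)
  m <- cylinder_mask(d3, c(13, 13), radius = 10)
  cl <- straight_centerline(c(13, 13), c(0, 259))
  am <- assign_voxels(m, cl)
  lab <- label_segments(am, c(10, 100, 150, 250), cl$arc_length)
  # analytic slab volume: pi R^2 x 90 mm for the AAo slab
  expect_lt(abs(sum(lab == 1L) / (pi * 100 * 90) - 1), 0.05)
  # three segments partition the non-excluded voxels
  n_lab <- sum(lab == 1L) + sum(lab == 2L) + sum(lab == 3L)
  expect_equal(n_lab, sum(lab > 0))
  # voxels before the first landmark plane are excluded (LVOT rule)
  pre <- which(m & am > 0 & array(rep(seq_len(d3[3]), each = prod(d3[1:2])),
                                  d3) <= 9)
  expect_true(all(lab[pre] == 0L))
  # landmark validation
  expect_error(label_segments(am, c(10, 5, 150, 250), cl$arc_length),
               "increasing")
  expect_error(label_segments(am, c(10, 100, 150, 400), cl$arc_length),
               "outside")
})
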