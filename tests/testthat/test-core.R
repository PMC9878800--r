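# build an along-track setup by hand: straight tube along z, planes with +z
# normals, so s = vz
tube_setup <- function(d3 = c(9, 9, 20), radius = 3.5, nt = 6) {
  xs <- seq_len(d3[1]) - 1
  D2 <- outer((xs - 4)^2, (xs - 4)^2, "+")
  m <- array(FALSE, d3)
  for (k in seq_len(d3[3])) m[, , k] <- D2 <= radius^2
  cl <- new_centerline(cbind(4, 4, 0:(d3[3] - 1)),
                       matrix(rep(c(0, 0, 1), d3[3]), ncol = 3, byrow = TRUE),
                       0:(d3[3] - 1))
  list(mask = m, cl = cl, planes = build_planes(cl),
       assignment = assign_voxels(m, cl))
}

mk_field <- function(d3, nt, vx = 0, vy = 0, vz = 0, dt_ms = 40) {
  velocity_field(array(vx, c(d3, nt)), array(vy, c(d3, nt)),
                 array(vz, c(d3, nt)), c(1, 1, 1), dt_ms, 150)
}

test_that("projection decomposes velocity along the plane normal", {
  s <- tube_setup()
  d3 <- dim(s$mask)
  # velocity parallel to the normal: s = speed, all forward
  f1 <- mk_field(d3, 3, vz = 100)
  at1 <- project_velocities(f1, s$assignment, s$planes)
  expect_true(all(at1$s == 100))
  # velocity perpendicular to the normal: s = 0
  f2 <- mk_field(d3, 3, vx = 250)
  at2 <- project_velocities(f2, s$assignment, s$planes)
  expect_true(all(at2$s == 0))
})

test_that("projection matches a per-voxel scalar-product oracle exactly", {
  spec <- tiny_spec()
  ds <- synthesize_phantom(spec)
  seeds <- phantom_seeds(ds)
  cl <- extract_centerline(ds$mask, seeds$valve, seeds$distal)
  planes <- build_planes(cl)
  am <- assign_voxels(ds$mask, cl)
  set.seed(3)
  d4 <- c(dim(ds$mask), 4)
  f <- velocity_field(array(rnorm(prod(d4)), d4), array(rnorm(prod(d4)), d4),
                      array(rnorm(prod(d4)), d4), c(1, 1, 1), 40, 150)
  at <- project_velocities(f, am, planes)
  idx <- at$voxels
  for (q in sample(seq_along(idx), 50)) {
    v <- idx[q]
    n <- planes$normals[am[v], ]
    for (t in 1:4) {
      s_ref <- f$vx[, , , t][v] * n[1] + f$vy[, , , t][v] * n[2] +
        f$vz[, , , t][v] * n[3]
      expect_identical(at$s[q, t], s_ref)
    }
  }
})

test_that("net flow curve is the face-area-scaled mean and is linear", {
  s <- tube_setup()
  d3 <- dim(s$mask)
  at <- project_velocities(mk_field(d3, 5, vz = 100), s$assignment, s$planes)
  expect_equal(net_flow_curve(at), rep(100, 5), tolerance = 1e-12)
  at0 <- project_velocities(mk_field(d3, 5), s$assignment, s$planes)
  expect_equal(net_flow_curve(at0), rep(0, 5))
  set.seed(9)
  fr <- mk_field(d3, 5)
  fr$vz <- array(rnorm(prod(d3) * 5, sd = 200), c(d3, 5))
  atr <- project_velocities(fr, s$assignment, s$planes)
  fr2 <- fr; fr2$vz <- 2 * fr$vz
  atr2 <- project_velocities(fr2, s$assignment, s$planes)
  expect_equal(net_flow_curve(atr2), 2 * net_flow_curve(atr),
               tolerance = 1e-12)
})

test_that("end systole is the first post-peak inflection of the flow curve", {
  # sine over one period, 16 frames: curvature changes sign at the
  # descending zero crossing, i.e. the half-period frame (1-based frame 9)
  Q <- sin(2 * pi * (0:15) / 16)
  expect_equal(detect_end_systole(Q), 9L)
  expect_equal(detect_end_systole(Q, smooth = FALSE), 9L)
  # phantom raised-cosine ejection: detector matches the ground-truth frame
  ds <- synthesize_phantom(tiny_disease_spec())
  seeds <- phantom_seeds(ds)
  run <- reverse_flow_run(ds, seeds$valve, seeds$distal,
                          phantom_landmarks(ds$spec), preprocess = FALSE)
  expect_lte(abs(run$window$k_es - ds$ground_truth$k_es), 1)
  # concave monotone decay has no sign change: falls back to post-peak min
  Qc <- c(0, 10, 9, 7.8, 6.3, 4.3)
  expect_warning(k <- detect_end_systole(Qc, smooth = FALSE),
                 "post-peak minimum")
  expect_equal(k, 6L)
  # degenerate peak at the end
  expect_error(detect_end_systole(c(0, 1, 2, 3, 4, 5), smooth = FALSE),
               "timing error")
  expect_error(detect_end_systole(c(1, 2, 1)), "at least 5")
})

test_that("window truncation keeps floor(600/dt) fully contained frames", {
  expect_equal(truncate_window(30, 40)$n_inc, 15L)
  expect_equal(truncate_window(30, 42)$n_inc, 14L)
  expect_equal(truncate_window(30, 36)$n_inc, 16L)
  expect_equal(truncate_window(12, 40)$n_inc, 12L)  # capped at acquired
  expect_error(truncate_window(10, 600), "too coarse")
  expect_error(cardiac_window(1, 10, 40), "k_es")
})

test_that("flow integration matches analytic values and identities", {
  s <- tube_setup(nt = 15)
  d3 <- dim(s$mask)
  # constant reverse 10 mm/s over 15 frames at dt 40: 6 mm^3 = 0.006 mL
  at <- project_velocities(mk_field(d3, 15, vz = -10), s$assignment, s$planes)
  maps <- integrate_flow(at, cardiac_window(6, 15, 40))
  expect_equal(unname(maps$reverse_whole),
               rep(0.006, length(maps$voxels)), tolerance = 1e-12)
  expect_true(all(maps$forward_whole == 0))
  # forward-only field: reverse map identically zero
  atf <- project_velocities(mk_field(d3, 15, vz = 80), s$assignment, s$planes)
  mf <- integrate_flow(atf, cardiac_window(6, 15, 40))
  expect_true(all(mf$reverse_whole == 0))
  # random fields: forward - reverse = net, exactly; whole = sys + dia
  set.seed(11)
  fr <- mk_field(d3, 15)
  for (cc in c("vx", "vy", "vz"))
    fr[[cc]] <- array(rnorm(prod(d3) * 15, sd = 300), c(d3, 15))
  atr <- project_velocities(fr, s$assignment, s$planes)
  mr <- integrate_flow(atr, cardiac_window(6, 15, 40))
  net_ref <- rowSums(atr$s) * 1 * 0.04 / 1000
  expect_equal(mr$forward_whole - mr$reverse_whole, net_ref,
               tolerance = 1e-12)
  expect_identical(mr$reverse_whole, mr$reverse_systolic + mr$reverse_diastolic)
  expect_identical(mr$forward_whole, mr$forward_systolic + mr$forward_diastolic)
  # scaling: alpha * v scales every map by alpha
  fr2 <- fr
  for (cc in c("vx", "vy", "vz")) fr2[[cc]] <- 2.5 * fr[[cc]]
  mr2 <- integrate_flow(project_velocities(fr2, s$assignment, s$planes),
                        cardiac_window(6, 15, 40))
  expect_equal(mr2$reverse_whole, 2.5 * mr$reverse_whole, tolerance = 1e-12)
})

test_that("segment means obey the partition identity", {
  s <- tube_setup(d3 = c(9, 9, 40), nt = 8)
  d3 <- c(9, 9, 40)
  set.seed(5)
  fr <- mk_field(d3, 8)
  fr$vz <- array(rnorm(prod(d3) * 8, mean = -50, sd = 100), c(d3, 8))
  at <- project_velocities(fr, s$assignment, s$planes)
  maps <- integrate_flow(at, cardiac_window(4, 8, 40))
  lab <- label_segments(s$assignment, c(2, 12, 22, 37), s$cl$arc_length)
  st <- segment_means(maps, lab)
  rev_sys <- st[st$direction == "reverse" & st$window == "systolic", ]
  pooled <- sum(rev_sys$mean_mL * rev_sys$n_voxels) / sum(rev_sys$n_voxels)
  union_mean <- mean(maps$reverse_systolic[lab[maps$voxels] > 0])
  expect_equal(pooled, union_mean, tolerance = 1e-12)
  # uniform map: every segment mean equal, SD zero
  atu <- project_velocities(mk_field(d3, 8, vz = -30), s$assignment, s$planes)
  stu <- segment_means(integrate_flow(atu, cardiac_window(4, 8, 40)), lab)
  ru <- stu[stu$direction == "reverse" & stu$window == "whole", ]
  expect_equal(ru$mean_mL, rep(ru$mean_mL[1], 3), tolerance = 1e-12)
  expect_equal(ru$sd_mL, rep(0, 3), tolerance = 1e-10)
  # empty segment reported as missing, not zero
  lab2 <- label_segments(s$assignment, c(2, 12, 22, 25), s$cl$arc_length)
  lab2[lab2 == 3L] <- 0L
  st2 <- segment_means(maps, lab2)
  expect_true(all(is.na(st2$mean_mL[st2$segment == "DAo"])))
})
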