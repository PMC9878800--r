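# shared fixtures: small phantoms built in code

# small candy-cane phantom that runs in a second or two
tiny_spec <- function(...) {
  args <- list(grid_shape = c(40, 28, 56), tube_radius_mm = 4,
               ascending_len_mm = 20, arch_radius_mm = 8,
               descending_len_mm = 24, n_frames = 12, dt_ms = 40,
               t_end_systole_ms = 280, peak_velocity_mms = 800)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# tiny phantom with both disease components active
tiny_disease_spec <- function(...) {
  tiny_spec(reverse_ring = list(inner_fraction = 0.6, amplitude_mms = 300,
                                frame_range = c(3, 4)),
            regurgitant = list(amplitude_mms = 50, frame_range = c(9, 12)),
            ...)
}

# full-size validation phantom: 64 x 64 x 96 at 1 mm, 15 frames at 40 ms,
# stenosis-like full-ring reversal in systole plus regurgitant plug in
# diastole
study_spec <- function(...) {
  phantom_spec(reverse_ring = list(inner_fraction = 0.6, amplitude_mms = 500,
                                   frame_range = c(3, 6)),
               regurgitant = list(amplitude_mms = 60, frame_range = c(10, 15)),
               ...)
}

# discrete ground truth: segment-agnostic lumen mean of the synthesized
# (voxelized) along-track series, per window -- isolates pipeline error from
# phantom voxelization error
discrete_gt_means <- function(ds, voxel_subset = NULL) {
  gt <- ds$ground_truth
  u <- gt$u
  if (!is.null(voxel_subset)) u <- u[gt$voxels %in% voxel_subset, , drop = FALSE]
  a <- 1
  dt_s <- ds$spec$dt_ms / 1000
  sys <- seq_len(gt$k_es - 1)
  dia <- seq(gt$k_es, gt$n_inc)
  c(systolic = mean(rowSums(pmax(-u[, sys, drop = FALSE], 0))) * a * dt_s / 1000,
    diastolic = mean(rowSums(pmax(-u[, dia, drop = FALSE], 0))) * a * dt_s / 1000)
}

# reverse-only segment stats of a run, as a named lookup
rev_stat <- function(run, segment, window) {
  st <- run$segment_stats
  st$mean_mL[st$segment == segment & st$window == window &
               st$direction == "reverse"]
}
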