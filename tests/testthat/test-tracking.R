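test_that("a stationary spot yields one track of zero-length steps", {
  pts <- tibble::tibble(frame = 1:10, row = 20, col = 30)
  tr <- link_tracks(pts)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
  st <- punctakit:::track_steps(tr)
  expect_equal(nrow(st), 9)
  expect_true(all(st$step_px == 0))
})

test_that("distant movers are never cross-linked at the gating radius", {
  pts <- dplyr::bind_rows(
    tibble::tibble(frame = 1:8, row = 10, col = 10 + (0:7)),
    tibble::tibble(frame = 1:8, row = 30, col = 10 + (0:7)))
  tr <- link_tracks(pts, max_step_px = 5)
  expect_equal(length(unique(tr$track_id)), 2)
  rows_by_track <- tapply(tr$row, tr$track_id, function(x) length(unique(x)))
  expect_true(all(rows_by_track == 1))
})

test_that("every detection joins at most one track", {
  sim <- gen_timelapse(scene_params(field_size_px = 192, n_spots = 40,
                                    seed = 51),
                       n_frames = 20, stim_frame = 6,
                       internalized_fraction = 0,
                       diffusion_coeff_um2s = 0.01, frame_interval_s = 0.1)
  pts <- sim$truth$tracks[, c("frame", "row", "col")]
  tr <- link_tracks(pts, min_length = 1)
  expect_lte(nrow(tr), nrow(pts))
  expect_false(any(duplicated(tr[, c("track_id", "frame")])))
  expect_false(any(duplicated(tr[, c("frame", "row", "col")])))
})

test_that("linked steps follow the generating particles", {
  sim <- gen_timelapse(scene_params(field_size_px = 256,
                                    density_per_um2 = 0.05, seed = 52),
                       n_frames = 40, stim_frame = 6,
                       internalized_fraction = 0,
                       diffusion_coeff_um2s = 0.01, frame_interval_s = 0.1)
  truth <- sim$truth$tracks
  tr <- link_tracks(truth[, c("frame", "row", "col")])
  # map each linked point back to its true particle by exact position
  key <- paste(truth$frame, truth$row, truth$col)
  ids <- truth$id[match(paste(tr$frame, tr$row, tr$col), key)]
  same <- unlist(tapply(ids, tr$track_id, function(x) diff(x) == 0))
  expect_gte(mean(same), 0.95)
})

test_that("raising the gating radius never loses linked steps", {
  sim <- gen_timelapse(scene_params(field_size_px = 128, n_spots = 25,
                                    seed = 53),
                       n_frames = 15, stim_frame = 6,
                       internalized_fraction = 0,
                       diffusion_coeff_um2s = 0.02, frame_interval_s = 0.1)
  pts <- sim$truth$tracks[, c("frame", "row", "col")]
  n_steps <- vapply(c(1, 2, 5, 10), function(ms) {
    tr <- link_tracks(pts, max_step_px = ms, min_length = 1)
    nrow(punctakit:::track_steps(tr))
  }, numeric(1))
  expect_true(all(diff(n_steps) >= 0))
})

test_that("displacement histogram bins per-step and per-track displacements", {
  pts <- tibble::tibble(frame = 1:4, row = c(0, 1, 2, 4), col = 0)
  tr <- link_tracks(pts, min_length = 3)
  h <- displacement_histogram(tr, bin_width_px = 1)
  steps <- h[h$kind == "step", ]
  expect_equal(steps$count[steps$bin_left == 1], 2)
  expect_equal(steps$count[steps$bin_left == 2], 1)
  # all-stationary tracks put all mass in bin 0
  still <- link_tracks(tibble::tibble(frame = 1:5, row = 3, col = 3))
  h0 <- displacement_histogram(still, 1)
  expect_equal(h0$count[h0$kind == "step" & h0$bin_left == 0], 4)
  expect_equal(attr(h0, "min_displacement_tracks"), 1)
  expect_error(displacement_histogram(tr, 0), "positive")
})

test_that("speeds convert steps through the calibration", {
  pts <- tibble::tibble(frame = 1:6, row = 10, col = 10 + 0:5)
  tr <- link_tracks(pts)
  sp <- average_speed(tr, pixel_size_nm = 160, frame_interval_s = 0.1)
  expect_equal(sp$pooled_mean, 1.6)
  expect_equal(glance(sp)$n_tracks, 1)
  still <- link_tracks(tibble::tibble(frame = 1:5, row = 3, col = 3))
  expect_equal(average_speed(still, 160, 0.1)$pooled_mean, 0)
  expect_error(average_speed(tr, 160, NULL), "required")
})

test_that("speed statistics are translation invariant", {
  sim <- gen_timelapse(scene_params(field_size_px = 128, n_spots = 20,
                                    seed = 54),
                       n_frames = 20, stim_frame = 6,
                       internalized_fraction = 0,
                       diffusion_coeff_um2s = 0.01, frame_interval_s = 0.1)
  pts <- sim$truth$tracks[, c("frame", "row", "col")]
  sp1 <- average_speed(link_tracks(pts), 160, 0.1)
  pts2 <- dplyr::mutate(pts, row = row + 40, col = col - 17)
  sp2 <- average_speed(link_tracks(pts2), 160, 0.1)
  expect_equal(sp2$pooled_mean, sp1$pooled_mean, tolerance = 1e-12)
})

test_that("Brownian tracks reproduce the Rayleigh speed", {
  sim <- gen_timelapse(scene_params(field_size_px = 256, n_spots = 50,
                                    seed = 55),
                       n_frames = 60, stim_frame = 10,
                       internalized_fraction = 0,
                       diffusion_coeff_um2s = 0.01, frame_interval_s = 0.1)
  tr <- link_tracks(sim$truth$tracks[, c("frame", "row", "col")])
  sp <- average_speed(tr, 160, 0.1)
  expect_equal(sp$pooled_mean, sqrt(pi * 0.01 * 0.1) / 0.1,
               tolerance = 0.1)
})
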