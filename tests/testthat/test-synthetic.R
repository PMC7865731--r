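test_that("generators are deterministic under a fixed seed", {
  a <- gen_two_channel_frame(scene_params(seed = 11))
  b <- gen_two_channel_frame(scene_params(seed = 11))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$spots_ch1, b$truth$spots_ch1)
  t1 <- gen_timelapse(scene_params(seed = 11), n_frames = 12, stim_frame = 6)
  t2 <- gen_timelapse(scene_params(seed = 11), n_frames = 12, stim_frame = 6)
  expect_identical(t1$stack$data, t2$stack$data)
  q1 <- gen_qpcr_table("g", 2, "ref", seed = 11)
  q2 <- gen_qpcr_table("g", 2, "ref", seed = 11)
  expect_identical(q1$cq, q2$cq)
  p1 <- gen_pla_scene(4, 10, seed = 11)
  p2 <- gen_pla_scene(4, 10, seed = 11)
  expect_identical(p1$stack$data, p2$stack$data)
})

test_that("zero-density scenes are blank apart from the backgrounds", {
  sc <- gen_two_channel_frame(scene_params(density_per_um2 = 0, seed = 2,
                                           poisson_noise = FALSE,
                                           gaussian_noise_sd = 0))
  expect_equal(nrow(sc$truth$spots_ch1), 0)
  f <- get_frame(sc$stack, 1)
  expect_setequal(unique(as.vector(f)), c(10, 50))
  expect_true(all(gen_pla_scene(3, 0, seed = 1)$truth$pla_counts == 0))
})

test_that("spot counts are Poisson with mean density x cell area", {
  params <- scene_params(seed = 1)
  area_um2 <- sum(gen_two_channel_frame(params)$cell_mask) * 0.16^2
  expected <- params$density_per_um2 * area_um2
  counts <- vapply(1:200, function(s) {
    nrow(gen_two_channel_frame(scene_params(seed = s))$truth$spots_ch1)
  }, numeric(1))
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # all ground-truth positions inside the cell mask
  sc <- gen_two_channel_frame(scene_params(seed = 3))
  inside <- sc$cell_mask[cbind(round(sc$truth$spots_ch1$row),
                               round(sc$truth$spots_ch1$col))]
  expect_true(all(inside))
})

test_that("coloc flags track the requested fraction binomially", {
  for (frac in c(0.25, 0.75)) {
    flags <- unlist(lapply(1:30, function(s) {
      gen_two_channel_frame(
        scene_params(coloc_fraction = frac, seed = s))$truth$spots_ch1$coloc
    }))
    se <- sqrt(frac * (1 - frac) / length(flags))
    expect_lt(abs(mean(flags) - frac), 4 * se)
  }
})

test_that("Brownian steps have the Rayleigh mean length", {
  sim <- gen_timelapse(scene_params(field_size_px = 256, n_spots = 80,
                                    seed = 9),
                       n_frames = 140, stim_frame = 20,
                       internalized_fraction = 0,
                       diffusion_coeff_um2s = 0.01, frame_interval_s = 0.1)
  tr <- sim$truth$tracks
  steps_um <- unlist(lapply(split(tr, tr$id), function(d) {
    sqrt(diff(d$row)^2 + diff(d$col)^2) * 0.16
  }))
  expect_gte(length(steps_um), 1e4)
  expect_equal(mean(steps_um), sqrt(pi * 0.01 * 0.1), tolerance = 0.02)
})

test_that("internalization ground truth matches its construction", {
  sim <- gen_timelapse(scene_params(n_spots = 12, seed = 4), n_frames = 25,
                       stim_frame = 8, internalized_fraction = 1,
                       loss_frames = 1)
  expect_equal(sim$truth$n_events, 12)
  expect_true(all(!is.na(sim$truth$event_frame)))
  expect_true(all(sim$truth$event_frame > 8))
  # post-event local amplitude is zero in the rendered truth
  amp <- sim$truth$tracks
  for (id in 1:12) {
    e <- sim$truth$event_frame[id]
    expect_true(all(amp$amplitude[amp$id == id & amp$frame >= e] == 0))
    expect_true(all(amp$amplitude[amp$id == id & amp$frame < e] > 0))
  }
  # conservation at fractional rates
  sim2 <- gen_timelapse(scene_params(n_spots = 20, seed = 5), n_frames = 25,
                        stim_frame = 8, internalized_fraction = 0.35)
  expect_equal(sim2$truth$n_events, round(0.35 * 20))
  expect_error(
    gen_timelapse(scene_params(seed = 1), n_frames = 10, stim_frame = 5,
                  diffusion_coeff_um2s = -1),
    ">= 0")
})

test_that("all generated intensities are non-negative", {
  sc <- gen_two_channel_frame(scene_params(seed = 13, gaussian_noise_sd = 30))
  expect_true(all(sc$stack$data >= 0))
  sim <- gen_timelapse(scene_params(seed = 13), n_frames = 12, stim_frame = 6)
  expect_true(all(sim$stack$data >= 0))
})

test_that("PLA scenes honour forced counts and Poisson totals", {
  forced <- gen_pla_scene(1, 99, forced_counts = 5L, seed = 2)
  expect_identical(forced$truth$pla_counts, 5L)
  expect_equal(nrow(forced$truth$dots), 5)
  totals <- vapply(1:5, function(s) {
    sum(gen_pla_scene(30, 40, seed = s)$truth$pla_counts)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 1200), 3 * sqrt(1200 / 5))
  # dots stay within the placement radius of the owning nucleus
  sc <- gen_pla_scene(6, 30, seed = 3)
  d <- sqrt((sc$truth$dots$row - sc$truth$centers[sc$truth$dots$cell, 1])^2 +
              (sc$truth$dots$col - sc$truth$centers[sc$truth$dots$cell, 2])^2)
  expect_true(all(d <= sc$truth$nucleus_radius_px +
                    sc$truth$placement_radius_px))
})

test_that("qPCR tables encode the requested fold change in Cq space", {
  tab1 <- gen_qpcr_table("g", 1, "ref", cq_noise_sd = 0, seed = 1)
  expect_equal(mean(tab1$cq[tab1$gene == "g" & tab1$condition == "treated"]),
               mean(tab1$cq[tab1$gene == "g" & tab1$condition == "untreated"]))
  tab2 <- gen_qpcr_table("g", 2, "ref", cq_noise_sd = 0, seed = 1)
  expect_equal(
    mean(tab2$cq[tab2$gene == "g" & tab2$condition == "untreated"]) -
      mean(tab2$cq[tab2$gene == "g" & tab2$condition == "treated"]),
    1)
  ref_rows <- tab2[tab2$gene == "ref", ]
  expect_equal(mean(ref_rows$cq[ref_rows$condition == "treated"]),
               mean(ref_rows$cq[ref_rows$condition == "untreated"]))
  expect_error(gen_qpcr_table("g", 0, "ref"), "positive")
})
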