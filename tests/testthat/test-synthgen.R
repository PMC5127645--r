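test_that("parameter validation rejects impossible geometries", {
  expect_error(organoid_sim_params(stack_shape = c(0, 10, 10)), "positive")
  expect_error(organoid_sim_params(n_alive = -1), "non-negative")
  expect_error(organoid_sim_params(fragment_radius_px = 6, alive_radius_px = 5),
               "smaller")
  expect_error(organoid_sim_params(snr = 1), "exceed 1")
})

test_that("empty field gives pure background and empty truth", {
  p <- organoid_sim_params(n_alive = 0, n_dead = 0, seed = 1)
  res <- make_organoid_stack(p)
  expect_equal(nrow(res$truth), 0)
  h2b <- stack_channel(res$stack, "H2B")
  # pure background: nothing near the foreground level
  expect_lt(max(h2b), p$bg_level * (1 + p$snr) / 2)
})

test_that("stack generation is deterministic and counts are forced by construction", {
  p <- organoid_sim_params(n_alive = 20, n_dead = 5, fragments_per_dead = 4,
                           seed = 42)
  a <- make_organoid_stack(p)
  b <- make_organoid_stack(p)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$voxels, b$truth$voxels)
  expect_equal(sum(a$truth$class == "alive"), 20)
  expect_equal(sum(a$truth$class == "dead-fragment"), 20) # 5 cells x 4 fragments
})

test_that("truth voxel sets are disjoint and PI marks only dead fragments", {
  p <- organoid_sim_params(n_alive = 12, n_dead = 4, seed = 7)
  res <- make_organoid_stack(p)
  vox <- unlist(res$truth$voxels)
  expect_equal(anyDuplicated(vox), 0)
  pi_arr <- stack_channel(res$stack, "PI")
  mid <- p$bg_level * (1 + p$snr) / 2
  pi_pos <- which(pi_arr >= mid)
  dead_vox <- unlist(res$truth$voxels[res$truth$class == "dead-fragment"])
  expect_true(all(pi_pos %in% dead_vox))
})

test_that("overcrowded fields fail loudly instead of overlapping", {
  p <- organoid_sim_params(stack_shape = c(24, 24, 4), n_alive = 200, seed = 1)
  expect_error(make_organoid_stack(p), class = "organoidr_overcrowded")
})

test_that("timelapse conserves counts: alive = initial + mitoses - apoptoses", {
  p <- organoid_sim_params(stack_shape = c(72, 72, 8), n_alive = 8, n_dead = 0,
                           seed = 5, pi_channel = FALSE)
  sched <- event_schedule(
    time_min = c(30, 45, 60, 60, 90, 105, 120),
    event_type = c("mitosis", "mitosis", "apoptosis", "mitosis", "mitosis",
                   "apoptosis", "mitosis"),
    object_id = c(1, 2, 3, 4, 9, 5, 6))
  tl <- make_timelapse(p, sched, frame_interval_min = 15, duration_min = 150)
  ft <- tl$frame_truth
  for (i in seq_len(nrow(ft))) {
    m <- sum(sched$time_min <= ft$time_min[i] & sched$event_type == "mitosis")
    a <- sum(sched$time_min <= ft$time_min[i] & sched$event_type == "apoptosis")
    expect_equal(ft$n_alive[i], 8 + m - a)
  }
  expect_equal(nrow(tl$event_log), nrow(sched))
  # one mitosis at t=30 with 15-min frames: extra object from frame index 3 (1-based)
  expect_equal(ft$n_alive[ft$time_min == 15], 8)
  expect_equal(ft$n_alive[ft$time_min == 30], 9)
})

test_that("empty schedule keeps the alive count constant across frames", {
  p <- organoid_sim_params(stack_shape = c(64, 64, 8), n_alive = 6, n_dead = 0,
                           seed = 2, pi_channel = FALSE)
  tl <- make_timelapse(p, event_schedule(), frame_interval_min = 15,
                       duration_min = 135)
  expect_equal(nrow(tl$frame_truth), 10)
  expect_true(all(tl$frame_truth$n_alive == 6))
})

test_that("timelapse rejects events on unknown objects and uncovered durations", {
  p <- organoid_sim_params(stack_shape = c(64, 64, 8), n_alive = 4, n_dead = 0,
                           seed = 2, pi_channel = FALSE)
  expect_error(
    make_timelapse(p, event_schedule(30, "mitosis", 99L), 15, 60),
    class = "organoidr_unknown_object")
  expect_error(
    make_timelapse(p, event_schedule(120, "mitosis", 1L), 15, 60),
    class = "organoidr_bad_schedule")
})

test_that("plate reads hit the 4PL limits and Bliss product exactly when noiseless", {
  da <- drug_truth(-7, 1)
  db <- drug_truth(-7, 1)
  # concentration far below IC50 behaves like vehicle; far above like plateau
  reads <- make_plate_reads(da, db, conc_a_nM = c(1e-4, 1e8),
                            conc_b_nM = c(1e-4, 1e8),
                            vehicle_signal = 10000, plateau_signal = 500,
                            noise_cv = 0, seed = 1)
  lo <- reads$signal[reads$conc_a_nM == 1e-4 & reads$conc_b_nM == 0]
  hi <- reads$signal[reads$conc_a_nM == 1e8 & reads$conc_b_nM == 0]
  expect_equal(lo, 10000, tolerance = 1e-6)
  expect_equal(hi, 500, tolerance = 1e-3)
  # combination well at per-drug viability 0.5 each -> v = 0.25
  reads2 <- make_plate_reads(da, db, conc_a_nM = 100, conc_b_nM = 100,
                             vehicle_signal = 10000, plateau_signal = 500,
                             noise_cv = 0, seed = 1)
  combo <- reads2$signal[reads2$conc_a_nM == 100 & reads2$conc_b_nM == 100]
  expect_equal(combo, 500 + 0.25 * 9500, tolerance = 1e-9)
})

test_that("plate reads are reproducible under a fixed seed and validate input", {
  da <- drug_truth(-7, 1)
  r1 <- make_plate_reads(da, NULL, conc_a_nM = conc_preset("fig3b"),
                         conc_b_nM = numeric(), noise_cv = 0.1, seed = 9)
  r2 <- make_plate_reads(da, NULL, conc_a_nM = conc_preset("fig3b"),
                         conc_b_nM = numeric(), noise_cv = 0.1, seed = 9)
  expect_identical(r1$signal, r2$signal)
  expect_error(make_plate_reads(da, NULL, conc_a_nM = 10, conc_b_nM = numeric(),
                                noise_cv = -0.1),
               class = "organoidr_bad_argument")
  expect_error(make_plate_reads(da, NULL, conc_a_nM = 10, conc_b_nM = numeric(),
                                vehicle_signal = 100, plateau_signal = 200),
               class = "organoidr_bad_params")
})

test_that("alamarBlue kinetics follow background + v*slope*min(t, sat)", {
  flat <- make_ab_kinetics(0, background_rfu = 120, noise_sd = 0)
  expect_true(all(flat$rfu == 120))
  lin <- make_ab_kinetics(1, background_rfu = 100, slope_rfu_per_h = 200,
                          saturation_t_h = 3, read_times_h = seq(0, 2, 0.25),
                          noise_sd = 0)
  expect_equal(diff(lin$rfu), rep(50, 8))
  s1 <- make_ab_kinetics(0.5, noise_sd = 10, seed = 4)
  s2 <- make_ab_kinetics(0.5, noise_sd = 10, seed = 4)
  expect_identical(s1$rfu, s2$rfu)
  expect_error(make_ab_kinetics(1, read_times_h = c(1, 2)), "start at 0")
})

test_that("conc presets match their published designs", {
  g3 <- conc_preset("fig3b")
  expect_length(g3, 14)
  expect_equal(range(g3), c(5, 5000))
  expect_equal(diff(log10(g3)), rep(diff(log10(c(5, 5000))) / 13, 13))
  g4 <- conc_preset("fig4")
  expect_length(g4, 22)
  expect_equal(range(g4), c(5, 20000))
  expect_length(conc_preset("fig9d"), 9)
})
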