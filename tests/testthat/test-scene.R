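# Ground-truth scene simulator.

test_that("generators are pure functions of (spec, seed)", {
  spec <- scene_spec(width = 48, height = 48, n_frames = 10, background = 25)
  a <- generate_calcium_scene(spec, seed = 5, n_events = 2, margin = 10,
                              min_separation = 10)
  b <- generate_calcium_scene(spec, seed = 5, n_events = 2, margin = 10,
                              min_separation = 10)
  expect_identical(unclass(a$timelapse), unclass(b$timelapse))
  expect_identical(a$truth$events, b$truth$events)
  c <- generate_calcium_scene(spec, seed = 6, n_events = 2, margin = 10,
                              min_separation = 10)
  expect_false(identical(unclass(a$timelapse), unclass(c$timelapse)))
})

test_that("noiseless calcium rendering follows the multiplicative spike model", {
  # no structures, no events, no noise: constant background
  spec0 <- scene_spec(width = 24, height = 24, n_frames = 4, background = 55,
                      shot_noise = FALSE, read_noise_sd = 0)
  sc0 <- generate_calcium_scene(spec0, seed = 1, n_events = 0)
  expect_true(all(sc0$timelapse == 55))
  # a dF/F0 = 1 spike doubles the footprint-centre intensity at onset
  ev <- tibble::tibble(frame = 3L, x = 12, y = 12, amplitude = 1,
                       tau_ms = 400, sigma_px = 2)
  spec1 <- scene_spec(width = 24, height = 24, n_frames = 8, background = 200,
                      shot_noise = FALSE, read_noise_sd = 0, events = ev)
  sc1 <- generate_calcium_scene(spec1, seed = 1)
  centre <- sc1$timelapse[13, 13, ]
  expect_equal(centre[3], 200)              # pre-onset
  expect_equal(centre[4], 400, tolerance = 0.01 * 400)  # onset
  # exponential decay at the scheduled tau (50 ms frames, tau 400 ms)
  expect_equal(centre[6] / 200 - 1, exp(-2 * 50 / 400), tolerance = 0.01)
  # events outside the field are rejected
  bad <- spec1; bad$events$x <- 500
  expect_error(generate_calcium_scene(bad, seed = 1), class = "etsted_spec_error")
})

test_that("camera noise yields integer non-negative counts", {
  spec <- scene_spec(width = 32, height = 32, n_frames = 5, background = 8,
                     shot_noise = TRUE, read_noise_sd = 2)
  sc <- generate_calcium_scene(spec, seed = 3, n_events = 0)
  expect_true(all(sc$timelapse >= 0))
  expect_true(all(sc$timelapse == round(sc$timelapse)))
})

test_that("dynamin scenes ramp linearly by the scheduled ratio", {
  ev <- tibble::tibble(frame = 0L, x = 16, y = 16, i0 = 100, ramp_ratio = 2.6,
                       ramp_frames = 5L, sigma_px = 2)
  spec <- scene_spec(width = 32, height = 32, n_frames = 8, background = 0,
                     shot_noise = FALSE, read_noise_sd = 0, events = ev)
  sc <- generate_dynamin_scene(spec, seed = 1)
  centre <- sc$timelapse[17, 17, ]
  # frames 0..4 ramp 100 -> 260 in equal steps, then hold
  expect_equal(centre[1:5] / centre[1], c(1, 1.4, 1.8, 2.2, 2.6),
               tolerance = 1e-9)
  expect_equal(centre[6:8], rep(centre[5], 3), tolerance = 1e-9)
  # ramp_ratio 1 gives a flat spot
  ev2 <- ev; ev2$ramp_ratio <- 1
  spec2 <- spec; spec2$events <- ev2
  sc2 <- generate_dynamin_scene(spec2, seed = 1)
  expect_equal(diff(sc2$timelapse[17, 17, ]), rep(0, 7), tolerance = 1e-9)
})

test_that("vesicle scenes honour diffusion, scripts and emitter counts", {
  spec <- scene_spec(width = 48, height = 48, n_frames = 25, background = 5,
                     shot_noise = FALSE, read_noise_sd = 0)
  # D = 0, no scripts: trajectories constant
  ves <- tibble::tibble(x = c(12, 30), y = c(12, 30), amplitude = 100, sigma = 1)
  sc <- generate_vesicle_scene(spec, seed = 2, vesicles = ves, d_um2_s = 0)
  tr <- sc$truth$trajectories
  for (v in 1:2) {
    expect_equal(length(unique(tr$x[tr$vesicle == v])), 1L)
    expect_equal(length(unique(tr$y[tr$vesicle == v])), 1L)
  }
  # scripted merge: rendered spot count drops by one at the merge frame
  sc2 <- generate_vesicle_scene(spec, seed = 2, vesicles = ves, d_um2_s = 0,
                                scripts = list(list(mover = 2, target = 1,
                                                    start_frame = 4,
                                                    merge_frame = 20)))
  tr2 <- sc2$truth$trajectories
  n_present <- tapply(tr2$present, tr2$frame, sum)
  expect_equal(as.numeric(n_present[as.character(19)]), 2)
  expect_equal(as.numeric(n_present[as.character(20)]), 1)
  expect_equal(sc2$truth$merges$frame, 20)
  # frame intensity integral drops accordingly in the noiseless render
  sums <- apply(sc2$timelapse, 3, sum)
  expect_lt(sums[21], sums[19] - 0.5 * sum(add_spot(matrix(0, 48, 48),
                                                    12, 12, 100, 1)))
})

test_that("Brownian track ensembles follow the 4 D dt law", {
  tracks <- simulate_brownian_tracks(50, 100, d_um2_s = 0.01, dt_s = 0.4,
                                     seed = 13)
  msd <- msd_ensemble(tracks, dt_frames = 1:3)
  expect_equal(msd$msd / (4 * 0.01 * 0.4 * (1:3)), rep(1, 3), tolerance = 0.1)
})

test_that("bead fields support exact and noisy calibration", {
  truth <- random_cubic_transform(magnitude = 1e-6, seed = 51)
  exact <- generate_bead_field(truth, n = 40, detection_noise_px = 0, seed = 52)
  fit <- fit_transform(exact)
  rep <- accuracy_report(fit, exact, pixel_size_nm = 100)
  expect_lt(attr(rep, "mean_error_px"), 1e-6)
  expect_error(generate_bead_field(truth, n = 5, seed = 1),
               class = "etsted_parameter_error")
  # seeded determinism
  a <- generate_bead_field(truth, 20, 0.5, seed = 53)
  b <- generate_bead_field(truth, 20, 0.5, seed = 53)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("scan ROI rendering honours geometry exactly", {
  spec <- scene_spec(width = 64, height = 64, n_frames = 4, background = 10,
                     shot_noise = FALSE, read_noise_sd = 0)
  sc <- generate_calcium_scene(spec, seed = 1, n_events = 0)
  # 1 x 1 um^2 at 25 nm -> 40 x 40 px
  stack <- render_scan_roi(sc, center = c(32, 32), size_um = 1, pixel_nm = 25,
                           frames = 3, noise = FALSE)
  expect_equal(dim(stack), c(40L, 40L, 3L))
  # empty truth: background-only
  expect_equal(length(unique(as.numeric(stack))), 1L)
  # a single emitter at the ROI centre peaks at the stack centre
  spec2 <- scene_spec(width = 64, height = 64, n_frames = 4, background = 10,
                      shot_noise = FALSE, read_noise_sd = 0,
                      structures = tibble::tibble(x = 32, y = 32,
                                                  amplitude = 200, sigma = 1))
  sc2 <- generate_calcium_scene(spec2, seed = 1, n_events = 0)
  st2 <- render_scan_roi(sc2, c(32, 32), size_um = 1, pixel_nm = 25,
                         frames = 1, noise = FALSE)
  peak <- which(st2[, , 1] == max(st2[, , 1]), arr.ind = TRUE)
  expect_true(all(abs(peak - 20.5) <= 1.5))
  # out-of-bounds ROI is rejected
  expect_error(render_scan_roi(sc, c(2, 2), size_um = 1, pixel_nm = 25),
               class = "etsted_roi_error")
})
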