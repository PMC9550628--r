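# The three real-time detection pipelines and their interface contract.

make_two_frames <- function(base = 100, block_value = 200,
                            block_at = c(20, 24), size = 48) {
  prev <- matrix(base, size, size)
  cur <- prev
  rows <- block_at[2]:(block_at[2] + 4) + 1
  cols <- block_at[1]:(block_at[1] + 4) + 1
  cur[rows, cols] <- block_value
  list(prev = prev, cur = cur)
}

test_that("rapid_signal_spikes finds nothing without frame-to-frame change", {
  p <- rapid_spikes_params(border_px = 2)
  st <- pipeline_state("rapid_signal_spikes")
  f <- matrix(100, 32, 32)
  r1 <- rapid_signal_spikes(f, st, NULL, p)     # priming call
  expect_equal(nrow(r1$events), 0L)
  r2 <- rapid_signal_spikes(f, r1$state, NULL, p)
  expect_equal(nrow(r2$events), 0L)
  # the ratiometric map is identically 1 away from the excluded border
  expect_equal(unique(as.numeric(r2$state$last_map[5:28, 5:28])), 1)
})

test_that("rapid_signal_spikes localizes an injected intensity block", {
  fr <- make_two_frames()
  p <- rapid_spikes_params(ratio_threshold = 1.5, border_px = 2)
  st <- pipeline_state("rapid_signal_spikes")
  st <- rapid_signal_spikes(fr$prev, st, NULL, p)$state
  res <- rapid_signal_spikes(fr$cur, st, NULL, p)
  expect_equal(nrow(res$events), 1L)
  # block centre at (22, 26); smoothing blurs the 2.0 ratio down slightly
  expect_lt(abs(res$events$x - 22), 1.5)
  expect_lt(abs(res$events$y - 26), 1.5)
  expect_gt(res$events$salience, 1.7)
  expect_lte(res$events$salience, 2.0 + 1e-9)
  expect_equal(res$events$frame, 1L)
})

test_that("rapid_signal_spikes orders events by ratiometric brightness", {
  prev <- matrix(100, 64, 64)
  cur <- prev
  cur[15:19 + 1, 15:19 + 1] <- 180   # ratio 1.8 at (17, 17)
  cur[40:44 + 1, 40:44 + 1] <- 250   # ratio 2.5 at (42, 42)
  p <- rapid_spikes_params(ratio_threshold = 1.5, border_px = 2)
  st <- rapid_signal_spikes(prev, pipeline_state("rapid_signal_spikes"),
                            NULL, p)$state
  res <- rapid_signal_spikes(cur, st, NULL, p)
  expect_equal(nrow(res$events), 2L)
  expect_equal(order(res$events$salience, decreasing = TRUE), 1:2)
  expect_lt(abs(res$events$x[1] - 42), 1.5)
  expect_lt(abs(res$events$x[2] - 17), 1.5)
})

test_that("pipelines enforce the mask, the border and shape agreement", {
  fr <- make_two_frames()
  p <- rapid_spikes_params(ratio_threshold = 1.5, border_px = 2)
  # masking out the block suppresses the event
  mask <- matrix(TRUE, 48, 48); mask[20:30, 15:30] <- FALSE
  st <- rapid_signal_spikes(fr$prev, pipeline_state("x"), mask, p)$state
  expect_equal(nrow(rapid_signal_spikes(fr$cur, st, mask, p)$events), 0L)
  # a block inside the border-exclusion strip is ignored
  fr2 <- make_two_frames(block_at = c(0, 0))
  p2 <- rapid_spikes_params(ratio_threshold = 1.5, border_px = 8)
  st2 <- rapid_signal_spikes(fr2$prev, pipeline_state("x"), NULL, p2)$state
  expect_equal(nrow(rapid_signal_spikes(fr2$cur, st2, NULL, p2)$events), 0L)
  # mask of the wrong shape is a structural error
  expect_error(rapid_signal_spikes(fr$cur, pipeline_state("x"),
                                   matrix(TRUE, 3, 3), p),
               class = "etsted_structural_error")
})

dynamin_ramp_scene <- function(ramp_ratio) {
  ev <- tibble::tibble(frame = 0L, x = 30, y = 32, i0 = 100,
                       ramp_ratio = ramp_ratio, ramp_frames = 5L, sigma_px = 2)
  spec <- scene_spec(width = 64, height = 64, n_frames = 10, background = 0,
                     shot_noise = FALSE, read_noise_sd = 0, events = ev)
  generate_dynamin_scene(spec, seed = 1)
}

dynamin_test_params <- function(...) {
  dynamin_rise_params(trace_length = 5, rise_ratio = 2, low_threshold = 1,
                      high_threshold = 1e5, border_px = 5,
                      background_sigma = 10, ...)
}

test_that("dynamin_rise triggers once on a sufficient rise, at the trace end", {
  sc <- dynamin_ramp_scene(2.6)
  ev <- detect_events(sc$timelapse, "dynamin_rise", dynamin_test_params())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$frame, 4L)            # exactly when the trace age reaches N
  expect_equal(c(ev$x, ev$y), c(30, 32))
  expect_equal(ev$salience, 2.6, tolerance = 0.05)
})

test_that("dynamin_rise stays silent below threshold and on flat spots", {
  expect_equal(nrow(detect_events(dynamin_ramp_scene(1.8)$timelapse,
                                  "dynamin_rise", dynamin_test_params())), 0L)
  # a stationary constant-intensity spot never fires (ratio 1)
  expect_equal(nrow(detect_events(dynamin_ramp_scene(1.0)$timelapse,
                                  "dynamin_rise", dynamin_test_params())), 0L)
})

test_that("dynamin_rise stored box intensities reproduce the scheduled ramp", {
  sc <- dynamin_ramp_scene(2.6)
  p <- dynamin_test_params()
  st <- pipeline_state("dynamin_rise")
  for (i in 0:4) {
    st <- dynamin_rise(get_frame(sc$timelapse, i), st, NULL, p)$state
  }
  tr <- st$linker$tracks[[1]]
  # preprocessing is linear in the frame, so the box-intensity trace is a
  # fixed multiple of the scheduled 100 -> 260 ramp
  expect_equal(tr$rows$intensity / tr$rows$intensity[1],
               c(1, 1.4, 1.8, 2.2, 2.6), tolerance = 1e-6)
})

test_that("dynamin_rise validates its trace-capacity precondition", {
  expect_error(dynamin_rise_params(trace_length = 30, history_frames = 20),
               class = "etsted_parameter_error")
  expect_error(dynamin_rise_params(low_threshold = 10, high_threshold = 5),
               class = "etsted_parameter_error")
})

test_that("vesicle_proximity fires once per approach-and-merge pair", {
  sc <- vesicle_merge_scene(seed = 1, merged = TRUE)
  ev <- detect_events(sc$timelapse, "vesicle_proximity",
                      vesicle_benchmark_params())
  expect_equal(nrow(ev), 1L)
  d <- sqrt((ev$x - sc$truth$merges$x)^2 + (ev$y - sc$truth$merges$y)^2)
  expect_lt(d, 3)
})

test_that("vesicle_proximity ignores stationary pairs and lone disappearances", {
  # two stationary vesicles 20 px apart: conditions 2 and 5 both fail
  spec <- scene_spec(width = 48, height = 48, n_frames = 30, background = 10)
  ves <- tibble::tibble(x = c(14, 34), y = c(24, 24), amplitude = 150,
                        sigma = 0.8)
  sc <- generate_vesicle_scene(spec, seed = 7, vesicles = ves, d_um2_s = 0)
  expect_equal(nrow(detect_events(sc$timelapse, "vesicle_proximity",
                                  vesicle_benchmark_params())), 0L)
  # a solitary vesicle photobleaching (track closes, nothing within r_prox):
  # hand-built frames, one moving spot vanishing at frame 18
  frames <- lapply(0:29, function(f) {
    if (f > 17) return(matrix(10, 48, 48))
    add_spot(matrix(10, 48, 48), 10 + 0.6 * f, 24, 150, 0.8)
  })
  tl <- wf_timelapse(frames)
  expect_equal(nrow(detect_events(tl, "vesicle_proximity",
                                  vesicle_benchmark_params())), 0L)
})

test_that("the pipeline interface contract supports stateful replay", {
  # frame-by-frame replay with carried state equals the batched evaluation,
  # and equals what the controller sees in validation mode
  sc <- calcium_benchmark_scene(seed = 2, n_events = 3)
  p <- rapid_spikes_params()
  batch <- detect_events(sc$timelapse, "rapid_signal_spikes", p)
  st <- pipeline_state("rapid_signal_spikes")
  manual <- list()
  for (i in seq_len(n_frames(sc$timelapse)) - 1L) {
    res <- rapid_signal_spikes(get_frame(sc$timelapse, i), st, NULL, p)
    st <- res$state
    manual[[i + 1L]] <- res$events
  }
  expect_equal(dplyr::bind_rows(manual), batch)
  cfg <- acquisition_config(pipeline = "rapid_signal_spikes", params = p,
                            mode = "validation")
  rec <- run_experiment(scene_source(sc), cfg, identity_transform(200, 200))
  expect_equal(rec$events[, c("frame", "x", "y", "salience")],
               batch[, c("frame", "x", "y", "salience")])
  # determinism: a fresh replay yields the identical event stream
  expect_identical(batch, detect_events(sc$timelapse, "rapid_signal_spikes", p))
})

test_that("emitted coordinates respect mask and border on noisy benchmarks", {
  sc <- calcium_benchmark_scene(seed = 8, n_events = 5)
  p <- rapid_spikes_params()   # border_px 10
  ev <- detect_events(sc$timelapse, "rapid_signal_spikes", p)
  expect_true(all(ev$x >= 10 & ev$x <= 189 & ev$y >= 10 & ev$y <= 189))
  expect_true(all(ev$salience >= p$ratio_threshold))
})

test_that("pipelines are discoverable by their instrument names", {
  for (nm in c("rapid_signal_spikes", "dynamin_rise", "vesicle_proximity")) {
    pl <- get_pipeline(nm)
    expect_true(is.function(pl$fn))
    expect_true(is.function(pl$default_params))
  }
  expect_error(get_pipeline("nope"), class = "etsted_parameter_error")
})
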