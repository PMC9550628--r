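# Post-acquisition quantification.

test_that("dF/F0 traces follow the defining formula", {
  tl <- wf_timelapse(array(80, dim = c(20, 20, 6)))
  tr <- dff0_trace(tl, c(10, 10), radius_px = 3)
  expect_equal(tr$dff0, rep(0, 6))
  # disc mean doubling at frame 5 gives dF/F0 = 1 from frame 5
  arr <- array(50, dim = c(20, 20, 8)); arr[, , 6:8] <- 100
  tr2 <- dff0_trace(wf_timelapse(arr), c(10, 10), radius_px = 2,
                    baseline_frames = 3)
  expect_equal(tr2$dff0, c(rep(0, 5), rep(1, 3)))
  # invariant under global gain
  tr3 <- dff0_trace(wf_timelapse(arr * 7), c(10, 10), radius_px = 2,
                    baseline_frames = 3)
  expect_equal(tr2$dff0, tr3$dff0)
  # invalid baseline
  z <- array(0, dim = c(10, 10, 3))
  expect_error(dff0_trace(wf_timelapse(z), c(5, 5), radius_px = 2),
               class = "etsted_parameter_error")
  expect_error(dff0_trace(wf_timelapse(arr), c(0, 0), radius_px = 3),
               class = "etsted_parameter_error")
})

test_that("dF/F0 recovers the scheduled spike kinetics of a noiseless scene", {
  ev <- tibble::tibble(frame = 4L, x = 20, y = 20, amplitude = 0.8,
                       tau_ms = 400, sigma_px = 5)
  spec <- scene_spec(width = 40, height = 40, n_frames = 20, background = 150,
                     shot_noise = FALSE, read_noise_sd = 0, events = ev)
  sc <- generate_calcium_scene(spec, seed = 1)
  tr <- dff0_trace(sc$timelapse, c(20, 20), radius_px = 1, baseline_frames = 3)
  t_rel <- (tr$frame - 4) * 50
  want <- ifelse(t_rel < 0, 0, 0.8 * exp(-t_rel / 400))
  expect_equal(tr$dff0, want, tolerance = 0.02)
})

test_that("detection quality ratios count greedy one-to-one matches", {
  det <- tibble::tibble(frame = c(1, 5, 9), x = c(10, 20, 30),
                        y = c(10, 20, 30))
  q <- evaluate_detection(det, det, r_tol = 2, t_tol = 1)
  expect_equal(c(q$true_ratio, q$det_ratio), c(1, 1))
  # 10 annotations, 9 detections of which 8 match
  ann <- tibble::tibble(frame = seq(0, 90, 10), x = seq(10, 100, 10), y = 50)
  det2 <- tibble::tibble(frame = c(seq(0, 70, 10), 55),
                         x = c(seq(10, 80, 10), 200), y = 50)
  q2 <- evaluate_detection(det2, ann, r_tol = 3, t_tol = 2)
  expect_equal(q2$true_ratio, 8 / 9, tolerance = 1e-12)
  expect_equal(q2$det_ratio, 0.8, tolerance = 1e-12)
  # no detections: true ratio undefined but flagged, det ratio 0
  q3 <- evaluate_detection(det2[0, ], ann, r_tol = 3, t_tol = 2)
  expect_true(is.na(q3$true_ratio))
  expect_false(q3$true_ratio_defined)
  expect_equal(q3$det_ratio, 0)
})

test_that("detection matching is invariant to detection order", {
  set.seed(17)
  ann <- tibble::tibble(frame = sample(0:50, 12), x = runif(12, 0, 80),
                        y = runif(12, 0, 80))
  det <- dplyr::bind_rows(
    dplyr::mutate(ann[1:9, ], x = x + rnorm(9, 0, 0.5), frame = frame),
    tibble::tibble(frame = c(3, 44), x = c(200, 300), y = c(5, 5)))
  q1 <- evaluate_detection(det, ann, r_tol = 3, t_tol = 1)
  perm <- det[sample(nrow(det)), ]
  q2 <- evaluate_detection(perm, ann, r_tol = 3, t_tol = 1)
  expect_equal(q1$true_ratio, q2$true_ratio)
  expect_equal(q1$det_ratio, q2$det_ratio)
})

test_that("histogram matching is exact on distinct values and monotone always", {
  set.seed(31)
  base <- matrix(runif(400, 10, 1000), 20, 20)   # all-distinct a.s.
  arr <- array(c(base, 0.5 * base), dim = c(20, 20, 2))
  out <- bleach_correct_histogram_match(wf_timelapse(arr), 0L)
  expect_identical(out[, , 1], base)             # reference unchanged
  expect_equal(sort(as.numeric(out[, , 2])), sort(as.numeric(base)),
               tolerance = 1e-12)
  # monotone on tied integer data
  set.seed(32)
  a <- matrix(rpois(400, 20), 20, 20)
  b <- matrix(rpois(400, 10), 20, 20)
  out2 <- bleach_correct_histogram_match(wf_timelapse(array(c(a, b),
                                                            dim = c(20, 20, 2))), 0L)
  v <- as.numeric(b); w <- as.numeric(out2[, , 2])
  ord <- order(v)
  expect_true(all(diff(w[ord]) >= -1e-9))
  expect_true(all(tapply(w, v, function(x) length(unique(x))) == 1))
})

test_that("histogram matching corrects an exponentially bleached movie", {
  set.seed(33)
  base <- matrix(rpois(900, 60) + runif(900, 0, 0.01), 30, 30)
  frames <- lapply(0:9, function(k) base * exp(-0.08 * k))
  tl <- wf_timelapse(frames)
  out <- bleach_correct_histogram_match(tl, 0L)
  means <- apply(out, 3, mean)
  expect_true(all(abs(means - mean(base)) / mean(base) < 0.02))
})

test_that("cluster segmentation measures a rasterized ellipse correctly", {
  # filled ellipse, semi-axes 20 x 10 px, at 30 nm/px
  img <- matrix(0, 60, 80)
  for (i in 1:60) for (j in 1:80) {
    if (((j - 40) / 20)^2 + ((i - 30) / 10)^2 <= 1) img[i, j] <- 100
  }
  # threshold at 20% of the plateau: the smoothed edge crosses this level
  # about 0.8 px outside the drawn boundary, compensating the one-pixel
  # erosion, so the measured region matches the drawn ellipse
  regions <- segment_clusters(img, global_threshold = 20, pixel_size_um = 0.03)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$aspect_ratio, 2.0, tolerance = 0.1)
  # area equals the brute-force eroded pixel count times the pixel area
  oracle_mask <- erode3x3_brute(gaussian_smooth(img, 1) >= 20)
  expect_equal(regions$n_pixels, sum(oracle_mask))
  expect_equal(regions$area_um2, sum(oracle_mask) * 0.03^2)
  # centroid at the ellipse centre, in um ((x, y) = (39, 29) zero-based)
  expect_equal(regions$centroid_x_um, 39 * 0.03, tolerance = 0.03)
  expect_equal(regions$centroid_y_um, 29 * 0.03, tolerance = 0.03)
  # the in-package erosion agrees with EBImage's on interior pixels
  if (requireNamespace("EBImage", quietly = TRUE)) {
    bin <- gaussian_smooth(img, 1) >= 20
    eb <- EBImage::erode(EBImage::Image(bin * 1),
                         EBImage::makeBrush(3, "box")) == 1
    interior <- matrix(FALSE, 60, 80); interior[2:59, 2:79] <- TRUE
    expect_identical((erode3x3_brute(bin) & interior), (eb & interior))
  }
})

test_that("objects at or below the minimum area are excluded", {
  # 6x6 block: smoothing at half-max rounds the corners off, and one
  # erosion leaves a 12-px core
  img <- matrix(0, 30, 30); img[14:19, 14:19] <- 100
  # 12 px at 30 nm/px is 0.0108 um^2 <= 0.015: excluded
  expect_equal(nrow(segment_clusters(img, 50, 0.03)), 0L)
  # the same 12 px at 60 nm/px is 0.0432 um^2: retained
  expect_equal(nrow(segment_clusters(img, 50, 0.06)), 1L)
  expect_equal(nrow(segment_clusters(matrix(0, 20, 20), 50, 0.03)), 0L)
  expect_error(segment_clusters(img, 50, -1), class = "etsted_parameter_error")
})

test_that("cluster traces link by minimum distance with the 0.3 um step limit", {
  reg <- function(f, x, y, area = 0.1) {
    tibble::tibble(frame = f, label = 1L, area_um2 = area, aspect_ratio = 1,
                   centroid_x_um = x, centroid_y_um = y, n_pixels = 100L)
  }
  # one stationary cluster over 10 frames: a single trace
  r1 <- dplyr::bind_rows(lapply(0:9, function(f) reg(f, 1, 1)))
  t1 <- link_cluster_traces(r1)
  expect_equal(length(unique(t1$trace)), 1L)
  expect_equal(nrow(t1), 10L)
  # a 0.5 um jump splits the trace
  r2 <- dplyr::bind_rows(lapply(0:4, function(f) reg(f, 1, 1)),
                         lapply(5:9, function(f) reg(f, 1.5, 1)))
  expect_equal(length(unique(link_cluster_traces(r2)$trace)), 2L)
  # two clusters 2 um apart drifting 0.1 um/frame: no identity swap
  r3 <- dplyr::bind_rows(
    lapply(0:9, function(f) reg(f, 0 + 0.1 * f, 0)),
    lapply(0:9, function(f) reg(f, 0 + 0.1 * f, 2)))
  t3 <- link_cluster_traces(r3)
  expect_equal(length(unique(t3$trace)), 2L)
  for (id in unique(t3$trace)) {
    expect_equal(length(unique(t3$y[t3$trace == id])), 1L)
  }
  # the trace seeded by the largest first-frame cluster carries the MSD flag
  r4 <- dplyr::bind_rows(lapply(0:5, function(f) reg(f, 1, 1, area = 0.5)),
                         lapply(0:5, function(f) reg(f, 3, 3, area = 0.2)))
  t4 <- link_cluster_traces(r4)
  flagged <- unique(t4$trace[t4$msd_flag])
  expect_equal(length(flagged), 1L)
  expect_equal(unique(t4$x[t4$trace == flagged]), 1)
})

test_that("MSD reproduces closed forms in both modes", {
  still <- tibble::tibble(frame = 0:9, x = 2, y = 3)
  expect_equal(compute_msd(still, 1)$msd, 0)
  expect_equal(compute_msd(still, 1, mode = "literal_distance")$msd, 0)
  # uniform motion 0.1 um/frame, lag 3: squared 0.09 um^2, literal 0.3 um
  uni <- tibble::tibble(frame = 0:19, x = 0.1 * (0:19), y = 0)
  expect_equal(compute_msd(uni, 3)$msd, 0.09, tolerance = 1e-12)
  expect_equal(compute_msd(uni, 3, mode = "literal_distance")$msd, 0.3,
               tolerance = 1e-12)
  expect_equal(compute_msd(uni, 0)$msd, 0)
  expect_error(compute_msd(still, 10), class = "etsted_parameter_error")
  # mode is recorded
  expect_equal(compute_msd(uni, 2)$mode, "squared")
})

test_that("ensemble MSD of Brownian traces is linear in the lag", {
  tracks <- simulate_brownian_tracks(40, 80, d_um2_s = 0.02, dt_s = 0.5,
                                     seed = 77)
  msd <- msd_ensemble(tracks, dt_frames = 1:4)
  slope <- coef(lm(msd ~ dt_frames, data = msd))[["dt_frames"]]
  expect_equal(slope, 4 * 0.02 * 0.5, tolerance = 0.1)
  expect_true(all(msd$msd >= 0))
})
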