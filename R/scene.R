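# Ground-truth scene simulator standing in for the microscope: widefield
# timelapses for the three event classes, bead fields for transform
# calibration, Brownian track ensembles, and a toy high-resolution ROI
# renderer. All generators are pure functions of (spec, seed).

#' Synthetic scene specification
#'
#' Describes a widefield field of view, its camera noise model, stationary
#' structures and scheduled events. The camera model is sCMOS-like: expected
#' photon counts drawn from a Poisson distribution, additive Gaussian read
#' noise, clamped at zero and rounded to integer counts. Disabling both noise
#' sources yields the continuous expected-intensity frames (useful for
#' oracle tests).
#'
#' @param width,height Field size in pixels.
#' @param n_frames Number of frames.
#' @param pixel_size_nm Widefield pixel size (nm); default 100.
#' @param frame_period_ms Frame period (ms); default 50, mirroring the tens
#'   of milliseconds widefield surveillance the method targets.
#' @param background Uniform expected background level (counts).
#' @param shot_noise Apply Poisson shot noise?
#' @param read_noise_sd Gaussian read-noise sigma (counts); 0 disables.
#' @param structures Optional tibble of stationary spots with columns
#'   `x`, `y`, `amplitude`, `sigma` (added to the baseline).
#' @param events Optional tibble of scheduled events; interpretation depends
#'   on the generator (see [generate_calcium_scene()] etc.). If `NULL`,
#'   generators schedule events themselves from their own parameters.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width = 200L, height = 200L, n_frames = 100L,
                       pixel_size_nm = 100, frame_period_ms = 50,
                       background = 30, shot_noise = TRUE, read_noise_sd = 2,
                       structures = NULL, events = NULL) {
  .check_number(width, "width", 1); .check_number(height, "height", 1)
  .check_number(n_frames, "n_frames", 1)
  .check_number(background, "background", 0)
  .check_number(read_noise_sd, "read_noise_sd", 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames),
                 pixel_size_nm = pixel_size_nm,
                 frame_period_ms = frame_period_ms,
                 background = background, shot_noise = isTRUE(shot_noise),
                 read_noise_sd = read_noise_sd,
                 structures = structures, events = events),
            class = "scene_spec")
}

#' Baseline level achieving a given spike signal-to-noise ratio
#'
#' For a multiplicative transient of peak amplitude `A` (dF/F0) on local
#' baseline `B`, the peak signal increment is `A * B` and the per-pixel noise
#' sd at baseline is `sqrt(B + read_noise_sd^2)` (shot + read noise). This
#' returns the baseline `B` for which their ratio equals `snr`.
#'
#' @param amplitude Peak dF/F0 amplitude `A`.
#' @param snr Target peak-increment-to-noise ratio.
#' @param read_noise_sd Read noise sigma in counts.
#' @export
spike_snr_baseline <- function(amplitude = 1, snr = 5, read_noise_sd = 2) {
  s2 <- snr^2
  (s2 + sqrt(s2^2 + 4 * amplitude^2 * s2 * read_noise_sd^2)) / (2 * amplitude^2)
}

# Run expr with a private, restored RNG stream.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Add a 2-D Gaussian of peak `amp`, centre (x, y) (0-based), sd `sigma` to `m`
# over a +/- 5 sigma window.
.add_gaussian <- function(m, x, y, amp, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  r <- ceiling(5 * sigma)
  rows <- max(1L, floor(y + 1 - r)):min(nr, ceiling(y + 1 + r))
  cols <- max(1L, floor(x + 1 - r)):min(nc, ceiling(x + 1 + r))
  if (!length(rows) || !length(cols)) return(m)
  gy <- exp(-((rows - 1 - y)^2) / (2 * sigma^2))
  gx <- exp(-((cols - 1 - x)^2) / (2 * sigma^2))
  m[rows, cols] <- m[rows, cols] + amp * outer(gy, gx)
  m
}

.baseline_field <- function(spec) {
  b <- matrix(spec$background, spec$height, spec$width)
  if (!is.null(spec$structures) && nrow(spec$structures) > 0L) {
    for (k in seq_len(nrow(spec$structures))) {
      s <- spec$structures[k, ]
      b <- .add_gaussian(b, s$x, s$y, s$amplitude, s$sigma)
    }
  }
  b
}

.apply_camera_noise <- function(expected, spec) {
  if (!spec$shot_noise && spec$read_noise_sd == 0) return(expected)
  v <- as.numeric(expected)
  if (spec$shot_noise) v <- rpois(length(v), pmax(v, 0))
  if (spec$read_noise_sd > 0) v <- v + rnorm(length(v), 0, spec$read_noise_sd)
  matrix(pmax(round(v), 0), nrow(expected), ncol(expected))
}

# Schedule event sites uniformly with a border margin and minimum separation.
.schedule_sites <- function(n, width, height, margin, min_sep, max_tries = 5000L) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < max_tries) {
    tries <- tries + 1L
    x <- runif(1, margin, width - 1 - margin)
    y <- runif(1, margin, height - 1 - margin)
    if (!length(xs) || all(.dist2d(x, y, xs, ys) >= min_sep)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < n) .err("could not place event sites", "etsted_spec_error")
  tibble(x = xs, y = ys)
}

.check_events_inside <- function(ev, spec) {
  if (any(ev$x < 0 | ev$x > spec$width - 1 | ev$y < 0 | ev$y > spec$height - 1) ||
      any(ev$frame < 0 | ev$frame > spec$n_frames - 1)) {
    .err("scheduled events fall outside the field or frame range",
         "etsted_spec_error")
  }
  invisible(ev)
}

#' Simulate a calcium-activity scene
#'
#' Renders stationary baseline structures plus scheduled local transients:
#' inside a Gaussian spatial footprint the baseline intensity is multiplied
#' by `1 + A * exp(-(t - t_on)/tau)` for `t >= t_on` — an instantaneous spike
#' with exponential decay, the characteristic shape of calcium-indicator
#' activity. Camera noise is applied last. The multiplicative form makes the
#' dF/F0 amplitude independent of the local baseline brightness.
#'
#' If `spec$events` is `NULL`, `n_events` spikes are scheduled at random
#' sites (>= `margin` px from the border, >= `min_separation` px apart) and
#' random onset frames.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param n_events,amplitude,tau_ms,sigma_spot_px Scheduling defaults used
#'   when `spec$events` is `NULL`: number of spikes, peak dF/F0, decay time
#'   constant (ms) and footprint sigma (px).
#' @param margin,min_separation Site-placement constraints (px).
#' @return A list of class `et_scene` with elements `timelapse`
#'   ([wf_timelapse()]), `truth` (ground-truth record: `events` tibble with
#'   `frame`, `x`, `y`, `amplitude`, `tau_ms`, `sigma_px`) and `spec`.
#' @export
generate_calcium_scene <- function(spec, seed, n_events = 10L, amplitude = 1,
                                   tau_ms = 400, sigma_spot_px = 2,
                                   margin = 15, min_separation = 20) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(derive_seed(seed, "calcium"), {
    ev <- spec$events
    if (is.null(ev)) {
      if (n_events > 0L) {
        sites <- .schedule_sites(n_events, spec$width, spec$height,
                                 margin, min_separation)
        ev <- tibble(frame = sort(sample(2:(spec$n_frames - 5L), n_events,
                                         replace = FALSE)),
                     x = sites$x, y = sites$y,
                     amplitude = amplitude, tau_ms = tau_ms,
                     sigma_px = sigma_spot_px)
      } else {
        ev <- tibble(frame = integer(), x = numeric(), y = numeric(),
                     amplitude = numeric(), tau_ms = numeric(),
                     sigma_px = numeric())
      }
    }
    if (nrow(ev)) .check_events_inside(ev, spec)
    base <- .baseline_field(spec)
    frames <- vector("list", spec$n_frames)
    for (t in seq_len(spec$n_frames) - 1L) {
      mult <- matrix(1, spec$height, spec$width)
      act <- ev[ev$frame <= t, , drop = FALSE]
      if (nrow(act)) {
        for (k in seq_len(nrow(act))) {
          e <- act[k, ]
          decay <- exp(-(t - e$frame) * spec$frame_period_ms / e$tau_ms)
          mult <- .add_gaussian(mult, e$x, e$y, e$amplitude * decay, e$sigma_px)
        }
      }
      frames[[t + 1L]] <- .apply_camera_noise(base * mult, spec)
    }
    structure(list(timelapse = wf_timelapse(frames, spec$pixel_size_nm,
                                            spec$frame_period_ms),
                   truth = list(kind = "calcium", events = ev),
                   spec = spec),
              class = "et_scene")
  })
}

#' Simulate a slowly-rising (protein recruitment) scene
#'
#' Scheduled spots ramp linearly from peak intensity `I0` to `r * I0` over
#' `M` frames starting at their onset frame, then hold — emulating the
#' roughly one-second local accumulation of a recruited protein at an
#' endocytic site. Rendering is additive on the background.
#'
#' If `spec$events` is `NULL`, `n_events` spots are scheduled with the given
#' kinetics; columns of the events tibble: `frame` (onset), `x`, `y`, `i0`,
#' `ramp_ratio`, `ramp_frames`, `sigma_px`.
#'
#' @inheritParams generate_calcium_scene
#' @param i0,ramp_ratio,ramp_frames,sigma_spot_px Scheduling defaults.
#' @export
generate_dynamin_scene <- function(spec, seed, n_events = 5L, i0 = 100,
                                   ramp_ratio = 2.6, ramp_frames = 5L,
                                   sigma_spot_px = 2, margin = 15,
                                   min_separation = 20) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(derive_seed(seed, "dynamin"), {
    ev <- spec$events
    if (is.null(ev)) {
      if (n_events > 0L) {
        sites <- .schedule_sites(n_events, spec$width, spec$height,
                                 margin, min_separation)
        ev <- tibble(frame = sort(sample(0:(spec$n_frames - ramp_frames), n_events,
                                         replace = TRUE)),
                     x = sites$x, y = sites$y, i0 = i0,
                     ramp_ratio = ramp_ratio,
                     ramp_frames = as.integer(ramp_frames),
                     sigma_px = sigma_spot_px)
      } else {
        ev <- tibble(frame = integer(), x = numeric(), y = numeric(),
                     i0 = numeric(), ramp_ratio = numeric(),
                     ramp_frames = integer(), sigma_px = numeric())
      }
    }
    if (nrow(ev)) .check_events_inside(ev, spec)
    base <- .baseline_field(spec)
    frames <- vector("list", spec$n_frames)
    for (t in seq_len(spec$n_frames) - 1L) {
      f <- base
      act <- ev[ev$frame <= t, , drop = FALSE]
      if (nrow(act)) {
        for (k in seq_len(nrow(act))) {
          e <- act[k, ]
          prog <- if (e$ramp_frames > 1L)
            min(t - e$frame, e$ramp_frames - 1L) / (e$ramp_frames - 1L) else 1
          amp <- e$i0 * (1 + (e$ramp_ratio - 1) * prog)
          f <- .add_gaussian(f, e$x, e$y, amp, e$sigma_px)
        }
      }
      frames[[t + 1L]] <- .apply_camera_noise(f, spec)
    }
    structure(list(timelapse = wf_timelapse(frames, spec$pixel_size_nm,
                                            spec$frame_period_ms),
                   truth = list(kind = "dynamin", events = ev),
                   spec = spec),
              class = "et_scene")
  })
}

#' Simulate diffusing vesicles with scripted approach-and-merge events
#'
#' Point emitters perform 2-D Brownian motion (per-axis step sd
#' `sqrt(2 D dt)`), reflected at a border margin. A scripted
#' approach-and-merge event overrides the mover's Brownian path from
#' `start_frame`, moving it linearly onto the target's position by
#' `merge_frame`; from `merge_frame` on the two emitters are unresolvable and
#' the mover is no longer rendered (its truth trajectory ends).
#'
#' @inheritParams generate_calcium_scene
#' @param vesicles Tibble with columns `x`, `y`, `amplitude`, `sigma`
#'   (initial positions, px; brightness; PSF sigma, px). If `NULL`,
#'   `n_vesicles` are placed at random sites.
#' @param n_vesicles,amplitude,sigma_spot_px Placement defaults when
#'   `vesicles` is `NULL`.
#' @param d_um2_s Diffusion coefficient (um^2/s).
#' @param scripts Optional list of scripted events, each
#'   `list(mover =, target =, start_frame =, merge_frame =)` (vesicle row
#'   indices), with optional `profile = "linear"` to override the default
#'   smoothstep (ease-in-out) approach.
#' @param margin Border margin (px) for placement and reflection.
#' @return An `et_scene`; `truth$trajectories` is a tibble
#'   (`vesicle`, `frame`, `x`, `y`, `present`), `truth$merges` a tibble
#'   (`frame`, `x`, `y`, `mover`, `target`).
#' @export
generate_vesicle_scene <- function(spec, seed, vesicles = NULL, n_vesicles = 5L,
                                   amplitude = 150, sigma_spot_px = 1.2,
                                   d_um2_s = 0.01, scripts = list(),
                                   margin = 8) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(derive_seed(seed, "vesicle"), {
    if (is.null(vesicles)) {
      sites <- .schedule_sites(n_vesicles, spec$width, spec$height,
                               margin, 4 * sigma_spot_px)
      vesicles <- tibble(x = sites$x, y = sites$y, amplitude = amplitude,
                         sigma = sigma_spot_px)
    }
    nv <- nrow(vesicles); nt <- spec$n_frames
    dt_s <- spec$frame_period_ms / 1000
    sd_px <- sqrt(2 * d_um2_s * dt_s) * 1000 / spec$pixel_size_nm
    X <- matrix(0, nt, nv); Y <- matrix(0, nt, nv)
    present <- matrix(TRUE, nt, nv)
    X[1L, ] <- vesicles$x; Y[1L, ] <- vesicles$y
    if (nt > 1L) for (t in 2:nt) {
      X[t, ] <- pmin(pmax(X[t - 1L, ] + rnorm(nv, 0, sd_px),
                          margin), spec$width - 1 - margin)
      Y[t, ] <- pmin(pmax(Y[t - 1L, ] + rnorm(nv, 0, sd_px),
                          margin), spec$height - 1 - margin)
    }
    merges <- tibble(frame = integer(), x = numeric(), y = numeric(),
                     mover = integer(), target = integer())
    for (sc in scripts) {
      s <- sc$start_frame; m <- sc$merge_frame
      stopifnot(s >= 0, m > s, m <= nt - 1L)
      mv <- sc$mover; tg <- sc$target
      u <- (seq(s, m) - s) / (m - s)
      # ease-in-out (smoothstep) by default: an approaching vesicle
      # decelerates as it docks, so its last resolvable detection lies at
      # the merge separation instead of overshooting it
      frac <- if (identical(sc$profile, "linear")) u else u^2 * (3 - 2 * u)
      # move linearly from the mover's position at script start onto the
      # target's (possibly diffusing) position, frame by frame
      X[(s:m) + 1L, mv] <- X[s + 1L, mv] + frac * (X[(s:m) + 1L, tg] - X[s + 1L, mv])
      Y[(s:m) + 1L, mv] <- Y[s + 1L, mv] + frac * (Y[(s:m) + 1L, tg] - Y[s + 1L, mv])
      if (m < nt - 1L) present[(m + 2L):nt, mv] <- FALSE
      present[m + 1L, mv] <- FALSE  # merged: rendered as a single emitter
      merges <- bind_rows(merges,
                          tibble(frame = m, x = X[m + 1L, tg], y = Y[m + 1L, tg],
                                 mover = mv, target = tg))
    }
    frames <- vector("list", nt)
    for (t in seq_len(nt)) {
      f <- matrix(spec$background, spec$height, spec$width)
      for (v in seq_len(nv)) {
        if (present[t, v]) {
          f <- .add_gaussian(f, X[t, v], Y[t, v], vesicles$amplitude[v],
                             vesicles$sigma[v])
        }
      }
      frames[[t]] <- .apply_camera_noise(f, spec)
    }
    traj <- tibble(vesicle = rep(seq_len(nv), each = nt),
                   frame = rep(seq_len(nt) - 1L, nv),
                   x = as.numeric(X), y = as.numeric(Y),
                   present = as.logical(present))
    structure(list(timelapse = wf_timelapse(frames, spec$pixel_size_nm,
                                            spec$frame_period_ms),
                   truth = list(kind = "vesicle", trajectories = traj,
                                merges = merges, vesicles = vesicles),
                   spec = spec),
              class = "et_scene")
  })
}

#' Simulate a bead calibration field
#'
#' Scatters `n` beads uniformly over the widefield domain, maps them with the
#' ground-truth transform into scan space and perturbs the scan-side
#' "detections" with isotropic Gaussian noise of sd `detection_noise_px` —
#' emulating the bead-based calibration of the widefield-to-scan transform.
#'
#' @param true_transform Either a `poly_transform2d` or a function taking a
#'   tibble with `x`, `y` and returning the mapped tibble.
#' @param n Number of beads (>= 10).
#' @param detection_noise_px Isotropic detection noise sd in px.
#' @param seed Integer seed.
#' @param width,height Widefield domain extent (px).
#' @return A [control_points()] tibble; the noiseless scan positions are
#'   attached as attribute `truth`.
#' @export
generate_bead_field <- function(true_transform, n, detection_noise_px = 0,
                                seed = 1L, width = 200, height = 200) {
  if (n < 10) .err("at least 10 beads are required", "etsted_parameter_error")
  .with_seed(derive_seed(seed, "beads"), {
    src <- tibble(x = runif(n, 0, width - 1), y = runif(n, 0, height - 1))
    dst <- if (is.function(true_transform)) true_transform(src) else
      apply_transform(true_transform, src)
    pts <- control_points(src$x, src$y,
                          dst$x + rnorm(n, 0, detection_noise_px),
                          dst$y + rnorm(n, 0, detection_noise_px))
    attr(pts, "truth") <- tibble(x_scan_true = dst$x, y_scan_true = dst$y)
    pts
  })
}

#' Random ground-truth cubic transform
#'
#' Identity plus third-order polynomial perturbation with coefficients drawn
#' uniformly in `[-magnitude, magnitude]` on raw pixel coordinates; returned
#' as a plain evaluation function usable as `true_transform` in
#' [generate_bead_field()]. Knowing the generating truth makes fitted
#' transforms testable without real bead data.
#'
#' @param magnitude Coefficient magnitude on raw px monomials.
#' @param seed Integer seed.
#' @export
random_cubic_transform <- function(magnitude = 1e-6, seed = 1L) {
  .with_seed(derive_seed(seed, "cubic"), {
    ex <- .poly_exponents()
    cx <- runif(nrow(ex), -magnitude, magnitude)
    cy <- runif(nrow(ex), -magnitude, magnitude)
    f <- function(coords) {
      A <- .poly_design(coords$x, coords$y)
      tibble(x = coords$x + as.numeric(A %*% cx),
             y = coords$y + as.numeric(A %*% cy))
    }
    attr(f, "coef_x") <- cx
    attr(f, "coef_y") <- cy
    f
  })
}

#' Brownian track ensemble
#'
#' Pure 2-D Brownian trajectories in micrometres (per-axis step sd
#' `sqrt(2 D dt)`), for benchmarking MSD estimation: the ensemble MSD at lag
#' `k` frames should approach `4 D k dt`.
#'
#' @param n_tracks,n_steps Ensemble size.
#' @param d_um2_s Diffusion coefficient (um^2/s).
#' @param dt_s Frame interval (s).
#' @param seed Integer seed.
#' @return Tibble with `track`, `frame`, `x`, `y` (um).
#' @export
simulate_brownian_tracks <- function(n_tracks, n_steps, d_um2_s, dt_s, seed = 1L) {
  .with_seed(derive_seed(seed, "brownian"), {
    sd_um <- sqrt(2 * d_um2_s * dt_s)
    out <- lapply(seq_len(n_tracks), function(tr) {
      tibble(track = tr, frame = 0:(n_steps - 1L),
             x = cumsum(c(0, rnorm(n_steps - 1L, 0, sd_um))),
             y = cumsum(c(0, rnorm(n_steps - 1L, 0, sd_um))))
    })
    bind_rows(out)
  })
}

#' Render a triggered high-resolution scan ROI
#'
#' Toy STED-like renderer: draws the scene's emitters at scan sampling with a
#' narrow Gaussian PSF. Frame count and ROI size are honoured exactly (for
#' example 3 x 3 um^2 at 25 nm/px gives 120 x 120 px frames). For vesicle
#' scenes the emitters continue along their ground-truth trajectories,
#' frame-for-frame from `start_frame`; other scenes render their stationary
#' structures and event sites.
#'
#' @param scene An `et_scene`.
#' @param center Length-2 numeric `(x, y)` scan-ROI centre in widefield px.
#' @param size_um ROI side length (um).
#' @param pixel_nm Scan pixel size (nm), typically 25-30.
#' @param frames Number of scan frames.
#' @param psf_fwhm_nm Rendered PSF full width at half maximum (nm).
#' @param start_frame Widefield frame index at which the scan begins.
#' @param noise Apply the scene's camera noise model?
#' @return A 3-D array `[row, col, frame]` of scan counts.
#' @export
render_scan_roi <- function(scene, center, size_um, pixel_nm = 25,
                            frames = 1L, psf_fwhm_nm = 40,
                            start_frame = 0L, noise = TRUE) {
  stopifnot(inherits(scene, "et_scene"), length(center) == 2L)
  spec <- scene$spec
  half_wf <- size_um * 1000 / 2 / spec$pixel_size_nm
  if (center[1L] - half_wf < 0 || center[1L] + half_wf > spec$width - 1 ||
      center[2L] - half_wf < 0 || center[2L] + half_wf > spec$height - 1) {
    .err("scan ROI exceeds the field bounds", "etsted_roi_error")
  }
  npx <- as.integer(round(size_um * 1000 / pixel_nm))
  sigma_px <- (psf_fwhm_nm / 2.3548) / pixel_nm
  scale <- spec$pixel_size_nm / pixel_nm  # wf px -> scan px
  orig <- center - half_wf               # wf coords of ROI corner
  emitters_at <- function(t) {
    if (identical(scene$truth$kind, "vesicle")) {
      tt <- min(t, max(scene$truth$trajectories$frame))
      tr <- scene$truth$trajectories
      tr <- tr[tr$frame == tt & tr$present, , drop = FALSE]
      tibble(x = tr$x, y = tr$y,
             amplitude = scene$truth$vesicles$amplitude[tr$vesicle])
    } else {
      em <- tibble(x = numeric(), y = numeric(), amplitude = numeric())
      if (!is.null(spec$structures) && NROW(spec$structures)) {
        em <- bind_rows(em, tibble(x = spec$structures$x, y = spec$structures$y,
                                   amplitude = spec$structures$amplitude))
      }
      ev <- scene$truth$events
      if (!is.null(ev) && nrow(ev)) {
        amp <- if ("i0" %in% names(ev)) ev$i0 else 100 * ev$amplitude
        em <- bind_rows(em, tibble(x = ev$x, y = ev$y, amplitude = amp))
      }
      em
    }
  }
  out <- array(0, dim = c(npx, npx, frames))
  for (k in seq_len(frames)) {
    f <- matrix(spec$background / 10, npx, npx)
    em <- emitters_at(start_frame + k - 1L)
    if (nrow(em)) {
      for (e in seq_len(nrow(em))) {
        sx <- (em$x[e] - orig[1L]) * scale
        sy <- (em$y[e] - orig[2L]) * scale
        if (sx > -5 * sigma_px && sx < npx - 1 + 5 * sigma_px &&
            sy > -5 * sigma_px && sy < npx - 1 + 5 * sigma_px) {
          f <- .add_gaussian(f, sx, sy, em$amplitude[e], sigma_px)
        }
      }
    }
    if (noise) f <- .apply_camera_noise(f, spec)
    out[, , k] <- f
  }
  out
}

# ---- benchmark scenes -----------------------------------------------------

#' Benchmark scenes and parameter blocks
#'
#' Fixed study conditions used by the package's detection benchmarks (and by
#' `scripts/acceptance.R`), so that tests, scripts and documentation all run
#' the same scenes.
#'
#' `calcium_benchmark_scene()`: 200 x 200 px, 100 frames, camera noise on, a
#' uniform baseline at the level where a dF/F0 = 1 spike has a peak-to-noise
#' ratio of 5 (see [spike_snr_baseline()]), and `n_events` scheduled spikes
#' (amplitude 1.0, tau 400 ms, footprint sigma 2 px); `n_events = 0` gives
#' the matched noise-only control.
#'
#' `vesicle_merge_scene()`: 64 x 64 px, 40 frames; with `merged = TRUE` a
#' mover vesicle docks onto a quasi-stationary target (axis-aligned linear
#' approach of 12 px over 21 frames, merge at frame 26, about 0.5 px/frame —
#' slow enough that the mover's last resolvable detection lies within the
#' peak-merge separation of the merge site); with `merged = FALSE`, two
#' independent vesicles 23 px apart that never interact. Spot sigma is
#' 0.8 px, the diffraction-limited width at 100 nm pixels.
#'
#' `vesicle_benchmark_params()`: the matching [vesicle_proximity_params()]
#' block (no extra smoothing — spot peaks are ~40x the noise sd — and a
#' low threshold of 50 counts).
#'
#' @param seed Integer seed.
#' @param n_events Number of scheduled spikes (0 for the noise-only
#'   control).
#' @name benchmark_scenes
#' @export
calcium_benchmark_scene <- function(seed, n_events = 10L) {
  spec <- scene_spec(width = 200L, height = 200L, n_frames = 100L,
                     background = spike_snr_baseline(1, 5, 2),
                     shot_noise = TRUE, read_noise_sd = 2)
  generate_calcium_scene(spec, seed, n_events = n_events, amplitude = 1,
                         tau_ms = 400, sigma_spot_px = 2,
                         margin = 15, min_separation = 20)
}

#' @rdname benchmark_scenes
#' @param merged Scripted approach-and-merge (`TRUE`) or independent
#'   well-separated vesicles (`FALSE`).
#' @export
vesicle_merge_scene <- function(seed, merged = TRUE) {
  spec <- scene_spec(width = 64L, height = 64L, n_frames = 40L,
                     background = 10)
  if (merged) {
    ves <- tibble(x = c(32, 44), y = c(32, 32), amplitude = 150, sigma = 0.8)
    generate_vesicle_scene(spec, seed, vesicles = ves, d_um2_s = 0.002,
                           scripts = list(list(mover = 2L, target = 1L,
                                               start_frame = 5L,
                                               merge_frame = 26L,
                                               profile = "linear")))
  } else {
    ves <- tibble(x = c(16, 48), y = c(16, 48), amplitude = 150, sigma = 0.8)
    generate_vesicle_scene(spec, seed, vesicles = ves, d_um2_s = 0.002)
  }
}

#' @rdname benchmark_scenes
#' @export
vesicle_benchmark_params <- function() {
  vesicle_proximity_params(low_threshold = 50, smoothing_sigma = 0,
                           border_px = 4)
}
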