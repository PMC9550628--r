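# Closed-loop acquisition controller — the "virtual microscope": consumes a
# frame source, runs the chosen pipeline on every widefield frame, and on a
# detected event transforms the coordinate, requests a simulated STED scan
# around it, stores the evidence bundle, and resumes widefield mode.

#' Record the binary sample mask
#'
#' Averages exactly 10 frames and applies a global user-provided intensity
#' threshold: `mask = (mean >= threshold)`. The 10-frame count is the
#' instrument's fixed procedure; pass `n_override` (logged by the caller) to
#' deviate deliberately.
#'
#' @param frames A list of 10 frames, or a 3-D array with 10 planes.
#' @param threshold Global intensity threshold (counts).
#' @param n_override Optional deliberate override of the required frame count.
#' @return A logical matrix.
#' @export
record_binary_mask <- function(frames, threshold, n_override = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(i) frames[, , i])
  }
  need <- if (is.null(n_override)) 10L else as.integer(n_override)
  if (length(frames) != need) {
    .err(sprintf("mask recording requires exactly %d frames (got %d)",
                 need, length(frames)), "etsted_parameter_error")
  }
  .check_number(threshold, "threshold")
  shapes <- unique(lapply(frames, dim))
  if (length(shapes) != 1L) {
    .err("mask frames must share one shape", "etsted_structural_error")
  }
  avg <- Reduce(`+`, frames) / length(frames)
  avg >= threshold
}

#' Acquisition configuration
#'
#' @param pipeline Pipeline name (see [get_pipeline()]).
#' @param params Pipeline parameter block (`NULL` for that pipeline's
#'   defaults).
#' @param mode One of `"endless"` (keep triggering), `"single_trigger"`
#'   (stop after the first triggered scan), `"validation"` (record events,
#'   never scan) or `"visualization"` (validation plus retained
#'   preprocessed maps).
#' @param buffer_frames Number of widefield frames saved leading up to each
#'   detected event (>= 1).
#' @param scan_size_um Side of the triggered scan ROI (um); always smaller
#'   than the widefield field.
#' @param scan_pixel_nm Scan pixel size (nm), typically 25-30.
#' @param scan_frames Number of scan frames per trigger.
#' @param mask_threshold If no mask is supplied to [run_experiment()], a mask
#'   is recorded from the first 10 frames at this threshold; `NULL` means
#'   all-on.
#' @param seed Seed for the run's stochastic components (scan rendering
#'   noise); pass-through for reproducibility.
#' @param refractory_radius_px,refractory_frames Optional per-site refractory
#'   suppression: a new trigger within this radius of a previous one, within
#'   this many frames, is logged but not scanned. Default off (0), matching
#'   the instrument's behaviour of re-arming freely.
#' @export
acquisition_config <- function(pipeline = "rapid_signal_spikes", params = NULL,
                               mode = c("endless", "single_trigger",
                                        "validation", "visualization"),
                               buffer_frames = 10L, scan_size_um = 3,
                               scan_pixel_nm = 25, scan_frames = 5L,
                               mask_threshold = NULL, seed = 1L,
                               refractory_radius_px = 0,
                               refractory_frames = 0L) {
  mode <- match.arg(mode)
  .check_number(buffer_frames, "buffer_frames", 1)
  .check_number(scan_size_um, "scan_size_um", 0, strict = TRUE)
  .check_number(scan_pixel_nm, "scan_pixel_nm", 0, strict = TRUE)
  .check_number(scan_frames, "scan_frames", 1)
  structure(list(pipeline = pipeline, params = params, mode = mode,
                 buffer_frames = as.integer(buffer_frames),
                 scan_size_um = scan_size_um, scan_pixel_nm = scan_pixel_nm,
                 scan_frames = as.integer(scan_frames),
                 mask_threshold = mask_threshold, seed = seed,
                 refractory_radius_px = refractory_radius_px,
                 refractory_frames = as.integer(refractory_frames)),
            class = "acquisition_config")
}

#' Frame sources for the controller
#'
#' A frame source hands widefield frames to the controller one by one and
#' answers its scan requests through a callback, so the controller is
#' identical for a synthetic scene or a future hardware backend.
#' `scene_source()` wraps a simulated [et_scene][generate_calcium_scene];
#' its scan callback renders the scene's ground-truth emitters with
#' [render_scan_roi()]. `timelapse_source()` replays a stored timelapse; its
#' scan callback returns an upsampled crop of the triggering widefield frame
#' (a stand-in when no ground truth exists), or `NULL` in validation use.
#'
#' @param scene An `et_scene`.
#' @return A list with fields `n_frames`, `frame_fn(i)` (0-based),
#'   `scan_fn(center_wf, size_um, pixel_nm, frames, start_frame)`,
#'   `pixel_size_nm`, `frame_period_ms`, `width`, `height`.
#' @export
scene_source <- function(scene) {
  stopifnot(inherits(scene, "et_scene"))
  tl <- scene$timelapse
  list(n_frames = n_frames(tl),
       frame_fn = function(i) get_frame(tl, i),
       scan_fn = function(center_wf, size_um, pixel_nm, frames, start_frame) {
         render_scan_roi(scene, center_wf, size_um, pixel_nm, frames,
                         start_frame = start_frame)
       },
       pixel_size_nm = pixel_size_nm(tl),
       frame_period_ms = frame_period_ms(tl),
       width = dim(tl)[2L], height = dim(tl)[1L])
}

#' @rdname scene_source
#' @param timelapse A [wf_timelapse()].
#' @export
timelapse_source <- function(timelapse) {
  tl <- timelapse
  list(n_frames = n_frames(tl),
       frame_fn = function(i) get_frame(tl, i),
       scan_fn = function(center_wf, size_um, pixel_nm, frames, start_frame) {
         f <- get_frame(tl, min(start_frame, n_frames(tl) - 1L))
         half_wf <- size_um * 1000 / 2 / pixel_size_nm(tl)
         npx <- as.integer(round(size_um * 1000 / pixel_nm))
         xs <- seq(center_wf[1L] - half_wf, center_wf[1L] + half_wf,
                   length.out = npx)
         ys <- seq(center_wf[2L] - half_wf, center_wf[2L] + half_wf,
                   length.out = npx)
         crop <- f[pmin(pmax(round(ys) + 1L, 1L), nrow(f)),
                   pmin(pmax(round(xs) + 1L, 1L), ncol(f)), drop = FALSE]
         array(crop, dim = c(npx, npx, frames))
       },
       pixel_size_nm = pixel_size_nm(tl),
       frame_period_ms = frame_period_ms(tl),
       width = dim(tl)[2L], height = dim(tl)[1L])
}

#' Run a closed-loop acquisition experiment
#'
#' Per widefield frame: run the pipeline; if it reports events and the mode
#' triggers scans, take the first (most salient) event, map its coordinate
#' into scan space with the calibrated transform, request a scan stack
#' centred there from the source's scan callback, store the evidence bundle
#' (pre-event widefield buffer ending at the triggering frame, scan stack,
#' both coordinates, timing log entry), reset the pipeline state, and resume
#' (endless) or stop (single_trigger). Validation mode records events but
#' requests no scans; visualization mode additionally retains the
#' preprocessed maps. An event whose scan ROI would exceed the field bounds
#' is skipped with a logged warning (border exclusion normally precludes
#' this). Deterministic given the source and config.
#'
#' @param source A [scene_source()] or [timelapse_source()].
#' @param config An [acquisition_config()].
#' @param transform A calibrated [fit_transform()] result mapping widefield
#'   to scan coordinates.
#' @param mask Optional pre-recorded logical mask; if `NULL` and
#'   `config$mask_threshold` is set, a mask is recorded from the first 10
#'   frames (which then only prime the mask, not the pipeline).
#' @return An `experiment_record`: list with `events` (tibble of every
#'   detected event, with `triggered` flag), `bundles` (list of evidence
#'   bundles), `n_frames_processed`, `mask`, `config`, `maps`
#'   (visualization mode only), `timings` tibble.
#' @export
run_experiment <- function(source, config, transform, mask = NULL) {
  stopifnot(inherits(config, "acquisition_config"))
  if (!inherits(transform, "poly_transform2d")) {
    .err("`transform` must be a calibrated poly_transform2d", "etsted_startup_error")
  }
  set.seed(derive_seed(config$seed, "run"))
  pl <- get_pipeline(config$pipeline)
  params <- config$params %||% pl$default_params()
  triggering <- config$mode %in% c("endless", "single_trigger")
  first_frame <- 0L
  if (is.null(mask) && !is.null(config$mask_threshold)) {
    if (source$n_frames < 10L) {
      .err("mask recording needs 10 frames", "etsted_startup_error")
    }
    mask <- record_binary_mask(lapply(0:9, source$frame_fn),
                               config$mask_threshold)
    first_frame <- 10L
  }
  st <- pipeline_state(config$pipeline)
  buffer <- list()
  events_all <- list(); bundles <- list(); maps <- list(); timings <- list()
  half_wf <- config$scan_size_um * 1000 / 2 / source$pixel_size_nm
  i <- first_frame
  while (i < source$n_frames) {
    frame <- source$frame_fn(i)
    buffer[[length(buffer) + 1L]] <- frame
    if (length(buffer) > config$buffer_frames) buffer <- buffer[-1L]
    t0 <- proc.time()[["elapsed"]]
    res <- pl$fn(frame, st, mask, params)
    t_analysis <- (proc.time()[["elapsed"]] - t0) * 1000
    st <- res$state
    ev <- res$events
    if (nrow(ev)) {
      ev$triggered <- FALSE
      if (config$mode == "visualization" && !is.null(st$last_map)) {
        maps[[as.character(i)]] <- st$last_map
      }
      if (triggering) {
        cand <- ev[1L, ]  # most salient; single-scanner semantics
        # optional per-site refractory suppression
        suppressed <- FALSE
        if (config$refractory_radius_px > 0 && length(bundles)) {
          for (b in bundles) {
            if (i - b$event$frame <= config$refractory_frames &&
                .dist2d(cand$x, cand$y, b$event$x, b$event$y) <=
                config$refractory_radius_px) { suppressed <- TRUE; break }
          }
        }
        in_bounds <- cand$x - half_wf >= 0 && cand$x + half_wf <= source$width - 1 &&
          cand$y - half_wf >= 0 && cand$y + half_wf <= source$height - 1
        if (!in_bounds) {
          ev$skipped_out_of_bounds <- c(TRUE, rep(FALSE, nrow(ev) - 1L))
        } else if (!suppressed) {
          t1 <- proc.time()[["elapsed"]]
          scan_xy <- apply_transform(transform, tibble(x = cand$x, y = cand$y))
          t_transform <- (proc.time()[["elapsed"]] - t1) * 1000
          scan <- source$scan_fn(c(cand$x, cand$y), config$scan_size_um,
                                 config$scan_pixel_nm, config$scan_frames,
                                 start_frame = i)
          t_total <- (proc.time()[["elapsed"]] - t0) * 1000
          ev$triggered[1L] <- TRUE
          bundles[[length(bundles) + 1L]] <- list(
            widefield_buffer = wf_timelapse(buffer, source$pixel_size_nm,
                                            source$frame_period_ms),
            scan_stack = scan,
            event = as.list(ev[1L, c("frame", "x", "y", "salience", "pipeline")]),
            scan_coordinate = c(x = scan_xy$x, y = scan_xy$y),
            log = list(frame = i, x_wf = cand$x, y_wf = cand$y,
                       x_scan = scan_xy$x, y_scan = scan_xy$y,
                       analysis_ms = t_analysis, transform_ms = t_transform,
                       overhead_ms = 0, total_ms = t_total))
          timings[[length(timings) + 1L]] <- tibble(
            frame = i, analysis_ms = t_analysis, transform_ms = t_transform,
            total_ms = t_total)
          # the widefield stream is interrupted: re-prime the pipeline
          st <- pipeline_state(config$pipeline)
          buffer <- list()
          if (config$mode == "single_trigger") {
            events_all[[length(events_all) + 1L]] <- ev
            i <- i + 1L
            break
          }
        }
      }
      events_all[[length(events_all) + 1L]] <- ev
    }
    i <- i + 1L
  }
  events <- if (length(events_all)) bind_rows(events_all) else {
    e <- .empty_events(config$pipeline); e$triggered <- logical(); e
  }
  structure(list(events = events, bundles = bundles,
                 n_frames_processed = i - first_frame,
                 n_triggers = length(bundles),
                 mask = mask, config = config,
                 maps = if (config$mode == "visualization") maps else NULL,
                 timings = if (length(timings)) bind_rows(timings) else
                   tibble(frame = integer(), analysis_ms = numeric(),
                          transform_ms = numeric(), total_ms = numeric())),
            class = "experiment_record")
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf("<experiment_record> %s mode, %d frames, %d events, %d triggered scans\n",
              x$config$mode, x$n_frames_processed, nrow(x$events), x$n_triggers))
  invisible(x)
}

#' @rdname run_experiment
#' @param x An `experiment_record`.
#' @param ... Unused.
#' @method glance experiment_record
#' @export
glance.experiment_record <- function(x, ...) {
  tibble(mode = x$config$mode, pipeline = x$config$pipeline,
         n_frames = x$n_frames_processed, n_events = nrow(x$events),
         n_triggers = x$n_triggers,
         mean_analysis_ms = if (nrow(x$timings)) mean(x$timings$analysis_ms)
         else NA_real_)
}
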