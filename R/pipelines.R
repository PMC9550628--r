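# Real-time event-detection pipelines. Each pipeline conforms to one
# interface contract: it takes the current widefield frame, its carry-over
# state (holding whatever it needs from previous frames), a binary sample
# mask and a parameter block, and returns the detected event coordinates in
# widefield space plus the updated state. Replaying a timelapse frame by
# frame therefore reproduces exactly what the closed-loop controller sees.

#' Parameters for the rapid-signal-spikes pipeline
#'
#' @param smoothing_sigma Gaussian sigma (px) applied to both frames before
#'   the per-pixel comparison.
#' @param window Odd maximum-filter window (px) for peak detection.
#' @param ratio_threshold Ratiometric trigger threshold (unitless, > 1): a
#'   peak fires when the smoothed current/previous intensity ratio reaches
#'   this value.
#' @param min_intensity Minimum raw intensity (counts) for a pixel to be
#'   considered; suppresses division noise where the denominator is dark.
#' @param border_px Border exclusion (px): peaks closer than this to the
#'   frame edge are discarded so a triggered scan ROI always fits.
#' @param epsilon Division floor (counts) for the previous-frame denominator.
#' @param mode `"ratio"` (default) compares frames as
#'   `smooth(cur)/max(smooth(prev), epsilon)`; `"normdiff"` as
#'   `(smooth(cur)-smooth(prev))/max(smooth(prev), epsilon)` (then the
#'   threshold is on the relative increase, > 0).
#' @export
rapid_spikes_params <- function(smoothing_sigma = 1.5, window = 5L,
                                ratio_threshold = 1.5, min_intensity = 10,
                                border_px = 10, epsilon = 1,
                                mode = c("ratio", "normdiff")) {
  mode <- match.arg(mode)
  .check_number(smoothing_sigma, "smoothing_sigma", 0)
  .check_number(ratio_threshold, "ratio_threshold",
                if (mode == "ratio") 1 else 0, strict = TRUE)
  .check_number(min_intensity, "min_intensity", 0)
  .check_number(border_px, "border_px", 0)
  .check_number(epsilon, "epsilon", 0, strict = TRUE)
  structure(list(smoothing_sigma = smoothing_sigma, window = as.integer(window),
                 ratio_threshold = ratio_threshold,
                 min_intensity = min_intensity, border_px = border_px,
                 epsilon = epsilon, mode = mode),
            class = "rapid_spikes_params")
}

#' Fresh pipeline state
#'
#' A pipeline's state after processing frame `k` suffices to process frame
#' `k + 1` with no other history; the value returned here is a valid input
#' for the first frame. The controller resets the state after every
#' triggered scan, because the widefield stream is interrupted and
#' frame-difference maps across the gap would be invalid.
#'
#' @param pipeline Pipeline name.
#' @export
pipeline_state <- function(pipeline) {
  list(pipeline = pipeline, frames_processed = 0L)
}

.empty_events <- function(pipeline) {
  tibble(frame = integer(), x = numeric(), y = numeric(),
         salience = numeric(), pipeline = character())
}

# Zero out a border strip of `border` px around the map.
.exclude_border <- function(m, border) {
  b <- as.integer(ceiling(border))
  if (b <= 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (2L * b >= nr || 2L * b >= nc) { m[] <- 0; return(m) }
  m[c(seq_len(b), (nr - b + 1L):nr), ] <- 0
  m[, c(seq_len(b), (nc - b + 1L):nc)] <- 0
  m
}

#' Rapid signal spikes pipeline
#'
#' Detects sudden local intensity increases (calcium spikes, pHluorin
#' unquenching) as peaks in a smoothed map comparing each pixel of the
#' current frame with the previous one. The map is the per-pixel ratio of
#' the smoothed current to the smoothed previous frame (floored at
#' `epsilon`), zeroed outside the sample mask, below the raw-intensity gate
#' and inside the border-exclusion strip. Local maxima of the map at or
#' above `ratio_threshold` become events, sorted salience-descending so that
#' a consumer taking the first event takes the ratiometrically brightest
#' peak. The first call only primes the state and emits nothing.
#'
#' @param frame Current widefield frame (numeric matrix of counts).
#' @param state Pipeline state ([pipeline_state()] for a fresh run).
#' @param mask Logical sample mask (same shape), or `NULL` for all-on.
#' @param params A [rapid_spikes_params()] block.
#' @return `list(events, state)`: `events` is a tibble with columns `frame`,
#'   `x`, `y`, `salience`, `pipeline`; the preprocessed map is retained in
#'   `state$last_map` for visualization mode.
#' @export
rapid_signal_spikes <- function(frame, state, mask = NULL,
                                params = rapid_spikes_params()) {
  .check_frame(frame)
  mask <- .check_mask(mask, frame)
  f_idx <- state$frames_processed
  cur_s <- gaussian_smooth(frame, params$smoothing_sigma)
  if (is.null(state$prev_smooth)) {
    state$prev_smooth <- cur_s
    state$frames_processed <- f_idx + 1L
    state$last_map <- NULL
    return(list(events = .empty_events("rapid_signal_spikes"), state = state))
  }
  denom <- pmax(state$prev_smooth, params$epsilon)
  map <- if (params$mode == "ratio") cur_s / denom else (cur_s - denom) / denom
  map[!mask] <- 0
  map[frame < params$min_intensity] <- 0
  map <- .exclude_border(map, params$border_px)
  peaks <- find_local_maxima(map, params$window,
                             min_value = params$ratio_threshold)
  peaks <- threshold_peaks(peaks, params$ratio_threshold)
  events <- tibble(frame = rep(f_idx, nrow(peaks)),
                   x = peaks$x, y = peaks$y, salience = peaks$value,
                   pipeline = rep("rapid_signal_spikes", nrow(peaks)))
  state$prev_smooth <- cur_s
  state$last_map <- map
  state$frames_processed <- f_idx + 1L
  list(events = events, state = state)
}

#' Parameters for the rising-signal (dynamin) pipeline
#'
#' @param trace_length `N`: a track must stay detected for exactly this many
#'   frames before its intensity trend is evaluated (user-definable; >= 2).
#' @param rise_ratio Trigger ratio `rho` (> 1): last over first box intensity
#'   of the N-frame trace. Monotonicity is not required — the endpoint ratio
#'   is robust to frame-to-frame noise.
#' @param low_threshold,high_threshold Preprocessed peak-intensity gates
#'   discarding noise (below low) and large bright clusters (above high).
#' @param box_half_width Half-width `a` (px) of the (2a+1)^2 box whose mean
#'   preprocessed intensity forms the trace.
#' @param link_distance,memory Track-linking parameters (px, frames).
#' @param smoothing_sigma,background_sigma Preprocessing sigmas (px);
#'   `background_sigma` must exceed `smoothing_sigma`.
#' @param window Odd maximum-filter window (px).
#' @param border_px Border exclusion (px).
#' @param history_frames Stored-window capacity (frames); `trace_length`
#'   may not exceed it.
#' @export
dynamin_rise_params <- function(trace_length = 5L, rise_ratio = 2,
                                low_threshold = 10, high_threshold = 1e4,
                                box_half_width = 2L, link_distance = 5,
                                memory = 1L, smoothing_sigma = 1,
                                background_sigma = 10, window = 5L,
                                border_px = 10, history_frames = 20L) {
  .check_number(trace_length, "trace_length", 2)
  .check_number(rise_ratio, "rise_ratio", 1, strict = TRUE)
  if (low_threshold >= high_threshold) {
    .err("`low_threshold` must be below `high_threshold`", "etsted_parameter_error")
  }
  if (background_sigma <= smoothing_sigma) {
    .err("`background_sigma` must exceed `smoothing_sigma`", "etsted_parameter_error")
  }
  if (trace_length > history_frames) {
    .err("`trace_length` exceeds the stored window capacity `history_frames`",
         "etsted_parameter_error")
  }
  structure(list(trace_length = as.integer(trace_length), rise_ratio = rise_ratio,
                 low_threshold = low_threshold, high_threshold = high_threshold,
                 box_half_width = as.integer(box_half_width),
                 link_distance = link_distance, memory = as.integer(memory),
                 smoothing_sigma = smoothing_sigma,
                 background_sigma = background_sigma, window = as.integer(window),
                 border_px = border_px,
                 history_frames = as.integer(history_frames)),
            class = "dynamin_rise_params")
}

# Shared preprocessing for the tracking pipelines: smooth, wide-kernel
# background subtraction, mask and border gating.
.track_preprocess <- function(frame, mask, smoothing_sigma, background_sigma,
                              border_px) {
  sm <- gaussian_smooth(frame, smoothing_sigma)
  pre <- pmax(sm - gaussian_smooth(sm, background_sigma), 0)
  pre[!mask] <- 0
  .exclude_border(pre, border_px)
}

# Mean preprocessed intensity in the (2a+1)^2 box around (x, y), clipped to
# the frame bounds.
.box_mean <- function(m, x, y, a) {
  r0 <- max(1L, round(y) + 1L - a); r1 <- min(nrow(m), round(y) + 1L + a)
  c0 <- max(1L, round(x) + 1L - a); c1 <- min(ncol(m), round(x) + 1L + a)
  mean(m[r0:r1, c0:c1])
}

#' Rising signal (dynamin recruitment) pipeline
#'
#' Detects slowly rising intensity peaks developing over multiple frames,
#' such as local dynamin1 accumulation at an endocytic site. Per frame the
#' image is smoothed and background-reduced; peaks are detected and gated by
#' low/high intensity thresholds; the mean intensity of a small box around
#' each peak is extracted; the peak positions and intensities are stored in
#' the carry-over state and linked into tracks. When a track has stayed
#' detected for exactly `N = trace_length` frames, it triggers one event at
#' its last coordinate if its last box intensity is at least `rise_ratio`
#' times its first; each track is evaluated (and can trigger) only once.
#'
#' @inheritParams rapid_signal_spikes
#' @param params A [dynamin_rise_params()] block.
#' @return `list(events, state)` as in [rapid_signal_spikes()].
#' @export
dynamin_rise <- function(frame, state, mask = NULL,
                         params = dynamin_rise_params()) {
  .check_frame(frame)
  mask <- .check_mask(mask, frame)
  f_idx <- state$frames_processed
  if (is.null(state$linker)) {
    state$linker <- .linker_new(params$link_distance, params$memory)
    state$evaluated <- integer()
  }
  pre <- .track_preprocess(frame, mask, params$smoothing_sigma,
                           params$background_sigma, params$border_px)
  peaks <- find_local_maxima(pre, params$window,
                             min_value = params$low_threshold)
  peaks <- peaks[peaks$value <= params$high_threshold, , drop = FALSE]
  det <- tibble(x = peaks$x, y = peaks$y,
                intensity = vapply(seq_len(nrow(peaks)), function(i)
                  .box_mean(pre, peaks$x[i], peaks$y[i], params$box_half_width),
                  numeric(1L)))
  state$linker <- .linker_step(state$linker, f_idx, det)
  events <- .empty_events("dynamin_rise")
  for (tr in state$linker$tracks) {
    if (tr$id %in% state$evaluated) next
    if (nrow(tr$rows) == params$trace_length) {
      state$evaluated <- c(state$evaluated, tr$id)
      ratio <- tr$rows$intensity[nrow(tr$rows)] / tr$rows$intensity[1L]
      if (is.finite(ratio) && ratio >= params$rise_ratio) {
        events <- bind_rows(events,
                            tibble(frame = f_idx, x = tr$last_x, y = tr$last_y,
                                   salience = ratio, pipeline = "dynamin_rise"))
      }
    }
  }
  events <- events[order(-events$salience, events$y, events$x), , drop = FALSE]
  state$last_map <- pre
  state$frames_processed <- f_idx + 1L
  list(events = events, state = state)
}

#' Parameters for the vesicle-proximity pipeline
#'
#' @param r_prox Proximity radius (px): maximum distance between a surviving
#'   track and the disappeared track's last position. The last resolvable
#'   detection of a merging vesicle systematically sits a merge distance
#'   (roughly the PSF full width) away from its partner, so this radius is
#'   wider than the optical resolution itself; 5 px is 0.5 um at 100 nm
#'   pixels.
#' @param lookback `k` (frames): the disappearance must have occurred at most
#'   this many frames ago.
#' @param window_frames `L` (frames): length of the rolling window over which
#'   presence and movement are evaluated; must be >= `lookback`.
#' @param presence_fraction `q` in (0, 1]: both tracks must have been
#'   detected in at least `q * L` of the last `L` frames ("consistently
#'   present"); the default tolerates the detection dropouts that occur as
#'   two spots approach the resolution limit.
#' @param d_net Net-displacement threshold (px): magnitude of the summed step
#'   vectors over the window ("accumulated vectorial distance").
#' @param d_path Path-length threshold (px): sum of step magnitudes over the
#'   window ("absolute distance").
#' @param low_threshold,high_threshold Preprocessed peak-intensity gates.
#' @inheritParams dynamin_rise_params
#' @export
vesicle_proximity_params <- function(r_prox = 5, lookback = 3L,
                                     window_frames = 15L,
                                     presence_fraction = 0.6,
                                     d_net = 4, d_path = 5,
                                     link_distance = 5, memory = 1L,
                                     low_threshold = 20, high_threshold = 1e4,
                                     smoothing_sigma = 1, background_sigma = 8,
                                     window = 3L, border_px = 8) {
  .check_number(r_prox, "r_prox", 0, strict = TRUE)
  .check_number(lookback, "lookback", 1)
  .check_number(window_frames, "window_frames", 1)
  if (window_frames < lookback) {
    .err("`window_frames` must be at least `lookback`", "etsted_parameter_error")
  }
  if (presence_fraction <= 0 || presence_fraction > 1) {
    .err("`presence_fraction` must be in (0, 1]", "etsted_parameter_error")
  }
  .check_number(d_net, "d_net", 0, strict = TRUE)
  .check_number(d_path, "d_path", 0, strict = TRUE)
  structure(list(r_prox = r_prox, lookback = as.integer(lookback),
                 window_frames = as.integer(window_frames),
                 presence_fraction = presence_fraction,
                 d_net = d_net, d_path = d_path,
                 link_distance = link_distance, memory = as.integer(memory),
                 low_threshold = low_threshold, high_threshold = high_threshold,
                 smoothing_sigma = smoothing_sigma,
                 background_sigma = background_sigma,
                 window = as.integer(window), border_px = border_px),
            class = "vesicle_proximity_params")
}

# Net displacement and path length of a track's positions within the rolling
# window (frames > f - L).
.window_motion <- function(rows, f, L) {
  w <- rows[rows$frame > f - L, , drop = FALSE]
  if (nrow(w) < 2L) return(c(net = 0, path = 0))
  dx <- diff(w$x); dy <- diff(w$y)
  c(net = .dist2d(w$x[1L], w$y[1L], w$x[nrow(w)], w$y[nrow(w)]),
    path = sum(sqrt(dx^2 + dy^2)))
}

#' Vesicle proximity pipeline
#'
#' Tracks point-like vesicles frame to frame and detects when two of them
#' approach each other and become unresolvable. At every frame, each track
#' that disappeared (was closed by the linking memory rule) within the last
#' `lookback` frames is evaluated against every surviving track. Five
#' conditions must all hold: (1) the track has disappeared; (2) the other
#' track's current position is within `r_prox` of its last position; (3) the
#' disappearance occurred at most `lookback` frames ago; (4) both tracks
#' were present in at least `presence_fraction * window_frames` of the last
#' `window_frames` frames; (5) at least one of the two tracks moved, over
#' that window, a net displacement of at least `d_net` *and* a path length
#' of at least `d_path`. The event coordinate is the disappeared track's
#' last position; each track pair triggers at most once.
#'
#' @inheritParams rapid_signal_spikes
#' @param params A [vesicle_proximity_params()] block.
#' @return `list(events, state)` as in [rapid_signal_spikes()]; event
#'   salience is the larger net window displacement of the pair.
#' @export
vesicle_proximity <- function(frame, state, mask = NULL,
                              params = vesicle_proximity_params()) {
  .check_frame(frame)
  mask <- .check_mask(mask, frame)
  f_idx <- state$frames_processed
  if (is.null(state$linker)) {
    state$linker <- .linker_new(params$link_distance, params$memory)
    state$triggered_pairs <- character()
  }
  pre <- .track_preprocess(frame, mask, params$smoothing_sigma,
                           params$background_sigma, params$border_px)
  peaks <- find_local_maxima(pre, params$window,
                             min_value = params$low_threshold)
  peaks <- peaks[peaks$value <= params$high_threshold, , drop = FALSE]
  det <- tibble(x = peaks$x, y = peaks$y)
  state$linker <- .linker_step(state$linker, f_idx, det)
  events <- .empty_events("vesicle_proximity")
  trs <- state$linker$tracks
  open <- vapply(trs, `[[`, TRUE, "open")
  gone <- which(!open & (f_idx - vapply(trs, `[[`, 0, "last_frame"))
                <= params$lookback)
  L <- params$window_frames
  need <- params$presence_fraction * L
  for (gi in gone) {
    d <- trs[[gi]]
    for (si in which(open)) {
      s <- trs[[si]]
      key <- paste(sort(c(d$id, s$id)), collapse = "-")
      if (key %in% state$triggered_pairs) next
      if (.dist2d(s$last_x, s$last_y, d$last_x, d$last_y) > params$r_prox) next
      pres_d <- sum(d$rows$frame > f_idx - L)
      pres_s <- sum(s$rows$frame > f_idx - L)
      if (pres_d < need || pres_s < need) next
      m_d <- .window_motion(d$rows, f_idx, L)
      m_s <- .window_motion(s$rows, f_idx, L)
      moved <- (m_d[["net"]] >= params$d_net && m_d[["path"]] >= params$d_path) ||
        (m_s[["net"]] >= params$d_net && m_s[["path"]] >= params$d_path)
      if (!moved) next
      state$triggered_pairs <- c(state$triggered_pairs, key)
      events <- bind_rows(events,
                          tibble(frame = f_idx, x = d$last_x, y = d$last_y,
                                 salience = max(m_d[["net"]], m_s[["net"]]),
                                 pipeline = "vesicle_proximity"))
    }
  }
  events <- events[order(-events$salience, events$y, events$x), , drop = FALSE]
  state$last_map <- pre
  state$frames_processed <- f_idx + 1L
  list(events = events, state = state)
}

#' Look up a pipeline by name
#'
#' Pipelines are discoverable by the names used on the instrument:
#' `"rapid_signal_spikes"`, `"dynamin_rise"`, `"vesicle_proximity"`.
#'
#' @param name Pipeline name.
#' @return A list with elements `fn` (the pipeline function) and
#'   `default_params` (its parameter constructor).
#' @export
get_pipeline <- function(name) {
  reg <- list(
    rapid_signal_spikes = list(fn = rapid_signal_spikes,
                               default_params = rapid_spikes_params),
    dynamin_rise = list(fn = dynamin_rise,
                        default_params = dynamin_rise_params),
    vesicle_proximity = list(fn = vesicle_proximity,
                             default_params = vesicle_proximity_params))
  if (!name %in% names(reg)) {
    .err(sprintf("unknown pipeline '%s' (available: %s)", name,
                 paste(names(reg), collapse = ", ")),
         "etsted_parameter_error")
  }
  reg[[name]]
}

#' Replay a stored timelapse through a pipeline offline
#'
#' Runs a pipeline frame by frame over a recorded timelapse without any
#' triggering — the validation-mode equivalent for archived data — and
#' returns the full event stream. Identical to what the closed-loop
#' controller would detect in validation mode.
#'
#' @param timelapse A [wf_timelapse()] (or 3-D array).
#' @param pipeline Pipeline name (see [get_pipeline()]).
#' @param params Pipeline parameter block; `NULL` for defaults.
#' @param mask Optional logical sample mask.
#' @return Tibble of events (`frame`, `x`, `y`, `salience`, `pipeline`).
#' @export
detect_events <- function(timelapse, pipeline = "rapid_signal_spikes",
                          params = NULL, mask = NULL) {
  p <- get_pipeline(pipeline)
  if (is.null(params)) params <- p$default_params()
  st <- pipeline_state(pipeline)
  out <- vector("list", dim(timelapse)[3L])
  for (i in seq_len(dim(timelapse)[3L])) {
    res <- p$fn(timelapse[, , i, drop = TRUE], st, mask, params)
    st <- res$state
    out[[i]] <- res$events
  }
  bind_rows(out)
}
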