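# Post-acquisition quantification: dF/F0 trace extraction, detection-quality
# ratios against manual annotations, histogram-matching bleach correction,
# and cluster segmentation / trace linking / MSD analysis.

#' Extract a dF/F0 intensity trace
#'
#' `F(t)` is the mean intensity in a disc of radius `radius_px` around the
#' coordinate, per frame; the baseline `F0` is the mean of `F` over the
#' first `baseline_frames` frames (`baseline_frames = 1` uses `F(t0)`
#' alone); `dF/F0 = (F(t) - F0)/F0`. This is the standard readout of
#' calcium-indicator activity, and is invariant under global gain.
#'
#' @param timelapse A [wf_timelapse()] or 3-D array.
#' @param coordinate Length-2 `(x, y)` in pixels (0-based).
#' @param radius_px Disc radius (px); the disc must lie inside the frame.
#' @param baseline_frames Number of initial frames averaged into `F0`.
#' @return A tibble of class `intensity_trace` with columns `frame`, `t_s`,
#'   `f`, `dff0`; `F0` is attached as attribute `f0`.
#' @export
dff0_trace <- function(timelapse, coordinate, radius_px = 3,
                       baseline_frames = 1L) {
  stopifnot(length(coordinate) == 2L)
  .check_number(radius_px, "radius_px", 0, strict = TRUE)
  .check_number(baseline_frames, "baseline_frames", 1)
  d <- dim(timelapse)
  x <- coordinate[1L]; y <- coordinate[2L]
  if (x - radius_px < 0 || x + radius_px > d[2L] - 1 ||
      y - radius_px < 0 || y + radius_px > d[1L] - 1) {
    .err("disc does not fit inside the frame", "etsted_parameter_error")
  }
  cols <- which(abs(seq_len(d[2L]) - 1 - x) <= radius_px)
  rows <- which(abs(seq_len(d[1L]) - 1 - y) <= radius_px)
  disc <- outer((rows - 1 - y)^2, (cols - 1 - x)^2, "+") <= radius_px^2
  f <- vapply(seq_len(d[3L]), function(k) {
    sub <- timelapse[rows, cols, k]
    mean(sub[disc])
  }, numeric(1L))
  f0 <- mean(f[seq_len(min(baseline_frames, length(f)))])
  if (f0 <= 0) .err("invalid baseline: F0 <= 0", "etsted_parameter_error")
  period_s <- frame_period_ms(timelapse) / 1000
  out <- tibble(frame = seq_along(f) - 1L, t_s = (seq_along(f) - 1L) * period_s,
                f = f, dff0 = (f - f0) / f0)
  attr(out, "f0") <- f0
  class(out) <- c("intensity_trace", class(out))
  out
}

#' Compare detections against manual annotations
#'
#' Greedy one-to-one matching of detections to annotated events within a
#' temporal and spatial tolerance, closest in time then space first. From
#' the matching two ratios are computed: the true-positive detection ratio
#' (`true_ratio` = matched detections / all detections) and the detected
#' annotated events ratio (`det_ratio` = matched annotations / all
#' annotations). With zero detections `true_ratio` is undefined (`NA`,
#' flagged) and `det_ratio` is 0.
#'
#' @param detections,annotations Data frames with columns `frame`, `x`, `y`.
#' @param r_tol Spatial matching tolerance (px).
#' @param t_tol Temporal matching tolerance (frames).
#' @return A list of class `detection_quality`: `true_ratio`, `det_ratio`,
#'   `n_detections`, `n_annotations`, `n_matched`, tolerances, and the
#'   matched index pairs.
#' @export
evaluate_detection <- function(detections, annotations, r_tol = 5, t_tol = 2) {
  .check_number(r_tol, "r_tol", 0, strict = TRUE)
  .check_number(t_tol, "t_tol", 0, strict = TRUE)
  nd <- nrow(detections); na <- nrow(annotations)
  matched <- tibble(detection = integer(), annotation = integer())
  if (nd > 0L && na > 0L) {
    dt <- abs(outer(detections$frame, annotations$frame, "-"))
    dr <- sqrt(outer(detections$x, annotations$x, "-")^2 +
                 outer(detections$y, annotations$y, "-")^2)
    ok <- which(dt <= t_tol & dr <= r_tol, arr.ind = TRUE)
    if (nrow(ok) > 0L) {
      ord <- order(dt[ok], dr[ok], ok[, 1L], ok[, 2L])
      used_d <- logical(nd); used_a <- logical(na)
      for (k in ord) {
        di <- ok[k, 1L]; ai <- ok[k, 2L]
        if (used_d[di] || used_a[ai]) next
        used_d[di] <- TRUE; used_a[ai] <- TRUE
        matched <- bind_rows(matched, tibble(detection = di, annotation = ai))
      }
    }
  }
  nm <- nrow(matched)
  structure(list(true_ratio = if (nd > 0L) nm / nd else NA_real_,
                 det_ratio = if (na > 0L) nm / na else NA_real_,
                 true_ratio_defined = nd > 0L,
                 n_detections = nd, n_annotations = na, n_matched = nm,
                 r_tol = r_tol, t_tol = t_tol, matches = matched),
            class = "detection_quality")
}

#' @export
print.detection_quality <- function(x, ...) {
  cat(sprintf("<detection_quality> True = %s, Det = %s (%d det, %d ann, %d matched)\n",
              format(x$true_ratio, digits = 3), format(x$det_ratio, digits = 3),
              x$n_detections, x$n_annotations, x$n_matched))
  invisible(x)
}

#' @rdname evaluate_detection
#' @param x A `detection_quality`.
#' @param ... Unused.
#' @method glance detection_quality
#' @export
glance.detection_quality <- function(x, ...) {
  tibble(true_ratio = x$true_ratio, det_ratio = x$det_ratio,
         n_detections = x$n_detections, n_annotations = x$n_annotations,
         n_matched = x$n_matched)
}

#' Histogram-matching bleach correction
#'
#' Monotonically remaps each frame's empirical intensity distribution onto a
#' reference frame's distribution, correcting photobleaching without
#' distorting intensity order within a frame. Ranks (ties averaged) are
#' mapped by interpolation into the reference frame's sorted intensities;
#' the reference frame itself is unchanged, and the mapping is monotone
#' non-decreasing by construction.
#'
#' @param timelapse A [wf_timelapse()] or 3-D array.
#' @param reference_frame Index (0-based) of the reference frame.
#' @return A timelapse of the same shape and attributes.
#' @export
bleach_correct_histogram_match <- function(timelapse, reference_frame = 0L) {
  d <- dim(timelapse)
  stopifnot(reference_frame >= 0, reference_frame < d[3L])
  ref_sorted <- sort(as.numeric(timelapse[, , reference_frame + 1L]))
  n <- length(ref_sorted)
  out <- timelapse
  for (k in seq_len(d[3L])) {
    if (k == reference_frame + 1L) next
    v <- as.numeric(timelapse[, , k])
    rk <- rank(v, ties.method = "average")
    out[, , k] <- matrix(approx(seq_len(n), ref_sorted, xout = rk,
                                rule = 2)$y, d[1L], d[2L])
  }
  out
}

# Binary erosion by a 3 x 3 square structuring element; pixels outside the
# frame count as background, so the border is eroded.
.erode3x3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  shift <- function(m, dr, dc) {
    o <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    o[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    o
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out & shift(mask, dr, dc)
  }
  out
}

#' Segment fluorescent clusters in one frame
#'
#' The cluster-extraction recipe applied to each (bleach-corrected) frame:
#' Gaussian smoothing with sigma 1 px, binarization at a timelapse-constant
#' global threshold, one binary erosion with a 3 x 3 structuring element,
#' 8-connected component labelling, and removal of objects with area at or
#' below `min_area_um2`. Each surviving region is measured for area (pixel
#' count times pixel area), aspect ratio (major over minor axis of the
#' second-moment equivalent ellipse) and unweighted binary centroid (um).
#'
#' @param frame Numeric matrix.
#' @param global_threshold Timelapse-constant intensity threshold.
#' @param pixel_size_um Pixel size in um (> 0).
#' @param smoothing_sigma Smoothing sigma (px); default 1.
#' @param min_area_um2 Minimum area (um^2); objects at or below it are
#'   discarded. Default 0.015.
#' @return A tibble with columns `label`, `area_um2`, `aspect_ratio`,
#'   `centroid_x_um`, `centroid_y_um`, `n_pixels`.
#' @export
segment_clusters <- function(frame, global_threshold, pixel_size_um,
                             smoothing_sigma = 1, min_area_um2 = 0.015) {
  .check_frame(frame)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    .err("`pixel_size_um` must be > 0", "etsted_parameter_error")
  }
  sm <- gaussian_smooth(frame, smoothing_sigma)
  bin <- .erode3x3(sm >= global_threshold)
  if (!any(bin)) {
    return(tibble(label = integer(), area_um2 = numeric(),
                  aspect_ratio = numeric(), centroid_x_um = numeric(),
                  centroid_y_um = numeric(), n_pixels = integer()))
  }
  lab <- .label8(bin)
  idx <- which(bin)
  comp <- lab[idx]
  rows <- (idx - 1L) %% nrow(frame)      # 0-based y
  cols <- (idx - 1L) %/% nrow(frame)     # 0-based x
  out <- lapply(sort(unique(comp)), function(cc) {
    sel <- comp == cc
    xs <- cols[sel]; ys <- rows[sel]
    np <- length(xs)
    area <- np * pixel_size_um^2
    if (area <= min_area_um2) return(NULL)
    mx <- mean(xs); my <- mean(ys)
    # second-moment equivalent ellipse; 1/12 is the variance of one pixel
    cxx <- mean((xs - mx)^2) + 1 / 12
    cyy <- mean((ys - my)^2) + 1 / 12
    cxy <- mean((xs - mx) * (ys - my))
    tr <- cxx + cyy; det <- cxx * cyy - cxy^2
    l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
    l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
    tibble(label = cc, area_um2 = area,
           aspect_ratio = sqrt(l1 / max(l2, 1e-12)),
           centroid_x_um = mx * pixel_size_um,
           centroid_y_um = my * pixel_size_um,
           n_pixels = np)
  })
  out <- bind_rows(out)
  if (nrow(out)) out$label <- seq_len(nrow(out))
  out
}

#' Link cluster regions into traces across frames
#'
#' Frame-to-frame matching of region centroids by minimum Euclidean
#' distance, with an upper limit of `max_step_um` movement per frame; links
#' beyond the limit are rejected and unmatched regions end or begin traces.
#' The trace seeded by the largest cluster in the first frame is flagged
#' (`msd_flag`) for MSD analysis.
#'
#' @param regions A tibble of per-frame regions (as from
#'   [segment_clusters()]) with an added `frame` column (0-based).
#' @param max_step_um Per-frame movement limit (um); default 0.3.
#' @return A tibble with columns `trace`, `frame`, `x`, `y` (um),
#'   `area_um2`, `aspect_ratio`, `msd_flag`.
#' @export
link_cluster_traces <- function(regions, max_step_um = 0.3) {
  stopifnot(all(c("frame", "centroid_x_um", "centroid_y_um") %in% names(regions)))
  det <- tibble(frame = regions$frame,
                x = regions$centroid_x_um, y = regions$centroid_y_um,
                area_um2 = regions$area_um2,
                aspect_ratio = regions$aspect_ratio)
  tr <- link_tracks(det, max_link_distance = max_step_um, memory = 0L)
  names(tr)[names(tr) == "track"] <- "trace"
  first <- min(regions$frame)
  f0 <- regions[regions$frame == first, , drop = FALSE]
  if (nrow(f0)) {
    big <- f0[which.max(f0$area_um2), ]
    seed <- tr[tr$frame == first &
                 abs(tr$x - big$centroid_x_um) < 1e-9 &
                 abs(tr$y - big$centroid_y_um) < 1e-9, , drop = FALSE]
    tr$msd_flag <- tr$trace %in% seed$trace
  } else {
    tr$msd_flag <- logical(nrow(tr))
  }
  as_tibble(tr)
}

#' Mean squared displacement of a centroid trace
#'
#' For each lag `dt_frames`, averages over all valid times `t`. The default
#' `"squared"` mode is the mean of the squared Euclidean displacement
#' between positions at `t` and `t + dt` (um^2) — the form whose reported
#' units (um^2) require; `"literal_distance"` mode instead averages the
#' unsquared Euclidean distance (um), reproducing the descriptive wording
#' "mean Euclidean distance" verbatim. The mode used is recorded in the
#' output.
#'
#' @param trace A data frame with columns `frame`, `x`, `y` (positions in
#'   um).
#' @param dt_frames Integer lag(s); each must be smaller than the trace
#'   length.
#' @param mode `"squared"` (default) or `"literal_distance"`.
#' @return A tibble with columns `dt_frames`, `msd`, `n_pairs`, `mode`.
#' @export
compute_msd <- function(trace, dt_frames = 1L,
                        mode = c("squared", "literal_distance")) {
  mode <- match.arg(mode)
  stopifnot(all(c("frame", "x", "y") %in% names(trace)))
  trace <- trace[order(trace$frame), , drop = FALSE]
  nlen <- nrow(trace)
  out <- lapply(as.integer(dt_frames), function(dt) {
    if (dt >= nlen) {
      .err(sprintf("lag %d is not below the trace length %d", dt, nlen),
           "etsted_parameter_error")
    }
    if (dt == 0L) return(tibble(dt_frames = 0L, msd = 0, n_pairs = nlen,
                                mode = mode))
    idx2 <- match(trace$frame + dt, trace$frame)
    ok <- !is.na(idx2)
    d2 <- (trace$x[idx2[ok]] - trace$x[ok])^2 +
      (trace$y[idx2[ok]] - trace$y[ok])^2
    val <- if (mode == "squared") mean(d2) else mean(sqrt(d2))
    tibble(dt_frames = dt, msd = val, n_pairs = sum(ok), mode = mode)
  })
  bind_rows(out)
}

#' Ensemble MSD over many traces
#'
#' Pools displacement pairs over all traces at each lag (weighted by pair
#' count), e.g. over a Brownian ensemble or all linked cluster traces.
#'
#' @param traces A data frame with columns `track` (or `trace`), `frame`,
#'   `x`, `y`.
#' @inheritParams compute_msd
#' @export
msd_ensemble <- function(traces, dt_frames = 1L,
                         mode = c("squared", "literal_distance")) {
  mode <- match.arg(mode)
  idcol <- if ("track" %in% names(traces)) "track" else "trace"
  per <- lapply(split(traces, traces[[idcol]]), function(tr) {
    keep <- dt_frames[dt_frames < nrow(tr)]
    if (!length(keep)) return(NULL)
    compute_msd(tr, keep, mode)
  })
  per <- bind_rows(per)
  per |>
    group_by(.data$dt_frames) |>
    summarise(msd = sum(.data$msd * .data$n_pairs) / sum(.data$n_pairs),
              n_pairs = sum(.data$n_pairs), .groups = "drop") |>
    mutate(mode = mode)
}
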