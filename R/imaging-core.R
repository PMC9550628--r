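# Shared image primitives: smoothing, background reduction, maximum-filter
# peak detection, thresholding, and nearest-neighbour track linking.

#' Gaussian smoothing with reflective boundaries
#'
#' Separable discrete Gaussian convolution. The kernel is truncated at
#' 4 sigma and renormalised to unit sum, so total intensity of interior
#' features is conserved; boundaries are handled by half-sample reflection
#' (no edge darkening, which would otherwise create false ratiometric peaks
#' at the frame border).
#'
#' @param frame Numeric matrix of intensities.
#' @param sigma Gaussian sigma in pixels; `sigma = 0` returns the input
#'   unchanged.
#' @return Matrix of the same shape.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 100
#' sum(gaussian_smooth(m, 1))  # ~100: mass conserved
#' @export
gaussian_smooth <- function(frame, sigma) {
  .check_frame(frame)
  .check_number(sigma, "sigma", 0)
  if (sigma == 0) return(frame)
  r <- as.integer(ceiling(4 * sigma))
  w <- dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  .conv_separable(frame, w, r)
}

# One separable pass per axis; `w` has length 2r + 1.
.conv_separable <- function(m, w, r) {
  nr <- nrow(m); nc <- ncol(m)
  # rows (vertical axis)
  p <- m[.reflect_idx(nr, r), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(w)) {
    out <- out + w[k] * p[(k):(k + nr - 1L), , drop = FALSE]
  }
  # columns (horizontal axis)
  p <- out[, .reflect_idx(nc, r), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(w)) {
    out <- out + w[k] * p[, (k):(k + nc - 1L), drop = FALSE]
  }
  out
}

#' Background reduction by wide-kernel subtraction
#'
#' Estimates the smooth local background as a wide Gaussian blur of the frame
#' and subtracts it, clipping at zero. `sigma_bg` should be clearly larger
#' than the feature scale (and than any smoothing sigma used downstream) so
#' that point-like structures survive subtraction.
#'
#' @inheritParams gaussian_smooth
#' @param sigma_bg Background kernel sigma in pixels (> 0).
#' @return Matrix of the same shape; constant frames map to zero, and
#'   additive offsets are removed exactly.
#' @export
subtract_background <- function(frame, sigma_bg) {
  .check_frame(frame)
  .check_number(sigma_bg, "sigma_bg", 0, strict = TRUE)
  pmax(frame - gaussian_smooth(frame, sigma_bg), 0)
}

# Separable square maximum filter with reflective boundary.
.max_filter <- function(m, window) {
  half <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  p <- m[.reflect_idx(nr, half), , drop = FALSE]
  out <- p[1L:nr, , drop = FALSE]
  if (half >= 1L) {
    for (k in 1L:(2L * half)) {
      out <- pmax(out, p[(1L + k):(nr + k), , drop = FALSE])
    }
  }
  p <- out[, .reflect_idx(nc, half), drop = FALSE]
  out <- p[, 1L:nc, drop = FALSE]
  if (half >= 1L) {
    for (k in 1L:(2L * half)) {
      out <- pmax(out, p[, (1L + k):(nc + k), drop = FALSE])
    }
  }
  out
}

# 8-connected component labelling by iterative minimum-label propagation.
# Returns an integer matrix: 0 outside `mask`, component id inside.
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  ids <- matrix(Inf, nr, nc)
  ids[mask] <- which(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    nb <- ids
    for (d in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                   c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
      nb <- pmin(nb, shift(ids, d[1L], d[2L]))
    }
    nb[!mask] <- Inf
    if (identical(nb, ids)) break
    ids <- nb
  }
  ids[!mask] <- 0
  lab <- matrix(match(ids, sort(unique(ids[mask]))), nr, nc)
  lab[!mask] <- 0L
  lab
}

#' Local maxima by maximum-filter comparison
#'
#' Finds local maxima as the pixels where the image equals a `window` x
#' `window` maximum-filtered version of itself. Connected plateaus of equal
#' maxima (8-connectivity) collapse to one representative, the pixel with the
#' smallest row, then column. Candidates outside `mask` are removed. The
#' result is sorted by value descending, ties broken by (row, column).
#'
#' @param image Numeric matrix (e.g. a ratiometric or preprocessed map).
#' @param window Odd window size in pixels (>= 3).
#' @param mask Optional logical matrix gating the detection region.
#' @param min_value Optional floor: candidate pixels with values below it are
#'   dropped before plateau collapse. Because a plateau is constant-valued,
#'   this is equivalent to thresholding the returned list, but avoids
#'   labelling large sub-threshold plateaus (such as the zeroed region outside
#'   the sample mask).
#' @return A tibble with columns `x`, `y` (0-based pixel coordinates) and
#'   `value` (the image value at the peak).
#' @export
find_local_maxima <- function(image, window = 3L, mask = NULL, min_value = -Inf) {
  .check_frame(image, "image")
  if (window %% 2L == 0L || window < 3L) {
    .err("`window` must be odd and >= 3", "etsted_parameter_error")
  }
  mask <- .check_mask(mask, image)
  cand <- (image == .max_filter(image, as.integer(window))) & mask &
    (image >= min_value)
  if (!any(cand)) {
    return(tibble(x = numeric(), y = numeric(), value = numeric()))
  }
  lab <- .label8(cand)
  idx <- which(cand)
  comp <- lab[idx]
  # representative per component: smallest linear index == smallest column-major
  # position; we need smallest (row, col), i.e. minimise col * nr + row.
  rows <- (idx - 1L) %% nrow(image) + 1L
  cols <- (idx - 1L) %/% nrow(image) + 1L
  key <- rows * (ncol(image) + 1) + cols  # lexicographic (row, col)
  keep <- idx[tapply(seq_along(idx), comp, function(ii) ii[which.min(key[ii])])]
  rows <- (keep - 1L) %% nrow(image) + 1L
  cols <- (keep - 1L) %/% nrow(image) + 1L
  vals <- image[keep]
  ord <- order(-vals, rows, cols)
  tibble(x = cols[ord] - 1, y = rows[ord] - 1, value = vals[ord])
}

#' Threshold a peak list on salience
#'
#' Retains peaks whose `value` is at least `threshold`; input ordering is
#' preserved.
#'
#' @param peaks A tibble as returned by [find_local_maxima()].
#' @param threshold Finite salience threshold.
#' @export
threshold_peaks <- function(peaks, threshold) {
  .check_number(threshold, "threshold")
  peaks[peaks$value >= threshold, , drop = FALSE]
}

# ---- nearest-neighbour track linking -------------------------------------

# Incremental linker used both by link_tracks() and the real-time pipelines.
# State layout:
#   tracks: list of list(id, rows = tibble(frame, x, y, ...), last_frame,
#                        open, extra fields preserved)
#   next_id, params.
.linker_new <- function(max_link_distance, memory) {
  .check_number(max_link_distance, "max_link_distance", 0, strict = TRUE)
  .check_number(memory, "memory", 0)
  list(tracks = list(), next_id = 1L,
       max_link_distance = max_link_distance, memory = as.integer(memory),
       closed_now = integer())
}

# Advance the linker by one frame. `det` is a data frame with columns x, y
# (plus any extra columns, carried into track rows). Greedy distance-sorted
# one-to-one matching; deterministic given input order.
.linker_step <- function(st, frame, det) {
  st$closed_now <- integer()
  # close tracks unmatched for more than `memory` frames
  for (i in seq_along(st$tracks)) {
    tr <- st$tracks[[i]]
    if (tr$open && (frame - tr$last_frame - 1L) > st$memory) {
      st$tracks[[i]]$open <- FALSE
      st$closed_now <- c(st$closed_now, tr$id)
    }
  }
  nd <- if (is.null(det)) 0L else nrow(det)
  open_idx <- which(vapply(st$tracks, `[[`, TRUE, "open"))
  if (nd > 0L && length(open_idx) > 0L) {
    lx <- vapply(st$tracks[open_idx], function(t) t$last_x, 0)
    ly <- vapply(st$tracks[open_idx], function(t) t$last_y, 0)
    dmat <- outer(lx, det$x, "-")^2 + outer(ly, det$y, "-")^2
    cand <- which(dmat <= st$max_link_distance^2, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      dd <- dmat[cand]
      ord <- order(dd, cand[, 1L], cand[, 2L])
      used_t <- logical(length(open_idx)); used_d <- logical(nd)
      for (k in ord) {
        ti <- cand[k, 1L]; di <- cand[k, 2L]
        if (used_t[ti] || used_d[di]) next
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        gi <- open_idx[ti]
        tr <- st$tracks[[gi]]
        row <- det[di, , drop = FALSE]
        row$frame <- frame
        tr$rows <- rbind(tr$rows, row[, c("frame", setdiff(names(row), "frame")),
                                      drop = FALSE])
        tr$last_x <- det$x[di]; tr$last_y <- det$y[di]
        tr$last_frame <- frame
        st$tracks[[gi]] <- tr
      }
      unmatched <- which(!used_d)
    } else {
      unmatched <- seq_len(nd)
    }
  } else {
    unmatched <- seq_len(nd)
  }
  for (di in unmatched) {
    row <- det[di, , drop = FALSE]
    row$frame <- frame
    st$tracks[[length(st$tracks) + 1L]] <- list(
      id = st$next_id,
      rows = row[, c("frame", setdiff(names(row), "frame")), drop = FALSE],
      last_x = det$x[di], last_y = det$y[di], last_frame = frame,
      open = TRUE)
    st$next_id <- st$next_id + 1L
  }
  st
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame greedy nearest-neighbour assignment: candidate
#' track-detection pairs are sorted by distance and matched one-to-one; links
#' beyond `max_link_distance` are rejected; unmatched detections start new
#' tracks. A track left unmatched for at most `memory` frames may be resumed
#' across the gap; after more than `memory` unmatched frames it is closed
#' ("disappears"). Deterministic given input order. This greedy rule (rather
#' than globally optimal assignment) matches common particle-linking
#' behaviour at the low densities involved.
#'
#' @param detections A data frame with columns `frame` (integer, 0-based),
#'   `x`, `y`; additional columns are carried along into the track rows.
#' @param max_link_distance Maximum per-step link distance in pixels.
#' @param memory Number of frames a track may go undetected and still be
#'   resumed.
#' @return A tibble with columns `track`, `frame`, `x`, `y`, ... — every
#'   input detection belongs to exactly one track. Link parameters are
#'   attached as attributes.
#' @export
link_tracks <- function(detections, max_link_distance, memory = 0L) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  st <- .linker_new(max_link_distance, memory)
  if (nrow(detections) > 0L) {
    frames <- seq(min(detections$frame), max(detections$frame))
    for (f in frames) {
      det <- detections[detections$frame == f, , drop = FALSE]
      st <- .linker_step(st, f, det)
    }
  }
  rows <- lapply(st$tracks, function(tr) {
    out <- as_tibble(tr$rows)
    out$track <- tr$id
    out
  })
  out <- if (length(rows)) bind_rows(rows) else
    tibble(frame = integer(), x = numeric(), y = numeric(), track = integer())
  out <- out[order(out$track, out$frame), c("track", setdiff(names(out), "track"))]
  attr(out, "max_link_distance") <- max_link_distance
  attr(out, "memory") <- as.integer(memory)
  as_tibble(out)
}
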