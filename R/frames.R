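#' Widefield frames and timelapses
#'
#' A *frame* is a plain numeric matrix of non-negative camera counts indexed
#' `[row, col]`. A *timelapse* is a 3-D array `[row, col, frame]` of class
#' `wf_timelapse` carrying the pixel size (nm) and frame period (ms) as
#' attributes.
#'
#' Throughout the package, point coordinates are `(x, y)` with `x` = column
#' and `y` = row, **0-based**, continuous, with the origin at the centre of
#' the top-left pixel; frame indices are 0-based as well. So pixel
#' `(x, y) = (j, i)` is matrix element `[i + 1, j + 1]`. This matches the
#' scan-coordinate semantics of the instrument and keeps sub-pixel positions
#' unambiguous.
#'
#' @param frames A 3-D numeric array `[row, col, frame]`, or a list of
#'   equally-sized matrices.
#' @param pixel_size_nm Widefield pixel size in nanometres (default 100).
#' @param frame_period_ms Time between frame starts in milliseconds
#'   (default 50).
#' @return `wf_timelapse()` returns the classed 3-D array.
#' @examples
#' tl <- wf_timelapse(array(0, dim = c(8, 8, 3)))
#' n_frames(tl)
#' @export
wf_timelapse <- function(frames, pixel_size_nm = 100, frame_period_ms = 50) {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L) {
      .err("all frames in a timelapse must share one shape", "etsted_format_error")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shapes[[1L]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    .err("`frames` must be a [row, col, frame] array or list of matrices",
         "etsted_format_error")
  }
  .check_number(pixel_size_nm, "pixel_size_nm", 0, strict = TRUE)
  .check_number(frame_period_ms, "frame_period_ms", 0, strict = TRUE)
  if (anyNA(frames) || any(!is.finite(frames)) || any(frames < 0)) {
    .err("frame intensities must be finite and non-negative", "etsted_format_error")
  }
  structure(frames,
            pixel_size_nm = pixel_size_nm,
            frame_period_ms = frame_period_ms,
            class = "wf_timelapse")
}

#' @rdname wf_timelapse
#' @param tl A `wf_timelapse`.
#' @export
n_frames <- function(tl) dim(tl)[3L]

#' @rdname wf_timelapse
#' @param i 0-based frame index.
#' @export
get_frame <- function(tl, i) {
  stopifnot(i >= 0, i < dim(tl)[3L])
  tl[, , i + 1L, drop = TRUE]
}

#' @rdname wf_timelapse
#' @export
pixel_size_nm <- function(tl) attr(tl, "pixel_size_nm") %||% 100

#' @rdname wf_timelapse
#' @export
frame_period_ms <- function(tl) attr(tl, "frame_period_ms") %||% 50

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wf_timelapse <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<wf_timelapse> %d x %d px, %d frames, %g nm/px, %g ms/frame\n",
              d[2L], d[1L], d[3L], pixel_size_nm(x), frame_period_ms(x)))
  invisible(x)
}

.check_frame <- function(frame, name = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    .err(sprintf("`%s` must be a numeric matrix", name), "etsted_format_error")
  }
  if (anyNA(frame) || any(!is.finite(frame))) {
    .err(sprintf("`%s` must be finite", name), "etsted_format_error")
  }
  invisible(frame)
}

.check_mask <- function(mask, frame) {
  if (is.null(mask)) return(matrix(TRUE, nrow(frame), ncol(frame)))
  if (!is.matrix(mask) || !identical(dim(mask), dim(frame))) {
    .err("mask shape must equal frame shape", "etsted_structural_error")
  }
  storage.mode(mask) <- "logical"
  mask
}
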