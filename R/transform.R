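# Third-order 2-D polynomial mapping between widefield and scan coordinates:
# calibration (Levenberg-Marquardt damped least squares), application,
# accuracy reporting, and JSON serialization.

# Monomial exponent table for a full third-order 2-D polynomial (10 terms),
# in a fixed deterministic order.
.poly_exponents <- function() {
  ex <- NULL
  for (d in 0:3) for (i in d:0) ex <- rbind(ex, c(i, d - i))
  colnames(ex) <- c("i", "j")
  ex
}

# Design matrix of monomials u^i v^j over normalized inputs.
.poly_design <- function(u, v) {
  ex <- .poly_exponents()
  vapply(seq_len(nrow(ex)),
         function(k) u^ex[k, 1L] * v^ex[k, 2L],
         numeric(length(u)))
}

#' Control points for coordinate-transform calibration
#'
#' Builds a validated set of matched point pairs — the same physical spots
#' annotated in the widefield image and in the scan image — used to calibrate
#' the widefield-to-scan transform.
#'
#' @param x_wf,y_wf Widefield (source) coordinates in pixels.
#' @param x_scan,y_scan Scan (target) coordinates in pixels.
#' @return A tibble of class `control_points`.
#' @export
control_points <- function(x_wf, y_wf, x_scan, y_scan) {
  pts <- tibble(x_wf = as.numeric(x_wf), y_wf = as.numeric(y_wf),
                x_scan = as.numeric(x_scan), y_scan = as.numeric(y_scan))
  if (anyNA(pts) || any(!vapply(pts, function(c) all(is.finite(c)), TRUE))) {
    .err("control points must be finite", "etsted_format_error")
  }
  if (anyDuplicated(pts[, c("x_wf", "y_wf")])) {
    .err("duplicated source points in control-point set", "etsted_format_error")
  }
  class(pts) <- c("control_points", class(pts))
  pts
}

#' Fit the widefield-to-scan polynomial transform
#'
#' Fits a general third-order 2-D polynomial per output axis (10 coefficients
#' each) minimising the summed squared distance between transformed source
#' points and their annotated targets, using damped (Levenberg-Marquardt)
#' least squares. Source coordinates are normalised to \[-1, 1\] before the
#' monomial design is built: third-order monomials on raw few-hundred-pixel
#' coordinates are catastrophically ill-conditioned. Because the model is
#' linear in its coefficients, the damped fit agrees with the direct linear
#' solution to high precision (this agreement is itself tested).
#'
#' @param points A `control_points` tibble (or any data frame with columns
#'   `x_wf`, `y_wf`, `x_scan`, `y_scan`); at least 10 pairs.
#' @return An object of class `poly_transform2d`.
#' @seealso [apply_transform()], [accuracy_report()], [write_transform()]
#' @export
fit_transform <- function(points) {
  stopifnot(all(c("x_wf", "y_wf", "x_scan", "y_scan") %in% names(points)))
  n <- nrow(points)
  if (n < 10L) {
    .err("at least 10 control-point pairs are required (model has 10 coefficients per axis)",
         "etsted_underdetermined_error")
  }
  cx <- (max(points$x_wf) + min(points$x_wf)) / 2
  cy <- (max(points$y_wf) + min(points$y_wf)) / 2
  sx <- max((max(points$x_wf) - min(points$x_wf)) / 2, 1e-9)
  sy <- max((max(points$y_wf) - min(points$y_wf)) / 2, 1e-9)
  u <- (points$x_wf - cx) / sx
  v <- (points$y_wf - cy) / sy
  A <- .poly_design(u, v)
  if (qr(A)$rank < ncol(A)) {
    .err(paste("control-point design is rank deficient; add more spread-out,",
               "non-collinear points across the field"),
         "etsted_conditioning_error")
  }
  fit_axis <- function(target) {
    res_fn <- function(par) A %*% par - target
    jac_fn <- function(par) A
    out <- minpack.lm::nls.lm(par = rep(0, ncol(A)), fn = res_fn, jac = jac_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    out$par
  }
  coef_x <- fit_axis(points$x_scan)
  coef_y <- fit_axis(points$y_scan)
  pred <- cbind(A %*% coef_x, A %*% coef_y)
  resid <- sqrt((pred[, 1L] - points$x_scan)^2 + (pred[, 2L] - points$y_scan)^2)
  structure(list(coef_x = as.numeric(coef_x), coef_y = as.numeric(coef_y),
                 center = c(x = cx, y = cy), scale = c(x = sx, y = sy),
                 n_points = n, rms_residual_px = sqrt(mean(resid^2)),
                 mean_residual_px = mean(resid)),
            class = "poly_transform2d")
}

#' Apply a fitted transform to coordinates
#'
#' Evaluates both polynomial axes for each input point. Vectorised; the
#' per-point cost is a 10-term monomial sum, far below a millisecond.
#'
#' @param transform A `poly_transform2d`.
#' @param coords A data frame with columns `x`, `y` (widefield pixels), or a
#'   2-column matrix.
#' @return A tibble with transformed `x`, `y` (scan pixels).
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "poly_transform2d"))
  if (is.matrix(coords)) coords <- tibble(x = coords[, 1L], y = coords[, 2L])
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y))) {
    .err("coordinates must be finite", "etsted_format_error")
  }
  u <- (coords$x - transform$center[["x"]]) / transform$scale[["x"]]
  v <- (coords$y - transform$center[["y"]]) / transform$scale[["y"]]
  A <- .poly_design(u, v)
  tibble(x = as.numeric(A %*% transform$coef_x),
         y = as.numeric(A %*% transform$coef_y))
}

#' Transform accuracy report
#'
#' Transforms each validation source point and measures the Euclidean
#' distance to its annotated target, in nm, producing both per-point
#' distances (a spatial accuracy map, for inspecting spatial correlation of
#' the error) and their arithmetic mean.
#'
#' @param transform A `poly_transform2d`.
#' @param validation A `control_points` tibble; may be the training set
#'   itself or an independent set (recorded in the report).
#' @param pixel_size_nm Size of one pixel in nm used to convert distances.
#' @param independent Logical flag recorded in the report: whether
#'   `validation` is disjoint from the training data.
#' @return A tibble of class `accuracy_report` with per-point columns
#'   `x_wf`, `y_wf`, `error_px`, `error_nm`, and attributes
#'   `mean_error_nm`, `mean_error_px`, `pixel_size_nm`, `independent`.
#' @export
accuracy_report <- function(transform, validation, pixel_size_nm = 100,
                            independent = FALSE) {
  if (nrow(validation) == 0L) {
    .err("validation set is empty", "etsted_parameter_error")
  }
  .check_number(pixel_size_nm, "pixel_size_nm", 0, strict = TRUE)
  pred <- apply_transform(transform,
                          tibble(x = validation$x_wf, y = validation$y_wf))
  err_px <- .dist2d(pred$x, pred$y, validation$x_scan, validation$y_scan)
  out <- tibble(x_wf = validation$x_wf, y_wf = validation$y_wf,
                x_pred = pred$x, y_pred = pred$y,
                x_scan = validation$x_scan, y_scan = validation$y_scan,
                error_px = err_px, error_nm = err_px * pixel_size_nm)
  attr(out, "mean_error_px") <- mean(err_px)
  attr(out, "mean_error_nm") <- mean(err_px) * pixel_size_nm
  attr(out, "pixel_size_nm") <- pixel_size_nm
  attr(out, "independent") <- independent
  class(out) <- c("accuracy_report", class(out))
  out
}

#' @export
print.poly_transform2d <- function(x, ...) {
  cat(sprintf("<poly_transform2d> third-order, fitted on %d points, RMS residual %.3g px\n",
              x$n_points, x$rms_residual_px))
  invisible(x)
}

#' @rdname fit_transform
#' @param x A `poly_transform2d`.
#' @param ... Unused.
#' @method tidy poly_transform2d
#' @export
tidy.poly_transform2d <- function(x, ...) {
  ex <- .poly_exponents()
  tibble(term = sprintf("x^%d*y^%d", ex[, 1L], ex[, 2L]),
         i = ex[, 1L], j = ex[, 2L],
         coef_x = x$coef_x, coef_y = x$coef_y)
}

#' @rdname fit_transform
#' @method glance poly_transform2d
#' @export
glance.poly_transform2d <- function(x, ...) {
  tibble(n_points = x$n_points,
         rms_residual_px = x$rms_residual_px,
         mean_residual_px = x$mean_residual_px)
}

#' Serialize / restore a transform as JSON
#'
#' Coefficients and input normalization are stored in a plain JSON document
#' so a calibration can be reused across sessions, as on the instrument.
#' `read_transform(write_transform(t, path))` round-trips exactly.
#'
#' @param transform A `poly_transform2d`.
#' @param path File path for the JSON document.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   the restored `poly_transform2d`.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "poly_transform2d"))
  doc <- list(schema = "etsted/poly_transform2d/1",
              order = 3L,
              coef_x = transform$coef_x, coef_y = transform$coef_y,
              center = as.list(transform$center), scale = as.list(transform$scale),
              n_points = transform$n_points,
              rms_residual_px = transform$rms_residual_px,
              mean_residual_px = transform$mean_residual_px)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "etsted/poly_transform2d/1")) {
    .err("not a transform JSON document", "etsted_format_error")
  }
  structure(list(coef_x = as.numeric(doc$coef_x), coef_y = as.numeric(doc$coef_y),
                 center = c(x = doc$center$x, y = doc$center$y),
                 scale = c(x = doc$scale$x, y = doc$scale$y),
                 n_points = doc$n_points,
                 rms_residual_px = doc$rms_residual_px,
                 mean_residual_px = doc$mean_residual_px),
            class = "poly_transform2d")
}

#' Identity transform over a pixel domain
#'
#' Convenience constructor for simulations where scan coordinates coincide
#' with widefield coordinates: fits the transform on a regular grid mapped by
#' the identity.
#'
#' @param width,height Domain extent in pixels.
#' @export
identity_transform <- function(width, height) {
  g <- expand.grid(x = seq(0, width - 1, length.out = 5),
                   y = seq(0, height - 1, length.out = 5))
  fit_transform(control_points(g$x, g$y, g$x, g$y))
}
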