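# Independent brute-force oracles used across the test files. These are
# deliberately naive (element-wise loops, exhaustive scans) and share no code
# with the implementation they check.

# Reflect (half-sample) an out-of-range 1-based index into 1..n.
reflect1 <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# Direct truncated-kernel Gaussian convolution, element by element.
conv2_brute <- function(m, sigma) {
  r <- as.integer(ceiling(4 * sigma))
  w1 <- dnorm(seq(-r, r), sd = sigma)
  w1 <- w1 / sum(w1)
  K <- outer(w1, w1)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + K[di + r + 1L, dj + r + 1L] *
            m[reflect1(i + di, nr), reflect1(j + dj, nc)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Exhaustive local-maximum scan with plateau collapse: a pixel is a candidate
# if its value is >= every in-bounds neighbour within the Chebyshev radius;
# 8-connected candidate components collapse to their (row, col)-smallest
# pixel. Returns a tibble sorted value-desc, ties by (row, col), matching the
# documented output contract.
local_maxima_brute <- function(m, window, mask = NULL, min_value = -Inf) {
  half <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  cand <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j] || m[i, j] < min_value) next
      nb <- m[max(1L, i - half):min(nr, i + half),
              max(1L, j - half):min(nc, j + half)]
      if (m[i, j] >= max(nb)) cand[i, j] <- TRUE
    }
  }
  # flood-fill plateau collapse (8-connectivity)
  seen <- matrix(FALSE, nr, nc)
  reps <- NULL
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!cand[i, j] || seen[i, j]) next
      stack <- list(c(i, j)); comp <- NULL
      seen[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        comp <- rbind(comp, p)
        for (di in -1:1) for (dj in -1:1) {
          qi <- p[1L] + di; qj <- p[2L] + dj
          if (qi >= 1L && qi <= nr && qj >= 1L && qj <= nc &&
              cand[qi, qj] && !seen[qi, qj]) {
            seen[qi, qj] <- TRUE
            stack[[length(stack) + 1L]] <- c(qi, qj)
          }
        }
      }
      ord <- order(comp[, 1L], comp[, 2L])
      reps <- rbind(reps, comp[ord[1L], , drop = FALSE])
    }
  }
  if (is.null(reps)) {
    return(tibble::tibble(x = numeric(), y = numeric(), value = numeric()))
  }
  vals <- m[cbind(reps[, 1L], reps[, 2L])]
  ord <- order(-vals, reps[, 1L], reps[, 2L])
  tibble::tibble(x = unname(reps[ord, 2L]) - 1, y = unname(reps[ord, 1L]) - 1,
                 value = unname(vals[ord]))
}

# Direct 3x3 binary erosion by neighbourhood scan (border = background).
erode3x3_brute <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      keep <- TRUE
      for (di in -1:1) for (dj in -1:1) {
        qi <- i + di; qj <- j + dj
        if (qi < 1L || qi > nr || qj < 1L || qj > nc || !mask[qi, qj]) {
          keep <- FALSE
        }
      }
      out[i, j] <- keep
    }
  }
  out
}

# Closed-form linear least-squares fit of the third-order polynomial model,
# via QR on the same normalisation; the independent check of the package's
# damped (Levenberg-Marquardt) fit.
qr_poly_fit <- function(points) {
  cx <- (max(points$x_wf) + min(points$x_wf)) / 2
  cy <- (max(points$y_wf) + min(points$y_wf)) / 2
  sx <- (max(points$x_wf) - min(points$x_wf)) / 2
  sy <- (max(points$y_wf) - min(points$y_wf)) / 2
  u <- (points$x_wf - cx) / sx
  v <- (points$y_wf - cy) / sy
  ex <- NULL
  for (d in 0:3) for (i in d:0) ex <- rbind(ex, c(i, d - i))
  A <- sapply(seq_len(nrow(ex)), function(k) u^ex[k, 1] * v^ex[k, 2])
  list(coef_x = qr.solve(A, points$x_scan),
       coef_y = qr.solve(A, points$y_scan),
       predict = function(px, py) {
         uu <- (px - cx) / sx; vv <- (py - cy) / sy
         AA <- sapply(seq_len(nrow(ex)), function(k) uu^ex[k, 1] * vv^ex[k, 2])
         if (is.null(dim(AA))) AA <- matrix(AA, nrow = 1)
         cbind(AA %*% qr.solve(A, points$x_scan),
               AA %*% qr.solve(A, points$y_scan))
       })
}

# Render a Gaussian spot into a matrix (independent of the package's
# internal renderer; used to build hand-made frames).
add_spot <- function(m, x, y, amp, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      m[i, j] <- m[i, j] + amp * exp(-(((i - 1) - y)^2 + ((j - 1) - x)^2) /
                                       (2 * sigma^2))
    }
  }
  m
}

# Rscript invocation of the installed CLI with the current library path.
run_cli <- function(args) {
  script <- system.file("exec", "etsted", package = "etsted")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(shQuote(script), args), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}

md5_of <- function(path) as.character(tools::md5sum(path))
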