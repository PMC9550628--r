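# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can distinguish error kinds.
.err <- function(msg, class) {
  abort(msg, class = c(class, "etsted_error"))
}

.check_number <- function(x, name, min = -Inf, strict = FALSE, finite = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (!finite || is.finite(x)) && (if (strict) x > min else x >= min)
  if (!ok) {
    .err(sprintf("`%s` must be a single finite number %s %s", name,
                 if (strict) ">" else ">=", format(min)),
         "etsted_parameter_error")
  }
  invisible(x)
}

#' Derive a reproducible substream seed
#'
#' Deterministically derives a 32-bit seed from a top-level seed and a text
#' label, so one integer reproduces a whole workflow: each module or
#' repetition draws its own substream (`derive_seed(seed, "beads")`,
#' `derive_seed(seed, "spike3")`, ...) without coupling their random
#' streams.
#'
#' @param seed Integer top-level seed.
#' @param label Character label naming the substream.
#' @return An integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483647)
}

# Reflect (half-sample symmetric) index vector for padding a length-n axis by r.
.reflect_idx <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  left <- pmin(pmax(seq(r, 1L), 1L), n)
  right <- pmin(pmax(seq(n, n - r + 1L), 1L), n)
  c(left, seq_len(n), right)
}

# Euclidean distance between two (x, y) points.
.dist2d <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
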