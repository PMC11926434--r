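stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

## Piecewise-linear interpolation with explicit end rules.
## right = "clamp" holds the last value; right = "zero" returns 0 beyond the
## table end (used for the IDD so the distal fringe vanishes).  Left end is
## always clamped (depths start at 0; negative queries are caught upstream).
## The arithmetic (y0 + t*(y1-y0)) matches the compiled kernels bit-for-bit.
interp_table <- function(x, y, xout, right = c("clamp", "zero")) {
  right <- match.arg(right)
  n <- length(x)
  idx <- findInterval(xout, x)
  out <- numeric(length(xout))
  lo <- idx <= 0L
  hi <- idx >= n
  mid <- !lo & !hi
  out[lo] <- y[1L]
  out[hi] <- if (right == "clamp") y[n] else 0
  ## exact knot at the right end stays a table value, not the "beyond" rule
  at_end <- hi & xout == x[n]
  out[at_end] <- y[n]
  if (any(mid)) {
    i <- idx[mid]
    t <- (xout[mid] - x[i]) / (x[i + 1L] - x[i])
    out[mid] <- y[i] + t * (y[i + 1L] - y[i])
  }
  out
}

## cumulative trapezoid integral of y over x, same length as x, starts at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(0.5 * (y[-1L] + y[-n]) * diff(x)))
}
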