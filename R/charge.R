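#' Integrate current over a time window (charge)
#'
#' Trapezoidal integral of the baseline-subtracted current over a window.
#' With currents in pA and time in ms the result is in pA*ms = fC, so an
#' inward (negative) current yields a negative charge. Summary tables report
#' charge magnitudes; the sign is preserved here.
#'
#' Window endpoints may fall between samples; the trace is linearly
#' interpolated at the endpoints so the integral is exact for piecewise
#' linear signals.
#'
#' @param samples current trace (pA).
#' @param dt sampling interval (ms).
#' @param window numeric `c(start, end)` in ms, on the axis where the first
#'   sample sits at t = 0.
#' @param baseline baseline current (pA) subtracted before integration.
#' @return charge in fC (signed).
#' @examples
#' # -100 pA rectangular pulse lasting 1 ms -> -100 fC
#' x <- c(rep(0, 10), rep(-100, 51), rep(0, 10))
#' integrate_charge(x, dt = 0.02, window = c(0.2, 1.2))
#' @export
integrate_charge <- function(samples, dt, window, baseline = 0) {
  if (!is.finite(baseline)) stop("baseline must be finite")
  if (length(window) != 2L || window[2] < window[1])
    stop("window must be c(start, end) with end >= start")
  n <- length(samples)
  tmax <- (n - 1) * dt
  if (window[1] < -1e-9 || window[2] > tmax + 1e-9)
    stop(sprintf("window [%g, %g] ms outside trace [0, %g] ms",
                 window[1], window[2], tmax))
  y <- samples - baseline
  trapz_window(y, dt, window[1], window[2])
}

# trapezoid with linear interpolation at fractional endpoints; slices the
# trace first so cost scales with the window, not the trace
trapz_window <- function(y, dt, a, b) {
  if (b <= a) return(0)
  i_lo <- max(1L, floor(a / dt) - 1L)
  i_hi <- min(length(y), ceiling(b / dt) + 2L)
  if (i_lo > 1L || i_hi < length(y)) {
    off <- (i_lo - 1L) * dt
    return(trapz_core(y[i_lo:i_hi], dt, a - off, b - off))
  }
  trapz_core(y, dt, a, b)
}

trapz_core <- function(y, dt, a, b) {
  n <- length(y)
  t <- (seq_len(n) - 1) * dt
  ya <- lin_interp(t, y, a)
  yb <- lin_interp(t, y, b)
  i1 <- ceiling(a / dt + 1e-12) + 1     # first full sample strictly inside
  i2 <- floor(b / dt - 1e-12) + 1       # last full sample strictly inside
  i1 <- max(1L, min(i1, n)); i2 <- max(1L, min(i2, n))
  if (i2 < i1) return((b - a) * (ya + yb) / 2)
  inner <- if (i2 > i1) sum((y[i1:(i2 - 1)] + y[(i1 + 1):i2]) / 2) * dt else 0
  left <- (t[i1] - a) * (ya + y[i1]) / 2
  right <- (b - t[i2]) * (y[i2] + yb) / 2
  inner + left + right
}

lin_interp <- function(t, y, x) {
  n <- length(t)
  if (x <= t[1]) return(y[1])
  if (x >= t[n]) return(y[n])
  i <- findInterval(x, t)
  y[i] + (y[i + 1] - y[i]) * (x - t[i]) / (t[i + 1] - t[i])
}
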