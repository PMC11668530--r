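#' Spontaneous rate and SR class
#'
#' The spontaneous rate (SR) is the number of detected events whose onset
#' falls inside any of the supplied unstimulated windows, divided by the
#' summed window duration. Synapses are classified as high SR when
#' SR >= 1 event/s, low otherwise (the boundary value 1.0 is high).
#'
#' @param events an `epsc_events` data frame (see [detect_events()]); evoked
#'   events are excluded automatically.
#' @param windows list of `c(start, end)` pairs (ms) of unstimulated
#'   recording, or a single such pair.
#' @return list with `sr` (events/s), `sr_class` (`"low"`/`"high"`),
#'   `n_events` and `analyzed_time` (s).
#' @examples
#' ev <- data.frame(onset = c(1000, 4000), evoked = FALSE)
#' spontaneous_rate(ev, list(c(0, 10000)))   # 0.2/s, low
#' @export
spontaneous_rate <- function(events, windows) {
  if (is.numeric(windows)) windows <- list(windows)
  total_ms <- sum(vapply(windows, function(w) {
    if (length(w) != 2L || w[2] < w[1]) stop("windows must be c(start, end)")
    w[2] - w[1]
  }, numeric(1)))
  if (total_ms <= 0) stop("total window duration must be positive")
  on <- events$onset
  if (!is.null(events$evoked)) on <- on[!events$evoked]
  inside <- vapply(on, function(t)
    any(vapply(windows, function(w) t >= w[1] && t < w[2], logical(1))),
    logical(1))
  n <- sum(inside)
  sr <- n / (total_ms / 1000)
  list(sr = sr, sr_class = if (sr >= 1) "high" else "low",
       n_events = n, analyzed_time = total_ms / 1000)
}

#' Summarize sEPSC amplitude, charge and kinetics distributions
#'
#' Computes mean amplitude and charge, adjusted Fisher-Pearson sample
#' skewness and coefficient of variation (SD/mean, on magnitudes), the
#' monophasic fraction, and mean kinetic parameters.
#'
#' @param events an `epsc_events` data frame with at least one row.
#' @return list of class `"spont_summary"` with fields `n_events`,
#'   `mean_amp`, `mean_charge`, `skew_amp`, `cv_amp`, `skew_charge`,
#'   `cv_charge`, `frac_monophasic`, `mean_rise`, `mean_tau_decay`,
#'   `mean_fwhm`. Skewness is `NaN` (with a warning) for fewer than 3
#'   events.
#' @export
summarize_events <- function(events) {
  if (nrow(events) < 1) stop("need at least one event")
  a <- abs(events$amplitude)
  q <- events$charge
  structure(list(
    n_events = nrow(events),
    mean_amp = mean(events$amplitude),
    mean_charge = mean(q),
    skew_amp = sample_skewness(a),
    cv_amp = stats::sd(a) / mean(a),
    skew_charge = sample_skewness(q),
    cv_charge = stats::sd(q) / mean(q),
    frac_monophasic = mean(events$phasic_class == "monophasic"),
    mean_rise = mean(events$rise_10_90, na.rm = TRUE),
    mean_tau_decay = mean(events$tau_decay, na.rm = TRUE),
    mean_fwhm = mean(events$fwhm, na.rm = TRUE)
  ), class = "spont_summary")
}

#' Adjusted Fisher-Pearson sample skewness
#' @param x numeric vector (length >= 3 for a finite result).
#' @return skewness; `NaN` with a warning for n < 3.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) {
    warning("skewness undefined for n < 3")
    return(NaN)
  }
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / n)
  if (s == 0) return(NaN)
  g1 <- sum((x - m)^3) / n / s^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' @export
print.spont_summary <- function(x, ...) {
  cat(sprintf("<spont_summary> %d events\n", x$n_events))
  cat(sprintf("  amplitude: mean %.1f pA (CV %.2f, skew %.2f)\n",
              x$mean_amp, x$cv_amp, x$skew_amp))
  cat(sprintf("  charge: mean %.1f fC (CV %.2f, skew %.2f)\n",
              x$mean_charge, x$cv_charge, x$skew_charge))
  cat(sprintf("  monophasic %.0f%%; rise %.2f ms, tau_decay %.2f ms, FWHM %.2f ms\n",
              100 * x$frac_monophasic, x$mean_rise, x$mean_tau_decay,
              x$mean_fwhm))
  invisible(x)
}

#' Unstimulated windows of a sweep
#'
#' Complements the stimulation epochs of a sweep's epoch table (with a
#' settle margin after each epoch) to yield the windows over which SR may be
#' computed.
#'
#' @param sweep a [sweep_record()].
#' @param margin_ms dead time appended after each stimulation epoch (ms).
#' @return list of `c(start, end)` windows (ms, sweep time axis).
#' @export
unstimulated_windows <- function(sweep, margin_ms = 50) {
  tmax <- sweep$t0 + (length(sweep$v_cmd) - 1) * sweep$dt
  se <- stim_epochs(sweep)
  if (is.null(se) || nrow(se) == 0) return(list(c(sweep$t0, tmax)))
  se <- se[order(se$start), , drop = FALSE]
  out <- list()
  cur <- sweep$t0
  for (j in seq_len(nrow(se))) {
    if (se$start[j] > cur) out[[length(out) + 1L]] <- c(cur, se$start[j])
    cur <- max(cur, se$end[j] + margin_ms)
  }
  if (cur < tmax) out[[length(out) + 1L]] <- c(cur, tmax)
  out
}
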