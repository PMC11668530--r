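#' Detect spontaneous and evoked EPSCs on a postsynaptic trace
#'
#' Threshold-crossing detection: the trace is detrended with a running
#' median (window `drift_ms`) to track slow baseline drift, lightly smoothed
#' with a local quadratic (Savitzky-Golay) filter of window `smooth_ms`, and
#' events are negative excursions exceeding `threshold_mult` (default 4)
#' times the SD of the processed baseline window. Overlapping excursions are
#' split into distinct events wherever the trace re-crosses 50% of the
#' threshold between peaks; excursions that stay below half threshold merge
#' into one (possibly multiphasic) event. The onset of an event is the last
#' crossing of the full threshold before its peak (linearly interpolated).
#'
#' Each detected event is measured ([measure_event()]) and classified
#' ([classify_waveform()]).
#'
#' @param sweep a [sweep_record()].
#' @param baseline_window `c(start, end)` in ms on the sweep time axis: an
#'   unstimulated stretch of at least 100 ms used for the noise SD.
#' @param threshold_mult threshold in baseline SDs (default 4).
#' @param smooth_ms Savitzky-Golay window (ms) for smoothing and derivative
#'   estimation.
#' @param drift_ms running-median window (ms) for baseline tracking.
#' @param decay_r2_min minimum R-squared of the monoexponential decay fit
#'   for an event to qualify as monophasic.
#' @param min_width_ms minimum dwell time below threshold (ms): excursions
#'   that stay below threshold for less than this are rejected as noise
#'   crossings (an EPSC at the detection limit dwells below threshold for
#'   roughly its FWHM, far longer than correlated-noise excursions).
#' @return data frame of class `"epsc_events"` with one row per event:
#'   `onset`, `peak_time` (ms), `amplitude` (pA, negative), `charge` (fC,
#'   magnitude), `rise_10_90`, `tau_decay`, `fwhm` (ms), `decay_r2`,
#'   `n_inflections`, `phasic_class` (`"monophasic"`/`"multiphasic"`),
#'   `evoked` (onset inside a stimulation epoch). The detection threshold
#'   (pA) and baseline SD are attached as attributes.
#' @export
detect_events <- function(sweep, baseline_window, threshold_mult = 4,
                          smooth_ms = 0.3, drift_ms = 20,
                          decay_r2_min = 0.90, min_width_ms = 0.15) {
  pt <- process_trace(sweep, baseline_window, threshold_mult, smooth_ms,
                      drift_ms)
  n <- length(pt$y_s)
  dt <- sweep$dt
  min_w <- max(1L, round(min_width_ms / dt))
  below_half <- pt$y_s < -pt$thr / 2
  r <- rle(below_half)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regs <- which(r$values)
  rows <- list()
  for (g in regs) {
    i1 <- starts[g]; i2 <- ends[g]
    pk <- i1 - 1L + which.min(pt$y_s[i1:i2])
    if (pt$y_s[pk] >= -pt$thr) next                 # never crossed threshold
    rb <- rle(pt$y_s[i1:i2] < -pt$thr)
    if (max(rb$lengths[rb$values]) < min_w) next    # noise-width excursion
    rows[[length(rows) + 1L]] <-
      measure_region(pt, i1, i2, pk, dt, sweep$t0, decay_r2_min)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else empty_events()
  ev$evoked <- rep(FALSE, nrow(ev))
  se <- stim_epochs(sweep)
  if (!is.null(se) && nrow(se) && nrow(ev)) {
    for (j in seq_len(nrow(se)))
      ev$evoked <- ev$evoked |
        (ev$onset >= se$start[j] & ev$onset <= se$end[j] + 2)
  }
  structure(ev, class = c("epsc_events", "data.frame"),
            threshold = pt$thr, baseline_sd = pt$sd_b)
}

empty_events <- function() {
  data.frame(onset = numeric(0), peak_time = numeric(0),
             amplitude = numeric(0), charge = numeric(0),
             rise_10_90 = numeric(0), tau_decay = numeric(0),
             fwhm = numeric(0), decay_r2 = numeric(0),
             n_inflections = integer(0), phasic_class = character(0))
}

# shared preprocessing: drift removal, smoothing, derivative, threshold
process_trace <- function(sweep, baseline_window, threshold_mult = 4,
                          smooth_ms = 0.3, drift_ms = 20) {
  dt <- sweep$dt
  if (length(baseline_window) != 2L ||
      diff(baseline_window) < 100 - 1e-9)
    stop("baseline window must span at least 100 ms of unstimulated trace")
  x <- sweep$i_post
  n <- length(x)
  k_d <- max(3L, round(drift_ms / dt)); if (k_d %% 2 == 0) k_d <- k_d + 1L
  k_d <- min(k_d, if (n %% 2 == 0) n - 1L else n)
  base <- stats::runmed(x, k_d, endrule = "median")
  y <- x - base
  k_s <- max(5L, round(smooth_ms / dt)); if (k_s %% 2 == 0) k_s <- k_s + 1L
  y_s <- signal::sgolayfilt(y, p = 2, n = k_s)
  d <- signal::sgolayfilt(y, p = 2, n = k_s, m = 1) / dt
  b1 <- max(1L, floor((baseline_window[1] - sweep$t0) / dt) + 1L)
  b2 <- min(n, floor((baseline_window[2] - sweep$t0) / dt) + 1L)
  if (b2 <= b1) stop("baseline window outside trace")
  # robust noise SD (Gaussian-consistent MAD): spontaneous events inside the
  # baseline window must not inflate the detection threshold
  sd_b <- stats::mad(y_s[b1:b2])
  if (!is.finite(sd_b) || sd_b == 0)
    stop("degenerate trace: baseline SD is zero")
  sd_d <- stats::mad(d[b1:b2])
  list(y = y, y_s = y_s, d = d, sd_b = sd_b, sd_d = sd_d,
       thr = threshold_mult * sd_b, dt = dt, t0 = sweep$t0)
}

# full measurement of one detected region (indices on the processed trace)
measure_region <- function(pt, i1, i2, pk, dt, t0, decay_r2_min = 0.90) {
  y_s <- pt$y_s; y <- pt$y; n <- length(y_s)
  amp <- y_s[pk]
  # onset: last upward crossing of -thr before the peak
  io <- pk
  while (io > 1 && y_s[io - 1] < -pt$thr) io <- io - 1
  onset_idx <- io
  onset <- if (io > 1)
    cross_time(io - 1, y_s[io - 1], y_s[io], -pt$thr, dt) else (io - 1) * dt
  # event end: return to baseline (2% of amplitude or a quarter threshold)
  lvl_end <- -max(0.02 * abs(amp), 0.25 * pt$thr)
  ie <- pk
  lim <- min(n, pk + round(50 / dt))
  while (ie < lim && y_s[ie] < lvl_end) ie <- ie + 1
  # rising-limb 10%/90% crossings (interpolated, searching back from peak)
  t10 <- rise_cross(y_s, onset_idx, pk, 0.10 * amp, dt)
  t90 <- rise_cross(y_s, onset_idx, pk, 0.90 * amp, dt)
  rise <- max(t90 - t10, dt / 100)
  # FWHM
  th <- amp / 2
  tl <- rise_cross(y_s, onset_idx, pk, th, dt)
  ir <- pk
  while (ir < lim && y_s[ir] < th) ir <- ir + 1
  tr <- if (ir > pk) cross_time(ir - 1, y_s[ir - 1], y_s[ir], th, dt) else pk * dt
  fwhm <- max(tr - tl, dt / 100)
  # monoexponential decay fit from 90% of peak on the falling limb
  id <- pk
  while (id < ie && y_s[id] < 0.90 * amp) id <- id + 1
  dec <- fit_decay(y_s, id, ie, dt)
  # charge over onset -> return-to-baseline, on the unsmoothed trace,
  # plus the analytic exponential tail beyond the integration end
  q <- trapz_window(y, dt, (onset_idx - 1) * dt, (ie - 1) * dt)
  if (is.finite(dec$tau) && ie < n) q <- q + y_s[ie] * dec$tau
  # inflection count: derivative sign reversals beyond 2 x derivative noise
  d <- pt$d[onset_idx:ie]
  rel_pk <- pk - onset_idx + 1L
  # decay-side reversals only count once the derivative has turned positive
  # (right after the smoothed peak it is legitimately still negative)
  d_dec <- d[rel_pk:length(d)]
  first_pos <- which(d_dec > 0)[1]
  dec_rev <- if (is.na(first_pos)) 0L else
    count_runs(d_dec[first_pos:length(d_dec)] < -2 * pt$sd_d)
  n_inf <- count_runs(d[seq_len(rel_pk)] > 2 * pt$sd_d) + dec_rev
  mono <- n_inf == 0L && is.finite(dec$r2) && dec$r2 >= decay_r2_min
  data.frame(onset = t0 + onset, peak_time = t0 + (pk - 1) * dt,
             amplitude = amp, charge = abs(q), rise_10_90 = rise,
             tau_decay = dec$tau, fwhm = fwhm, decay_r2 = dec$r2,
             n_inflections = n_inf,
             phasic_class = if (mono) "monophasic" else "multiphasic")
}

# interpolated time (ms, trace axis) where the segment [i, i+1] crosses lvl
cross_time <- function(i, y1, y2, lvl, dt) {
  f <- if (y2 == y1) 0 else (lvl - y1) / (y2 - y1)
  (i - 1 + f) * dt
}

# time of last crossing of lvl on the rising limb before the peak
rise_cross <- function(y_s, i_on, pk, lvl, dt) {
  i <- pk
  while (i > i_on && y_s[i - 1] < lvl) i <- i - 1
  if (i == i_on || y_s[i - 1] == y_s[i]) return((i - 1) * dt)
  cross_time(i - 1, y_s[i - 1], y_s[i], lvl, dt)
}

count_runs <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  sum(r$values)
}

# single-exponential decay fit; returns tau (ms) and R^2 on the segment
fit_decay <- function(y_s, i_from, i_to, dt) {
  if (i_to - i_from < 4) return(list(tau = NaN, r2 = NaN))
  seg <- -y_s[i_from:i_to]
  t <- (seq_along(seg) - 1) * dt
  a0 <- seg[1]
  below <- which(seg < a0 / exp(1))
  tau0 <- if (length(below)) max(t[below[1]], dt) else t[length(t)] / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(seg ~ a * exp(-t / tau),
                      start = list(a = a0, tau = tau0),
                      lower = c(0, dt / 10),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(tau = NaN, r2 = NaN))
  res <- stats::resid(fit)
  tss <- sum((seg - mean(seg))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NaN
  list(tau = stats::coef(fit)[["tau"]], r2 = r2)
}

#' Measure kinetics of one EPSC
#'
#' Re-measures a single event inside `window`: baseline-subtracted peak
#' amplitude, 10-90% rise time (linear interpolation between samples),
#' monoexponential decay time constant fitted from 90% of peak to the return
#' to baseline, FWHM, and charge (trapezoidal integral from onset to return
#' to baseline with an analytic exponential tail correction).
#'
#' @inheritParams detect_events
#' @param window `c(start, end)` in ms bracketing the event.
#' @return one-row data frame as in [detect_events()] (without `evoked`).
#' @export
measure_event <- function(sweep, window, baseline_window,
                          threshold_mult = 4, smooth_ms = 0.3,
                          drift_ms = 20, decay_r2_min = 0.90) {
  pt <- process_trace(sweep, baseline_window, threshold_mult, smooth_ms,
                      drift_ms)
  dt <- sweep$dt
  i1 <- max(1L, floor((window[1] - sweep$t0) / dt) + 1L)
  i2 <- min(length(pt$y_s), floor((window[2] - sweep$t0) / dt) + 1L)
  if (i2 <= i1) stop("empty event window")
  pk <- i1 - 1L + which.min(pt$y_s[i1:i2])
  measure_region(pt, i1, i2, pk, dt, sweep$t0, decay_r2_min)
}

#' Classify an EPSC waveform as monophasic or multiphasic
#'
#' Monophasic means a steady rise to peak (no derivative sign reversal on
#' the rising limb exceeding twice the derivative noise SD) together with a
#' well-fitting monoexponential decay (R-squared at least `decay_r2_min`);
#' anything else is multiphasic.
#'
#' @inheritParams measure_event
#' @return `"monophasic"` or `"multiphasic"`.
#' @export
classify_waveform <- function(sweep, window, baseline_window,
                              threshold_mult = 4, smooth_ms = 0.3,
                              drift_ms = 20, decay_r2_min = 0.90) {
  ev <- measure_event(sweep, window, baseline_window, threshold_mult,
                      smooth_ms, drift_ms, decay_r2_min)
  ev$phasic_class
}

#' @export
print.epsc_events <- function(x, ...) {
  cat(sprintf("<epsc_events> %d events (threshold %.2f pA, baseline SD %.2f pA)\n",
              nrow(x), attr(x, "threshold"), attr(x, "baseline_sd")))
  if (nrow(x)) {
    cat(sprintf("  amplitude %.1f +/- %.1f pA, charge %.1f fC, %.0f%% monophasic\n",
                mean(x$amplitude), stats::sd(x$amplitude), mean(x$charge),
                100 * mean(x$phasic_class == "monophasic")))
    utils::head(as.data.frame(x), 5) |> print()
  }
  invisible(x)
}
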