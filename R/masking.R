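#' Average cumulative EPSC charge in response to the masker
#'
#' Baseline-subtracts the postsynaptic current of every repetition (mean
#' current over the 50 ms preceding the masker), averages across
#' repetitions, and integrates the average to a cumulative charge trace
#' (fC, magnitude of the inward charge) aligned to masker onset.
#'
#' @param sweeps repetitions of one forward-masking condition (same epoch
#'   table).
#' @return object of class `"q_trace"`: list with `t` (ms from masker
#'   onset), `q` (cumulative fC), `n_reps`, `masker_onset` (ms, sweep
#'   axis), `low_n` flag (fewer than 3 repetitions).
#' @export
average_masker_response <- function(sweeps) {
  if (!length(sweeps)) stop("no sweeps supplied")
  low_n <- length(sweeps) < 3
  if (low_n)
    warning("fewer than 3 repetitions; masker average will be noisy")
  sw1 <- sweeps[[1]]
  se <- stim_epochs(sw1)
  if (is.null(se) || nrow(se) == 0) stop("no masker epoch found")
  m_on <- se$start[1] - sw1$t0
  dt <- sw1$dt
  # repetitions of different ISI conditions share the masker but differ in
  # total length: align on the masker and crop to the shortest
  n <- min(vapply(sweeps, function(s) length(s$i_post), integer(1)))
  i0 <- max(1L, round((m_on - 50) / dt)); i1 <- round(m_on / dt)
  acc <- numeric(n)
  for (sw in sweeps)
    acc <- acc + (sw$i_post[seq_len(n)] - mean(sw$i_post[i0:i1]))
  avg <- acc / length(sweeps)
  on_idx <- round(m_on / dt) + 1L
  seg <- avg[on_idx:n]
  q <- -c(0, cumsum((seg[-length(seg)] + seg[-1]) / 2) * dt)
  structure(list(t = (seq_along(q) - 1) * dt, q = q, n_reps = length(sweeps),
                 masker_onset = se$start[1], low_n = low_n, dt = dt),
            class = "q_trace")
}

#' @export
print.q_trace <- function(x, ...) {
  cat(sprintf("<q_trace> mean of %d repetition(s), %.0f ms, final Q = %.0f fC\n",
              x$n_reps, max(x$t), x$q[length(x$q)]))
  invisible(x)
}

#' @export
plot.q_trace <- function(x, xlim = c(0, 100), ...) {
  plot(x$t, x$q, type = "l", xlab = "time from masker onset (ms)",
       ylab = "cumulative Q_EPSC (fC)", xlim = xlim, ...)
  invisible(x)
}

#' Latency and jitter of the first evoked EPSC
#'
#' Per repetition, the synaptic delay is the onset of the first detected
#' EPSC after stimulus onset minus the stimulus onset; the mean across
#' repetitions is the latency and their SD the jitter.
#'
#' @param sweeps repetitions of a stimulation sweep.
#' @param baseline_window unstimulated window for [detect_events()]
#'   (defaults to the stretch before the first stimulation epoch).
#' @param max_latency_ms ignore events later than this after onset (ms).
#' @param ... passed to [detect_events()].
#' @return list with `latency_mean`, `jitter_sd` (ms), `latencies`,
#'   `n_with_event`, `n_missing`.
#' @export
latency_stats <- function(sweeps, baseline_window = NULL,
                          max_latency_ms = 50, ...) {
  if (length(sweeps) < 3) warning("fewer than 3 repetitions")
  lats <- vapply(sweeps, function(sw) {
    se <- stim_epochs(sw)
    if (is.null(se) || nrow(se) == 0) return(NA_real_)
    on <- se$start[1]
    bw <- baseline_window
    if (is.null(bw)) bw <- c(sw$t0, on)
    ev <- detect_events(sw, bw, ...)
    cand <- ev$onset[ev$onset >= on & ev$onset <= on + max_latency_ms]
    if (!length(cand)) NA_real_ else min(cand) - on
  }, numeric(1))
  ok <- is.finite(lats)
  list(latency_mean = mean(lats[ok]), jitter_sd = stats::sd(lats[ok]),
       latencies = lats[ok], n_with_event = sum(ok), n_missing = sum(!ok))
}

#' Fit RRP depletion: exponential plus line
#'
#' Fits \eqn{y_0 + A_1 (1 - e^{-(x-x_0)/\tau}) + (x-x_0) \, slope} to the
#' first `fit_ms` (default 50) ms of the average cumulative charge trace in
#' response to the masker. Derived quanta use the pair's mean sEPSC charge:
#' RRP size \eqn{= A_1 / \bar{Q}_{sEPSC}} (vesicles), sustained rate
#' \eqn{= slope / \bar{Q}_{sEPSC}} (converted to vesicles/s), initial rate
#' \eqn{= (A_1/\tau + slope)/\bar{Q}_{sEPSC}} (the derivative of the fit at
#' \eqn{x_0}), and the depression ratio initial/sustained (NaN when the
#' sustained rate is zero). `x0` is constrained to at most `x0_max` (5 ms)
#' after the masker onset so the line term cannot absorb the exponential.
#'
#' @param q_trace an [average_masker_response()] result, or a list with
#'   `t` (ms) and `q` (fC).
#' @param mean_sepsc_charge mean spontaneous EPSC charge of the same pair
#'   (fC, magnitude).
#' @param fit_ms fitted stretch after masker onset (ms).
#' @param x0_max upper bound of the fit-onset offset (ms).
#' @return object of class `"depletion_fit"` with `y0`, `a1` (fC), `x0`
#'   (ms), `tau` (ms), `line_slope` (fC/ms), `rrp_sv`, `initial_rate`,
#'   `sustained_rate` (SV/s), `depression_ratio`, `rmse`, `fit_ok`.
#' @export
fit_depletion <- function(q_trace, mean_sepsc_charge, fit_ms = 50,
                          x0_max = 5) {
  if (!is.finite(mean_sepsc_charge) || mean_sepsc_charge <= 0)
    stop("mean_sepsc_charge must be positive")
  t <- q_trace$t; q <- q_trace$q
  if (max(t) < fit_ms - 1e-9)
    stop("trace must cover at least ", fit_ms, " ms after masker onset")
  sel <- t <= fit_ms
  dat <- data.frame(x = t[sel], y = q[sel])
  a1_0 <- max(stats::quantile(dat$y, 0.5), 1e-6)
  slope_0 <- max((dat$y[nrow(dat)] - a1_0) / fit_ms, 0)
  starts <- list(
    list(y0 = 0, a1 = a1_0, x0 = 1, tau = 5, slope = slope_0),
    list(y0 = 0, a1 = a1_0 * 1.5, x0 = 0.5, tau = 15, slope = slope_0 / 2),
    list(y0 = dat$y[1], a1 = a1_0 / 2, x0 = 2, tau = 2, slope = slope_0 * 2)
  )
  model <- y ~ y0 + a1 * (1 - exp(-pmax(x - x0, 0) / tau)) +
    pmax(x - x0, 0) * slope
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(model, data = dat, start = st,
                        lower = c(-Inf, 0, 0, 1e-3, 0),
                        upper = c(Inf, Inf, x0_max, Inf, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(structure(list(y0 = NaN, a1 = NaN, x0 = NaN, tau = NaN,
                          line_slope = NaN, rrp_sv = NaN,
                          initial_rate = NaN, sustained_rate = NaN,
                          depression_ratio = NaN, rmse = NaN,
                          fit_ok = FALSE),
                     class = "depletion_fit"))
  cf <- stats::coef(best$fit)
  qbar <- mean_sepsc_charge
  rrp <- cf[["a1"]] / qbar
  sus <- cf[["slope"]] / qbar * 1000                 # 1/ms -> 1/s
  init <- (cf[["a1"]] / cf[["tau"]] + cf[["slope"]]) / qbar * 1000
  # a numerically-zero line slope means no sustained release: the
  # depression ratio is undefined, not astronomically large
  if (sus < 1e-6 * max(init, 1)) sus <- 0
  structure(list(y0 = cf[["y0"]], a1 = cf[["a1"]], x0 = cf[["x0"]],
                 tau = cf[["tau"]], line_slope = cf[["slope"]],
                 rrp_sv = rrp, initial_rate = init, sustained_rate = sus,
                 depression_ratio = if (sus > 0) init / sus else NaN,
                 rmse = sqrt(best$rss / nrow(dat)), fit_ok = TRUE),
            class = "depletion_fit")
}

#' @export
coef.depletion_fit <- function(object, ...) {
  c(y0 = object$y0, a1 = object$a1, x0 = object$x0, tau = object$tau,
    slope = object$line_slope)
}

#' @export
print.depletion_fit <- function(x, ...) {
  if (!x$fit_ok) {
    cat("<depletion_fit> flagged failure\n"); return(invisible(x))
  }
  cat(sprintf("<depletion_fit> A1 = %.0f fC, tau = %.2f ms, slope = %.2f fC/ms (x0 %.2f ms)\n",
              x$a1, x$tau, x$line_slope, x$x0))
  cat(sprintf("  RRP = %.2f SV; rates: initial %.0f, sustained %.0f SV/s (ratio %.2f)\n",
              x$rrp_sv, x$initial_rate, x$sustained_rate,
              x$depression_ratio))
  invisible(x)
}

#' Recovery of the probe response after the masker
#'
#' Groups forward-masking sweeps by their interstimulus interval (inferred
#' from the epoch table: gap between masker end and probe start), averages
#' each condition, and computes the ratio of probe to masker charge over the
#' first 10 ms of the respective depolarization. The masker-to-masker
#' interval (default 20 s) is appended with ratio 1 by definition. Also
#' reports the delay from probe offset to the first spontaneous EPSC within
#' the 400 ms post-probe window (mean across sweeps with such an event;
#' NaN when none).
#'
#' @param sweeps forward-masking sweeps (all repetitions, all ISIs).
#' @param window_ms charge-integration window from stimulus onset (ms).
#' @param masker_interval_ms masker-to-masker interval appended with ratio
#'   1 (ms).
#' @param detect_args list of arguments passed to [detect_events()] for the
#'   post-probe spontaneous events.
#' @return object of class `"recovery_curve"`: data frame `isi_ms`,
#'   `ratio`, plus attributes `time_to_first_sepsc` (ms) and `flagged`
#'   (TRUE when a masker released no charge).
#' @export
recovery_curve <- function(sweeps, window_ms = 10,
                           masker_interval_ms = 20000,
                           detect_args = list()) {
  if (!length(sweeps)) stop("no FM sweeps supplied")
  isi_of <- function(sw) {
    se <- stim_epochs(sw)
    if (is.null(se) || nrow(se) < 2) return(NA_real_)
    se <- se[order(se$start), ]
    se$start[2] - se$end[1]
  }
  isis <- vapply(sweeps, isi_of, numeric(1))
  if (anyNA(isis)) stop("FM sweeps must contain masker and probe epochs")
  flagged <- FALSE
  ttf_all <- numeric(0)
  rows <- lapply(sort(unique(isis)), function(isi) {
    grp <- sweeps[isis == isi]
    sw1 <- grp[[1]]
    se <- stim_epochs(sw1); se <- se[order(se$start), ]
    dt <- sw1$dt
    qm <- qp <- 0
    for (sw in grp) {
      i0 <- max(1L, round((se$start[1] - sw$t0 - 50) / dt))
      i1 <- round((se$start[1] - sw$t0) / dt)
      base <- mean(sw$i_post[i0:i1])
      qm <- qm + abs(trapz_window(sw$i_post - base, dt, se$start[1] - sw$t0,
                                  se$start[1] - sw$t0 + window_ms))
      qp <- qp + abs(trapz_window(sw$i_post - base, dt, se$start[2] - sw$t0,
                                  se$start[2] - sw$t0 + window_ms))
    }
    if (qm <= 0) flagged <<- TRUE
    # time from probe offset to the first spontaneous event
    for (sw in grp) {
      probe_off <- se$end[2]
      bw <- c(sw$t0, se$start[1])
      ev <- tryCatch(do.call(detect_events, c(list(sw, bw), detect_args)),
                     error = function(e) empty_events())
      cand <- ev$onset[ev$onset > probe_off + 2 &
                         ev$onset <= probe_off + 400]
      if (length(cand))
        ttf_all <<- c(ttf_all, min(cand) - probe_off)
    }
    data.frame(isi_ms = isi, ratio = if (qm > 0) qp / qm else NaN)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(isi_ms = masker_interval_ms, ratio = 1))
  structure(out, class = c("recovery_curve", "data.frame"),
            time_to_first_sepsc = if (length(ttf_all)) mean(ttf_all) else NaN,
            flagged = flagged)
}

#' @export
plot.recovery_curve <- function(x, ...) {
  plot(x$isi_ms, x$ratio, log = "x", pch = 16, type = "b",
       xlab = "interstimulus interval (ms)",
       ylab = "Q_probe / Q_masker", ylim = c(0, max(1, x$ratio)), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Fit the recovery time constant
#'
#' Single-exponential fit \eqn{R(t) = 1 - (1 - R_0) e^{-t/\tau}} to the
#' recovery ratios over interstimulus intervals from `fit_from` (default
#' 16 ms, excluding the anomalous 4 ms point) to the masker-to-masker
#' interval, with full recovery (R = 1) imposed at infinity.
#'
#' @param curve a [recovery_curve()] data frame.
#' @param fit_from smallest ISI included in the fit (ms).
#' @return list of class `"recovery_fit"` with `tau_recovery` (ms), `r0`,
#'   `fit_ok`, `reason`.
#' @export
fit_recovery <- function(curve, fit_from = 16) {
  sel <- curve$isi_ms >= fit_from & is.finite(curve$ratio)
  dat <- data.frame(t = curve$isi_ms[sel], r = curve$ratio[sel])
  if (nrow(dat) < 3)
    return(structure(list(tau_recovery = NaN, r0 = NaN, fit_ok = FALSE,
                          reason = "fewer than 3 usable ratios"),
                     class = "recovery_fit"))
  if (all(abs(dat$r - 1) < 1e-9))
    return(structure(list(tau_recovery = NaN, r0 = 1, fit_ok = FALSE,
                          reason = "no depression: all ratios 1"),
                     class = "recovery_fit"))
  r0_0 <- min(dat$r)
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ 1 - (1 - r0) * exp(-t / tau), data = dat,
                      start = list(r0 = max(min(r0_0, 0.99), 0), tau = 300),
                      lower = c(-1, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(tau_recovery = NaN, r0 = NaN, fit_ok = FALSE,
                          reason = "fit did not converge"),
                     class = "recovery_fit"))
  cf <- stats::coef(fit)
  ok <- is.finite(cf[["tau"]]) && cf[["tau"]] > 0 && cf[["r0"]] < 1
  structure(list(tau_recovery = cf[["tau"]], r0 = cf[["r0"]], fit_ok = ok,
                 reason = if (ok) NULL else "non-monotone recovery data"),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  if (x$fit_ok)
    cat(sprintf("<recovery_fit> tau = %.0f ms (R0 = %.2f)\n",
                x$tau_recovery, x$r0))
  else cat("<recovery_fit> flagged:", x$reason, "\n")
  invisible(x)
}
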