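#' Leak-subtract a sweep using P/n calibration sweeps
#'
#' The P/n calibration sweeps carry a scaled replica of the main command.
#' The scale factor `s` (1/n for a classic P/n protocol, -1/n for the
#' inverted -P/n variant) is estimated by least squares from the stored
#' command waveforms, and the leak-corrected presynaptic current is
#' `i_pre - mean(pn i_pre)/s`. For textbook P/n sweeps (s = 1/n) this equals
#' the usual `i_pre - n * mean(pn)`.
#'
#' @param main the sweep to correct.
#' @param pn_sweeps list of P/n sweeps (equal length, same dt).
#' @param n expected divisor (used only as a fallback when the commands are
#'   flat and the scale cannot be estimated).
#' @return a copy of `main` with `i_pre` leak-subtracted.
#' @export
leak_subtract <- function(main, pn_sweeps, n = 4) {
  stopifnot(inherits(main, "sweep"), length(pn_sweeps) >= 1)
  len <- length(main$i_pre)
  for (s in pn_sweeps)
    if (length(s$i_pre) != len)
      stop("P/n sweep length does not match the main sweep")
  pn_i <- rowMeans(vapply(pn_sweeps, `[[`, numeric(len), "i_pre"))
  v_hold <- main$v_cmd[1]
  dv_main <- main$v_cmd - v_hold
  dv_pn <- pn_sweeps[[1]]$v_cmd - pn_sweeps[[1]]$v_cmd[1]
  denom <- sum(dv_main^2)
  s <- if (denom > 0) sum(dv_pn * dv_main) / denom else 1 / n
  if (abs(s) < 1e-6) s <- 1 / n
  # only the pulse-evoked delta of the calibration sweeps is scaled: any
  # standing current at holding must not be amplified by 1/s
  at_hold <- abs(dv_pn) < 1e-9
  base_pn <- if (any(at_hold)) mean(pn_i[at_hold]) else 0
  out <- main
  out$i_pre <- main$i_pre - (pn_i - base_pn) / s
  out
}

#' Build the Ca2+ current-voltage curve
#'
#' For each IV sweep, the evoked Ca2+ current is averaged over a 10 ms
#' window after the start of the depolarization (`i_ca`) and integrated
#' over the same window (`q_ca`). By default nothing further is subtracted:
#' a P/n-corrected trace is the Ca2+ current, including its standing
#' component at holding, and removing the pre-step level would distort the
#' chord conductance near threshold. Set `baseline_ms` to subtract the mean
#' current over that many ms before each step (for traces with uncorrected
#' offsets).
#'
#' @param sweeps list of (leak-subtracted) IV sweeps, one step each.
#' @param avg_ms averaging/integration window after step onset (ms).
#' @param baseline_ms optional pre-step baseline window (ms); `NULL` (the
#'   default) subtracts nothing.
#' @return data frame of class `"iv_curve"` with columns `v` (mV,
#'   increasing), `i_ca` (pA) and `q_ca` (fC).
#' @export
iv_curve <- function(sweeps, avg_ms = 10, baseline_ms = NULL) {
  rows <- lapply(sweeps, function(sw) {
    se <- stim_epochs(sw)
    if (is.null(se) || nrow(se) == 0)
      stop("IV sweep without a stimulation epoch")
    st <- se$start[1] - sw$t0
    en <- se$end[1] - sw$t0
    if (en - st < avg_ms - 1e-9)
      stop(sprintf("step (%.3g ms) shorter than the %g ms averaging window",
                   en - st, avg_ms))
    dt <- sw$dt
    base <- 0
    if (!is.null(baseline_ms)) {
      n0 <- max(1L, floor(st / dt) - round(baseline_ms / dt))
      base <- mean(sw$i_pre[n0:max(n0, floor(st / dt))])
    }
    i_ca <- trapz_window(sw$i_pre - base, dt, st, st + avg_ms) / avg_ms
    q_ca <- trapz_window(sw$i_pre - base, dt, st, st + avg_ms)
    data.frame(v = se$level[1], i_ca = i_ca, q_ca = q_ca)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$v), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("iv_curve", "data.frame"))
}

#' Reversal potential from the linear limb of the IV curve
#'
#' Fits a line through the IV points from 10 mV above the voltage of peak
#' inward current up to the maximal depolarization and returns its zero
#' crossing.
#'
#' @param iv an [iv_curve()] data frame.
#' @param min_points minimum qualifying points (default 3).
#' @return the reversal potential (mV) with attribute `extrapolated` set to
#'   `TRUE` when the zero crossing lies outside the fitted voltage range.
#' @export
reversal_potential <- function(iv, min_points = 3) {
  v_peak <- iv$v[which.min(iv$i_ca)]
  sel <- iv$v >= v_peak + 10
  if (sum(sel) < min_points)
    stop("fewer than ", min_points, " IV points above the Ca2+ current peak",
         " + 10 mV; record a wider voltage protocol")
  fit <- stats::lm(i_ca ~ v, data = iv[sel, ])
  cf <- stats::coef(fit)
  if (abs(cf[2]) < .Machine$double.eps)
    stop("flat IV limb: reversal potential undefined")
  v_rev <- -cf[[1]] / cf[[2]]
  extrap <- v_rev < min(iv$v[sel]) || v_rev > max(iv$v[sel])
  structure(v_rev, extrapolated = extrap)
}

#' Fit the Boltzmann activation curve of the Ca2+ conductance
#'
#' Chord conductances \eqn{g = I_{Ca}/(V - V_{rev})} are computed from the
#' IV points (voltages within `exclude_mv` of the reversal potential are
#' excluded because the chord blows up there) and fitted with a first-order
#' Boltzmann \eqn{g = g_{max}/(1 + e^{(V_{half} - V)/S})} by least squares
#' with multi-start initialization (half-max crossing for V_half, 25--75%
#' span for the slope).
#'
#' @param iv an [iv_curve()].
#' @param v_rev reversal potential (mV), e.g. from [reversal_potential()].
#' @param exclude_mv exclusion half-width around `v_rev` (mV).
#' @param threshold_frac fractional activation defining the reported
#'   voltage threshold of Ca2+ influx (default 0.05).
#' @return object of class `"boltzmann_fit"`: `g_max` (nS), `v_half` (mV),
#'   `slope` (mV), `v_rev`, `threshold_v` (voltage of 5% activation),
#'   `rmse`, `ok`, plus the data used. `coef()`, `predict()` (fractional
#'   activation at new voltages) and `print()` methods are provided.
#' @export
fit_boltzmann <- function(iv, v_rev, exclude_mv = 5, threshold_frac = 0.05) {
  sel <- abs(iv$v - v_rev) > exclude_mv & iv$v < v_rev
  v <- iv$v[sel]
  g <- iv$i_ca[sel] / (v - v_rev)           # pA/mV = nS
  dat <- data.frame(v = v, g = g)
  g_max0 <- max(g)
  if (g_max0 <= 0) return(flag_boltzmann(iv, v_rev, dat))
  vh0 <- stats::approx(g / g_max0, v, xout = 0.5, ties = mean)$y
  v25 <- stats::approx(g / g_max0, v, xout = 0.25, ties = mean)$y
  v75 <- stats::approx(g / g_max0, v, xout = 0.75, ties = mean)$y
  s0 <- if (is.finite(v25) && is.finite(v75) && v75 > v25)
    (v75 - v25) / (2 * log(3)) else 7
  if (!is.finite(vh0)) vh0 <- stats::median(v)
  starts <- list(
    list(gmax = g_max0, vh = vh0, s = s0),
    list(gmax = g_max0 * 1.2, vh = vh0 - 5, s = s0 * 2),
    list(gmax = g_max0 * 1.1, vh = vh0 + 5, s = max(s0 / 2, 1))
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(g ~ gmax / (1 + exp((vh - v) / s)), data = dat,
                        start = st, lower = c(1e-6, -150, 0.1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(flag_boltzmann(iv, v_rev, dat))
  cf <- stats::coef(best$fit)
  structure(list(
    g_max = cf[["gmax"]], v_half = cf[["vh"]], slope = cf[["s"]],
    v_rev = as.numeric(v_rev),
    threshold_v = cf[["vh"]] - cf[["s"]] * log(1 / threshold_frac - 1),
    rmse = sqrt(best$rss / nrow(dat)), ok = TRUE, data = dat
  ), class = "boltzmann_fit")
}

flag_boltzmann <- function(iv, v_rev, dat) {
  structure(list(g_max = NaN, v_half = NaN, slope = NaN,
                 v_rev = as.numeric(v_rev), threshold_v = NaN, rmse = NaN,
                 ok = FALSE, data = dat),
            class = "boltzmann_fit")
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(g_max = object$g_max, v_half = object$v_half, slope = object$slope,
    v_rev = object$v_rev)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$v else
    if (is.data.frame(newdata)) newdata$v else newdata
  boltz_frac(v, object$v_half, object$slope)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (!x$ok) {
    cat("<boltzmann_fit> failed to converge\n"); return(invisible(x))
  }
  cat(sprintf("<boltzmann_fit> g_max = %.3g nS, V_half = %.2f mV, slope = %.2f mV\n",
              x$g_max, x$v_half, x$slope))
  cat(sprintf("  V_rev = %.1f mV, 5%% activation threshold = %.2f mV, RMSE %.3g nS\n",
              x$v_rev, x$threshold_v, x$rmse))
  invisible(x)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  plot(x$data$v, x$data$g / x$g_max, xlab = "V (mV)",
       ylab = "fractional activation", pch = 16, ...)
  vv <- seq(min(x$data$v), max(x$data$v), length.out = 200)
  graphics::lines(vv, predict(x, vv))
  graphics::abline(v = x$v_half, lty = 3)
  invisible(x)
}

#' @export
plot.iv_curve <- function(x, ...) {
  plot(x$v, x$i_ca, type = "b", pch = 16, xlab = "V (mV)",
       ylab = "I_Ca (pA)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
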