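#' Estimate access resistance, capacitance and membrane resistance
#'
#' Offline passive-membrane estimates from the capacitive transient evoked
#' by a small voltage step (default 10 mV test pulse). The decay phase of
#' the transient is fitted with a double exponential
#' \eqn{I(t) = A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s} + I_{ss}}; then
#' \itemize{
#' \item \eqn{R_s = \Delta V / I(0^+)} with \eqn{I(0^+) = A_f + A_s + I_{ss}},
#' \item \eqn{R_m = \Delta V / I_{ss} - R_s},
#' \item \eqn{C_m} from the area under the fast component,
#'   \eqn{A_f \tau_f / \Delta V}, corrected by \eqn{((R_s+R_m)/R_m)^2} for
#'   the steady-state current carried by \eqn{R_m} (the correction makes the
#'   estimate exact for a single-RC cell).
#' }
#' When the data are effectively single-exponential the slow component is
#' dropped. Units: MOhm, pF, with mV/pA traces (1 mV/MOhm = 1000 pA).
#'
#' @param testpulse a [sweep_record()] containing the step response in
#'   `i_post` and the step in `v_cmd` (epoch table used to locate it).
#' @param step_mv step amplitude (mV).
#' @return object of class `"access_estimate"`: list with `rs`, `cm`, `rm`
#'   (NaN when flagged), `ok`, `reason`, `tau_fast`, `tau_slow`.
#' @examples
#' tp <- simulate_testpulse(rs = 60, cm = 1.7, rm = 1500)
#' estimate_access(tp)
#' @export
estimate_access <- function(testpulse, step_mv = 10) {
  stopifnot(inherits(testpulse, "sweep"))
  dt <- testpulse$dt
  i <- testpulse$i_post
  ep <- testpulse$epoch_table
  if (!is.null(ep) && nrow(ep)) {
    on <- round(ep$start[1] / dt) + 1L
    off <- min(length(i), round(ep$end[1] / dt))
  } else {
    dv <- abs(diff(testpulse$v_cmd))
    on <- which(dv > 1e-6)[1] + 1L
    if (is.na(on)) return(flag_access("no voltage step found"))
    off <- length(i)
  }
  base_sd <- if (on > 2) stats::sd(i[1:(on - 1)]) else 0
  seg <- i[on:off]
  pk <- which.max(abs(seg))
  iss <- mean(seg[max(1, length(seg) - round(length(seg) / 5)):length(seg)])
  sgn <- sign(seg[pk] - iss)
  if (sgn == 0 || abs(seg[pk] - iss) <= max(5 * base_sd, 1e-6))
    return(flag_access("no capacitive transient above noise"))
  y <- sgn * (seg[pk:length(seg)] - iss)          # positive decay, offset out
  t <- (seq_along(y) - 1) * dt
  # single-exponential start from log-linear regression on the early decay
  pos <- which(y > max(y) * 0.02)
  pos <- pos[pos <= max(10, floor(length(y) / 2))]
  if (length(pos) < 4) return(flag_access("decay too short to fit"))
  lf <- stats::lm(log(y[pos]) ~ t[pos])
  tau1 <- max(dt / 2, -1 / stats::coef(lf)[[2]])
  a1 <- exp(stats::coef(lf)[[1]])
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      y ~ af * exp(-t / tf) + as * exp(-t / ts),
      start = list(af = a1 * 0.9, tf = tau1 * 0.7, as = a1 * 0.1, ts = tau1 * 4),
      lower = c(0, dt / 10, 0, dt / 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  use_double <- FALSE
  if (!is.null(fit2)) {
    cf <- stats::coef(fit2)
    # keep the double fit only if the components are genuinely distinct
    if (is.finite(cf["ts"]) && cf["ts"] > 1.5 * cf["tf"] &&
        cf["as"] > 1e-3 * cf["af"]) use_double <- TRUE
  }
  if (use_double) {
    af <- cf[["af"]]; tf <- cf[["tf"]]; as_ <- cf[["as"]]; ts_ <- cf[["ts"]]
  } else {
    fit1 <- tryCatch(
      minpack.lm::nlsLM(y ~ af * exp(-t / tf),
                        start = list(af = a1, tf = tau1),
                        lower = c(0, dt / 10)),
      error = function(e) NULL)
    if (is.null(fit1)) return(flag_access("transient fit did not converge"))
    cf <- stats::coef(fit1)
    af <- cf[["af"]]; tf <- cf[["tf"]]; as_ <- 0; ts_ <- NA_real_
  }
  i0 <- sgn * (af + as_) + iss                     # extrapolated I(0+), pA
  if (abs(i0) < 1e-9 || abs(iss) < 1e-12)
    return(flag_access("degenerate current levels"))
  rs <- 1000 * step_mv / abs(i0)
  rm <- 1000 * step_mv / abs(iss) - rs
  if (!is.finite(rm) || rm <= 0)
    return(flag_access("non-physical membrane resistance"))
  cm <- (af * tf) / step_mv * ((rs + rm) / rm)^2
  structure(list(rs = rs, cm = cm, rm = rm, ok = TRUE, reason = NULL,
                 tau_fast = tf, tau_slow = ts_),
            class = "access_estimate")
}

flag_access <- function(reason) {
  structure(list(rs = NaN, cm = NaN, rm = NaN, ok = FALSE, reason = reason,
                 tau_fast = NaN, tau_slow = NaN),
            class = "access_estimate")
}

#' @export
print.access_estimate <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<access_estimate> Rs = %.1f MOhm, Cm = %.2f pF, Rm = %.0f MOhm (tau_f %.3g ms)\n",
                x$rs, x$cm, x$rm, x$tau_fast))
  else cat("<access_estimate> flagged:", x$reason, "\n")
  invisible(x)
}
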