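#' Biexponential EPSC kernel
#'
#' Unit event waveform \eqn{k(t) = A (e^{-t/\tau_d} - e^{-t/\tau_r})},
#' scaled so the extremum equals `amp`. The extremum occurs at
#' \eqn{t^* = \tau_r \tau_d / (\tau_d - \tau_r) \, \ln(\tau_d/\tau_r)} and the
#' total charge is \eqn{A(\tau_d - \tau_r)} (fC for pA amplitudes and ms
#' taus).
#'
#' @param amp extremum of the kernel (pA); EPSCs use negative values.
#' @param tau_rise,tau_decay rise and decay time constants (ms);
#'   `tau_rise < tau_decay` required.
#' @param dt sampling interval (ms).
#' @param n_tail kernel length in units of `tau_decay` (default 12, keeping
#'   truncation error below 1e-5 of the charge).
#' @return numeric waveform samples starting at t = 0.
#' @seealso [kernel_charge()], [kernel_peak_time()]
#' @export
make_epsc_kernel <- function(amp, tau_rise, tau_decay, dt = 0.02, n_tail = 12) {
  if (!(tau_rise > 0 && tau_decay > tau_rise))
    stop("need 0 < tau_rise < tau_decay")
  tmax <- n_tail * tau_decay
  t <- seq(0, tmax, by = dt)
  shape <- exp(-t / tau_decay) - exp(-t / tau_rise)
  peak <- kernel_peak_factor(tau_rise, tau_decay)
  amp * shape / peak
}

# value of exp(-t*/tau_d) - exp(-t*/tau_r) at the extremum
kernel_peak_factor <- function(tau_rise, tau_decay) {
  ts <- kernel_peak_time(tau_rise, tau_decay)
  exp(-ts / tau_decay) - exp(-ts / tau_rise)
}

#' @rdname make_epsc_kernel
#' @export
kernel_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' @rdname make_epsc_kernel
#' @export
kernel_charge <- function(amp, tau_rise, tau_decay) {
  amp / kernel_peak_factor(tau_rise, tau_decay) * (tau_decay - tau_rise)
}
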