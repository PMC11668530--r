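#' Ground truth for simulated paired recordings
#'
#' Collects every parameter of the generative model, and after simulation
#' also the exact release-event times, so each analysis stage can be scored
#' by parameter recovery. Defaults describe a typical afferent IHC--SGN
#' synapse of a hearing mouse: right-skewed quantal amplitudes (mean 80 pA,
#' CV 0.68, mean charge near 70 fC with the default kernel), Boltzmann-gated
#' whole-cell Ca2+ current, and a readily releasable pool of ~14 vesicles
#' that depletes with a ~6 ms time constant and recovers with a ~450 ms time
#' constant. Use [ground_truth_preset()] for the high-SR / low-SR parameter
#' sets.
#'
#' @param sr_true spontaneous release rate (events/s), 0--18/s physiological.
#' @param amp_mean,amp_cv mean and coefficient of variation of quantal EPSC
#'   amplitude magnitudes (pA); amplitudes are gamma distributed, so the
#'   implied skewness is `2 * amp_cv`.
#' @param tau_rise,tau_decay EPSC kernel time constants (ms).
#' @param frac_multiphasic fraction of release events rendered as 2--4
#'   jittered sub-events (compound, multiphasic waveforms).
#' @param g_max,v_half,slope,v_rev Boltzmann Ca2+ conductance parameters
#'   (nS, mV, mV, mV).
#' @param leak_g linear leak conductance (nS), relative to holding.
#' @param tau_act Ca2+-current activation time constant (ms).
#' @param coupling_m apparent Ca2+ cooperativity exponent: the fraction of
#'   release sites recruited by a depolarization scales with the increment
#'   of the Ca2+ drive over its standing value at holding, raised to this
#'   power.
#' @param n_rrp readily releasable pool size (vesicles).
#' @param tau_depletion RRP depletion time constant at the reference
#'   (saturating) depolarization (ms).
#' @param sustained_rate sustained release rate at the reference
#'   depolarization (vesicles/s).
#' @param tau_recovery pool replenishment time constant (ms).
#' @param latency0 fixed synaptic delay (ms).
#' @param latency_jitter mean of the exponential latency jitter (ms).
#' @param v_ref_release depolarization level (mV) at which release-site
#'   recruitment saturates (all sites recruited). The default -35 mV places
#'   the saturation of release well below the Ca2+-current maximum, which
#'   reproduces the measured release-intensity curves (release saturating
#'   near -38 mV while the Ca2+ current still grows).
#' @param noise_sd_post,noise_sd_pre Gaussian recording noise SD (pA).
#' @param seed integer seed; all simulator output is reproducible from it.
#' @return object of class `"ground_truth"`.
#' @export
ground_truth <- function(sr_true = 1,
                         amp_mean = 80, amp_cv = 0.68,
                         tau_rise = 0.15, tau_decay = 0.55,
                         frac_multiphasic = 0.5,
                         g_max = 5, v_half = -30, slope = 7, v_rev = 60,
                         leak_g = 0.5, tau_act = 0.3,
                         coupling_m = 1.0,
                         n_rrp = 14, tau_depletion = 6.3,
                         sustained_rate = 430, tau_recovery = 450,
                         latency0 = 1.2, latency_jitter = 0.3,
                         v_ref_release = -35,
                         noise_sd_post = 6, noise_sd_pre = 3,
                         seed = NULL) {
  stopifnot(sr_true >= 0, amp_mean > 0, amp_cv >= 0,
            tau_rise > 0, tau_decay > tau_rise,
            frac_multiphasic >= 0, frac_multiphasic <= 1,
            g_max >= 0, slope > 0, leak_g >= 0, tau_act > 0,
            coupling_m > 0, n_rrp > 0, tau_depletion > 0,
            sustained_rate >= 0, tau_recovery > 0,
            latency0 >= 0, latency_jitter >= 0,
            noise_sd_post >= 0, noise_sd_pre >= 0)
  structure(list(
    sr_true = sr_true, amp_mean = amp_mean, amp_cv = amp_cv,
    tau_rise = tau_rise, tau_decay = tau_decay,
    frac_multiphasic = frac_multiphasic,
    g_max = g_max, v_half = v_half, slope = slope, v_rev = v_rev,
    leak_g = leak_g, tau_act = tau_act, coupling_m = coupling_m,
    n_rrp = n_rrp, tau_depletion = tau_depletion,
    sustained_rate = sustained_rate, tau_recovery = tau_recovery,
    latency0 = latency0, latency_jitter = latency_jitter,
    v_ref_release = v_ref_release,
    noise_sd_post = noise_sd_post, noise_sd_pre = noise_sd_pre,
    seed = seed, event_times = NULL
  ), class = "ground_truth")
}

#' High-SR / low-SR simulator presets
#'
#' Parameter sets emulating the two synapse classes: high-SR synapses have
#' larger quantal amplitudes, more monophasic events, shorter latency and
#' jitter, faster pool depletion and lower apparent Ca2+ cooperativity
#' (m near 0.8); low-SR synapses the converse (m near 1.4, slower depletion,
#' longer and more variable latency).
#'
#' @param class `"high"` or `"low"`.
#' @param ... overrides passed on to [ground_truth()].
#' @return a [ground_truth()] object.
#' @export
ground_truth_preset <- function(class = c("high", "low"), ...) {
  class <- match.arg(class)
  args <- if (class == "high") {
    list(sr_true = 4, amp_mean = 105, frac_multiphasic = 0.48,
         coupling_m = 0.8, n_rrp = 14, tau_depletion = 6.3,
         sustained_rate = 445, tau_recovery = 450,
         latency0 = 1.17, latency_jitter = 0.38)
  } else {
    list(sr_true = 0.2, amp_mean = 62, frac_multiphasic = 0.7,
         coupling_m = 1.4, n_rrp = 14.3, tau_depletion = 20.9,
         sustained_rate = 455, tau_recovery = 450,
         latency0 = 3.34, latency_jitter = 1.0)
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(ground_truth, args)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> SR %.2g /s, quanta %.0f pA (CV %.2f), m = %.2f\n",
              x$sr_true, x$amp_mean, x$amp_cv, x$coupling_m))
  cat(sprintf("  Boltzmann: g_max %.2g nS, V_half %.1f mV, slope %.1f mV, V_rev %.0f mV\n",
              x$g_max, x$v_half, x$slope, x$v_rev))
  cat(sprintf("  pool: %.3g SV, tau_dep %.3g ms, sustained %.0f SV/s, tau_rec %.0f ms\n",
              x$n_rrp, x$tau_depletion, x$sustained_rate, x$tau_recovery))
  if (!is.null(x$event_times))
    cat(sprintf("  %d recorded release events\n", nrow(x$event_times)))
  invisible(x)
}
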