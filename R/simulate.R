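#' Simulate spontaneous EPSC activity
#'
#' Homogeneous Poisson release at `truth$sr_true` with gamma-distributed
#' quantal amplitudes (mean `amp_mean`, CV `amp_cv`). A fraction
#' `frac_multiphasic` of events is rendered as compound waveforms of 2--4
#' sub-events whose onsets are jittered within a 1.5 ms window (minimum
#' separation 0.2 ms so sub-events remain resolvable). Gaussian recording
#' noise of SD `noise_sd_post` is added to the postsynaptic trace and
#' `noise_sd_pre` to the presynaptic trace. The exact event onsets (after
#' synaptic placement) are recorded in the returned ground truth.
#'
#' @param truth a [ground_truth()] object; `truth$seed` (if non-NULL) makes
#'   the output reproducible.
#' @param duration_ms recording duration (ms).
#' @param v_hold holding potential written to `v_cmd` (mV).
#' @param dt sampling interval (ms).
#' @return list with elements `sweep` (a [sweep_record()], tag `"spont"`)
#'   and `truth` (input truth with `event_times` filled: data frame with
#'   columns `t_ms`, `amp`, `n_sub`, `evoked`).
#' @export
simulate_spontaneous <- function(truth, duration_ms = 10000, v_hold = -58,
                                 dt = 0.02) {
  stopifnot(inherits(truth, "ground_truth"), duration_ms > 0)
  if (!is.null(truth$seed)) set.seed(truth$seed)
  n <- round(duration_ms / dt)
  ev <- sim_poisson_events(truth$sr_true, duration_ms)
  res <- sim_events_to_trace(ev, n, dt, truth, latency = FALSE)
  i_post <- res$trace + stats::rnorm(n, 0, truth$noise_sd_post)
  i_pre <- stats::rnorm(n, 0, truth$noise_sd_pre)
  sw <- sweep_record(rep(v_hold, n), i_pre, i_post, dt = dt,
                     protocol_tag = "spont")
  truth$event_times <- res$events
  list(sweep = sw, truth = truth)
}

# homogeneous Poisson onset times in (0, duration)
sim_poisson_events <- function(rate_per_s, duration_ms) {
  lambda <- rate_per_s * duration_ms / 1000
  k <- stats::rpois(1, lambda)
  data.frame(t_ms = sort(stats::runif(k, 0, duration_ms)),
             evoked = rep(FALSE, k))
}

# draw quantal amplitude magnitudes (pA)
sim_amplitudes <- function(k, truth) {
  if (k == 0) return(numeric(0))
  if (truth$amp_cv <= 0) return(rep(truth$amp_mean, k))
  shape <- 1 / truth$amp_cv^2
  stats::rgamma(k, shape = shape, scale = truth$amp_mean / shape)
}

# Render release events into a postsynaptic current trace (pA, negative
# deflections). Applies synaptic latency when asked, splits multiphasic
# events into jittered sub-kernels, convolves with the EPSC kernel.
# Returns the noiseless trace plus the realized event table.
sim_events_to_trace <- function(events, n, dt, truth, latency = TRUE) {
  k <- nrow(events)
  kern <- make_epsc_kernel(-1, truth$tau_rise, truth$tau_decay, dt)
  imp <- numeric(n + length(kern))
  if (k > 0) {
    t_on <- events$t_ms
    if (latency)
      t_on <- t_on + truth$latency0 +
        (if (truth$latency_jitter > 0) stats::rexp(k, 1 / truth$latency_jitter) else 0)
    amp <- sim_amplitudes(k, truth)
    multi <- stats::runif(k) < truth$frac_multiphasic
    n_sub <- ifelse(multi, sample(2:4, k, replace = TRUE), 1L)
    keep <- t_on < n * dt
    for (i in which(keep)) {
      if (n_sub[i] == 1L) {
        offs <- 0
        w <- amp[i]
      } else {
        gmax <- min(0.75, 1.5 / (n_sub[i] - 1))
        gaps <- stats::runif(n_sub[i] - 1, 0.4, max(gmax, 0.45))
        offs <- c(0, cumsum(gaps))
        w <- stats::runif(n_sub[i], 0.5, 1.5)
        w <- amp[i] * w / sum(w)
      }
      idx <- floor((t_on[i] + offs) / dt) + 1L
      ok <- idx >= 1 & idx <= n
      for (j in which(ok)) imp[idx[j]] <- imp[idx[j]] + w[j]
    }
    events <- data.frame(t_ms = t_on, amp = amp, n_sub = n_sub,
                         evoked = events$evoked)[keep, , drop = FALSE]
  } else {
    events <- data.frame(t_ms = numeric(0), amp = numeric(0),
                         n_sub = integer(0), evoked = logical(0))
  }
  trace <- if (any(imp != 0)) sim_conv(imp, kern)[seq_len(n)] else numeric(n)
  list(trace = trace, events = events)
}

# FFT convolution of an impulse train with a unit kernel, zero-padded to a
# 2-3-5-smooth length so the FFT stays O(n log n) for any trace length
sim_conv <- function(imp, kern) {
  n <- length(imp)
  m <- length(kern)
  nf <- stats::nextn(n + m - 1, c(2, 3, 5))
  x <- c(imp, numeric(nf - n))
  y <- c(kern, numeric(nf - m))
  out <- Re(stats::fft(stats::fft(x) * stats::fft(y), inverse = TRUE)) / nf
  out[seq_len(n)]
}

# Boltzmann fractional activation
boltz_frac <- function(v, v_half, slope) 1 / (1 + exp((v_half - v) / slope))

# presynaptic whole-cell current for one command waveform (pA)
sim_ica_trace <- function(v, truth, dt, v_hold, noise = TRUE) {
  gf_inf <- boltz_frac(v, truth$v_half, truth$slope)
  a <- exp(-dt / truth$tau_act)
  gf <- stats::filter(gf_inf * (1 - a), a, method = "recursive",
                      init = gf_inf[1])
  gf <- as.numeric(gf)
  i <- truth$g_max * gf * (v - truth$v_rev) + truth$leak_g * (v - v_hold)
  if (noise && truth$noise_sd_pre > 0)
    i <- i + stats::rnorm(length(i), 0, truth$noise_sd_pre)
  i
}

#' Simulate presynaptic Ca2+ currents for a protocol
#'
#' The whole-cell current is modelled as a Boltzmann-gated conductance with
#' first-order activation kinetics (`tau_act`) plus a linear leak:
#' \eqn{I(t) = g_{max} \, g_f(t) \, (V - V_{rev}) + g_{leak}(V - V_{hold})}
#' with \eqn{g_f} relaxing toward \eqn{1/(1+e^{(V_{half}-V)/S})}.
#'
#' @inheritParams simulate_spontaneous
#' @param protocol a [protocol_iv()]-style protocol.
#' @return list of [sweep_record()] objects with `i_pre` filled (and pure
#'   noise in `i_post`).
#' @export
simulate_ca_current <- function(protocol, truth) {
  stopifnot(inherits(protocol, "protocol"), inherits(truth, "ground_truth"))
  if (!is.null(truth$seed)) set.seed(truth$seed)
  lapply(protocol$sweeps, function(sw) {
    v <- protocol_vcmd(sw, protocol$v_hold, protocol$dt)
    n <- length(v)
    i_pre <- sim_ica_trace(v, truth, protocol$dt, protocol$v_hold)
    i_post <- stats::rnorm(n, 0, truth$noise_sd_post)
    sweep_record(v, i_pre, i_post, dt = protocol$dt, protocol_tag = sw$tag,
                 epoch_table = sw$epochs)
  })
}

#' Simulate P/n leak-calibration sweeps
#'
#' For every sweep of `protocol`, generates `reps` sweeps whose command is
#' the main command scaled by `1/n`, delivered from a hyperpolarized leak
#' holding potential (`leak_hold`, default -98 mV) and inverted (a -P/n
#' protocol). At those potentials Ca2+ channels neither gate open nor carry
#' a standing window current, so the calibration samples the linear leak
#' alone, which is standard practice. [leak_subtract()] detects the scale
#' factor (including its sign) from the stored commands.
#'
#' @inheritParams simulate_ca_current
#' @param n scale divisor (default 4).
#' @param reps sweeps per main sweep.
#' @param invert use hyperpolarizing replicas (default `TRUE`).
#' @param leak_hold holding potential of the calibration sweeps (mV).
#' @return list (one element per protocol sweep) of lists of sweeps, tag
#'   `"PN"`.
#' @export
simulate_pn <- function(protocol, truth, n = 4, reps = 4, invert = TRUE,
                        leak_hold = -98) {
  stopifnot(inherits(protocol, "protocol"))
  sgn <- if (invert) -1 else 1
  lapply(protocol$sweeps, function(sw) {
    v_main <- protocol_vcmd(sw, protocol$v_hold, protocol$dt)
    v <- leak_hold + sgn * (v_main - protocol$v_hold) / n
    ep <- sw$epochs
    if (!is.null(ep))
      ep$level <- leak_hold + sgn * (ep$level - protocol$v_hold) / n
    lapply(seq_len(reps), function(r) {
      i_pre <- sim_ica_trace(v, truth, protocol$dt, protocol$v_hold)
      sweep_record(v, i_pre, stats::rnorm(length(v), 0, truth$noise_sd_post),
                   dt = protocol$dt, protocol_tag = "PN", epoch_table = ep)
    })
  })
}

# release drive: Boltzmann Ca2+ influx magnitude, 0 below reversal crossing
release_drive <- function(v, truth) {
  boltz_frac(v, truth$v_half, truth$slope) * pmax(truth$v_rev - v, 0)
}

# Release-site recruitment fraction F(V): the increment of the Ca2+ drive
# over its standing value at holding (the quantity the IV analysis actually
# measures), normalized to the saturation reference and raised to the
# apparent cooperativity m, capped at 1 (all sites recruited).
release_F <- function(v, truth, v_hold) {
  dref <- release_drive(truth$v_ref_release, truth) -
    release_drive(v_hold, truth)
  dv <- pmax(release_drive(v, truth) - release_drive(v_hold, truth), 0)
  pmin(1, (dv / dref)^truth$coupling_m)
}

# Simulate release events for one sweep descriptor with the
# partial-depletion occupancy model: a depolarization to V recruits the
# fraction F(V) of release sites; the recruited, occupied part of the pool
# releases with hazard 1/tau_depletion and the pool refills with
# tau_recovery:
#   d occ/dt = -max(occ - (1 - F), 0)/tau_dep + (1 - occ)/tau_rec
# Release rate (events/ms):
#   r(t) = n_rrp * max(occ - (1 - F), 0)/tau_dep   (RRP transient)
#        + F * sustained_rate/1000                 (resupply-fed, non-depleting)
#        + occ * sr_true/1000                      (spontaneous)
# so the expected charge of a step scales with F(V) (and hence with
# (delta Q_Ca)^m before saturation), while the release kinetics keep the
# tau_depletion time constant. Returns event onsets (before latency) and
# the pool occupancy at sweep end.
sim_release_events <- function(sw, truth, dt, v_hold, occ0 = 1) {
  # piecewise-constant segments
  bounds <- c(0, sw$dur)
  if (!is.null(sw$epochs))
    bounds <- sort(unique(c(bounds, sw$epochs$start, sw$epochs$end)))
  seg_lvl <- vapply(seq_len(length(bounds) - 1), function(j) {
    mid <- (bounds[j] + bounds[j + 1]) / 2
    lv <- v_hold
    if (!is.null(sw$epochs)) {
      hit <- which(sw$epochs$start <= mid & sw$epochs$end > mid)
      if (length(hit)) lv <- sw$epochs$level[hit[1]]
    }
    lv
  }, numeric(1))
  tau_d <- truth$tau_depletion
  tau_r <- truth$tau_recovery
  n_rrp <- truth$n_rrp
  sus_ms <- truth$sustained_rate / 1000
  sr_ms <- truth$sr_true / 1000
  occ <- occ0
  t_all <- numeric(0)
  ev_all <- logical(0)
  emit <- function(lam, t1) {
    cnt <- stats::rpois(length(lam), lam)
    hit <- which(cnt > 0)
    if (length(hit)) {
      reps <- rep(hit, cnt[hit])
      t_all <<- c(t_all, t1 + (reps - 1) * dt + stats::runif(length(reps)) * dt)
    }
    length(if (length(hit)) reps else integer(0))
  }
  for (j in seq_along(seg_lvl)) {
    FF <- release_F(seg_lvl[j], truth, v_hold)
    t1 <- bounds[j]; t2 <- bounds[j + 1]
    m <- round((t2 - t1) / dt)
    if (m <= 0) next
    floor_occ <- 1 - FF
    if (occ < floor_occ - 1e-12) {
      # sub-threshold occupancy: pure recovery until occ reaches 1 - F
      t_star <- tau_r * log((1 - occ) / max(FF, 1e-12))
      m1 <- min(m, ceiling(t_star / dt))
      ts <- (seq_len(m1) - 0.5) * dt
      occ_t <- 1 - (1 - occ) * exp(-ts / tau_r)
      k <- emit((FF * sus_ms + occ_t * sr_ms) * dt, t1)
      ev_all <- c(ev_all, rep(FF > 0, k))
      occ <- 1 - (1 - occ) * exp(-(m1 * dt) / tau_r)
      t1 <- t1 + m1 * dt
      m <- m - m1
      if (m <= 0) next
    }
    a <- if (FF > 0) 1 / tau_d + 1 / tau_r else 1 / tau_r      # 1/ms
    occ_ss <- if (FF > 0) (floor_occ / tau_d + 1 / tau_r) / a else 1
    ts <- (seq_len(m) - 0.5) * dt                              # bin centers
    occ_t <- occ_ss + (occ - occ_ss) * exp(-a * ts)
    rate <- n_rrp * pmax(occ_t - floor_occ, 0) / tau_d * (FF > 0) +
      FF * sus_ms + occ_t * sr_ms                              # events/ms
    k <- emit(rate * dt, t1)
    ev_all <- c(ev_all, rep(FF > 0, k))
    occ <- occ_ss + (occ - occ_ss) * exp(-a * (t2 - t1))
  }
  o <- order(t_all)
  list(events = data.frame(t_ms = t_all[o], evoked = ev_all[o]), occ_end = occ)
}

#' Simulate evoked release for a protocol
#'
#' Release is drawn from a depleting, replenishing vesicle pool with
#' voltage-dependent release-site recruitment: a depolarization to V
#' recruits the fraction \eqn{F(V) = \min(1, (\Delta drive(V)/\Delta
#' drive(V_{ref}))^m)} of the release sites, where \eqn{\Delta drive} is
#' the increment of the Boltzmann Ca2+ influx over its standing value at
#' holding and \eqn{m} the apparent Ca2+ cooperativity. The recruited,
#' occupied part of the pool releases with hazard \eqn{1/\tau_{dep}} and
#' the pool refills with \eqn{\tau_{rec}}:
#' \eqn{d\,occ/dt = -\max(occ-(1-F),0)/\tau_{dep} + (1-occ)/\tau_{rec}},
#' so the expected charge of a 10 ms step scales with \eqn{(\Delta
#' Q_{Ca})^m} below saturation while the release kinetics keep the
#' \eqn{\tau_{dep}} time constant. Events (RRP transient, a non-depleting
#' sustained component `F * sustained_rate`, and occupancy-scaled
#' spontaneous release) are drawn as an inhomogeneous Poisson process,
#' shifted by the synaptic latency (`latency0` plus exponential jitter) and
#' convolved with the quantal EPSC kernel. Presynaptic Ca2+ currents are
#' generated with the same Boltzmann model as [simulate_ca_current()].
#'
#' @inheritParams simulate_ca_current
#' @return list with `sweeps` (length `length(protocol$sweeps) *
#'   protocol$reps`; repetitions of the same condition are consecutive) and
#'   `truth` with `event_times` (data frame with `sweep`, `t_ms`, `amp`,
#'   `n_sub`, `evoked`).
#' @export
simulate_evoked <- function(protocol, truth) {
  stopifnot(inherits(protocol, "protocol"), inherits(truth, "ground_truth"))
  if (!is.null(truth$seed)) set.seed(truth$seed)
  dt <- protocol$dt
  sweeps <- list()
  evs <- list()
  si <- 0L
  for (sw in protocol$sweeps) {
    for (r in seq_len(protocol$reps)) {
      si <- si + 1L
      v <- protocol_vcmd(sw, protocol$v_hold, dt)
      n <- length(v)
      rel <- sim_release_events(sw, truth, dt, protocol$v_hold, occ0 = 1)
      res <- sim_events_to_trace(rel$events, n, dt, truth, latency = TRUE)
      i_post <- res$trace + stats::rnorm(n, 0, truth$noise_sd_post)
      i_pre <- sim_ica_trace(v, truth, dt, protocol$v_hold)
      sweeps[[si]] <- sweep_record(v, i_pre, i_post, dt = dt,
                                   protocol_tag = sw$tag,
                                   epoch_table = sw$epochs)
      if (nrow(res$events))
        evs[[si]] <- cbind(sweep = si, res$events)
    }
  }
  truth$event_times <- if (length(evs)) do.call(rbind, evs) else
    data.frame(sweep = integer(0), t_ms = numeric(0), amp = numeric(0),
               n_sub = integer(0), evoked = logical(0))
  list(sweeps = sweeps, truth = truth)
}

#' Simulate a complete paired recording
#'
#' Assembles a [pair_record()] with a spontaneous stretch, an IV protocol
#' (Ca2+ currents, evoked EPSCs and -P/n leak-calibration sweeps) and a
#' forward-masking protocol, all generated from one [ground_truth()] under a
#' single seed.
#'
#' @param truth a [ground_truth()]; its `seed` governs all randomness.
#' @param pair_id identifier for the pair.
#' @param position synapse position label.
#' @param spont_ms duration of the spontaneous stretch (ms); 0 skips it.
#' @param iv an IV [protocol_iv()] or `NULL` to skip.
#' @param fm an FM [protocol_fm()] or `NULL` to skip.
#' @param pn_n P/n divisor for leak-calibration sweeps (NULL skips).
#' @return a [pair_record()] with `truth` attached (including all event
#'   times, tagged by protocol).
#' @export
simulate_pair <- function(truth, pair_id = "sim", position = "unknown",
                          spont_ms = 10000, iv = protocol_iv(),
                          fm = protocol_fm(), pn_n = 4) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.null(truth$seed)) set.seed(truth$seed)
  core <- truth
  core$seed <- NULL      # seed applied once; components advance the stream
  sweeps <- list()
  events <- list()
  if (spont_ms > 0) {
    sp <- simulate_spontaneous(core, duration_ms = spont_ms)
    sweeps <- c(sweeps, list(sp$sweep))
    if (nrow(sp$truth$event_times))
      events$spont <- cbind(protocol = "spont", sweep = 1L,
                            sp$truth$event_times)
  }
  if (!is.null(iv)) {
    ev <- simulate_evoked(iv, core)
    sweeps <- c(sweeps, ev$sweeps)
    if (nrow(ev$truth$event_times))
      events$iv <- cbind(protocol = "IV", ev$truth$event_times)
    if (!is.null(pn_n)) {
      pn <- simulate_pn(iv, core, n = pn_n)
      sweeps <- c(sweeps, unlist(pn, recursive = FALSE))
    }
  }
  if (!is.null(fm)) {
    ev <- simulate_evoked(fm, core)
    sweeps <- c(sweeps, ev$sweeps)
    if (nrow(ev$truth$event_times))
      events$fm <- cbind(protocol = "FM", ev$truth$event_times)
  }
  truth$event_times <- if (length(events)) {
    events <- lapply(events, function(e) {
      if (!"sweep" %in% names(e)) e$sweep <- NA_integer_
      e[, c("protocol", "sweep", "t_ms", "amp", "n_sub", "evoked")]
    })
    do.call(rbind, c(events, make.row.names = FALSE))
  } else NULL
  qc <- qc_result(leak_pre = 0, leak_post = 0, rs_pre = 15, rs_post = 60,
                  cm_post = 1.7, rm_post = 1500)
  pair_record(pair_id, sweeps, position = position, qc = qc, truth = truth)
}

#' Simulate a capacitive test-pulse response of a single-RC cell
#'
#' Analytic response of the series-resistance / membrane circuit to a
#' voltage step: \eqn{I(t) = (\Delta V/R_s) e^{-t/\tau} + \Delta V/(R_s+R_m)}
#' with \eqn{\tau = C_m R_s R_m/(R_s+R_m)}. Used as the independent oracle
#' for [estimate_access()].
#'
#' @param rs series resistance (MOhm).
#' @param cm membrane capacitance (pF).
#' @param rm membrane resistance (MOhm).
#' @param step_mv voltage step (mV).
#' @param pre_ms,dur_ms time before the step and step duration (ms).
#' @param dt sampling interval (ms).
#' @param noise_sd Gaussian current noise SD (pA).
#' @return a [sweep_record()] (tag `"testpulse"`) whose `i_post` holds the
#'   transient; `v_cmd` steps from 0 to `step_mv`.
#' @export
simulate_testpulse <- function(rs, cm, rm, step_mv = 10, pre_ms = 2,
                               dur_ms = 10, dt = 0.02, noise_sd = 0) {
  tau <- cm * (rs * rm / (rs + rm)) / 1000        # pF*MOhm -> us -> ms
  n_pre <- round(pre_ms / dt); n_step <- round(dur_ms / dt)
  t <- (seq_len(n_step) - 1) * dt
  i_step <- 1000 * step_mv * rm / (rs * (rs + rm)) * exp(-t / tau) +
    1000 * step_mv / (rs + rm)                    # mV/MOhm = nA -> pA; I(0+) = dV/Rs
  i <- c(rep(0, n_pre), i_step)
  if (noise_sd > 0) i <- i + stats::rnorm(length(i), 0, noise_sd)
  v <- c(rep(0, n_pre), rep(step_mv, n_step))
  # fast transients (small cells behind low Rs) may need dt below the
  # 20-50 kHz acquisition band, so the rate check is waived here
  sweep_record(v, rep(0, length(v)), i, dt = dt, protocol_tag = "testpulse",
               epoch_table = data.frame(start = pre_ms,
                                        end = pre_ms + dur_ms,
                                        level = step_mv),
               check_rate = FALSE)
}
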