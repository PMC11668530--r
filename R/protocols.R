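#' Stimulation protocols
#'
#' Builders for the three command-voltage protocols used throughout:
#'
#' * `protocol_iv()`: 10 ms steps from -70 (or -60) to +70 mV in 5 mV
#'   increments, nominally separated by 1.5 s. Only a window around each step
#'   is simulated/stored per sweep (`pre_ms` baseline + step + `post_ms`);
#'   the long inter-sweep interval is metadata (`inter_sweep_ms`).
#' * `protocol_fm()`: forward masking - a 100 ms masker and a 15 ms probe,
#'   both to -19 mV from the -58 mV holding potential, separated by
#'   interstimulus intervals of 4, 16, 64 and 256 ms; 400 ms of unstimulated
#'   recording precede the masker and follow the probe, and maskers are 20 s
#'   apart.
#' * `protocol_spont()`: continuous unstimulated recording at holding.
#'
#' @param v_from,v_to,dv IV step range and increment (mV).
#' @param step_ms step duration (ms).
#' @param pre_ms,post_ms unstimulated time before/after the stimulation in
#'   each stored sweep (ms).
#' @param level masker/probe level (mV).
#' @param masker_ms,probe_ms masker and probe durations (ms).
#' @param isis interstimulus intervals (ms).
#' @param reps number of repetitions per condition.
#' @param duration_ms duration of the spontaneous recording (ms).
#' @param v_hold holding potential (mV).
#' @param dt sampling interval (ms).
#' @param inter_sweep_ms nominal interval between sweep starts (ms).
#' @return object of class `"protocol"`: a list with `kind`, `dt`, `v_hold`,
#'   `reps`, `inter_sweep_ms` and `sweeps`, the latter a list of per-sweep
#'   descriptors (`dur`, `epochs` data frame with start/end/level, `tag`,
#'   and for FM sweeps the `isi`).
#' @export
protocol_iv <- function(v_from = -70, v_to = 70, dv = 5, step_ms = 10,
                        pre_ms = 100, post_ms = 40, v_hold = -58,
                        dt = 0.02, inter_sweep_ms = 1500) {
  levels <- seq(v_from, v_to, by = dv)
  sweeps <- lapply(levels, function(v) {
    list(dur = pre_ms + step_ms + post_ms,
         epochs = data.frame(start = pre_ms, end = pre_ms + step_ms, level = v),
         tag = "IV")
  })
  structure(list(kind = "IV", dt = dt, v_hold = v_hold, reps = 1,
                 inter_sweep_ms = inter_sweep_ms, sweeps = sweeps),
            class = "protocol")
}

#' @rdname protocol_iv
#' @export
protocol_fm <- function(isis = c(4, 16, 64, 256), masker_ms = 100,
                        probe_ms = 15, level = -19, pre_ms = 400,
                        post_ms = 400, v_hold = -58, dt = 0.02, reps = 10,
                        inter_sweep_ms = 20000) {
  sweeps <- lapply(isis, function(isi) {
    m0 <- pre_ms
    p0 <- pre_ms + masker_ms + isi
    list(dur = p0 + probe_ms + post_ms,
         epochs = data.frame(start = c(m0, p0),
                             end = c(m0 + masker_ms, p0 + probe_ms),
                             level = c(level, level)),
         tag = "FM", isi = isi)
  })
  structure(list(kind = "FM", dt = dt, v_hold = v_hold, reps = reps,
                 inter_sweep_ms = inter_sweep_ms, sweeps = sweeps),
            class = "protocol")
}

#' @rdname protocol_iv
#' @export
protocol_spont <- function(duration_ms = 10000, v_hold = -58, dt = 0.02) {
  structure(list(kind = "spont", dt = dt, v_hold = v_hold, reps = 1,
                 inter_sweep_ms = 0,
                 sweeps = list(list(dur = duration_ms,
                                    epochs = NULL, tag = "spont"))),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol '%s'> %d sweep(s) x %d rep(s), dt = %g ms, holding %g mV\n",
              x$kind, length(x$sweeps), x$reps, x$dt, x$v_hold))
  invisible(x)
}

# per-sample command waveform of one sweep descriptor
protocol_vcmd <- function(sw, v_hold, dt) {
  n <- round(sw$dur / dt)
  v <- rep(v_hold, n)
  if (!is.null(sw$epochs)) {
    for (j in seq_len(nrow(sw$epochs))) {
      i1 <- floor(sw$epochs$start[j] / dt) + 1
      i2 <- min(n, ceiling(sw$epochs$end[j] / dt))
      v[i1:i2] <- sw$epochs$level[j]
    }
  }
  v
}
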