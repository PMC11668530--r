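#' Construct a recording sweep
#'
#' A sweep is one synchronized triple of command potential, presynaptic (IHC)
#' current and postsynaptic (bouton) current, sampled at a common interval.
#' Units are fixed package-wide: mV, pA, ms (so charge integrals come out in
#' pA*ms = fC).
#'
#' @param v_cmd command potential samples (mV).
#' @param i_pre presynaptic current samples (pA); inward current is negative.
#' @param i_post postsynaptic current samples (pA); EPSCs are negative.
#' @param dt sampling interval (ms). The default 0.02 ms corresponds to
#'   50 kHz acquisition; rates between 20 and 50 kHz (dt 0.02--0.05 ms) are
#'   accepted without comment, others require `check_rate = FALSE`.
#' @param t0 time of the first sample (ms).
#' @param protocol_tag free-form protocol label, e.g. `"IV"`, `"FM"`,
#'   `"spont"`, `"testpulse"`, `"PN"`.
#' @param epoch_table optional data frame with columns `start`, `end`
#'   (ms, on the sweep time axis) and `level` (mV) describing the command
#'   waveform steps. When given, the levels must reproduce `v_cmd` at the
#'   epoch midpoints.
#' @param check_rate if `TRUE` (default), reject sampling intervals outside
#'   the 20--50 kHz acquisition range.
#' @return an object of class `"sweep"`.
#' @examples
#' sw <- sweep_record(v_cmd = rep(-58, 100), i_pre = rnorm(100),
#'                    i_post = rnorm(100), dt = 0.02)
#' sw
#' @export
sweep_record <- function(v_cmd, i_pre, i_post, dt = 0.02, t0 = 0,
                         protocol_tag = "spont", epoch_table = NULL,
                         check_rate = TRUE) {
  n <- length(v_cmd)
  if (n < 2L || length(i_pre) != n || length(i_post) != n)
    stop("v_cmd, i_pre and i_post must have equal length >= 2")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive sampling interval (ms)")
  if (check_rate && (dt < 1 / 50 - 1e-12 || dt > 1 / 20 + 1e-12))
    stop("dt = ", dt, " ms is outside the 20-50 kHz acquisition range; ",
         "pass check_rate = FALSE to override")
  sw <- structure(list(
    t0 = t0, dt = dt,
    v_cmd = as.numeric(v_cmd),
    i_pre = as.numeric(i_pre),
    i_post = as.numeric(i_post),
    protocol_tag = as.character(protocol_tag)[1],
    epoch_table = epoch_table
  ), class = "sweep")
  if (!is.null(epoch_table)) {
    et <- as.data.frame(epoch_table)
    if (!all(c("start", "end", "level") %in% names(et)))
      stop("epoch_table needs columns start, end, level")
    sw$epoch_table <- et[, c("start", "end", "level")]
    mid <- (et$start + et$end) / 2
    idx <- pmin(pmax(round((mid - t0) / dt) + 1, 1L), n)
    dev <- abs(sw$v_cmd[idx] - et$level)
    if (any(dev > 1e-9))
      stop("epoch levels do not reproduce v_cmd at epoch midpoints (max dev ",
           format(max(dev)), " mV)")
  }
  sw
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep '%s'> %d samples, dt = %g ms (%.3g s), t0 = %g ms\n",
              x$protocol_tag, length(x$v_cmd), x$dt,
              length(x$v_cmd) * x$dt / 1000, x$t0))
  if (!is.null(x$epoch_table))
    cat(sprintf("  %d command epochs, levels %s mV\n", nrow(x$epoch_table),
                paste(unique(round(x$epoch_table$level, 1)), collapse = ", ")))
  invisible(x)
}

#' Time axis of a sweep
#' @param sweep a [sweep_record()] object.
#' @return numeric vector of sample times (ms).
#' @export
sweep_time <- function(sweep) {
  sweep$t0 + (seq_along(sweep$v_cmd) - 1) * sweep$dt
}

# Epochs whose level departs from the holding potential (stimulation epochs).
stim_epochs <- function(sweep, v_hold = NULL, tol = 0.5) {
  et <- sweep$epoch_table
  if (is.null(et) || nrow(et) == 0) return(et)
  if (is.null(v_hold)) {
    # holding = most common command level
    tab <- table(round(sweep$v_cmd, 6))
    v_hold <- as.numeric(names(tab)[which.max(tab)])
  }
  et[abs(et$level - v_hold) > tol, , drop = FALSE]
}

#' Construct a paired-recording record
#'
#' Bundles all sweeps and metadata of one paired IHC / SGN-bouton recording.
#' Reported potentials are assumed to be liquid-junction-potential corrected
#' already; the correction constants are stored for provenance and never
#' re-applied by the package.
#'
#' @param pair_id identifier string.
#' @param sweeps list of [sweep_record()] objects.
#' @param position synapse position on the IHC: `"pillar"`, `"modiolar"` or
#'   `"unknown"`.
#' @param holding_v_pre,holding_v_post holding potentials (mV); defaults
#'   -58 (IHC) and -94 (bouton).
#' @param ljp_pre,ljp_post liquid junction potentials already subtracted
#'   (mV); defaults 19 and 4.
#' @param qc optional [qc_result()].
#' @param truth optional ground-truth object attached by the simulator.
#' @return an object of class `"pair_record"`. `sr_class` starts `"unset"`
#'   and is filled by the spontaneous analysis.
#' @export
pair_record <- function(pair_id, sweeps = list(), position = "unknown",
                        holding_v_pre = -58, holding_v_post = -94,
                        ljp_pre = 19, ljp_post = 4, qc = NULL, truth = NULL) {
  position <- match.arg(position, c("pillar", "modiolar", "unknown"))
  stopifnot(all(vapply(sweeps, inherits, logical(1), "sweep")))
  structure(list(
    pair_id = as.character(pair_id)[1], sweeps = sweeps, position = position,
    holding_v_pre = holding_v_pre, holding_v_post = holding_v_post,
    ljp_pre = ljp_pre, ljp_post = ljp_post,
    qc = qc, sr_class = "unset", truth = truth
  ), class = "pair_record")
}

#' @export
print.pair_record <- function(x, ...) {
  tags <- vapply(x$sweeps, `[[`, character(1), "protocol_tag")
  cat(sprintf("<pair_record '%s'> %s side, %d sweeps, SR class: %s\n",
              x$pair_id, x$position, length(x$sweeps), x$sr_class))
  if (length(tags)) print(table(tags))
  if (!is.null(x$qc))
    cat("  QC:", if (isTRUE(x$qc$pass)) "pass" else
      paste("FAIL -", paste(x$qc$reasons, collapse = "; ")), "\n")
  invisible(x)
}

#' Sweeps of a pair by protocol tag
#' @param pair a [pair_record()].
#' @param tag protocol tag to select.
#' @return list of sweeps.
#' @export
pair_sweeps <- function(pair, tag) {
  Filter(function(s) identical(s$protocol_tag, tag), pair$sweeps)
}

#' Quality-control record for a paired recording
#'
#' Recordings are excluded when leak currents at holding exceed -60 pA (IHC)
#' or -100 pA (bouton), i.e. are more negative than those limits, or when a
#' passive-membrane estimate is undefined.
#'
#' @param leak_pre,leak_post leak currents at holding (pA).
#' @param rs_pre,rs_post series resistances (MOhm).
#' @param cm_post bouton capacitance (pF).
#' @param rm_post bouton membrane resistance (MOhm).
#' @return object of class `"qc_result"` with logical `pass` and character
#'   `reasons`.
#' @export
qc_result <- function(leak_pre = NA_real_, leak_post = NA_real_,
                      rs_pre = NA_real_, rs_post = NA_real_,
                      cm_post = NA_real_, rm_post = NA_real_) {
  reasons <- character(0)
  if (!is.finite(leak_pre) || leak_pre < -60)
    reasons <- c(reasons, sprintf("IHC leak %.1f pA exceeds -60 pA limit", leak_pre))
  if (!is.finite(leak_post) || leak_post < -100)
    reasons <- c(reasons, sprintf("bouton leak %.1f pA exceeds -100 pA limit", leak_post))
  ests <- c(rs_pre = rs_pre, rs_post = rs_post, cm_post = cm_post, rm_post = rm_post)
  bad <- names(ests)[!is.finite(ests)]
  if (length(bad)) reasons <- c(reasons, paste("undefined estimate:", paste(bad, collapse = ", ")))
  structure(list(leak_pre = leak_pre, leak_post = leak_post,
                 rs_pre = rs_pre, rs_post = rs_post,
                 cm_post = cm_post, rm_post = rm_post,
                 pass = length(reasons) == 0L, reasons = reasons),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %s\n", if (x$pass) "pass" else "FAIL"))
  cat(sprintf("  leak pre/post: %.1f / %.1f pA; Rs pre/post: %.1f / %.1f MOhm; Cm %.2f pF; Rm %.0f MOhm\n",
              x$leak_pre, x$leak_post, x$rs_pre, x$rs_post, x$cm_post, x$rm_post))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}
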