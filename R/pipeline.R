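#' Analyze one paired recording end to end
#'
#' Runs the full per-pair analysis: sEPSC detection and spontaneous-rate
#' classification on the spontaneous stretch, leak subtraction and Ca2+
#' IV / Boltzmann activation analysis, release-intensity sigmoid and
#' Ca2+-cooperativity fits from the IV protocol, and latency / depletion /
#' recovery analysis from the forward-masking protocol. Missing protocols
#' are skipped silently; their metrics come back `NaN`.
#'
#' @param pair a [pair_record()].
#' @param threshold_mult detection threshold in baseline SDs.
#' @param sr_cutoff SR classification boundary (events/s); at or above is
#'   `"high"`.
#' @param pn_n P/n divisor assumed when leak sweeps are present.
#' @param coop_tail_frac plateau fraction for the cooperativity truncation.
#' @param min_events_quantal minimum number of spontaneous events required
#'   before the pair's mean sEPSC charge is trusted for quantal conversions
#'   (RRP size, release rates).
#' @param max_fm_spont number of forward-masking sweeps whose unstimulated
#'   stretches are additionally scanned for spontaneous events.
#' @return list of class `"pair_analysis"`: `pair_id`, `position`,
#'   `sr_class`, `metrics` (named numeric vector), plus the fitted objects
#'   (`spont`, `iv`, `boltzmann`, `sigmoid`, `cooperativity`, `depletion`,
#'   `recovery`, `latency`).
#' @export
analyze_pair <- function(pair, threshold_mult = 4, sr_cutoff = 1,
                         pn_n = 4, coop_tail_frac = 0.95,
                         min_events_quantal = 5, max_fm_spont = 8) {
  stopifnot(inherits(pair, "pair_record"))
  met <- c(sr = NaN, n_sepsc = NaN, mean_amp = NaN, mean_charge = NaN,
           cv_amp = NaN, skew_amp = NaN, frac_monophasic = NaN,
           mean_rise = NaN, mean_tau_decay = NaN, mean_fwhm = NaN,
           i_ca_peak = NaN, v_ca_peak = NaN, v_rev = NaN, v_half = NaN,
           act_slope = NaN, ca_threshold_v = NaN,
           q50 = NaN, q10 = NaN, q90 = NaN, rel_slope = NaN,
           dynamic_range = NaN, m_coop = NaN,
           latency_mean = NaN, jitter_sd = NaN,
           rrp_sv = NaN, tau_depletion = NaN, initial_rate = NaN,
           sustained_rate = NaN, depression_ratio = NaN,
           tau_recovery = NaN, time_to_first_sepsc = NaN)
  out <- list(pair_id = pair$pair_id, position = pair$position,
              sr_class = "unset")
  # --- spontaneous ---------------------------------------------------------
  # SR and quantal statistics pool the dedicated spontaneous stretch with
  # the unstimulated segments before/after the forward-masking stimuli
  sp_sweeps <- pair_sweeps(pair, "spont")
  fm_sweeps <- pair_sweeps(pair, "FM")
  ev_pool <- list()
  n_in <- 0
  t_total <- 0
  scan <- c(sp_sweeps, utils::head(fm_sweeps, max_fm_spont))
  for (sw in scan) {
    dur <- (length(sw$i_post) - 1) * sw$dt
    se <- stim_epochs(sw)
    bw_end <- if (!is.null(se) && nrow(se)) min(se$start[1], sw$t0 + 1000)
      else sw$t0 + min(1000, dur)
    if (bw_end - sw$t0 < 100) next
    ev <- tryCatch(detect_events(sw, c(sw$t0, bw_end),
                                 threshold_mult = threshold_mult),
                   error = function(e) NULL)
    if (is.null(ev)) next
    wins <- unstimulated_windows(sw)
    cnt <- spontaneous_rate(ev, wins)
    n_in <- n_in + cnt$n_events
    t_total <- t_total + cnt$analyzed_time
    keep <- !ev$evoked &
      vapply(ev$onset, function(o)
        any(vapply(wins, function(w) o >= w[1] && o < w[2], logical(1))),
        logical(1))
    if (any(keep)) ev_pool[[length(ev_pool) + 1L]] <-
      as.data.frame(ev)[keep, , drop = FALSE]
  }
  events <- if (length(ev_pool)) do.call(rbind, ev_pool) else NULL
  if (t_total > 0) {
    met["sr"] <- n_in / t_total
    out$sr_class <- if (met["sr"] >= sr_cutoff) "high" else "low"
  }
  if (!is.null(events) && nrow(events)) {
    # skewness is reported only for n >= 3; the n < 3 warning is expected
    ss <- suppressWarnings(summarize_events(events))
    met["n_sepsc"] <- ss$n_events
    met["mean_amp"] <- ss$mean_amp
    met["cv_amp"] <- ss$cv_amp
    met["skew_amp"] <- if (ss$n_events >= 3) ss$skew_amp else NaN
    met["frac_monophasic"] <- ss$frac_monophasic
    met["mean_rise"] <- ss$mean_rise
    met["mean_tau_decay"] <- ss$mean_tau_decay
    met["mean_fwhm"] <- ss$mean_fwhm
    if (ss$n_events >= min_events_quantal)
      met["mean_charge"] <- ss$mean_charge
    out$spont <- ss
  }
  # --- Ca2+ IV and release intensity --------------------------------------
  iv_sweeps <- pair_sweeps(pair, "IV")
  pn_sweeps <- pair_sweeps(pair, "PN")
  if (length(iv_sweeps) >= 5) {
    main <- if (length(pn_sweeps))
      lapply(iv_sweeps, function(sw) {
        grp <- match_pn(sw, pn_sweeps, pn_n)
        if (length(grp)) leak_subtract(sw, grp, n = pn_n) else sw
      })
    else iv_sweeps
    iv <- iv_curve(main)
    out$iv <- iv
    met["i_ca_peak"] <- min(iv$i_ca)
    met["v_ca_peak"] <- iv$v[which.min(iv$i_ca)]
    vr <- tryCatch(reversal_potential(iv), error = function(e) NaN)
    met["v_rev"] <- as.numeric(vr)
    if (is.finite(vr)) {
      bf <- fit_boltzmann(iv, vr)
      out$boltzmann <- bf
      if (bf$ok) {
        met["v_half"] <- bf$v_half
        met["act_slope"] <- bf$slope
        met["ca_threshold_v"] <- bf$threshold_v
      }
    }
    ri <- release_intensity(iv_sweeps)
    out$release <- ri
    if (!isTRUE(attr(ri, "undefined"))) {
      # release tracks Ca2+ influx, which falls again beyond its peak
      # voltage; the sigmoid describes the rising limb only
      ri_fit <- ri[ri$v <= met["v_ca_peak"], , drop = FALSE]
      sf <- fit_release_sigmoid(ri_fit)
      out$sigmoid <- sf
      if (sf$fit_ok) {
        met["q50"] <- sf$q50; met["q10"] <- sf$q10; met["q90"] <- sf$q90
        met["rel_slope"] <- sf$slope
        met["dynamic_range"] <- sf$dynamic_range
      }
      # cooperativity relates the change of release to the change of Ca2+
      # influx, so it uses baseline-subtracted charges on the rising limb
      iv_d <- iv_curve(main, baseline_ms = 2)
      sel <- iv_d$v <= met["v_ca_peak"] & abs(iv_d$q_ca) > 0
      riv <- ri[match(iv_d$v[sel], ri$v), ]
      cp <- tryCatch(
        fit_cooperativity(abs(iv_d$q_ca[sel]), riv$q_epsc,
                          plateau_frac = coop_tail_frac),
        error = function(e) NULL)
      if (!is.null(cp) && cp$fit_ok) {
        out$cooperativity <- cp
        met["m_coop"] <- cp$m
      }
    }
  }
  # --- forward masking -----------------------------------------------------
  if (length(fm_sweeps) >= 3) {
    lat <- latency_stats(fm_sweeps, threshold_mult = threshold_mult)
    out$latency <- lat
    met["latency_mean"] <- lat$latency_mean
    met["jitter_sd"] <- lat$jitter_sd
    qtr <- average_masker_response(fm_sweeps)
    out$q_trace <- qtr
    if (is.finite(met["mean_charge"]) && met["mean_charge"] > 0) {
      dep <- fit_depletion(qtr, met["mean_charge"])
      out$depletion <- dep
      if (dep$fit_ok) {
        met["rrp_sv"] <- dep$rrp_sv
        met["tau_depletion"] <- dep$tau
        met["initial_rate"] <- dep$initial_rate
        met["sustained_rate"] <- dep$sustained_rate
        met["depression_ratio"] <- dep$depression_ratio
      }
    }
    rc <- tryCatch(recovery_curve(fm_sweeps), error = function(e) NULL)
    if (!is.null(rc)) {
      out$recovery <- rc
      met["time_to_first_sepsc"] <- attr(rc, "time_to_first_sepsc")
      rf <- fit_recovery(rc)
      out$recovery_fit <- rf
      if (rf$fit_ok) met["tau_recovery"] <- rf$tau_recovery
    }
  }
  out$metrics <- met
  class(out) <- "pair_analysis"
  out
}

# match P/n calibration sweeps to a main IV sweep by scaled step level
match_pn <- function(main, pn_sweeps, n) {
  se <- stim_epochs(main)
  if (is.null(se) || nrow(se) == 0) return(list())
  v_hold <- main$v_cmd[1]
  e_main <- se$level[1] - v_hold
  Filter(function(p) {
    pe <- p$epoch_table
    if (is.null(pe) || nrow(pe) == 0) return(FALSE)
    e_p <- pe$level[1] - p$v_cmd[1]
    abs(abs(e_p) - abs(e_main) / n) < 1e-6 + 0.01 * abs(e_main) / n
  }, pn_sweeps)
}

#' @export
print.pair_analysis <- function(x, ...) {
  cat(sprintf("<pair_analysis '%s'> %s side, SR class %s\n", x$pair_id,
              x$position, x$sr_class))
  m <- x$metrics[is.finite(x$metrics)]
  for (nm in names(m)) cat(sprintf("  %-20s %.4g\n", nm, m[[nm]]))
  invisible(x)
}

#' Run the cohort pipeline
#'
#' Orchestrates the per-pair analysis over a cohort and produces the report
#' bundle: a cohort CSV (one row per pair, all metrics), per-pair JSON
#' files, group comparisons of every metric between high- and low-SR
#' synapses (gated t / Mann-Whitney rule, see [compare_groups()]), and a
#' run log recording seeds and configured thresholds. Per-pair failures are
#' logged and skipped; they never abort the cohort.
#'
#' @param config a list, or path to a YAML/JSON file, with entries:
#'   \describe{
#'   \item{pairs}{character vector of container directories
#'     ([load_pair()]), and/or}
#'   \item{simulate}{list with `n_high`, `n_low`, `seed`, and optional
#'     `spont_ms`, `fm_reps`, `iv` (logical), `fm` (logical) to generate a
#'     synthetic cohort from the high/low presets,}
#'   \item{out_dir}{output directory (default `tempdir()`),}
#'   \item{threshold_mult, sr_cutoff}{analysis options.}
#'   }
#' @return list of class `"pipeline_report"` with `cohort` (data frame),
#'   `comparisons` (list of [compare_groups()] results), `failures`,
#'   `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% tempdir()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$threshold_mult %||% 4
  sr_cut <- config$sr_cutoff %||% 1
  log_lines <- c(sprintf("pairsynapse %s run %s",
                         as.character(utils::packageVersion("pairsynapse")),
                         format(Sys.time())),
                 sprintf("R %s.%s", R.version$major, R.version$minor),
                 sprintf("threshold_mult = %g, sr_cutoff = %g", thr, sr_cut))
  pairs <- list()
  for (p in config$pairs %||% character(0)) {
    pairs[[length(pairs) + 1L]] <- tryCatch(load_pair(p), error = function(e) {
      log_lines <<- c(log_lines, sprintf("FAILED to load %s: %s", p,
                                         conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    seed <- sim$seed %||% 1
    log_lines <- c(log_lines, sprintf("simulated cohort seed = %d", seed))
    spont_ms <- sim$spont_ms %||% 10000
    iv <- if (isFALSE(sim$iv)) NULL else
      protocol_iv(v_from = -70, v_to = 10)
    mk <- function(cls, k, idx) {
      tr <- ground_truth_preset(cls, seed = seed + idx)
      fm <- if (isFALSE(sim$fm)) NULL else
        protocol_fm(reps = sim$fm_reps %||% 5)
      simulate_pair(tr, pair_id = sprintf("sim_%s_%02d", cls, k),
                    position = if (cls == "high") "pillar" else "modiolar",
                    spont_ms = spont_ms, iv = iv, fm = fm)
    }
    idx <- 0L
    for (k in seq_len(sim$n_high %||% 0)) {
      idx <- idx + 1L
      pairs[[length(pairs) + 1L]] <- mk("high", k, idx)
    }
    for (k in seq_len(sim$n_low %||% 0)) {
      idx <- idx + 1L
      pairs[[length(pairs) + 1L]] <- mk("low", k, idx)
    }
  }
  pairs <- Filter(Negate(is.null), pairs)
  rows <- list(); failures <- character(0); analyses <- list()
  for (pr in pairs) {
    res <- tryCatch(
      analyze_pair(pr, threshold_mult = thr, sr_cutoff = sr_cut),
      error = function(e) {
        failures <<- c(failures, sprintf("%s: %s", pr$pair_id,
                                         conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    analyses[[res$pair_id]] <- res
    rows[[length(rows) + 1L]] <-
      data.frame(pair_id = res$pair_id, position = res$position,
                 sr_class = res$sr_class, t(res$metrics))
    jsonlite::write_json(
      list(pair_id = res$pair_id, position = res$position,
           sr_class = res$sr_class, metrics = as.list(res$metrics)),
      file.path(out_dir, paste0(res$pair_id, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cohort <- if (length(rows)) do.call(rbind, rows) else data.frame()
  csv <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, csv, row.names = FALSE)
  comparisons <- list()
  if (nrow(cohort) > 0 && length(unique(cohort$sr_class)) == 2) {
    for (v in setdiff(names(cohort), c("pair_id", "position", "sr_class"))) {
      hi <- cohort[[v]][cohort$sr_class == "high"]
      lo <- cohort[[v]][cohort$sr_class == "low"]
      if (sum(is.finite(hi)) >= 3 && sum(is.finite(lo)) >= 3)
        comparisons[[v]] <- tryCatch(compare_groups(hi, lo, variable = v),
                                     error = function(e) NULL)
    }
    comparisons <- Filter(Negate(is.null), comparisons)
  }
  log_lines <- c(log_lines,
                 sprintf("%d pair(s) analyzed, %d failure(s)", nrow(cohort),
                         length(failures)), failures)
  if (nrow(cohort) == 0) {
    warning("empty cohort: report contains no pairs")
    log_lines <- c(log_lines, "WARNING: empty cohort")
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  structure(list(cohort = cohort, comparisons = comparisons,
                 analyses = analyses, failures = failures,
                 files = list(cohort_csv = csv,
                              log = file.path(out_dir, "run.log"),
                              out_dir = out_dir)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d pair(s), %d comparison(s), %d failure(s)\n",
              nrow(x$cohort), length(x$comparisons), length(x$failures)))
  if (nrow(x$cohort))
    print(table(x$cohort$sr_class))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
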