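# shared helpers for the pairsynapse test suite

# a quiet, fast ground truth for detector-oriented tests: near-constant
# quantal amplitude so SNR = amp_mean / noise_sd_post is well defined
snr_truth <- function(snr, noise = 6, rate = 10, seed = 1, ...) {
  ground_truth(sr_true = rate, amp_mean = snr * noise, amp_cv = 0.05,
               frac_multiphasic = 0, noise_sd_post = noise, seed = seed, ...)
}

# recall/precision of detected onsets against true onsets (ms)
match_events <- function(detected, truth_t, tol = 0.5) {
  if (!length(truth_t))
    return(c(recall = NA_real_, precision = NA_real_))
  hit_det <- vapply(detected, function(o) any(abs(truth_t - o) <= tol),
                    logical(1))
  hit_tru <- vapply(truth_t, function(t) any(abs(detected - t) <= tol),
                    logical(1))
  c(recall = mean(hit_tru),
    precision = if (length(detected)) mean(hit_det) else NaN)
}

# build a sweep holding a given postsynaptic trace at -58 mV holding
post_sweep <- function(i_post, dt = 0.02, epoch_table = NULL, t0 = 0) {
  n <- length(i_post)
  sweep_record(rep(-58, n), rep(0, n), i_post, dt = dt, t0 = t0,
               protocol_tag = if (is.null(epoch_table)) "spont" else "IV",
               epoch_table = epoch_table, check_rate = FALSE)
}

# brute-force, loop-based re-count of qualifying detections on a processed
# trace: maximal stretches below -thr/2 that contain at least min_w
# consecutive samples below -thr (independent of the detector's vectorized
# bookkeeping)
brute_count <- function(y_s, thr, min_w) {
  n_ev <- 0L
  i <- 1L
  n <- length(y_s)
  while (i <= n) {
    if (y_s[i] < -thr / 2) {
      j <- i
      best <- 0L
      run <- 0L
      while (j <= n && y_s[j] < -thr / 2) {
        if (y_s[j] < -thr) run <- run + 1L else run <- 0L
        best <- max(best, run)
        j <- j + 1L
      }
      if (best >= min_w) n_ev <- n_ev + 1L
      i <- j
    } else i <- i + 1L
  }
  n_ev
}
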