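# forward masking: averaging, latency, depletion fit, recovery

fm_epochs <- function(isi, masker = 100, probe = 15, pre = 400) {
  data.frame(start = c(pre, pre + masker + isi),
             end = c(pre + masker, pre + masker + isi + probe),
             level = c(-19, -19))
}

fm_sweep <- function(i_post, isi = 16, dt = 0.02, pre = 400) {
  n <- length(i_post)
  ep <- fm_epochs(isi, pre = pre)
  v <- rep(-58, n)
  for (j in 1:2)
    v[(round(ep$start[j] / dt) + 1):min(n, round(ep$end[j] / dt))] <- -19
  sweep_record(v, numeric(n), i_post, dt = dt, protocol_tag = "FM",
               epoch_table = ep)
}

test_that("masker averaging is linear and idempotent", {
  dt <- 0.02
  n <- round(600 / dt)
  tpl <- numeric(n)
  tpl[(round(400 / dt) + 1):round(500 / dt)] <- -40   # square masker response
  s1 <- fm_sweep(tpl)
  # identical repetitions: average equals any single trace
  q1 <- average_masker_response(list(s1, s1, s1))
  single <- suppressWarnings(average_masker_response(list(s1)))
  expect_warning(average_masker_response(list(s1, s1)), "fewer than 3")
  expect_equal(q1$q, single$q)
  # two traces with different charge: averaged cumulative charge is the mean
  s2 <- fm_sweep(2 * tpl)
  q12 <- average_masker_response(list(s1, s1, s2))
  at50 <- which.min(abs(q12$t - 50))
  q_a <- -sum(tpl[(round(400 / dt) + 1):(round(450 / dt))]) * dt
  expect_equal(q12$q[at50], q_a * 4 / 3, tolerance = 0.01 * q_a)
})

test_that("latency and jitter come from first-event onsets", {
  dt <- 0.02
  kern <- make_epsc_kernel(-150, 0.15, 0.55, dt)
  mk <- function(lat) {
    n <- round(700 / dt)
    x <- rnorm(n, 0, 2)
    i0 <- round((400 + lat) / dt)
    x[i0:(i0 + length(kern) - 1)] <- x[i0:(i0 + length(kern) - 1)] + kern
    fm_sweep(x)
  }
  set.seed(1)
  sw <- lapply(rep(1.2, 5), mk)
  ls <- latency_stats(sw)
  expect_equal(ls$latency_mean, 1.2, tolerance = 0.15)
  expect_lt(ls$jitter_sd, 0.1)
  expect_equal(ls$n_missing, 0)
  # exponential latencies: mean and SD recovered within sampling error
  set.seed(2)
  lats <- 1.0 + rexp(20, 1 / 0.4)
  ls2 <- latency_stats(lapply(lats, mk))
  expect_equal(ls2$latency_mean, 1.4, tolerance = 0.3)
  expect_equal(ls2$jitter_sd, 0.4, tolerance = 0.5 * 0.4 + 0.2)
})

test_that("high-SR presets keep shorter latencies than low-SR presets", {
  ord <- vapply(1:6, function(s) {
    lat_of <- function(cls) {
      tr <- ground_truth_preset(cls, seed = s)
      ev <- simulate_evoked(protocol_fm(reps = 5, isis = 16, pre_ms = 200,
                                        post_ms = 50), tr)
      latency_stats(ev$sweeps)$latency_mean
    }
    lat_of("high") < lat_of("low")
  }, logical(1))
  expect_gte(mean(ord), 5 / 6)
})

test_that("noiseless exponential-plus-line traces are fitted exactly", {
  t <- seq(0, 60, 0.05)
  a1 <- 980; tau <- 6.3; slope <- 30; x0 <- 1.5; y0 <- 3
  q <- y0 + a1 * (1 - exp(-pmax(t - x0, 0) / tau)) + pmax(t - x0, 0) * slope
  dep <- fit_depletion(list(t = t, q = q), mean_sepsc_charge = 70)
  expect_true(dep$fit_ok)
  expect_lt(abs(dep$a1 - a1) / a1, 1e-6)
  expect_lt(abs(dep$tau - tau) / tau, 1e-6)
  expect_lt(abs(dep$line_slope - slope) / slope, 1e-6)
  # derived quanta per the quantal identities (printed fit values give
  # RRP = 14 vesicles and tau = 6.3 ms)
  expect_equal(dep$rrp_sv, a1 / 70, tolerance = 1e-6)
  expect_equal(dep$rrp_sv, 14, tolerance = 1e-3)
  expect_equal(dep$sustained_rate, slope / 70 * 1000, tolerance = 1e-6)
  expect_equal(dep$initial_rate, (a1 / tau + slope) / 70 * 1000,
               tolerance = 1e-6)
  expect_equal(dep$depression_ratio, dep$initial_rate / dep$sustained_rate,
               tolerance = 1e-12)
})

test_that("pure-exponential depletion yields NaN depression ratio", {
  t <- seq(0, 60, 0.05)
  q <- 900 * (1 - exp(-t / 8))
  dep <- fit_depletion(list(t = t, q = q), 70)
  expect_true(dep$fit_ok)
  expect_equal(dep$sustained_rate, 0, tolerance = 1e-6)
  expect_true(is.nan(dep$depression_ratio))
  expect_error(fit_depletion(list(t = seq(0, 30, 0.1), q = seq(0, 30, 0.1)),
                             70), "50 ms")
  expect_error(fit_depletion(list(t = t, q = q), 0), "positive")
})

test_that("recovery ratios and the recovery fit behave per the model", {
  # probe identical to masker -> all ratios 1 -> degenerate recovery flagged
  dt <- 0.02
  resp <- function(scale_probe, isi) {
    n <- round((400 + 100 + isi + 15 + 450) / dt)
    x <- numeric(n)
    m0 <- round(400 / dt); p0 <- round((500 + isi) / dt)
    x[(m0 + 1):(m0 + 500)] <- -40
    x[(p0 + 1):(p0 + 500)] <- -40 * scale_probe
    fm_sweep(x, isi = isi)
  }
  sweeps_eq <- lapply(c(4, 16, 64, 256), function(i) resp(1, i))
  rc <- recovery_curve(sweeps_eq)
  expect_equal(rc$ratio, rep(1, 5), tolerance = 1e-9)
  rf <- fit_recovery(rc)
  expect_false(rf$fit_ok)
  expect_match(rf$reason, "no depression")
  # probe at half the masker everywhere -> ratios 0.5
  sweeps_half <- lapply(c(4, 16, 64, 256), function(i) resp(0.5, i))
  rc2 <- recovery_curve(sweeps_half)
  expect_equal(rc2$ratio[rc2$isi_ms < 20000], rep(0.5, 4), tolerance = 1e-9)
  # ratios exactly on 1 - 0.8 exp(-t/200): tau recovered exactly
  curve <- data.frame(isi_ms = c(4, 16, 64, 256, 20000))
  curve$ratio <- 1 - 0.8 * exp(-curve$isi_ms / 200)
  rf2 <- fit_recovery(curve)
  expect_true(rf2$fit_ok)
  expect_equal(rf2$tau_recovery, 200, tolerance = 1e-5)
  expect_equal(rf2$r0, 0.2, tolerance = 1e-5)
})

test_that("occupancy-model recovery increases with ISI and centers on truth", {
  res <- vapply(1:6, function(s) {
    tr <- ground_truth_preset("high", seed = s)
    ev <- simulate_evoked(protocol_fm(reps = 12, pre_ms = 100, post_ms = 50),
                          tr)
    rc <- recovery_curve(ev$sweeps)
    c(inc = all(diff(rc$ratio[rc$isi_ms >= 16]) > -0.15),
      tau = fit_recovery(rc)$tau_recovery)
  }, numeric(2))
  # recovery ratios rise with ISI in the clear majority of simulations
  expect_gte(mean(res["inc", ]), 4 / 6)
  expect_lt(abs(median(res["tau", ]) - 450) / 450, 0.4)
})

test_that("fitted RRP grows with the simulated pool size", {
  rrp_of <- function(n_rrp, seed) {
    tr <- ground_truth_preset("high", seed = seed, n_rrp = n_rrp)
    ev <- simulate_evoked(protocol_fm(reps = 10, isis = 16, pre_ms = 100,
                                      post_ms = 50), tr)
    qtr <- average_masker_response(ev$sweeps)
    fit_depletion(qtr, abs(kernel_charge(tr$amp_mean, tr$tau_rise,
                                         tr$tau_decay)))$rrp_sv
  }
  grid <- c(7, 14, 28)
  est <- vapply(grid, rrp_of, numeric(1), seed = 5)
  expect_true(all(diff(est) > 0))
})
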