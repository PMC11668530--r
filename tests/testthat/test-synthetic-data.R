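# generative model: EPSC kernel, spontaneous trains, Ca2+ currents,
# evoked release from the depleting pool

test_that("EPSC kernel has the analytic extremum, charge and rise behavior", {
  dt <- 0.001
  k <- make_epsc_kernel(-100, 0.1, 1.0, dt = dt)
  ts <- kernel_peak_time(0.1, 1.0)
  expect_equal(ts, 0.1 * 1.0 / 0.9 * log(10))
  expect_equal(min(k), -100, tolerance = 1e-5)
  expect_equal((which.min(k) - 1) * dt, ts, tolerance = 2 * dt)
  # charge against trapezoidal integration
  q <- integrate_charge(k, dt, c(0, (length(k) - 1) * dt))
  expect_equal(q, kernel_charge(-100, 0.1, 1.0), tolerance = 1e-3)
  expect_error(make_epsc_kernel(-100, 1.0, 0.5), "tau_rise < tau_decay")
  # 10-90% rise time grows monotonically with tau_rise at fixed tau_decay
  rise_1090 <- function(tr) {
    kk <- make_epsc_kernel(-100, tr, 1.5, dt = dt)
    t10 <- which(kk < -10)[1]
    t90 <- which(kk < -90)[1]
    (t90 - t10) * dt
  }
  rises <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), rise_1090, numeric(1))
  expect_true(all(diff(rises) > 0))
})

test_that("spontaneous trains are Poisson with skewed gamma amplitudes", {
  tr0 <- ground_truth(sr_true = 0, seed = 1)
  sp0 <- simulate_spontaneous(tr0, duration_ms = 2000)
  expect_equal(nrow(sp0$truth$event_times), 0)
  expect_lt(max(abs(sp0$sweep$i_post)), 6 * tr0$noise_sd_post)
  # event count within 3*sqrt(lambda) of lambda = 1000 (rate 10/s, 100 s)
  tr <- ground_truth(sr_true = 10, seed = 3)
  sp <- simulate_spontaneous(tr, duration_ms = 100000)
  expect_lt(abs(nrow(sp$truth$event_times) - 1000), 3 * sqrt(1000))
  # amplitude law: CV and skewness targets at n = 1e4 within 10%
  set.seed(9)
  a <- pairsynapse:::sim_amplitudes(1e4, ground_truth(amp_cv = 0.68))
  expect_equal(sd(a) / mean(a), 0.68, tolerance = 0.10)
  expect_equal(sample_skewness(a), 2 * 0.68, tolerance = 0.10)
  expect_equal(mean(a), 80, tolerance = 0.05)
})

test_that("stochastic outputs are reproducible from the seed", {
  tr <- ground_truth(sr_true = 5, seed = 42)
  s1 <- simulate_spontaneous(tr, duration_ms = 3000)
  s2 <- simulate_spontaneous(tr, duration_ms = 3000)
  expect_identical(s1$sweep$i_post, s2$sweep$i_post)
  expect_identical(s1$truth$event_times, s2$truth$event_times)
  fm <- protocol_fm(reps = 2, isis = c(4, 16), pre_ms = 150, post_ms = 100)
  e1 <- simulate_evoked(fm, tr)
  e2 <- simulate_evoked(fm, tr)
  expect_identical(lapply(e1$sweeps, `[[`, "i_post"),
                   lapply(e2$sweeps, `[[`, "i_post"))
})

test_that("simulated Ca2+ current follows the Boltzmann model", {
  tr <- ground_truth(seed = 2, noise_sd_pre = 0, noise_sd_post = 0,
                     sr_true = 0, leak_g = 0)
  # step to the reversal potential: steady-state Ca2+ component is zero
  pr <- protocol_iv(v_from = 60, v_to = 60, pre_ms = 20, post_ms = 10)
  sw <- simulate_ca_current(pr, tr)[[1]]
  steady <- sw$i_pre[round(28 / 0.02)]   # 8 ms into the step
  expect_lt(abs(steady), 1e-6)
  # noiseless IV -> downstream Boltzmann fit recovers parameters within 1%
  tr2 <- ground_truth(seed = 2, noise_sd_pre = 0, noise_sd_post = 0,
                      sr_true = 0)
  pr2 <- protocol_iv(pre_ms = 20, post_ms = 10)
  main <- simulate_ca_current(pr2, tr2)
  pn <- simulate_pn(pr2, tr2)
  sub <- mapply(leak_subtract, main, pn, SIMPLIFY = FALSE)
  iv <- iv_curve(sub)
  bf <- fit_boltzmann(iv, tr2$v_rev)   # known reversal isolates activation
  expect_lt(abs(bf$v_half - tr2$v_half), 1)
  expect_lt(abs(bf$slope - tr2$slope) / tr2$slope, 0.05)
  expect_lt(abs(bf$g_max - tr2$g_max) / tr2$g_max, 0.05)
})

test_that("P/n subtraction cancels the leak of a leak-only cell", {
  tr <- ground_truth(seed = 3, g_max = 0, leak_g = 0.8, sr_true = 0,
                     noise_sd_pre = 0, noise_sd_post = 0)
  pr <- protocol_iv(v_from = -40, v_to = 20, dv = 20, pre_ms = 10, post_ms = 5)
  main <- simulate_ca_current(pr, tr)
  pn <- simulate_pn(pr, tr)
  for (i in seq_along(main)) {
    sub <- leak_subtract(main[[i]], pn[[i]], n = 4)
    expect_lt(max(abs(sub$i_pre)), 1e-9)   # exact cancellation, zero noise
  }
  # with noise the residual stays below twice the noise floor
  trn <- ground_truth(seed = 3, g_max = 0, leak_g = 0.8, sr_true = 0,
                      noise_sd_pre = 2)
  mainn <- simulate_ca_current(pr, trn)
  pnn <- simulate_pn(pr, trn)
  subn <- leak_subtract(mainn[[1]], pnn[[1]], n = 4)
  expect_lt(mean(abs(subn$i_pre)), 2 * 2 * sqrt(1 + 1 / 4))
})

test_that("pool occupancy is a fixed point without stimulation", {
  tr <- ground_truth(seed = 1, sr_true = 0)
  sw <- list(dur = 500, epochs = NULL, tag = "spont")
  rel <- pairsynapse:::sim_release_events(sw, tr, 0.02, -58, occ0 = 1)
  expect_equal(rel$occ_end, 1)
  expect_equal(nrow(rel$events), 0)
  # depleted pool recovers toward 1 with tau_recovery
  rel2 <- pairsynapse:::sim_release_events(sw, tr, 0.02, -58, occ0 = 0.2)
  expect_equal(rel2$occ_end, 1 - 0.8 * exp(-500 / tr$tau_recovery),
               tolerance = 1e-6)
})

test_that("increasing coupling_m steepens the fitted cooperativity", {
  fit_m <- function(m, seed) {
    tr <- ground_truth(coupling_m = m, seed = seed, sr_true = 0.2)
    pr <- protocol_iv(v_from = -70, v_to = -19, pre_ms = 20, post_ms = 20)
    ev <- simulate_evoked(pr, tr)
    pn <- simulate_pn(pr, tr)
    sub <- mapply(leak_subtract, ev$sweeps, pn, SIMPLIFY = FALSE)
    iv <- iv_curve(sub, baseline_ms = 2)   # cooperativity uses charge deltas
    ri <- release_intensity(ev$sweeps)
    sel <- iv$v <= iv$v[which.min(iv$i_ca)] & abs(iv$q_ca) > 0
    fit_cooperativity(abs(iv$q_ca[sel]), ri$q_epsc[match(iv$v[sel], ri$v)])$m
  }
  ms <- vapply(1:8, function(s)
    fit_m(2.0, s) - fit_m(0.8, s), numeric(1))
  expect_gt(mean(ms > 0), 0.7)    # steeper in the clear majority of seeds
})

test_that("protocols encode the stimulation patterns", {
  iv <- protocol_iv()
  expect_equal(length(iv$sweeps), length(seq(-70, 70, 5)))
  expect_equal(iv$sweeps[[1]]$epochs$level, -70)
  expect_equal(iv$sweeps[[1]]$epochs$end - iv$sweeps[[1]]$epochs$start, 10)
  expect_equal(iv$inter_sweep_ms, 1500)
  fm <- protocol_fm()
  expect_equal(vapply(fm$sweeps, `[[`, numeric(1), "isi"), c(4, 16, 64, 256))
  ep <- fm$sweeps[[2]]$epochs
  expect_equal(ep$end[1] - ep$start[1], 100)   # masker
  expect_equal(ep$end[2] - ep$start[2], 15)    # probe
  expect_equal(ep$start[2] - ep$end[1], 16)    # ISI
  expect_equal(unique(ep$level), -19)
  expect_equal(fm$inter_sweep_ms, 20000)
})
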