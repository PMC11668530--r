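# EPSC detection, kinetics measurement, waveform classification

test_that("detection respects the 4 x SD threshold", {
  dt <- 0.02
  n <- 20000   # 400 ms
  kern <- make_epsc_kernel(-1, 0.15, 0.55, dt)
  set.seed(1)
  noise <- rnorm(n, 0, 3)
  # a single event at 3.9 x SD of the raw noise stays below the smoothed
  # threshold scaled the same way: use an amplitude below 4 x the processed
  # SD to probe the boundary from below
  sw0 <- post_sweep(noise, dt)
  pt <- pairsynapse:::process_trace(sw0, c(0, 150))
  amp_small <- 3.9 * pt$sd_b
  x <- noise
  at <- 10000
  x[at:(at + length(kern) - 1)] <- x[at:(at + length(kern) - 1)] + amp_small * kern
  ev <- detect_events(post_sweep(x, dt), c(0, 150))
  expect_false(any(abs(ev$onset - at * dt) < 1))
  # five injected -50 pA kernels are all found at the right times
  x2 <- rnorm(n, 0, 3)
  at5 <- c(2000, 5000, 9000, 13000, 17000)
  for (a in at5)
    x2[a:(a + length(kern) - 1)] <- x2[a:(a + length(kern) - 1)] - 50 * (-kern)
  ev2 <- detect_events(post_sweep(x2, dt), c(0, 150))
  expect_equal(nrow(ev2), 5)
  expect_equal(sort(ev2$onset), (at5 - 1) * dt, tolerance = 0.2,
               ignore_attr = TRUE)
})

test_that("false positives on pure noise match a brute-force recount", {
  dt <- 0.02
  n_fp <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    sw <- post_sweep(rnorm(250000, 0, 3), dt)   # 5 s
    ev <- detect_events(sw, c(0, 500))
    pt <- pairsynapse:::process_trace(sw, c(0, 500))
    oracle <- brute_count(pt$y_s, pt$thr, max(1, round(0.15 / dt)))
    expect_equal(nrow(ev), oracle)
    n_fp <- n_fp + nrow(ev)
  }
  expect_lt(n_fp / 50, 0.5)   # < 0.5 false events per second
})

test_that("detection is translation-invariant and gain-covariant", {
  dt <- 0.02
  set.seed(5)
  tr <- ground_truth(sr_true = 8, seed = 5, frac_multiphasic = 0)
  sp <- simulate_spontaneous(tr, duration_ms = 5000)
  ev <- detect_events(sp$sweep, c(0, 500))
  # shift by 40 ms of prepended noise
  shift <- 2000
  set.seed(99)
  x2 <- c(rnorm(shift, 0, tr$noise_sd_post), sp$sweep$i_post)
  ev2 <- detect_events(post_sweep(x2, dt), c(0, 500))
  on2 <- ev2$onset - shift * dt
  core <- ev$onset[ev$onset > 200]
  frac <- mean(vapply(core, function(o) min(abs(on2 - o)) < 0.1, logical(1)))
  expect_gte(frac, 0.9)
  # scaling the trace scales the threshold; the event set is preserved
  ev3 <- detect_events(post_sweep(3.7 * sp$sweep$i_post, dt), c(0, 500))
  expect_equal(nrow(ev3), nrow(ev))
  expect_equal(ev3$onset, ev$onset, tolerance = 1e-6)
  expect_equal(ev3$amplitude, 3.7 * ev$amplitude, tolerance = 1e-6)
})

test_that("recall and precision exceed 0.95 on SNR >= 8 trains", {
  tr <- snr_truth(snr = 8, rate = 15, seed = 3)
  sp <- simulate_spontaneous(tr, duration_ms = 30000)
  ev <- detect_events(sp$sweep, c(0, 500))
  mp <- match_events(ev$onset, sp$truth$event_times$t_ms)
  expect_gte(mp["recall"], 0.95)
  expect_gte(mp["precision"], 0.95)
})

test_that("event kinetics match geometry and closed forms", {
  dt <- 0.005
  # symmetric triangular pulse of width 2 ms -> FWHM 1 ms
  half <- seq(0, -60, length.out = 201)
  tri <- c(rep(0, 25000), half, rev(half)[-1], rep(0, 4000))
  set.seed(8)
  sw <- post_sweep(tri + rnorm(length(tri), 0, 0.05), dt = dt)
  ev <- measure_event(sw, c(124, 128), c(0, 120), smooth_ms = 0.1)
  expect_equal(ev$fwhm, 1, tolerance = 0.03)
  # noiseless biexponential: FWHM within 1% of a numeric root-finding
  # oracle, charge within 0.5% of the analytic value
  kern <- make_epsc_kernel(-100, 0.1, 1.0, dt = dt)
  tt <- (seq_along(kern) - 1) * dt
  f <- approxfun(tt, kern + 50)
  left <- uniroot(f, c(0, kernel_peak_time(0.1, 1)))$root
  right <- uniroot(f, c(kernel_peak_time(0.1, 1), 10))$root
  x <- c(rep(0, 30000), kern, rep(0, 2000))
  sw2 <- post_sweep(x + rnorm(length(x), 0, 1e-4), dt = dt)
  ev2 <- measure_event(sw2, c(149, 157), c(0, 140), smooth_ms = 0.1)
  expect_equal(ev2$fwhm, right - left, tolerance = 0.01)
  expect_equal(ev2$charge, abs(kernel_charge(-100, 0.1, 1.0)),
               tolerance = 0.005)
  expect_equal(ev2$amplitude, -100, tolerance = 0.5)
  expect_equal(ev2$tau_decay, 1.0, tolerance = 0.05)
})

test_that("amplitude measurement of isolated events is nearly unbiased", {
  dt <- 0.02
  kern <- make_epsc_kernel(-60, 0.15, 0.55, dt)
  set.seed(11)
  amps <- replicate(60, {
    x <- rnorm(15000, 0, 3)
    x[6000:(6000 + length(kern) - 1)] <-
      x[6000:(6000 + length(kern) - 1)] + kern
    ev <- detect_events(post_sweep(x, dt), c(0, 110))
    hit <- which(abs(ev$onset - 120) < 1)
    if (length(hit)) ev$amplitude[hit[1]] else NA
  })
  expect_lt(abs(mean(amps, na.rm = TRUE) + 60), 2)   # bias << noise SD
})

test_that("waveform classification separates mono- and multiphasic events", {
  dt <- 0.02
  kern <- make_epsc_kernel(-80, 0.15, 0.55, dt)
  pad <- function(v, n) c(v, rep(0, n - length(v)))
  set.seed(13)
  base <- rnorm(10000, 0, 1.5)
  one <- base
  one[4000:(4000 + length(kern) - 1)] <-
    one[4000:(4000 + length(kern) - 1)] + kern
  ev1 <- detect_events(post_sweep(one, dt), c(0, 110))
  expect_equal(ev1$phasic_class[which.min(abs(ev1$onset - 80))], "monophasic")
  expect_equal(ev1$n_inflections[which.min(abs(ev1$onset - 80))], 0)
  # two equal kernels 1 ms apart merge into one multiphasic event
  two <- base
  k2 <- pad(kern, length(kern) + 50) + c(rep(0, 50), kern)
  two[4000:(4000 + length(k2) - 1)] <- two[4000:(4000 + length(k2) - 1)] + k2
  ev2 <- detect_events(post_sweep(two, dt), c(0, 110))
  hit <- which.min(abs(ev2$onset - 80))
  expect_equal(ev2$phasic_class[hit], "multiphasic")
  expect_gte(ev2$n_inflections[hit], 1)
})

test_that("classified multiphasic fraction tracks the simulated fraction", {
  tr <- ground_truth(sr_true = 4, seed = 2, frac_multiphasic = 0.5,
                     noise_sd_post = 2, amp_mean = 100)
  sp <- simulate_spontaneous(tr, duration_ms = 100000)   # ~400 events
  ev <- detect_events(sp$sweep, c(0, 1000))
  expect_gt(nrow(ev), 300)
  expect_equal(mean(ev$phasic_class == "multiphasic"), 0.5,
               tolerance = 0.07)
})

test_that("degenerate inputs raise the documented errors", {
  sw <- post_sweep(rnorm(10000), 0.02)
  expect_error(detect_events(sw, c(0, 50)), "100 ms")
  flat <- post_sweep(rep(0, 10000), 0.02)
  expect_error(detect_events(flat, c(0, 150)), "degenerate")
})
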