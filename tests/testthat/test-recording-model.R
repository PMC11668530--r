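# data model, charge integration, access-resistance QC, container round-trip

test_that("sweep invariants are enforced", {
  expect_error(sweep_record(1:5, 1:4, 1:5), "equal length")
  expect_error(sweep_record(1, 1, 1), "equal length")
  expect_error(sweep_record(1:10, 1:10, 1:10, dt = -1), "positive")
  expect_error(sweep_record(1:10, 1:10, 1:10, dt = 0.2), "20-50 kHz")
  sw <- sweep_record(1:10, 1:10, 1:10, dt = 0.2, check_rate = FALSE)
  expect_s3_class(sw, "sweep")
  # epoch levels must reproduce v_cmd at epoch midpoints
  v <- c(rep(-58, 50), rep(-20, 50), rep(-58, 50))
  expect_error(
    sweep_record(v, numeric(150), numeric(150), dt = 0.02,
                 epoch_table = data.frame(start = 1, end = 2, level = -25)),
    "midpoints")
  ok <- sweep_record(v, numeric(150), numeric(150), dt = 0.02,
                     epoch_table = data.frame(start = 1, end = 2, level = -20))
  expect_equal(ok$epoch_table$level, -20)
})

test_that("qc pass/fail follows the leak-current limits", {
  good <- qc_result(-30, -50, 15, 60, 1.7, 1500)
  expect_true(good$pass)
  expect_false(qc_result(-61, -50, 15, 60, 1.7, 1500)$pass)
  expect_false(qc_result(-30, -101, 15, 60, 1.7, 1500)$pass)
  bad <- qc_result(-30, -50, NA, 60, 1.7, 1500)
  expect_false(bad$pass)
  expect_match(bad$reasons, "undefined", all = FALSE)
  # boundary: exactly at the limit passes
  expect_true(qc_result(-60, -100, 15, 60, 1.7, 1500)$pass)
})

test_that("integrate_charge matches closed forms and is linear", {
  # rectangular -100 pA x 1 ms pulse -> -100 fC
  x <- c(rep(0, 50), rep(-100, 51), rep(0, 50))
  expect_equal(integrate_charge(x, 0.02, c(1, 2)), -100)
  # zero trace
  expect_equal(integrate_charge(numeric(500), 0.02, c(0, 5)), 0)
  # biexponential kernel vs analytic antiderivative at dt = 0.02
  k <- make_epsc_kernel(-80, 0.2, 1.4, dt = 0.02)
  q_num <- integrate_charge(k, 0.02, c(0, (length(k) - 1) * 0.02))
  expect_equal(q_num, kernel_charge(-80, 0.2, 1.4), tolerance = 1e-3)
  # linearity over random traces
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(1); b <- rnorm(1)
    x <- rnorm(300); y <- rnorm(300)
    w <- c(runif(1, 0, 2), runif(1, 3, 5.9))
    expect_equal(integrate_charge(a * x + b * y, 0.02, w),
                 a * integrate_charge(x, 0.02, w) +
                   b * integrate_charge(y, 0.02, w))
  }
  # window outside the trace is a range error; baseline must be finite
  expect_error(integrate_charge(numeric(100), 0.02, c(0, 10)), "outside")
  expect_error(integrate_charge(numeric(100), 0.02, c(0, 1), baseline = NA),
               "finite")
  # sign convention: inward (negative) current gives negative charge
  expect_lt(integrate_charge(rep(-5, 100), 0.02, c(0, 1)), 0)
})

test_that("estimate_access recovers noiseless single-RC circuits to < 2%", {
  grid <- expand.grid(rs = c(7, 30, 60, 100), cm = c(0.5, 1.7, 5))
  for (i in seq_len(nrow(grid))) {
    rs <- grid$rs[i]; cm <- grid$cm[i]; rm <- 1200
    # dt fine enough to resolve the fastest transient in the grid
    est <- estimate_access(simulate_testpulse(rs, cm, rm, dt = 0.002))
    expect_true(est$ok)
    expect_lt(abs(est$rs - rs) / rs, 0.02)
    expect_lt(abs(est$cm - cm) / cm, 0.02)
    expect_lt(abs(est$rm - rm) / rm, 0.02)
  }
})

test_that("estimate_access flags flat traces and survives noise", {
  flat <- sweep_record(c(rep(0, 100), rep(10, 400)), numeric(500),
                       numeric(500), dt = 0.02, protocol_tag = "testpulse",
                       epoch_table = data.frame(start = 2, end = 10, level = 10))
  est <- estimate_access(flat)
  expect_false(est$ok)
  expect_true(is.nan(est$rs) && is.nan(est$cm) && is.nan(est$rm))
  # Monte-Carlo: 0.5 pA RMS noise, rs within 5% of truth on average
  set.seed(7)
  errs <- replicate(25, {
    tp <- simulate_testpulse(60, 1.7, 1500, noise_sd = 0.5)
    e <- estimate_access(tp)
    abs(e$rs - 60) / 60
  })
  expect_lt(median(errs), 0.05)
})

test_that("container round-trip is bit-exact and errors are explicit", {
  tr <- ground_truth(sr_true = 3, seed = 5)
  sp <- simulate_spontaneous(tr, duration_ms = 500)
  sw2 <- sweep_record(c(rep(-58, 100), rep(-20, 100), rep(-58, 100)),
                      rnorm(300), rnorm(300), dt = 0.02, protocol_tag = "IV",
                      epoch_table = data.frame(start = 2, end = 4, level = -20))
  pair <- pair_record("rt1", list(sp$sweep, sw2), position = "pillar",
                      qc = qc_result(-10, -20, 15, 60, 1.7, 1500),
                      truth = sp$truth)
  d <- withr::local_tempdir()
  save_pair(pair, d)
  p2 <- load_pair(d)
  expect_identical(lapply(pair$sweeps, `[[`, "i_post"),
                   lapply(p2$sweeps, `[[`, "i_post"))
  expect_identical(lapply(pair$sweeps, `[[`, "i_pre"),
                   lapply(p2$sweeps, `[[`, "i_pre"))
  expect_identical(lapply(pair$sweeps, `[[`, "v_cmd"),
                   lapply(p2$sweeps, `[[`, "v_cmd"))
  expect_equal(p2$sweeps[[2]]$epoch_table, sw2$epoch_table)
  expect_identical(p2$pair_id, "rt1")
  expect_identical(p2$position, "pillar")
  expect_equal(p2$holding_v_pre, -58)
  expect_equal(p2$ljp_pre, 19)
  expect_true(p2$qc$pass)
  expect_equal(p2$truth$coupling_m, pair$truth$coupling_m)
  expect_equal(p2$truth$event_times$t_ms, pair$truth$event_times$t_ms)
  # corrupt container: missing sweeps group
  d2 <- withr::local_tempdir()
  save_pair(pair, d2)
  unlink(file.path(d2, "sweeps"), recursive = TRUE)
  expect_error(load_pair(d2), "corrupt container")
  # version mismatch
  d3 <- withr::local_tempdir()
  save_pair(pair, d3)
  meta <- jsonlite::read_json(file.path(d3, "meta.json"))
  meta$version <- "0.0"
  jsonlite::write_json(meta, file.path(d3, "meta.json"), auto_unbox = TRUE)
  expect_error(load_pair(d3), "version")
  expect_error(load_pair(withr::local_tempdir()), "corrupt container")
})

test_that("multi-pair dataset checksum survives the round-trip", {
  sums <- function(pairs) vapply(pairs, function(p)
    sum(vapply(p$sweeps, function(s) sum(s$i_post), numeric(1))), numeric(1))
  pairs <- lapply(1:3, function(k)
    simulate_pair(ground_truth(sr_true = 2, seed = k),
                  pair_id = paste0("p", k), spont_ms = 300,
                  iv = NULL, fm = NULL))
  before <- sums(pairs)
  d <- withr::local_tempdir()
  re <- lapply(seq_along(pairs), function(k) {
    save_pair(pairs[[k]], file.path(d, k))
    load_pair(file.path(d, k))
  })
  expect_identical(sums(re), before)
})
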