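test_that("onset detection: flat trace, analytic Gaussian bump", {
  dt <- 1 / 42
  flat <- voltage_trace(rep(-65, 5000), dt)
  expect_equal(nrow(detect_spike_onsets(flat)), 0L)

  # V(t) = -65 + 40 exp(-((t-50)/0.2)^2): onset voltage where the analytic
  # |dV/dt| crosses 25 mV/ms on the rising flank (root found independently)
  tt <- seq(0, 100, by = dt)
  v <- -65 + 40 * exp(-((tt - 50) / 0.2)^2)
  dvdt_abs <- function(t) 40 * abs(2 * (t - 50) / 0.04) *
    exp(-((t - 50) / 0.2)^2)
  t_on <- uniroot(function(t) dvdt_abs(t) - 25, c(49, 49.9),
                  tol = 1e-12)$root
  sp <- detect_spike_onsets(voltage_trace(v, dt))
  expect_equal(nrow(sp), 1L)
  v_on_ref <- -65 + 40 * exp(-((t_on - 50) / 0.2)^2)
  # within one sample of the analytic criterion crossing
  expect_lt(abs(sp$onset_time_ms - t_on), dt + 1e-12)
  i <- round(sp$onset_time_ms / dt) + 1
  expect_lt(abs(sp$onset_v_mV - v_on_ref),
            abs(v[i + 1] - v[i - 1]) / 2 + 1e-9)
  expect_lt(sp$onset_time_ms, sp$peak_time_ms)
  expect_lte(sp$onset_v_mV, sp$peak_v_mV)
})

test_that("onset detection recovers simulator-logged initiation times", {
  suite <- make_fixture_suite("rectified", seed = 21, duration_ms = 5000)
  sim <- suite$sims[[1]]
  sp <- detect_spike_onsets(sim$trace)
  expect_equal(nrow(sp), length(sim$spike_times_ms))
  d <- vapply(sp$onset_time_ms,
              function(t) min(abs(sim$spike_times_ms - t)), numeric(1))
  dt <- trace_dt(sim$trace)
  expect_gte(mean(d <= 2 * dt + 1e-9), 0.95)
  # sharp initiation: depolarization rate at onset at or above criterion
  v <- sim$trace$v_mV
  idx <- round(sp$onset_time_ms / dt) + 1
  dvdt <- (v[idx + 1] - v[idx - 1]) / (2 * dt)
  expect_gt(mean(dvdt >= 25) , 0.99)
})

test_that("onset voltage is robust to the dV/dt criterion (15-35 mV/ms)", {
  suite <- make_fixture_suite("rectified", seed = 22, duration_ms = 5000)
  med <- vapply(c(15, 25, 35), function(crit) {
    median(detect_spike_onsets(suite$sims[[1]]$trace,
                               criterion_mV_per_ms = crit)$onset_v_mV)
  }, numeric(1))
  expect_lt(max(med) - min(med), 1)
})

test_that("pre-spike statistics are exact on affine traces", {
  dt <- 0.02
  tt <- seq(0, 12, by = dt)
  v <- -70 + 2 * tt
  onset_t <- 10
  sp <- tibble::tibble(onset_time_ms = onset_t,
                       onset_v_mV = -70 + 2 * onset_t,
                       peak_time_ms = onset_t + 0.2,
                       peak_v_mV = 0, preceding_isi_ms = NA_real_)
  out <- prespike_stats(voltage_trace(v, dt), sp)
  # mean over [onset-5, onset): midpoint at onset - 2.5 (+ half-sample offset)
  expect_equal(out$prespike_mean_v_mV, -70 + 2 * (onset_t - 2.5) - 2 * dt / 2,
               tolerance = 1e-9)
  expect_equal(out$depol_rate_mV_per_ms, 2, tolerance = 1e-9)

  vconst <- rep(-60, length(tt))
  out2 <- prespike_stats(voltage_trace(vconst, dt), sp)
  expect_equal(out2$prespike_mean_v_mV, -60)
  expect_equal(out2$depol_rate_mV_per_ms, 0, tolerance = 1e-12)
})

test_that("windows running off the trace or over a previous spike yield NA", {
  dt <- 0.02
  v <- rep(-60, 1000)
  sp <- tibble::tibble(
    onset_time_ms = c(2, 8),          # first: 5 ms window precedes start
    onset_v_mV = c(-50, -50),
    peak_time_ms = c(3.5, 8.2),       # second's 5 ms window contains peak 1
    peak_v_mV = c(0, 0),
    preceding_isi_ms = c(NA, 6))
  out <- prespike_stats(voltage_trace(v, dt), sp)
  expect_true(is.na(out$prespike_mean_v_mV[1]))
  expect_true(is.na(out$prespike_mean_v_mV[2]))
  expect_false(is.na(out$depol_rate_mV_per_ms[2]))  # 1.5 ms window is clean
})

test_that("noisy-ramp slope estimate is unbiased within sampling error", {
  dt <- 1 / 24
  tt <- seq(0, 12, by = dt)
  sp <- tibble::tibble(onset_time_ms = 10, onset_v_mV = -50,
                       peak_time_ms = 10.2, peak_v_mV = 0,
                       preceding_isi_ms = NA_real_)
  set.seed(123)
  slopes <- replicate(100, {
    v <- -70 + 2 * tt + rnorm(length(tt), sd = 0.5)
    prespike_stats(voltage_trace(v, dt), sp)$depol_rate_mV_per_ms
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 2), 3 * se)
})

test_that("threshold correlations: identity, degeneracy, known generative slope", {
  # onset equals the mean-voltage predictor exactly
  sp <- tibble::tibble(onset_v_mV = c(-55, -53, -51, -54),
                       prespike_mean_v_mV = c(-55, -53, -51, -54),
                       depol_rate_mV_per_ms = c(1, 2, 3, 4),
                       preceding_isi_ms = c(NA, 10, 12, 9))
  out <- threshold_correlations(sp)
  mv <- out[out$predictor == "prespike_mean_v", ]
  expect_equal(mv$r, 1)
  expect_equal(mv$slope, 1)

  # identical onset voltages: degenerate, flagged, r and slope reported as 0
  spd <- sp
  spd$onset_v_mV <- rep(-53, 4)
  outd <- threshold_correlations(spd)
  expect_true(all(outd$degenerate))
  expect_true(all(outd$r == 0 & outd$slope == 0))

  # synthetic cohort with known generative slope 0.4 and r ~ 0.75
  set.seed(99)
  n <- 200
  mv_x <- rnorm(n, -60, 3)
  noise_sd <- 0.4 * 3 * sqrt(1 / 0.75^2 - 1)
  sp2 <- tibble::tibble(onset_v_mV = 0.4 * mv_x + rnorm(n, 0, noise_sd),
                        prespike_mean_v_mV = mv_x,
                        depol_rate_mV_per_ms = rnorm(n, 3, 1),
                        preceding_isi_ms = c(NA, rexp(n - 1, 1 / 50)))
  out2 <- threshold_correlations(sp2)
  s <- out2$slope[out2$predictor == "prespike_mean_v"]
  expect_gt(s, 0.3); expect_lt(s, 0.5)
  expect_gt(out2$r[out2$predictor == "prespike_mean_v"], 0.6)

  expect_error(threshold_correlations(sp[1:2, ]), "fewer than 3")
})

test_that("spike tables round-trip as CSV", {
  suite <- make_fixture_suite("constant", seed = 5, duration_ms = 3000)
  sp <- prespike_stats(suite$sims[[1]]$trace,
                       detect_spike_onsets(suite$sims[[1]]$trace))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spike_table(sp, f)
  sp2 <- read_spike_table(f)
  expect_equal(as.data.frame(sp2), as.data.frame(sp), tolerance = 1e-12)
})

test_that("spike blanking holds the waveform at its onset voltage", {
  suite <- make_fixture_suite("constant", seed = 61, duration_ms = 3000)
  sim <- suite$sims[[1]]
  sp <- detect_spike_onsets(sim$trace)
  blanked <- blank_spike_waveforms(sim$trace, sp$onset_time_ms)
  dt <- trace_dt(sim$trace)
  idx <- round((sp$onset_time_ms[1] - trace_t0(sim$trace)) / dt) + 1
  win <- idx:(idx + ceiling(1 / dt))
  expect_true(all(blanked$v_mV[win] == sim$trace$v_mV[idx]))
  # outside blanking windows the trace is untouched
  keep <- spikethresh:::excision_mask(nrow(sim$trace), dt, 0,
                                      sp$onset_time_ms, 1.05)
  expect_identical(blanked$v_mV[keep], sim$trace$v_mV[keep])
  # blanking caps the threshold excursion after spikes
  p <- threshold_params(1, -63, -62, 0, 1, 3)
  th_raw <- integrate_threshold(sim$trace, p)
  th_bl <- integrate_threshold(blanked, p)
  expect_lte(max(th_bl$theta_mV), max(th_raw$theta_mV))
})
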