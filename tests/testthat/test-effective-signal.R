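test_that("effective signal is the pointwise difference and aligns with predictions", {
  tr <- ou_voltage_fixture(500, seed = 13)
  p <- threshold_params(1, -60, -58, 0, 1, 4)
  th <- integrate_threshold(tr, p)

  # theta == V gives ES == 0
  es0 <- effective_signal(tr, tibble::tibble(time_ms = tr$time_ms,
                                             theta_mV = tr$v_mV))
  expect_equal(es0$es_mV, rep(0, nrow(tr)))

  # constant V at the fixed point gives constant ES = V - theta_inf(V)
  vc <- voltage_trace(rep(-64, 1000), 1 / 42)
  esc <- effective_signal(vc, p)
  expect_equal(esc$es_mV,
               rep(-64 - steady_state_threshold(p, -64), 1000),
               tolerance = 1e-12)

  # upward zero crossings of ES coincide with the raw crossing set of
  # predict_spikes (no refractory filtering)
  tr2 <- voltage_trace(tr$v_mV + 6, trace_dt(tr))  # push into crossing range
  es <- effective_signal(tr2, p)$es_mV
  runs <- which(es >= 0 & c(-1, head(es, -1)) < 0)
  pr <- predict_spikes(tr2, p, refractory_ms = 0)
  pred_idx <- round(pr$spikes$time_ms / trace_dt(tr2)) + 1
  expect_true(all(runs %in% pred_idx))

  expect_error(effective_signal(tr, th[1:10, ]), "lengths")
})

test_that("autocorrelogram matches white-noise and OU closed forms", {
  dt <- 0.1
  set.seed(21)
  n <- 5e4
  wn <- rnorm(n)
  ac <- autocorrelogram(wn, dt, max_lag_ms = 20)
  expect_equal(ac$acf[1], 1)
  expect_lt(max(abs(ac$acf[-1])), 3 / sqrt(n) * 1.5)

  # OU signal: acf at lag tau within 10% of 1/e
  x <- ou_current(2e4, 1 / 42, 0, 1, 3, seed = 4)$i_pA
  ac2 <- autocorrelogram(x, 1 / 42, max_lag_ms = 10)
  at_tau <- ac2$acf[which.min(abs(ac2$lag_ms - 3))]
  expect_lt(abs(at_tau - exp(-1)), 0.1 * exp(-1))

  expect_error(autocorrelogram(rep(1, 1e4), 0.1, max_lag_ms = 10),
               "zero variance")
  expect_error(autocorrelogram(rnorm(100), 0.1, max_lag_ms = 20), "longer")
})

test_that("spike excision removes waveform contamination from the acf", {
  x <- ou_current(2e4, 1 / 42, 0, 1, 3, seed = 6)$i_pA
  onsets <- seq(100, 19000, by = 100)
  x_spiked <- x
  for (on in onsets) {
    i <- round(on * 42) + 1
    x_spiked[i:(i + 30)] <- 40  # crude waveform
  }
  ac <- autocorrelogram(x_spiked, 1 / 42, onsets_ms = onsets,
                        excision_ms = 1, max_lag_ms = 10)
  at_tau <- ac$acf[which.min(abs(ac$lag_ms - 3))]
  expect_lt(abs(at_tau - exp(-1)), 0.15 * exp(-1))
  expect_error(
    autocorrelogram(x, 1 / 42, onsets_ms = seq(0, 2e4, by = 1.5),
                    excision_ms = 1, max_lag_ms = 10),
    "excised")
})

test_that("half-height width follows its geometric definition", {
  lag <- seq(0, 30, by = 0.05)
  tau <- 3.3
  tbl <- tibble::tibble(lag_ms = lag, acf = exp(-lag / tau))
  expect_equal(acf_hhw(tbl), 2 * tau * log(2), tolerance = 1e-3)

  tri <- tibble::tibble(lag_ms = lag, acf = pmax(0, 1 - lag / 8))
  expect_equal(acf_hhw(tri), 8, tolerance = 1e-9)

  flat <- tibble::tibble(lag_ms = lag, acf = rep(1, length(lag)))
  expect_error(acf_hhw(flat), "max_lag")

  # the membrane-time-constant conversion: HHW 4.6 ms -> tau_m 3.3 ms
  expect_equal(4.6 / (2 * log(2)), 3.318, tolerance = 1e-3)
})

test_that("constant threshold leaves sigma and HHW of the voltage untouched", {
  suite <- make_fixture_suite("constant", seed = 15, duration_ms = 5000)
  sim <- suite$sims[[1]]
  sp <- detect_spike_onsets(sim$trace)
  s <- es_summary(sim$trace, suite$thr, sp$onset_time_ms)
  expect_equal(s$sigma_es_mV, s$sigma_v_mV, tolerance = 1e-12)
  expect_equal(s$hhw_es_ms, s$hhw_v_ms, tolerance = 1e-12)
  expect_equal(s$tau_m_est_ms, s$hhw_v_ms / (2 * log(2)))
})

test_that("fast threshold adaptation shrinks sigma and the correlation window", {
  ok <- vapply(1:5, function(s) {
    suite <- make_fixture_suite("fast_rectified", seed = s,
                                duration_ms = 5000)
    sim <- suite$sims[[1]]
    sp <- detect_spike_onsets(sim$trace)
    su <- es_summary(sim$trace, suite$thr, sp$onset_time_ms, max_lag_ms = 15)
    su$sigma_es_mV < su$sigma_v_mV && su$hhw_es_ms < su$hhw_v_ms
  }, logical(1))
  expect_true(all(ok))
})

test_that("slow fluctuations are filtered out of the effective signal", {
  # slow sinusoid far above the knee with unit high-side slope: threshold
  # tracks the voltage, leaving almost no effective-signal modulation
  dt <- 1 / 42
  tt <- seq(0, 2000, by = dt)
  p <- threshold_params(1, -70, -60, 0, 1, 0.5)
  v <- -55 + 3 * sin(2 * pi * tt / 200)  # period 200 ms >> tau_theta
  tr <- voltage_trace(v, dt)
  es <- effective_signal(tr, p)$es_mV
  drop <- round(50 / dt)
  expect_lt(sd(es[-(1:drop)]) / sd(v[-(1:drop)]), 0.2)
})

test_that("sinusoidal gain follows the first-order high-pass law", {
  dt <- 1 / 42
  p <- threshold_params(1, -70, -60, 0, 1, 0.5)  # operating above the knee
  v0 <- -55
  for (f_khz in c(0.05, 0.1, 0.3, 1, 3)) {  # two decades of omega
    period <- 1 / f_khz
    ncyc <- max(20, ceiling(100 / period))
    tt <- seq(0, ncyc * period, by = dt)
    v <- v0 + 0.5 * sin(2 * pi * f_khz * tt)
    es <- effective_signal(voltage_trace(v, dt), p)$es_mV
    drop <- round(10 / dt)  # 10 ms >> 5 tau transient
    gain <- sd(es[-(1:drop)]) / sd(v[-(1:drop)] - v0)
    w <- 2 * pi * f_khz
    expect_equal(gain, w * 1 / sqrt(1 + w^2), tolerance = 0.05,
                 label = sprintf("gain at %g kHz", f_khz))
  }
})

test_that("threshold adaptation shortens the effective PSP", {
  dt <- 1 / 42
  psp <- make_psp_trace(3, tau_decay_ms = 3, baseline_mV = -65,
                        duration_ms = 120, onset_ms = 20, dt_ms = dt)
  p <- threshold_params(0.5, -80, -75, 0, 1, 0.5)  # baseline above knee
  es <- effective_signal(psp, p)$es_mV
  half_decay <- function(x, t) {
    pk <- which.max(x)
    base <- x[1]
    h <- base + (x[pk] - base) / 2
    after <- which(x[pk:length(x)] <= h)[1]
    t[pk + after - 1] - t[pk]
  }
  hd_v <- half_decay(psp$v_mV, psp$time_ms)
  hd_es <- half_decay(es, psp$time_ms)
  expect_lt(hd_es, hd_v)
})
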