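test_that("steady-state curve has the right value, asymptotic slopes and limits", {
  # degenerate constant-threshold curve: softplus term vanishes
  p0 <- threshold_params(1, -59, -61, 0, 0, 7)
  expect_equal(steady_state_threshold(p0, c(-90, -61, -10)), rep(-61, 3))

  # closed-form value at the knee: offset + k_a * log(2)
  p <- threshold_params(1, -59, -61, 0, 1, 7)
  expect_equal(steady_state_threshold(p, -59), -61 + 7 * log(2),
               tolerance = 1e-12)

  # slope tends to beta (= 1) well above the knee
  eps <- 1e-4
  v <- -59 + 10 * 7
  slope <- (steady_state_threshold(p, v + eps) -
              steady_state_threshold(p, v)) / eps
  expect_lt(abs(slope - 1), 1e-3)
  # and to alpha below
  v <- -59 - 10 * 7
  slope <- (steady_state_threshold(p, v + eps) -
              steady_state_threshold(p, v)) / eps
  expect_lt(abs(slope - 0), 1e-3)

  # alpha = beta gives an affine curve
  pl <- threshold_params(1, -60, -55, 1, 1, 3)
  v <- seq(-80, -40, by = 0.5)
  expect_equal(steady_state_threshold(pl, v), -55 + (v + 60),
               tolerance = 1e-12)

  # matches the plain-R reference on random parameter sets
  set.seed(1)
  for (k in 1:20) {
    a <- runif(1, 0, 1)
    pk <- threshold_params(runif(1, 0.1, 10), runif(1, -75, -45),
                           runif(1, -75, -45), a, a + runif(1, 0, 1),
                           runif(1, 0.5, 15))
    vv <- runif(20, -90, -30)
    expect_equal(steady_state_threshold(pk, vv), ss_ref(pk, vv),
                 tolerance = 1e-10)
  }
})

test_that("parameter validation rejects bad inputs", {
  expect_error(threshold_params(-1, -59, -61, 0, 1, 7), "tau_theta")
  expect_error(threshold_params(1, -59, -61, 0, 1, 0), "k_a")
  expect_error(threshold_params(1, -59, -61, 1, 0.5, 7), "beta")
  p <- threshold_params(1, -59, -61, 0, 1, 7)
  expect_error(steady_state_threshold(p, NaN), "finite")
  expect_error(voltage_trace(c(-60, NA, -60), 0.1), "non-finite")
  expect_error(voltage_trace(numeric(0), 0.1), "non-empty")
  expect_error(voltage_trace(-60, -0.1), "positive")
})

test_that("threshold integration: fixed point and closed-form relaxation", {
  p <- threshold_params(2, -60, -58, 0.1, 1, 5)
  dt <- 1 / 42
  v0 <- -62
  n <- round(10 * p$tau_theta_ms / dt)
  tr <- voltage_trace(rep(v0, n), dt)
  s <- steady_state_threshold(p, v0)

  th <- integrate_threshold(tr, p)  # theta0 defaults to the fixed point
  expect_equal(th$theta_mV, rep(s, n), tolerance = 1e-13)

  th5 <- integrate_threshold(tr, p, theta0 = s + 5)
  t_rel <- (seq_len(n) - 1) * dt
  expect_equal(th5$theta_mV - s, 5 * exp(-t_rel / p$tau_theta_ms),
               tolerance = 1e-9)
})

test_that("exact-update integration matches a 20x finer Euler oracle", {
  tr <- ou_voltage_fixture(1000, seed = 11)
  p <- threshold_params(0.26, -59, -61, 0.1, 1, 7)
  th <- integrate_threshold(tr, p)
  ref <- euler_threshold_ref(tr$v_mV, trace_dt(tr), p,
                             theta0 = ss_ref(p, tr$v_mV[1]))
  expect_lt(max(abs(th$theta_mV - ref)), 0.01)

  # and with a slower threshold
  p2 <- threshold_params(3, -63, -62, 0, 1, 3)
  th2 <- integrate_threshold(tr, p2)
  ref2 <- euler_threshold_ref(tr$v_mV, trace_dt(tr), p2,
                              theta0 = ss_ref(p2, tr$v_mV[1]))
  expect_lt(max(abs(th2$theta_mV - ref2)), 0.01)
})

test_that("limit behaviours: tau -> 0 tracks theta_inf; stiffness only warns", {
  tr <- ou_voltage_fixture(50, seed = 3)
  p <- threshold_params(1e-4, -60, -58, 0, 1, 5)
  expect_warning(th <- integrate_threshold(tr, p), "dt/100")
  s <- steady_state_threshold(p, tr$v_mV)
  # one-sample lag: theta[n] ~ theta_inf(V[n-1]) when tau << dt
  expect_lt(max(abs(th$theta_mV[-1] - s[-length(s)])), 1e-6)
})

test_that("pointwise-larger voltage gives pointwise-larger threshold", {
  p <- threshold_params(0.5, -60, -58, 0.2, 1.2, 4)
  set.seed(7)
  for (k in 1:10) {
    a <- ou_voltage_fixture(100, seed = k)
    b <- voltage_trace(a$v_mV + runif(1, 0.5, 3), trace_dt(a))
    tha <- integrate_threshold(a, p)
    thb <- integrate_threshold(b, p)
    expect_true(all(thb$theta_mV >= tha$theta_mV - 1e-12))
  }
})

test_that("spike prediction: no crossing, step crossing, slow ramp, refractory", {
  dt <- 1 / 42
  # trace everywhere well below its own steady-state threshold: no spikes
  tr <- ou_voltage_fixture(500, seed = 5, mean_mV = -70, sd_mV = 2)
  p <- threshold_params(1, -60, -55, 0, 1, 5)
  pr <- predict_spikes(tr, p)
  expect_equal(nrow(pr$spikes), 0L)

  # instantaneous step from -70 to -50: theta (~ -61) lags, so the first
  # spike lands exactly on the step sample; theta then relaxes toward
  # theta_inf(-50) = -52, which here sits below the plateau, so firing
  # continues at exactly the refractory interval
  pstep <- threshold_params(1, -59, -61, 0, 1, 0.05)
  n1 <- round(20 / dt)
  v <- c(rep(-70, n1), rep(-50, n1))
  prs <- predict_spikes(voltage_trace(v, dt), pstep)
  expect_equal(prs$spikes$time_ms[1], n1 * dt, tolerance = 1e-12)
  expect_true(all(diff(prs$spikes$time_ms) >= 0.5 - 1e-12))
  s50 <- steady_state_threshold(pstep, -50)
  expect_equal(s50, -52, tolerance = 1e-6)
  expect_equal(tail(prs$theta$theta_mV, 1), s50, tolerance = 1e-4)

  # slow ramp (0.1 mV/ms) against a curve that stays above the diagonal:
  # the threshold rises alongside the voltage and no spike occurs in 200 ms
  pr2 <- threshold_params(0.26, -63, -61, 0, 1, 0.05)
  tramp <- seq(0, 200, by = dt)
  vr <- pmin(-70 + 0.1 * tramp, -40)
  prr <- predict_spikes(voltage_trace(vr, dt), pr2)
  expect_equal(nrow(prr$spikes), 0L)
  # direct check that theta stays above V throughout
  expect_true(all(prr$theta$theta_mV > vr))

  # refractoriness: a suprathreshold plateau emits spikes >= 0.5 ms apart
  vplat <- c(rep(-70, 100), rep(-40, round(5 / dt)))
  prp <- predict_spikes(voltage_trace(vplat, dt), pstep, refractory_ms = 0.5)
  expect_gt(nrow(prp$spikes), 1)
  expect_true(all(diff(prp$spikes$time_ms) >= 0.5 - 1e-12))
})

test_that("constant-threshold parameters reduce prediction to plain voltage crossing", {
  p <- threshold_params(1, -60, -55, 0, 0, 5)
  tr <- ou_voltage_fixture(2000, seed = 9, mean_mV = -60, sd_mV = 4)
  pr <- predict_spikes(tr, p, refractory_ms = 0)
  crossings <- which(tr$v_mV >= -55)
  expect_equal(round(pr$spikes$time_ms / trace_dt(tr)) + 1, crossings)
})

test_that("parameters serialize to and from flat JSON losslessly", {
  p <- threshold_params(0.26123456789, -59.5, -61.25, 0.1, 1.05, 7.3)
  f <- withr::local_tempfile(fileext = ".json")
  write_threshold_params(p, f)
  keys <- names(jsonlite::read_json(f))
  expect_setequal(keys, c("tau_theta_ms", "V_i_mV", "theta_offset_mV",
                          "alpha", "beta", "k_a_mV"))
  p2 <- read_threshold_params(f)
  expect_equal(unclass(p2), unclass(p))
})
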