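make_flat_trace <- function(n = 4000, dt = 0.01, level = 0, sd = 0,
                            command = -70, seed = 1) {
  set.seed(seed)
  current_trace(dt_ms = dt, current_nA = level + rnorm(n, 0, sd),
                command_mV = rep(command, n))
}

test_that("baseline zeroing removes a constant offset exactly", {
  tr <- make_flat_trace(level = 3)
  z <- zero_baseline(tr, c(0, 10))
  expect_equal(z$current_nA, rep(0, length(z$current_nA)))
  expect_equal(zero_baseline(z, c(0, 10))$current_nA, z$current_nA)

  noisy <- make_flat_trace(level = 3, sd = 0.5, seed = 42)
  w <- c(0, 20); nwin <- 20 / noisy$dt_ms
  z2 <- zero_baseline(noisy, w)
  residual <- mean(z2$current_nA[1:nwin]) # bias of the zeroed window
  expect_lt(abs(residual), 4 * 0.5 / sqrt(nwin) + 1e-12)

  stepped <- current_trace(0.01, rep(0, 1000),
                           rep(c(-70, 20), each = 500))
  expect_error(zero_baseline(stepped, c(3, 7)), "overlaps")
})

test_that("resistance estimation applies Ohm's law on the pulse plateau", {
  # constructed 20 mV pulse with a 4 nA steady response -> 5 MOhm
  n <- 3000; dt <- 0.01
  cmd <- rep(c(0, 20, 0), c(1000, 1000, 1000))
  cur <- ifelse(cmd == 20, 4, 0)
  tr <- current_trace(dt, cur, cmd)
  est <- estimate_resistance(tr)
  expect_false(est$lower_bound)
  expect_equal(est$r_Mohm, 5)

  expect_error(estimate_resistance(current_trace(dt, cur, rep(0, n))),
               "no test pulse")
  expect_error(estimate_resistance(tr, pulse_amplitude_mV = 0), "zero")
})

test_that("resistance estimation recovers stage presets", {
  set.seed(2)
  presets <- list(BATH = stage_parameters("BATH", shsy5y),
                  APPROACH = stage_parameters("APPROACH", shsy5y),
                  SEALED = stage_parameters("SEALED", shsy5y))
  for (nm in names(presets)) {
    p <- presets[[nm]]
    tr <- simulate_voltage_clamp(p, test_pulse_protocol(), dt_ms = 0.01)
    est <- estimate_resistance(tr)
    expect_lt(abs(est$r_Mohm - p$stage_total_Mohm) / p$stage_total_Mohm,
              0.02)
  }
  # noisy recovery within 10% at sd 0.2 nA (bath-scale resistance)
  set.seed(3)
  p <- stage_parameters("BATH", shsy5y)
  tr <- simulate_voltage_clamp(p, test_pulse_protocol(pre_ms = 20,
                                                      post_ms = 10),
                               dt_ms = 0.01)
  tr$current_nA <- tr$current_nA + rnorm(length(tr$current_nA), 0, 0.2)
  est <- estimate_resistance(tr)
  expect_lt(abs(est$r_Mohm - p$stage_total_Mohm) / p$stage_total_Mohm, 0.10)
})

test_that("a current change below the noise floor yields a lower bound", {
  set.seed(4)
  n <- 3000
  cmd <- rep(c(0, 20, 0), each = 1000)
  cur <- rnorm(n, 0, 0.2)                 # no resolvable response at all
  est <- estimate_resistance(current_trace(0.01, cur, cmd))
  expect_true(est$lower_bound)
  expect_gt(est$r_Mohm, 100)
})

test_that("the detector finds a single noise-free drop at the right time", {
  sx <- sim_episode(seed = 3)
  det <- detect_injection_drops(sx$trace)
  expect_equal(nrow(det$events), 1)
  expect_lt(abs(det$events$time_ms - sx$truth$events$time_ms), 1)
  expect_equal(det$events$amplitude_nA, -11.9, tolerance = 0.01)
  expect_equal(det$accumulated_nA, -11.9, tolerance = 0.01)
  expect_true(det$success)
})

test_that("flat noise-only traces yield no events and no success", {
  det <- detect_injection_drops(make_flat_trace(sd = 0.05, seed = 9))
  expect_equal(nrow(det$events), 0)
  expect_false(det$success)
  expect_error(
    detect_injection_drops(current_trace(0.01, rep(0, 1000),
                                         rep(c(-70, 0), each = 500))),
    "constant")
})

test_that("threshold arithmetic: two -6 nA events succeed, one does not", {
  two <- make_flat_trace(n = 30000, dt = 0.01)
  t <- trace_times(two)
  two$current_nA <- -6 * (t >= 100) - 6 * (t >= 200)
  det2 <- detect_injection_drops(two)
  expect_equal(nrow(det2$events), 2)
  expect_equal(det2$accumulated_nA, -12, tolerance = 0.01)
  expect_true(det2$success)

  one <- make_flat_trace(n = 30000, dt = 0.01)
  one$current_nA <- -6 * (t >= 150)
  det1 <- detect_injection_drops(one)
  expect_equal(det1$accumulated_nA, -6, tolerance = 0.01)
  expect_false(det1$success)
})

test_that("noise-free scripted events are recovered completely", {
  for (seed in 1:10) {
    n_ev <- 1 + seed %% 3
    sx <- sim_episode(seed = seed * 13, n_events = n_ev, spacing_ms = 80,
                      pre_ms = 60, post_ms = 80)
    det <- detect_injection_drops(sx$trace)
    expect_equal(nrow(det$events), n_ev)
    expect_equal(det$events$amplitude_nA, sx$truth$events$drop_nA,
                 tolerance = 0.1 / 11.9)
    expect_lt(max(abs(det$events$time_ms - sx$truth$events$time_ms)), 1)
  }
})

test_that("the calibration pair inverts the injection-current relation", {
  expect_warning(r1 <- calibrate_access_pair(-11.9, -0.3), "4-8 MOhm")
  expect_equal(r1, 0.02521008, tolerance = 1e-6)
  expect_equal(calibrate_access_pair(-11.7, -0.3, warn = FALSE),
               0.02564103, tolerance = 1e-6)
  # round trip to machine precision
  for (e in c(-0.3, -1.2, 2)) {
    for (drop in c(-11.9, -5, 8)) {
      if (sign(e) != sign(drop)) next
      r <- calibrate_access_pair(drop, e, warn = FALSE)
      expect_equal(injection_current(e, r), drop, tolerance = 1e-14)
    }
  }
  expect_error(calibrate_access_pair(0, -0.3), "nonzero")
  expect_error(calibrate_access_pair(-11.9, 0.3), "same sign")
  expect_no_warning(calibrate_access_pair(-1, -5))
})

test_that("viability classification matches the conductance ground truth", {
  cases <- expand.grid(g_k = c(0.1, 0), g_na = c(0.3, 0))
  for (i in seq_len(nrow(cases))) {
    rep <- classify_viability(sim_step_family(cases$g_k[i], cases$g_na[i]))
    expect_identical(rep$k_active, cases$g_k[i] > 0)
    expect_identical(rep$na_active, cases$g_na[i] > 0)
    expect_identical(rep$verdict,
                     if (cases$g_k[i] > 0) "viable" else "non-viable")
  }
  expect_error(classify_viability(sim_step_family()[1:2]), "at least 3")
})

test_that("the HEK preset shows potassium-only activity", {
  traces <- sim_step_family(hek293$gating$k$g_max_uS,
                            hek293$gating$na$g_max_uS, base = hek293)
  rep <- classify_viability(traces)
  expect_true(rep$k_active)
  expect_false(rep$na_active)
  expect_identical(rep$verdict, "viable")
})

test_that("the control loop retries until the accumulated drop crosses", {
  ok <- sim_episode(seed = 21)$trace
  log1 <- control_loop(list(ok))
  expect_equal(log1$decision, "success")
  expect_true(attr(log1, "succeeded"))

  half <- function(seed) {
    tr <- make_flat_trace(n = 30000, dt = 0.01, seed = seed)
    tr$current_nA <- -6 * (trace_times(tr) >= 150)
    tr
  }
  log2 <- control_loop(list(half(1), half(2)))
  expect_equal(log2$decision, c("retry", "success"))

  flat <- lapply(1:3, function(s) make_flat_trace(sd = 0.05, seed = s))
  log3 <- control_loop(flat)
  expect_equal(log3$decision, rep("retry", 3))
  expect_false(attr(log3, "succeeded"))
})
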