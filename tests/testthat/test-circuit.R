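test_that("branch and injection currents follow Ohm's law in model units", {
  expect_equal(channel_current(100, -90, 20), 9.5)
  expect_equal(channel_current(-80, 60, 50), -2.8)
  expect_equal(channel_current(-90, -90, 20), 0)
  expect_error(channel_current(0, 0, 0), "> 0")

  expect_equal(injection_current(0, 5), 0)
  expect_equal(injection_current(-0.3, 0.02521008), -11.9, tolerance = 1e-6)
  expect_error(injection_current(-0.3, -1), "> 0")
  set.seed(1)
  for (i in 1:10) {
    e <- runif(1, -5, 5); r <- runif(1, 0.01, 10)
    expect_equal(sign(injection_current(e, r)), sign(e))
  }
})

test_that("Boltzmann gating has the right midpoint, limits and kinetics", {
  gp <- gating_parameters()
  expect_equal(gating_steady_state(gp$k$v_half_mV, gp)$n, 0.5)
  expect_equal(gating_steady_state(gp$na$v_half_mV, gp)$m, 0.5)
  expect_equal(gating_steady_state(1e4, gp)$n, 1, tolerance = 1e-12)
  expect_equal(gating_steady_state(-1e4, gp)$n, 0, tolerance = 1e-12)
  # inactivation decreases with depolarisation
  expect_lt(gating_steady_state(0, gp)$h, gating_steady_state(-80, gp)$h)

  st <- gating_steady_state(-30, gp)
  expect_equal(advance_gating(st, -30, 1, gp), st)          # fixed point
  far <- advance_gating(gating_steady_state(-80, gp), 20, 100, gp)
  expect_equal(far$n, gating_steady_state(20, gp)$n, tolerance = 1e-8)
  # semigroup: two half-steps equal one full step at constant V
  one <- advance_gating(st, 10, 0.8, gp)
  two <- advance_gating(advance_gating(st, 10, 0.4, gp), 10, 0.4, gp)
  expect_equal(one, two, tolerance = 1e-12)
})

test_that("channels-closed step response matches the analytic RC solution", {
  p <- circuit_parameters(r_seal_Mohm = Inf, r_access_Mohm = 10,
                          c_m_pF = 30, c_pipette_pF = 0)
  prot <- voltage_protocol(c(0, 20), c(5, 10))
  tr <- simulate_voltage_clamp(p, prot, dt_ms = 0.01)
  t <- trace_times(tr)
  edge <- which(tr$command_mV == 20)[1]
  expect_equal(tr$current_nA[edge], 2.0, tolerance = 1e-9)
  rel <- t[edge:length(t)] - t[edge]
  oracle <- rc_step_oracle(rel, 20, 10, 30)
  expect_lt(max(abs(tr$current_nA[edge:length(t)] - oracle)),
            0.01 * max(abs(oracle)))
  # charge delivered to the membrane = C_M * dV = 0.6 pC (trapezoid)
  ic <- tr$branches$i_c[edge:length(t)]
  charge_pC <- sum((ic[-1] + ic[-length(ic)]) / 2) * tr$dt_ms
  expect_equal(charge_pC, 0.6, tolerance = 0.01)
})

test_that("no DC path means zero steady current", {
  p <- circuit_parameters(r_seal_Mohm = Inf, c_pipette_pF = 0)
  tr <- simulate_voltage_clamp(p, voltage_protocol(-70, 50), dt_ms = 0.01)
  expect_lt(max(abs(tr$current_nA)), 1e-12)
})

test_that("zero-amplitude protocols give identically zero branches", {
  tr <- simulate_voltage_clamp(circuit_parameters(r_seal_Mohm = Inf),
                               voltage_protocol(0, 20), dt_ms = 0.01)
  for (b in tr$branches) expect_true(all(b == 0))
})

test_that("current decomposition satisfies both circuit identities", {
  p <- shsy5y
  p$switch <- switch_state(s_k = "closed", s_na = "closed")
  tr <- simulate_voltage_clamp(p, voltage_protocol(c(-70, 20, -70),
                                                   c(10, 30, 10)),
                               dt_ms = 0.01)
  dec <- decompose_currents(tr)
  expect_lt(dec$max_residual_total_nA, 1e-9)
  expect_lt(dec$max_residual_access_nA, 1e-9)
})

test_that("membrane capacitive current vanishes on plateaus", {
  p <- circuit_parameters(r_access_Mohm = 10, c_m_pF = 30)
  tr <- simulate_voltage_clamp(p, voltage_protocol(c(0, 20), c(5, 20)),
                               dt_ms = 0.01)
  t <- trace_times(tr)
  edge_t <- 5
  peak <- max(abs(tr$branches$i_c))
  tau_ms <- 10 * 30 / 1000
  # the RC envelope exp(-t/tau) falls below 0.1% only past ~7 tau; use 8
  plateau <- which(t >= edge_t + 8 * tau_ms)
  expect_lt(max(abs(tr$branches$i_c[plateau])), 0.001 * peak)
})

test_that("injection activation superposes the steady drop", {
  p <- shsy5y
  prot <- voltage_protocol(-70, 200)
  inj <- data.frame(time_ms = 100,
                    e_injection_mV = p$calibration$e_injection_mV,
                    r_access_Mohm = p$calibration$r_access_injection_Mohm)
  with_inj <- simulate_voltage_clamp(p, prot, dt_ms = 0.01,
                                     injections = inj)
  without <- simulate_voltage_clamp(p, prot, dt_ms = 0.01)
  t <- trace_times(with_inj)
  delta <- with_inj$current_nA - without$current_nA
  expect_equal(unique(delta[t < 100]), 0)
  expect_equal(delta[t >= 100], rep(-11.9, sum(t >= 100)),
               tolerance = 1e-9)
})

test_that("each channel branch current crosses zero at its battery", {
  p <- shsy5y
  p$switch <- switch_state(s_k = "closed", s_na = "closed")
  # small conductances keep the series-resistance voltage error small, so
  # the membrane potential actually sweeps across both batteries
  p$gating$k$g_max_uS <- 1e-3
  p$gating$na$g_max_uS <- 1e-3
  p$gating$na$tau_inact_ms <- 1e3   # keep h open so i_na is visible
  tr <- simulate_voltage_clamp(p, voltage_protocol(c(-70, -120, 80, -70),
                                                   c(10, 30, 30, 10)),
                               dt_ms = 0.01)
  vm <- tr$v_mem_mV
  expect_gt(max(vm), 60); expect_lt(min(vm), -90)
  nz <- abs(vm - p$e_k_mV) > 1e-9
  expect_true(all(sign(tr$branches$i_k[nz]) %in%
                    c(0, sign(vm[nz] - p$e_k_mV))))
  nz <- abs(vm - p$e_na_mV) > 1e-9
  expect_true(all(sign(tr$branches$i_na[nz]) %in%
                    c(0, sign(vm[nz] - p$e_na_mV))))
  expect_equal(channel_current(-90, -90, 3), 0)
  expect_equal(channel_current(60, 60, 3), 0)
})

test_that("halving dt changes the trace by less than 0.5% of its range", {
  p <- shsy5y
  p$switch <- switch_state(s_k = "closed", s_na = "closed")
  # pipette-capacitance spikes are one-sample impulses (they narrow as dt
  # does, like the physical delta); convergence is assessed with the
  # amplifier's capacitance neutralisation on
  p$compensate_pipette <- TRUE
  prot <- voltage_protocol(c(-70, 40, -70), c(10, 40, 10))
  a <- simulate_voltage_clamp(p, prot, dt_ms = 0.01)
  b <- simulate_voltage_clamp(p, prot, dt_ms = 0.005)
  common <- seq(1, length(b$current_nA), by = 2)
  rng <- diff(range(a$current_nA))
  expect_lt(max(abs(a$current_nA - b$current_nA[common])), 0.005 * rng)
})

test_that("too-coarse dt is rejected with the limiting time constant", {
  p <- circuit_parameters(r_access_Mohm = 5, c_m_pF = 30)
  expect_error(simulate_voltage_clamp(p, voltage_protocol(0, 10),
                                      dt_ms = 0.1),
               "time constant")
  expect_error(simulate_voltage_clamp(p, data.frame(level_mV = 0,
                                                    duration_ms = -5),
                                      dt_ms = 0.01), "> 0")
})

test_that("shipped presets keep the seal far above the access resistance", {
  for (p in list(shsy5y, hek293)) {
    expect_gt(p$r_seal_Mohm / p$r_access_Mohm, 100)
    expect_equal(p$e_k_mV, -90)
    expect_equal(p$e_na_mV, 60)
  }
  expect_equal(hek293$gating$na$g_max_uS, 0)
})
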