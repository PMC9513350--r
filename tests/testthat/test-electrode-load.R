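test_that("impedance magnitude matches its closed-form limits", {
  m <- interface_model(1e3, 32.7e3, 1e-12)
  # tiny capacitance: |Z| ~ Rs + Rp at bench frequencies
  expect_equal(impedance_magnitude(m, 1e3), 33.7e3, tolerance = 1e-6)
  m2 <- interface_model(1e3, 300e3, 5e-9)
  # high-frequency limit -> Rs
  expect_equal(impedance_magnitude(m2, 1e12), 1e3, tolerance = 1e-4)
  # monotonically non-increasing in frequency
  z <- impedance_magnitude(m2, 10^seq(0, 7, by = 0.25))
  expect_true(all(diff(z) <= 0))
})

test_that("fitted bench loads reproduce their 1 kHz targets", {
  m_metal <- bench_interface_model("metal")
  expect_equal(impedance_magnitude(m_metal, 1000), 33.7e3,
               tolerance = 1e-9)
  m_small <- bench_interface_model("small_tip")
  expect_equal(impedance_magnitude(m_small, 1000), 325e3,
               tolerance = 1e-9)
  # the shipped fixture file agrees with the runtime fit
  fix <- jsonlite::read_json(
    system.file("extdata", "bench_loads_synthetic.json",
                package = "icmstim"), simplifyVector = TRUE)
  expect_equal(fix$metal$c_parallel_f, m_metal$c_parallel_f,
               tolerance = 1e-9)
  expect_equal(fix$small_tip$c_parallel_f, m_small$c_parallel_f,
               tolerance = 1e-9)
})

test_that("in-compliance drive is an ideal current source", {
  m <- interface_model(1e3, 20e3, 1e-8)
  tau <- 20e3 * 1e-8  # 200 us
  wf <- rect_waveform(10, 2000, dt_us = 1)  # 10 tau, stays < 2.42 V
  res <- simulate_drive(m, wf)
  expect_equal(res$i_actual_ua, res$i_cmd_ua)
  expect_equal(nrow(res$clamped_intervals), 0)
  # steady state Vout = I (Rs + Rp)
  expect_equal(res$v_out_v[length(res$v_out_v)], 10e-6 * 21e3,
               tolerance = 1e-3)
  # actual current is load-independent in compliance
  for (rp in c(2e3, 20e3, 200e3)) {
    mi <- interface_model(1e3, rp, 1e-8)
    wfi <- rect_waveform(1, 500, dt_us = 1)
    ri <- simulate_drive(mi, wfi)
    expect_equal(ri$i_actual_ua, wfi$current_ua)
  }
})

test_that("capacitor voltage matches the closed-form RC response to <0.1%", {
  m <- interface_model(1e3, 20e3, 1e-8)
  tau_s <- 20e3 * 1e-8
  dur_us <- 500
  dt_us <- min(1, tau_s * 1e6 / 100)
  wf <- rect_waveform(10, dur_us, dt_us = dt_us)
  res <- simulate_drive(m, wf)
  t_s <- res$time_us * 1e-6
  vc_exact <- 10e-6 * 20e3 * (1 - exp(-t_s / tau_s))
  expect_lt(max(abs(res$v_cap_v - vc_exact)) / max(vc_exact), 1e-3)
  # delivered charge balances capacitor charge + resistive leakage
  q_in <- sum(res$i_actual_ua) * 1e-6 * dt_us * 1e-6
  q_cap <- 1e-8 * res$vc_final_v
  vc_nodes <- c(res$v_cap_v, res$vc_final_v)  # trapezoidal leakage integral
  q_leak <- sum((vc_nodes[-1] + vc_nodes[-length(vc_nodes)]) / 2 / 20e3) *
    dt_us * 1e-6
  expect_lt(abs(q_in - (q_cap + q_leak)) / q_in, 1e-3)
})

test_that("compliance clamping limits the current with the bench signature", {
  m <- bench_interface_model("small_tip")  # high |Z|: 325 kOhm at 1 kHz
  wf <- synthesize_pulse(pulse_spec(80, 80, 400, 400),
                         generator_settings(0), dt_us = 0.5)
  res <- simulate_drive(m, wf)
  expect_gt(nrow(res$clamped_intervals), 0)
  # current initially at command, then monotone decay while clamped
  cath <- which(res$time_us < 400)
  first_clamp <- min(which(res$clamped[cath]))
  expect_gt(first_clamp, 1)
  expect_equal(res$i_actual_ua[seq_len(first_clamp - 1)],
               res$i_cmd_ua[seq_len(first_clamp - 1)])
  clamped_run <- cath[res$clamped[cath]]
  mags <- abs(res$i_actual_ua[clamped_run])
  expect_true(all(diff(mags) <= 1e-12))
  # clamped output sits on the rail; the rail is never exceeded
  expect_equal(max(abs(res$v_out_v[res$clamped])), 2.42)
  expect_lte(max(abs(res$v_out_v)), 2.42 + 1e-3)
  # while clamped the actual current follows the analytic RC discharge
  # of the clamp circuit: Vc relaxes toward VL*Rp/(Rs+Rp) with
  # tau = Cp*Rs*Rp/(Rs+Rp)
  rs <- m$r_series_ohm; rp <- m$r_parallel_ohm; cp <- m$c_parallel_f
  k0 <- clamped_run[1]
  vc0 <- res$v_cap_v[k0]
  vinf <- -2.42 * rp / (rs + rp)
  tau <- cp * rs * rp / (rs + rp)
  t_rel <- (res$time_us[clamped_run] - res$time_us[k0]) * 1e-6
  vc_exact <- vinf + (vc0 - vinf) * exp(-t_rel / tau)
  i_exact <- (-2.42 - vc_exact) / rs * 1e6
  expect_lt(max(abs(res$i_actual_ua[clamped_run] - i_exact)) /
              max(abs(i_exact)), 1e-3)
})

test_that("inrush peak follows Ohm's law and vanishes with suppression", {
  m <- interface_model(1e3, 100e3, 1e-9)
  expect_equal(inrush_peak(m, 0, FALSE), 0)
  expect_equal(inrush_peak(m, 0.1, FALSE), 100)
  expect_equal(inrush_peak(m, 0.5, TRUE), 0)
})

test_that("shorting to reference discharges the interface", {
  m <- interface_model(1e3, 100e3, 1e-8)  # Rs*Cp = 10 us
  expect_equal(short_to_reference(m, 0.5, 0), 0.5)
  expect_lt(short_to_reference(m, 0.5, 50) / 0.5, 0.007)  # 5 tau

  # pulse train with a forced 1-LSB imbalance: Vc accumulates without
  # shorting, stays bounded with per-pulse shorting
  s <- generator_settings(0)
  res_lsb <- amplitude_resolution(s)
  wf <- synthesize_pulse(pulse_spec(30, 30 + res_lsb, 100, 100), s,
                         dt_us = 0.5)
  n_pulses <- 12
  vc_free <- numeric(n_pulses)
  vc_short <- numeric(n_pulses)
  v1 <- 0; v2 <- 0
  for (p in seq_len(n_pulses)) {
    v1 <- simulate_drive(m, wf, vc0 = v1)$vc_final_v
    vc_free[p] <- v1
    v2 <- simulate_drive(m, wf, vc0 = v2)$vc_final_v
    v2 <- short_to_reference(m, v2, 100)  # 10 tau short between pulses
    vc_short[p] <- v2
  }
  expect_true(all(diff(vc_free) > 0))
  expect_lt(max(abs(vc_short)), abs(vc_free[n_pulses]))
  expect_lt(max(abs(diff(vc_short[-(1:2)]))), 1e-6)
})

test_that("drive results and interface models survive file I/O", {
  m <- bench_interface_model("metal")
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(r_series_ohm = m$r_series_ohm, r_parallel_ohm = m$r_parallel_ohm,
         c_parallel_f = m$c_parallel_f, v_limit_v = m$v_limit_v),
    jpath, auto_unbox = TRUE, digits = NA)
  m2 <- read_interface_json(jpath)
  expect_equal(m2$c_parallel_f, m$c_parallel_f)

  res <- simulate_drive(m, rect_waveform(10, 100, 1))
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_drive_csv(res, cpath)
  back <- utils::read.csv(cpath)
  expect_equal(back$i_actual_uA, res$i_actual_ua)
  expect_equal(back$v_out_V, res$v_out_v)
})
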