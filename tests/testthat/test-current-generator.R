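test_that("DAC resolution is full scale over 2^6 for every range", {
  expect_equal(amplitude_resolution(generator_settings(0)), 1.5625)
  expect_equal(amplitude_resolution(generator_settings(3)), 6.25)
  # resolution scales linearly with full scale
  r <- vapply(0:3, function(code)
    amplitude_resolution(generator_settings(code)), 0)
  expect_equal(r / r[1], 1:4)
})

test_that("quantizer rounds to nearest code and saturates at 63", {
  s <- generator_settings(0)
  expect_equal(quantize_amplitude(0, s), list(code = 0L, amplitude_ua = 0))
  q <- quantize_amplitude(30, s)
  expect_equal(q$code, 19L)
  expect_equal(q$amplitude_ua, 29.6875)
  q <- quantize_amplitude(100, s)
  expect_equal(q$code, 63L)
  expect_equal(q$amplitude_ua, 98.4375)
  expect_error(quantize_amplitude(101, s), "full scale")
  expect_error(quantize_amplitude(-1, s), "full scale")
})

test_that("quantization error is at most half a DAC step below saturation", {
  for (code in 0:3) {
    s <- generator_settings(code)
    res <- amplitude_resolution(s)
    cmds <- seq(0, 63.5 * res, length.out = 401)
    err <- vapply(cmds, function(a)
      abs(quantize_amplitude(a, s)$amplitude_ua - a), 0)
    expect_lte(max(err), res / 2 + 1e-12)
  }
})

test_that("pulse synthesis applies quantization and pulse-width trim", {
  s <- generator_settings(0)
  wf <- synthesize_pulse(pulse_spec(30, 30, 200, 200), s)
  ch <- phase_charge(wf)
  expect_equal(unname(ch["cathodic_pc"]), unname(ch["anodic_pc"]))
  expect_equal(max(wf$current_ua), 29.6875)
  expect_equal(min(wf$current_ua), -29.6875)

  # trim -1: anodic (second) phase shortened by 1.95 us
  wf1 <- synthesize_pulse(pulse_spec(30, 30, 200, 200,
                                     pw_adjust_code = -1), s)
  expect_equal(pulse_duration(wf1), 200 + 198.05)
  expect_equal(unname(phase_charge(wf1)["anodic_pc"]), 29.6875 * 198.05)

  # trim +8: second phase lengthened by 15.6 us
  wf8 <- synthesize_pulse(pulse_spec(30, 30, 200, 200,
                                     pw_adjust_code = 8), s)
  expect_equal(pulse_duration(wf8), 200 + 215.6)

  # an over-trimmed short phase is rejected
  expect_error(
    synthesize_pulse(pulse_spec(30, 30, 10, 10, pw_adjust_code = -7), s),
    "second-phase duration")
})

test_that("phase charges integrate exactly", {
  wf <- rect_waveform(30, 200, dt_us = 0.1)
  expect_equal(unname(phase_charge(wf)["anodic_pc"]), 6000)
  s <- generator_settings(0)
  wf <- synthesize_pulse(pulse_spec(30, 30, 200, 200), s)
  expect_equal(unname(phase_charge(wf)["cathodic_pc"]), 5937.5)
  zero <- rect_waveform(1e-9, 10)
  zero$current_ua[] <- 0
  expect_equal(unname(phase_charge(zero)), c(0, 0))
  expect_equal(charge_imbalance(zero), 0)
})

test_that("worst-case quantization imbalance at 0.1 ms/phase is 156.25 pC", {
  s <- generator_settings(0)
  res <- amplitude_resolution(s)
  # symmetric quantized pulse balances to the grid
  expect_equal(
    charge_imbalance(synthesize_pulse(pulse_spec(30, 30, 100, 100), s)),
    0, tolerance = 1e-6)
  # a single-LSB amplitude mismatch over 100 us
  expect_equal(
    charge_imbalance(synthesize_pulse(
      pulse_spec(30, 30 + res, 100, 100), s)),
    res * 100)
  # brute force over all code pairs differing by at most one LSB
  worst <- 0
  for (cc in 0:63) {
    for (ac in intersect((cc - 1):(cc + 1), 0:63)) {
      wf <- synthesize_pulse(
        pulse_spec(cc * res, ac * res, 100, 100), s)
      worst <- max(worst, abs(charge_imbalance(wf)))
    }
  }
  expect_equal(worst, 156.25)
})

test_that("pulse-width optimizer never exceeds the unadjusted imbalance", {
  s <- generator_settings(0)
  res <- amplitude_resolution(s)

  # already balanced -> code 0, zero residual
  bal <- optimize_pw_adjust(pulse_spec(30, 30, 200, 200), s)
  expect_equal(bal$best_code, 0)
  expect_equal(bal$residual_pc, 0, tolerance = 1e-6)

  # anodic 1 LSB high -> shorten the anodic (second) phase
  sp <- pulse_spec(30, 30 + res, 200, 200)
  opt <- optimize_pw_adjust(sp, s)
  expect_lt(opt$best_code, 0)
  step_charge <- (19 + 1) * res * 1.95  # one trim step at the anodic amp
  expect_lt(abs(opt$residual_pc), step_charge)

  # definition: the chosen code beats every one of the 16 codes, checked
  # against an independent analytic oracle for the net charge
  withr::with_seed(5, {
    for (rep in 1:20) {
      camp <- runif(1, 5, 95)
      aamp <- runif(1, 5, 95)
      d <- runif(1, 50, 300)
      sp <- pulse_spec(camp, aamp, d, d)
      opt <- optimize_pw_adjust(sp, s)
      qa <- quantize_amplitude(aamp, s)$amplitude_ua
      qc <- quantize_amplitude(camp, s)$amplitude_ua
      oracle <- vapply(-7:8, function(code)
        qa * (d + code * 1.95) - qc * d, 0)
      expect_equal(unname(opt$imbalance_pc), oracle, tolerance = 1e-6)
      expect_lte(abs(opt$residual_pc), min(abs(oracle)) + 1e-6)
      expect_lte(abs(opt$residual_pc),
                 abs(opt$imbalance_pc[["0"]]) + 1e-6)
    }
  })
})

test_that("waveform CSV roundtrips", {
  wf <- synthesize_pulse(pulse_spec(30, 30, 50, 50), dt_us = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(wf, path)
  back <- read_waveform_csv(path)
  expect_equal(back$current_ua, wf$current_ua)
  expect_equal(back$dt_us, wf$dt_us)
})
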