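test_that("the threshold-shifted Hill curve has its stated landmarks", {
  p <- hill_params(0.9, 2.4, 2.5)
  expect_equal(hill_response(0.9, p), 0)
  expect_equal(hill_response(0.5, p), 0)
  expect_equal(hill_response(2.4, p), 0.5)
  # independent direct evaluation of the formula at q = 4
  oracle <- (4 - 0.9)^2.5 / ((4 - 0.9)^2.5 + (2.4 - 0.9)^2.5)
  expect_equal(hill_response(4, p), oracle)
  # continuous at threshold, strictly increasing above it, within [0, 1)
  q <- seq(0, 20, by = 0.01)
  r <- hill_response(q, p)
  expect_lt(hill_response(0.9 + 1e-9, p), 1e-6)
  expect_true(all(diff(r[q > 0.9]) > 0))
  expect_true(all(r >= 0 & r < 1))
  expect_error(hill_params(2.4, 0.9), "i_th")
})

test_that("noiseless dose-response points are recovered to machine level", {
  truth <- hill_params(0.9, 2.4, 2.5)
  tab <- synth_dose_response(params = truth)
  expect_equal(nrow(tab), 8)
  fit <- fit_hill(tab$charge_nc, tab$response_norm)
  expect_lt(abs(fit$params$i_th_nc - 0.9) / 0.9, 1e-6)
  expect_lt(abs(fit$params$i_50_nc - 2.4) / 2.4, 1e-6)
  expect_lt(abs(fit$params$n - 2.5) / 2.5, 1e-6)
})

test_that("degenerate dose-response data signal a fit failure", {
  expect_error(fit_hill(1:8, rep(0, 8)), class = "icmstim_fit_error")
  expect_error(fit_hill(1:8, rep(0.7, 8)), class = "icmstim_fit_error")
  expect_error(fit_hill(1:4, c(0, 0.1, 0.5, 0.9)), "at least 5")
})

test_that("noisy fits recover the half-max charge within tolerance", {
  truth <- hill_params(0.9, 2.4, 2.5)
  clean <- synth_dose_response(params = truth)
  withr::with_seed(101, {
    rel_err <- replicate(50, {
      resp <- clean$response_norm + rnorm(8, 0, 0.05)
      fit <- fit_hill(clean$charge_nc, resp)
      (fit$params$i_50_nc - 2.4) / 2.4
    })
  })
  expect_lt(stats::median(abs(rel_err)), 0.10)
})

test_that("the VSD movie generator is deterministic and zero-mean at rest", {
  el <- data.frame(x_mm = 3, y_mm = 3, charge_nc = 0, onset_ms = 10)
  m1 <- synth_vsd_movie(el, n_frames = 40, noise_sd = 0.02, seed = 99)
  m2 <- synth_vsd_movie(el, n_frames = 40, noise_sd = 0.02, seed = 99)
  expect_identical(m1$frames, m2$frames)
  # zero charge -> pure noise; ROI mean within 3 SEM of zero
  tr <- peak_amplitude(m1, roi_around(3, 3, 0.5))$trace
  n_roi_px <- (2 * 0.5 / m1$pixel_pitch_mm)^2
  sem <- 0.02 / sqrt(n_roi_px * length(tr))
  expect_lt(abs(mean(tr)), 3 * sem)
  # trial averaging shrinks the noise
  m16 <- synth_vsd_movie(el, n_frames = 40, noise_sd = 0.02, seed = 99,
                         n_trials = 16)
  expect_lt(stats::sd(m16$frames), stats::sd(m1$frames))
})

test_that("single-site movies peak at t_peak with Hill-scaled amplitude", {
  kin <- response_kinetics()
  charges <- c(1.5, 2.4, 4, 6)
  peaks <- vapply(charges, function(q) {
    el <- data.frame(x_mm = 3.1, y_mm = 3.1, charge_nc = q, onset_ms = 5)
    m <- synth_vsd_movie(el, kinetics = kin, n_frames = 160)
    pk <- peak_amplitude(m, roi_around(3.1, 3.1, 0.05))
    expect_equal(pk$t_peak_ms - 5, kin$t_peak_ms)
    pk$peak
  }, 0)
  # amplitude proportional to the Hill response across the charge series
  expect_equal(stats::cor(peaks, hill_response(charges)), 1,
               tolerance = 1e-6)
  # the undershoot bottoms out near its nominal time
  el <- data.frame(x_mm = 3.1, y_mm = 3.1, charge_nc = 4, onset_ms = 5)
  m <- synth_vsd_movie(el, kinetics = kin, n_frames = 160)
  tr <- peak_amplitude(m, roi_around(3.1, 3.1, 0.05))$trace
  expect_equal(which.min(tr) - 1 - 5, kin$undershoot_time_ms,
               tolerance = 0.05)
  expect_lt(min(tr), 0)
})

test_that("electrode pairs resolve into two foci at 0.6 mm but not 0.3 mm", {
  two <- function(sep_mm) {
    data.frame(x_mm = c(3 - sep_mm / 2, 3 + sep_mm / 2) + 0.01,
               y_mm = 3, charge_nc = 4, onset_ms = 0)
  }
  m_far <- synth_vsd_movie(two(0.6), n_frames = 10)
  expect_equal(count_activation_foci(m_far, 3), 2)
  m_near <- synth_vsd_movie(two(0.3), n_frames = 10)
  expect_equal(count_activation_foci(m_near, 3), 1)
})

test_that("sequential pulses inside the inhibition window are attenuated", {
  kin <- response_kinetics()  # gain 0.5 per predecessor within 20 ms
  seq3 <- data.frame(x_mm = c(2.5, 3.0, 3.5), y_mm = 3,
                     charge_nc = 4, onset_ms = c(10, 30, 50))
  m123 <- synth_vsd_movie(seq3, kinetics = kin, n_frames = 120)
  expect_equal(m123$gains, c(1, 0.5, 0.25))
  # pulse 3's own contribution (movie difference, generator is additive)
  m12 <- synth_vsd_movie(seq3[1:2, ], kinetics = kin, n_frames = 120)
  d3 <- max(m123$frames - m12$frames)
  m1 <- synth_vsd_movie(seq3[1, ], kinetics = kin, n_frames = 120)
  d1 <- max(m1$frames)
  expect_equal(d3 / d1, kin$inhibition_gain^2, tolerance = 1e-6)
  # pulses separated by more than the window reset to full gain
  spaced <- transform(seq3, onset_ms = c(10, 45, 80))
  expect_equal(synth_vsd_movie(spaced, n_frames = 5)$gains, c(1, 1, 1))
})

test_that("line profiles are unimodal for one source, bimodal for a pair", {
  one <- data.frame(x_mm = 3.1, y_mm = 3, charge_nc = 4, onset_ms = 0)
  m <- synth_vsd_movie(one, n_frames = 10)
  pr <- line_profile(m, c(1, 3), c(5, 3), window_ms = c(3, 4), n = 201)
  k <- which.max(pr$dff)
  expect_equal(pr$x_mm[k], 3.1, tolerance = 0.03)
  expect_true(all(diff(pr$dff[1:k]) >= 0))
  expect_true(all(diff(pr$dff[k:length(pr$dff)]) <= 0))

  pair <- data.frame(x_mm = c(2.71, 3.31), y_mm = 3, charge_nc = 4,
                     onset_ms = 0)
  m2 <- synth_vsd_movie(pair, n_frames = 10)
  pr2 <- line_profile(m2, c(1, 3), c(5, 3), window_ms = c(3, 4), n = 201)
  inner <- pr2$dff[2:(length(pr2$dff) - 1)]
  n_max <- sum(inner > pr2$dff[1:(length(pr2$dff) - 2)] &
                 inner > pr2$dff[3:length(pr2$dff)])
  expect_equal(n_max, 2)

  # profile integral scales with the Hill response
  ints <- vapply(c(2.4, 6), function(q) {
    mq <- synth_vsd_movie(transform(one, charge_nc = q), n_frames = 10)
    sum(line_profile(mq, c(1, 3), c(5, 3), window_ms = c(3, 4))$dff)
  }, 0)
  expect_equal(ints[1] / ints[2],
               hill_response(2.4) / hill_response(6), tolerance = 1e-6)
})

test_that("dose-response tables and movies survive file I/O", {
  tab <- synth_dose_response()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_response_csv(tab, path)
  back <- read_dose_response_csv(path)
  expect_equal(back$charge_nc, tab$charge_nc)
  expect_equal(back$response_norm, tab$response_norm)

  el <- data.frame(x_mm = 3, y_mm = 3, charge_nc = 4, onset_ms = 2)
  m <- synth_vsd_movie(el, n_frames = 8, n_px = 20, field_mm = 6.25)
  dir <- withr::local_tempdir()
  write_vsd_movie(m, dir)
  back <- read_vsd_movie(dir)
  expect_equal(back$frames, m$frames, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$pixel_pitch_mm, m$pixel_pitch_mm)
})
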