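# One 8-channel current generator: 6-bit DAC quantization, biphasic pulse
# synthesis with 4-bit pulse-width trimming of the second phase, and
# charge/imbalance accounting.  Units: current in uA, time in us, so
# integrated charge comes out in pC (uA x us).

#' Current-generator settings
#'
#' The maximum output range is selectable in four ~100 uA steps; the 6-bit
#' DAC then resolves the selected full scale into 64 amplitude codes.
#' Optional per-polarity gain factors model the fabrication mismatch
#' between anodic and cathodic mirrors (unity by default, i.e. an ideal
#' generator).
#'
#' @param max_range_code Range code 0..3; full scale = 100 * (code + 1) uA.
#' @param pw_step_us Pulse-width adjustment step, default 1.95 us.
#' @param anodic_gain,cathodic_gain Per-polarity amplitude gain factors.
#' @return An object of class `"generator_settings"` with `full_scale_ua`
#'   and `resolution_ua` derived from the range code.
#' @examples
#' generator_settings(0)$resolution_ua  # 1.5625
#' @export
generator_settings <- function(max_range_code = 0, pw_step_us = 1.95,
                               anodic_gain = 1, cathodic_gain = 1) {
  max_range_code <- as.integer(max_range_code)
  if (max_range_code < 0L || max_range_code > 3L)
    stop("'max_range_code' must be in 0..3")
  full_scale <- 100 * (max_range_code + 1)
  structure(
    list(max_range_code = max_range_code,
         full_scale_ua = full_scale,
         resolution_ua = full_scale / 2^6,
         pw_step_us = pw_step_us,
         anodic_gain = anodic_gain,
         cathodic_gain = cathodic_gain),
    class = "generator_settings"
  )
}

#' Amplitude resolution of the 6-bit DAC
#'
#' @param settings A [generator_settings()].
#' @return One DAC step in uA: full scale divided by 2^6 (1.5625 uA at the
#'   +/-100 uA range).
#' @export
amplitude_resolution <- function(settings = generator_settings()) {
  settings$full_scale_ua / 2^6
}

#' Quantize a commanded amplitude to a 6-bit DAC code
#'
#' Rounds to the nearest code, ties toward zero; codes saturate at 63, so
#' commands at the very top of the range land on 63 * resolution.
#'
#' @param cmd_amp_ua Commanded amplitude magnitude, 0..full scale, in uA.
#' @param settings A [generator_settings()].
#' @return List with `code` (integer 0..63) and `amplitude_ua`
#'   (= code * resolution).
#' @examples
#' quantize_amplitude(30, generator_settings(0))  # code 19, 29.6875 uA
#' @export
quantize_amplitude <- function(cmd_amp_ua, settings = generator_settings()) {
  if (cmd_amp_ua < 0 || cmd_amp_ua > settings$full_scale_ua)
    stop("'cmd_amp_ua' must be within 0..full scale")
  res <- settings$resolution_ua
  code <- as.integer(min(63, max(0, ceiling(cmd_amp_ua / res - 0.5))))
  list(code = code, amplitude_ua = code * res)
}

#' Specify a biphasic stimulus pulse
#'
#' @param cathodic_amp_ua,anodic_amp_ua Commanded phase amplitude
#'   magnitudes in uA (quantized by the DAC at synthesis time).
#' @param cathodic_dur_us,anodic_dur_us Nominal phase durations in us.
#' @param interphase_gap_us Zero-current gap between the phases, us.
#' @param order Which phase comes first.
#' @param pw_adjust_code 4-bit signed trim code -7..+8; the second phase's
#'   duration is lengthened by `code * pw_step_us`.
#' @return An object of class `"pulse_spec"`.
#' @export
pulse_spec <- function(cathodic_amp_ua, anodic_amp_ua,
                       cathodic_dur_us, anodic_dur_us,
                       interphase_gap_us = 0,
                       order = c("cathodic_first", "anodic_first"),
                       pw_adjust_code = 0) {
  order <- match.arg(order)
  pw_adjust_code <- as.integer(pw_adjust_code)
  if (cathodic_amp_ua < 0 || anodic_amp_ua < 0)
    stop("amplitudes are magnitudes and must be >= 0")
  if (cathodic_dur_us <= 0 || anodic_dur_us <= 0)
    stop("phase durations must be > 0")
  if (interphase_gap_us < 0) stop("'interphase_gap_us' must be >= 0")
  if (pw_adjust_code < -7L || pw_adjust_code > 8L)
    stop("'pw_adjust_code' must be in -7..+8")
  structure(
    list(cathodic_amp_ua = cathodic_amp_ua, anodic_amp_ua = anodic_amp_ua,
         cathodic_dur_us = cathodic_dur_us, anodic_dur_us = anodic_dur_us,
         interphase_gap_us = interphase_gap_us, order = order,
         pw_adjust_code = pw_adjust_code),
    class = "pulse_spec"
  )
}

.new_waveform <- function(time_us, current_ua, dt_us, bounds, spec = NULL,
                          settings = NULL) {
  structure(
    list(time_us = time_us, current_ua = current_ua, dt_us = dt_us,
         phase_bounds_us = bounds, spec = spec, settings = settings),
    class = "current_waveform"
  )
}

#' @export
print.current_waveform <- function(x, ...) {
  cat(sprintf("<current_waveform> %d samples, dt=%g us, %.4g us total\n",
              length(x$current_ua), x$dt_us, pulse_duration(x)))
  invisible(x)
}

#' Total duration of a waveform's pulse in us
#'
#' @param waveform A `"current_waveform"`.
#' @return Duration from pulse start to the end of the last phase, us.
#' @export
pulse_duration <- function(waveform) {
  b <- waveform$phase_bounds_us
  b[length(b)]
}

# Area-preserving sampler: sample k holds the mean current over
# [k*dt, (k+1)*dt), so the rectangular integral of the sampled trace is
# exact for piecewise-constant pulses even when phase boundaries fall
# between grid points.  Only boundary-straddling samples take fractional
# values; all others sit at the quantized phase amplitudes.
.sample_segments <- function(amps, durs, dt_us) {
  keep <- durs > 0
  amps <- amps[keep]
  durs <- durs[keep]
  bounds <- cumsum(c(0, durs))
  total <- bounds[length(bounds)]
  n <- as.integer(ceiling(total / dt_us - 1e-9))
  t0 <- (seq_len(n) - 1) * dt_us
  t1 <- t0 + dt_us
  cur <- numeric(n)
  for (j in seq_along(durs)) {
    if (amps[j] == 0) next
    ov <- pmax(0, pmin(t1, bounds[j + 1]) - pmax(t0, bounds[j]))
    cur <- cur + amps[j] * ov / dt_us
  }
  list(time_us = t0, current_ua = cur, bounds = bounds)
}

#' Synthesize the current waveform of a biphasic pulse
#'
#' Both phase amplitudes are quantized by the 6-bit DAC; the second phase's
#' duration is trimmed by `pw_adjust_code * pw_step_us`.  Cathodic samples
#' are negative, anodic positive.  Rise and fall are instantaneous (the
#' silicon's <= 5 us rise is not modelled).
#'
#' @param spec A [pulse_spec()].
#' @param settings A [generator_settings()].
#' @param dt_us Sample step, us; must be <= 1 so the 1.95 us trim step is
#'   resolved.  Default 0.1 us (>= 19 samples per trim step).
#' @return A `"current_waveform"` with uniform sample grid; samples are
#'   per-interval means, so `sum(current) * dt` integrates the pulse
#'   exactly.
#' @examples
#' wf <- synthesize_pulse(pulse_spec(30, 30, 200, 200), generator_settings())
#' charge_imbalance(wf)  # 0
#' @export
synthesize_pulse <- function(spec, settings = generator_settings(),
                             dt_us = 0.1) {
  stopifnot(inherits(spec, "pulse_spec"))
  if (dt_us <= 0 || dt_us > 1)
    stop("'dt_us' must be in (0, 1]")
  qc <- quantize_amplitude(spec$cathodic_amp_ua, settings)
  qa <- quantize_amplitude(spec$anodic_amp_ua, settings)
  c_amp <- -qc$amplitude_ua * settings$cathodic_gain
  a_amp <- qa$amplitude_ua * settings$anodic_gain
  adj <- spec$pw_adjust_code * settings$pw_step_us
  if (spec$order == "cathodic_first") {
    amps <- c(c_amp, 0, a_amp)
    durs <- c(spec$cathodic_dur_us, spec$interphase_gap_us,
              spec$anodic_dur_us + adj)
  } else {
    amps <- c(a_amp, 0, c_amp)
    durs <- c(spec$anodic_dur_us, spec$interphase_gap_us,
              spec$cathodic_dur_us + adj)
  }
  if (durs[3] <= 0)
    stop("adjusted second-phase duration must remain > 0")
  s <- .sample_segments(amps, durs, dt_us)
  .new_waveform(s$time_us, s$current_ua, dt_us, s$bounds, spec, settings)
}

#' Rectangular (monophasic) current waveform
#'
#' Convenience constructor for single-phase drives such as the LED test
#' pulse of the dynamic-operation demo.
#'
#' @param amp_ua Amplitude in uA (signed).
#' @param dur_us Duration in us.
#' @param dt_us Sample step in us.
#' @return A `"current_waveform"`.
#' @export
rect_waveform <- function(amp_ua, dur_us, dt_us = 1) {
  if (dur_us <= 0) stop("'dur_us' must be > 0")
  s <- .sample_segments(amp_ua, dur_us, dt_us)
  .new_waveform(s$time_us, s$current_ua, dt_us, s$bounds)
}

#' Charge delivered in each phase
#'
#' Rectangular time-integral of the sampled current, sign-separated:
#' negative samples count toward the cathodic phase, positive toward the
#' anodic.  Exact for synthesized pulses (see [synthesize_pulse()]).
#'
#' @param waveform A `"current_waveform"`.
#' @return Named vector `c(cathodic_pc = , anodic_pc = )`, both as positive
#'   magnitudes in pC.
#' @export
phase_charge <- function(waveform) {
  cur <- waveform$current_ua
  c(cathodic_pc = -sum(cur[cur < 0]) * waveform$dt_us,
    anodic_pc = sum(cur[cur > 0]) * waveform$dt_us)
}

#' Net charge imbalance of a pulse
#'
#' Time integral of the current over the whole pulse window (anodic charge
#' plus signed cathodic charge).  Zero for a perfectly balanced pulse;
#' bounded by one DAC step times the phase duration when only amplitude
#' quantization mismatches the phases.
#'
#' @param waveform A `"current_waveform"`.
#' @return Net charge in pC (positive = anodic excess).
#' @export
charge_imbalance <- function(waveform) {
  sum(waveform$current_ua) * waveform$dt_us
}

#' Choose the pulse-width trim code that minimizes charge imbalance
#'
#' Exhaustively evaluates all 16 trim codes (-7..+8) of the second phase
#' and returns the one with the smallest absolute net charge.  Ties are
#' broken toward code 0 (smallest |code|, then the negative one).
#'
#' @param spec A [pulse_spec()]; its own `pw_adjust_code` is ignored.
#' @param settings A [generator_settings()].
#' @param dt_us Sample step for the evaluation, us.
#' @return List with `best_code`, `residual_pc` and the named vector
#'   `imbalance_pc` over all 16 codes.
#' @export
optimize_pw_adjust <- function(spec, settings = generator_settings(),
                               dt_us = 0.1) {
  codes <- -7:8
  codes <- codes[order(abs(codes), codes)]
  imb <- vapply(codes, function(code) {
    s <- spec
    s$pw_adjust_code <- code
    charge_imbalance(synthesize_pulse(s, settings, dt_us))
  }, 0)
  names(imb) <- codes
  best <- which.min(abs(imb))
  list(best_code = codes[best], residual_pc = imb[[best]],
       imbalance_pc = imb[as.character(sort(codes))])
}

#' Write a current waveform to CSV
#'
#' Columns `time_us`, `current_uA`.
#'
#' @param waveform A `"current_waveform"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(
    data.frame(time_us = waveform$time_us,
               current_uA = waveform$current_ua),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a current waveform from CSV
#'
#' @param path File with columns `time_us`, `current_uA` on a uniform grid.
#' @return A `"current_waveform"`.
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_us", "current_uA") %in% names(d)))
    stop("waveform CSV needs columns time_us, current_uA")
  dt <- if (nrow(d) > 1) d$time_us[2] - d$time_us[1] else 1
  .new_waveform(d$time_us, d$current_uA, dt,
                c(0, d$time_us[nrow(d)] + dt))
}
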