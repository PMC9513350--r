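# Electrical model of the electrode-electrolyte interface: a series access
# resistor Rs feeding a parallel RC (Rp || Cp), driven by the current
# generator.  The generator behaves as an ideal current source while its
# output voltage stays inside the +/-2.42 V compliance window and clamps
# to the rail outside it.  The system is piecewise linear, so each sample
# step is advanced with the exact exponential solution (no Euler drift).

#' Interface model of an electrode load
#'
#' @param r_series_ohm Series (access/saline) resistance, Ohm.
#' @param r_parallel_ohm Interface charge-transfer resistance, Ohm.
#' @param c_parallel_f Interface capacitance, F.
#' @param v_limit_v Compliance limit of the current generator, V.
#' @return An object of class `"interface_model"`.
#' @export
interface_model <- function(r_series_ohm, r_parallel_ohm, c_parallel_f,
                            v_limit_v = 2.42) {
  if (r_series_ohm <= 0 || r_parallel_ohm <= 0 || c_parallel_f <= 0 ||
      v_limit_v <= 0)
    stop("all interface model parameters must be positive")
  structure(
    list(r_series_ohm = r_series_ohm, r_parallel_ohm = r_parallel_ohm,
         c_parallel_f = c_parallel_f, v_limit_v = v_limit_v),
    class = "interface_model"
  )
}

#' @export
print.interface_model <- function(x, ...) {
  cat(sprintf(
    "<interface_model> Rs=%.3g Ohm, Rp=%.3g Ohm, Cp=%.3g F, |Z|(1 kHz)=%.4g Ohm\n",
    x$r_series_ohm, x$r_parallel_ohm, x$c_parallel_f,
    impedance_magnitude(x, 1000)))
  invisible(x)
}

#' Impedance magnitude of the interface model
#'
#' @param model An [interface_model()].
#' @param f_hz Frequency in Hz (vectorized), >= 0.
#' @return `|Rs + Rp / (1 + i 2 pi f Rp Cp)|` in Ohm; monotonically
#'   non-increasing in frequency, from Rs + Rp at DC to Rs at high f.
#' @export
impedance_magnitude <- function(model, f_hz) {
  if (any(f_hz < 0)) stop("'f_hz' must be >= 0")
  rp <- model$r_parallel_ohm
  Mod(model$r_series_ohm +
        rp / (1 + 1i * 2 * pi * f_hz * rp * model$c_parallel_f))
}

#' Fit an interface model to an impedance magnitude at one frequency
#'
#' Bench electrode models are usually specified only by their impedance
#' magnitude at 1 kHz.  One magnitude cannot pin down both Rp and Cp, so
#' Rp is set to `rp_factor` times the target magnitude (the interface's
#' charge-transfer resistance dominates at DC) and Cp is solved by
#' root-finding so that `impedance_magnitude(model, f_hz)` reproduces the
#' target exactly.
#'
#' @param z_mag_ohm Target impedance magnitude, Ohm.
#' @param f_hz Frequency at which the magnitude is specified, Hz.
#' @param r_series_ohm Series resistance, Ohm.
#' @param rp_factor Ratio Rp / z_mag_ohm (> 1).
#' @param v_limit_v Compliance limit, V.
#' @return An [interface_model()] with
#'   `impedance_magnitude(model, f_hz) == z_mag_ohm` to root-finder
#'   precision.
#' @examples
#' m <- fit_interface_model(33.7e3)
#' impedance_magnitude(m, 1000)  # 33700
#' @export
fit_interface_model <- function(z_mag_ohm, f_hz = 1000,
                                r_series_ohm = 1000, rp_factor = 10,
                                v_limit_v = 2.42) {
  if (z_mag_ohm <= r_series_ohm)
    stop("'z_mag_ohm' must exceed the series resistance")
  rp <- rp_factor * z_mag_ohm
  obj <- function(log10_cp) {
    m <- interface_model(r_series_ohm, rp, 10^log10_cp, v_limit_v)
    impedance_magnitude(m, f_hz) - z_mag_ohm
  }
  root <- stats::uniroot(obj, c(-13, -2), tol = 1e-12)
  interface_model(r_series_ohm, rp, 10^root$root, v_limit_v)
}

#' Bench electrode load models
#'
#' The two dry-bench fixture circuits: one mimicking a metal microelectrode
#' usable for intracortical stimulation (|Z| = 33.7 kOhm at 1 kHz) and one
#' mimicking a similar electrode with much smaller surface area (325 kOhm
#' at 1 kHz), both behind a 1 kOhm series resistor.  Component values are
#' fitted (see [fit_interface_model()]); the same values are shipped in
#' `inst/extdata/bench_loads_synthetic.json`.
#'
#' @param which `"metal"` or `"small_tip"`.
#' @return An [interface_model()].
#' @export
bench_interface_model <- function(which = c("metal", "small_tip")) {
  which <- match.arg(which)
  target <- c(metal = 33.7e3, small_tip = 325e3)[[which]]
  fit_interface_model(target)
}

#' Simulate driving an electrode load with a commanded current
#'
#' In-compliance steps integrate the capacitor exactly:
#' `Vc -> I Rp + (Vc - I Rp) exp(-dt / Rp Cp)` with `Vout = I Rs + Vc`.
#' When the commanded current would push `|Vout|` past the compliance
#' limit, the output clamps to the rail: `Vout = +/- v_limit`,
#' `I_actual = (+/- v_limit - Vc) / Rs`, and the capacitor relaxes toward
#' `v_limit Rp / (Rs + Rp)` with time constant `Cp Rs Rp / (Rs + Rp)`.
#' Source mode is re-entered as soon as the command is feasible again.
#'
#' @param model An [interface_model()].
#' @param commanded A `"current_waveform"` (uniform grid).
#' @param vc0 Initial capacitor voltage, V.
#' @return An object of class `"drive_result"`: `time_us`, `i_cmd_ua`,
#'   `i_actual_ua`, `v_out_v`, `v_cap_v`, `clamped` (logical per sample),
#'   `clamped_intervals` (data frame of start/end us) and `vc_final_v`.
#' @export
simulate_drive <- function(model, commanded, vc0 = 0) {
  stopifnot(inherits(model, "interface_model"),
            inherits(commanded, "current_waveform"))
  dt <- commanded$dt_us * 1e-6
  if (dt <= 0) stop("'dt' must be > 0")
  i_cmd <- commanded$current_ua * 1e-6
  n <- length(i_cmd)
  rs <- model$r_series_ohm
  rp <- model$r_parallel_ohm
  cp <- model$c_parallel_f
  vl <- model$v_limit_v
  e_src <- exp(-dt / (rp * cp))
  e_clamp <- exp(-dt * (rs + rp) / (cp * rs * rp))
  vcap <- numeric(n)
  vout <- numeric(n)
  iact <- numeric(n)
  clamped <- logical(n)
  v <- vc0
  for (k in seq_len(n)) {
    I <- i_cmd[k]
    vo <- I * rs + v
    vcap[k] <- v
    if (abs(vo) <= vl) {
      iact[k] <- I
      vout[k] <- vo
      v <- I * rp + (v - I * rp) * e_src
    } else {
      s <- sign(vo)
      clamped[k] <- TRUE
      vout[k] <- s * vl
      iact[k] <- (s * vl - v) / rs
      vinf <- s * vl * rp / (rs + rp)
      v <- vinf + (v - vinf) * e_clamp
    }
  }
  runs <- rle(clamped)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ci <- data.frame(
    start_us = commanded$time_us[starts[runs$values]],
    end_us = commanded$time_us[ends[runs$values]] + commanded$dt_us)
  structure(
    list(time_us = commanded$time_us, i_cmd_ua = commanded$current_ua,
         i_actual_ua = iact * 1e6, v_out_v = vout, v_cap_v = vcap,
         clamped = clamped, clamped_intervals = ci, vc_final_v = v,
         model = model, dt_us = commanded$dt_us),
    class = "drive_result"
  )
}

#' @export
print.drive_result <- function(x, ...) {
  cat(sprintf(
    "<drive_result> %d samples, %d clamped, max |Vout| = %.3f V\n",
    length(x$time_us), sum(x$clamped), max(abs(x$v_out_v))))
  invisible(x)
}

#' Peak inrush current at channel connection
#'
#' Connecting an output switch when the electrode surface potential
#' differs from the current-mirror output drives an inrush transient
#' `v_mismatch / Rs`.  The inrush-suppression buffer pre-equalizes the
#' two potentials, removing the transient entirely.
#'
#' @param model An [interface_model()].
#' @param v_mismatch_v Potential difference at the switching instant, V.
#' @param suppression_on Logical; is the suppression buffer enabled?
#' @return Peak inrush current magnitude in uA.
#' @export
inrush_peak <- function(model, v_mismatch_v, suppression_on = TRUE) {
  if (suppression_on) return(0)
  abs(v_mismatch_v) / model$r_series_ohm * 1e6
}

#' Discharge the interface by shorting the channel to reference
#'
#' The accumulated interface voltage decays through the series path with
#' time constant `Rs * Cp`.
#'
#' @param model An [interface_model()].
#' @param vc_v Capacitor (interface) voltage before shorting, V.
#' @param duration_us Shorting duration, us.
#' @return Residual capacitor voltage after the short, V.
#' @export
short_to_reference <- function(model, vc_v, duration_us) {
  if (duration_us < 0) stop("'duration_us' must be >= 0")
  vc_v * exp(-duration_us * 1e-6 /
               (model$r_series_ohm * model$c_parallel_f))
}

#' Write a drive result to CSV
#'
#' Columns `time_us`, `i_cmd_uA`, `i_actual_uA`, `v_out_V`, `v_cap_V`.
#'
#' @param result A `"drive_result"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drive_csv <- function(result, path) {
  utils::write.csv(
    data.frame(time_us = result$time_us, i_cmd_uA = result$i_cmd_ua,
               i_actual_uA = result$i_actual_ua, v_out_V = result$v_out_v,
               v_cap_V = result$v_cap_v),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an interface model from JSON
#'
#' Fields `r_series_ohm`, `r_parallel_ohm`, `c_parallel_f` and optionally
#' `v_limit_v`.
#'
#' @param path JSON file path.
#' @return An [interface_model()].
#' @export
read_interface_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  interface_model(doc$r_series_ohm, doc$r_parallel_ohm, doc$c_parallel_f,
                  if (is.null(doc$v_limit_v)) 2.42 else doc$v_limit_v)
}
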