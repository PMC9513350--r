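# Multi-chip bus arithmetic.  Up to 64 chips (6-bit ID space) share one
# serial register-setting bus; chips are updated strictly sequentially,
# so phase times are n_chips x frame_bits / bitrate.

#' Multi-chip system configuration
#'
#' @param n_chips Number of module chips on the common bus, 0..64.
#' @param bitrate_bps Serial bus bit rate, bits/s.
#' @param frame_period_ms Stimulus-pattern update period, ms.
#' @return An object of class `"system_config"`.
#' @export
system_config <- function(n_chips = 64, bitrate_bps = 10e6,
                          frame_period_ms = 20) {
  n_chips <- as.integer(n_chips)
  if (n_chips < 0L || n_chips > 64L)
    stop("'n_chips' must be in 0..64 (6-bit ID space)")
  if (bitrate_bps <= 0) stop("'bitrate_bps' must be > 0")
  if (frame_period_ms <= 0) stop("'frame_period_ms' must be > 0")
  structure(list(n_chips = n_chips, bitrate_bps = bitrate_bps,
                 frame_period_ms = frame_period_ms),
            class = "system_config")
}

#' Initialization-phase time on the common bus
#'
#' Reg2 + Reg3 are loaded chip by chip with one 1362-bit init frame each.
#'
#' @param cfg A [system_config()].
#' @return Time in seconds: `n_chips * 1362 / bitrate` (136.2 us per chip
#'   at 10 Mbps).
#' @examples
#' init_phase_time(system_config(64)) * 1e3  # ~8.717 ms
#' @export
init_phase_time <- function(cfg = system_config()) {
  cfg$n_chips * bus_frame_length("init") / cfg$bitrate_bps
}

#' Stimulation-phase Reg1 update time on the common bus
#'
#' The stimulation-position registers are refreshed chip by chip with one
#' 73-bit frame each.
#'
#' @param cfg A [system_config()].
#' @return Time in seconds: `n_chips * 73 / bitrate` (7.3 us per chip at
#'   10 Mbps).
#' @examples
#' reg1_update_time(system_config(64)) * 1e6  # 467.2 us
#' @export
reg1_update_time <- function(cfg = system_config()) {
  cfg$n_chips * bus_frame_length("reg1") / cfg$bitrate_bps
}

#' Total stimulation channels of a multi-chip system
#'
#' @param cfg A [system_config()].
#' @return `64 * n_chips` (4096 with a full 64-chip array).
#' @export
total_channels <- function(cfg = system_config()) {
  64L * cfg$n_chips
}

#' Can the bus sustain the pattern frame rate?
#'
#' The Reg1 update of all chips must fit inside one frame period.
#'
#' @param cfg A [system_config()].
#' @return List with `feasible` (logical) and `overhead_fraction`
#'   (Reg1 update time / frame period).
#' @examples
#' frame_rate_feasible(system_config(64, 10e6, 20))$overhead_fraction
#' @export
frame_rate_feasible <- function(cfg = system_config()) {
  update_s <- reg1_update_time(cfg)
  period_s <- cfg$frame_period_ms * 1e-3
  list(feasible = update_s < period_s,
       overhead_fraction = update_s / period_s)
}

#' Bus timing report
#'
#' @param cfg A [system_config()].
#' @return Data frame of the timing quantities (also printed by the CLI's
#'   `bus-timing` subcommand).
#' @export
bus_timing_report <- function(cfg = system_config()) {
  feas <- frame_rate_feasible(cfg)
  data.frame(
    quantity = c("chips", "channels", "init phase (us)",
                 "reg1 update (us)", "frame period (ms)",
                 "reg1 overhead (%)", "frame rate feasible"),
    value = c(cfg$n_chips, total_channels(cfg),
              init_phase_time(cfg) * 1e6, reg1_update_time(cfg) * 1e6,
              cfg$frame_period_ms, feas$overhead_fraction * 100,
              as.numeric(feas$feasible)))
}
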