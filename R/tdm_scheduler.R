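# Eight-timeslot time-division semi-parallel scheduler.  Each of the 8
# current generators drives at most one of its 8 channels per timeslot;
# a channel's STS code places its pulse in one of the 8 slots of the
# stimulation window.

#' Build a stimulation schedule from a register file
#'
#' Every enabled channel (`stp = 1`, `rp = 0`; reference-flagged channels
#' emit no stimulus) is placed at the start of its STS timeslot.  The slot
#' duration is uniform: the longest enabled pulse plus the multiplexer
#' switching time, unless fixed explicitly.  Two enabled channels of the
#' same generator may not share a timeslot.
#'
#' @param regfile A [chip_register_file()].
#' @param specs A single [pulse_spec()] applied to every enabled channel,
#'   or a list of 64 (indexed by flat channel index + 1, `NULL` allowed for
#'   disabled channels).  Ignored when `waveforms` is given.
#' @param settings A [generator_settings()] used to synthesize pulses.
#' @param switch_time_us Multiplexer switching time, >= the 7.8 us design
#'   minimum.
#' @param dt_us Waveform sample step, us.
#' @param slot_duration_us Fixed slot duration, us; default computed from
#'   the pulses.
#' @param waveforms Alternative to `specs`: a single `"current_waveform"`
#'   recycled to all enabled channels, or a list of 64.
#' @return An object of class `"stim_schedule"`: `events` data frame
#'   (`generator`, `channel`, `slot`, `start_us`, `duration_us`),
#'   `slot_duration_us`, `window_duration_us` (= 8 slots) and the per-event
#'   waveforms.
#' @examples
#' rf <- chip_register_file(stp = rep(1, 64), sts = rep(0:7, times = 8))
#' sch <- build_schedule(rf, pulse_spec(30, 30, 200, 200))
#' nrow(sch$events)  # 64
#' @export
build_schedule <- function(regfile, specs = NULL,
                           settings = generator_settings(),
                           switch_time_us = 7.8, dt_us = 0.1,
                           slot_duration_us = NULL, waveforms = NULL) {
  stopifnot(inherits(regfile, "chip_register_file"))
  if (switch_time_us < 7.8)
    stop("'switch_time_us' cannot be below the 7.8 us design minimum")
  enabled <- which(regfile$stp == 1 & regfile$rp == 0)
  if (length(enabled) == 0) {
    events <- data.frame(generator = integer(), channel = integer(),
                         slot = integer(), start_us = numeric(),
                         duration_us = numeric())
    sd <- if (is.null(slot_duration_us)) switch_time_us else slot_duration_us
    return(structure(list(events = events, slot_duration_us = sd,
                          window_duration_us = 8 * sd,
                          switch_time_us = switch_time_us,
                          waveforms = list()),
                     class = "stim_schedule"))
  }
  gen <- (enabled - 1L) %/% 8L + 1L
  ch <- (enabled - 1L) %% 8L + 1L
  slot <- as.integer(regfile$sts[enabled])
  clash <- duplicated(data.frame(gen, slot))
  if (any(clash))
    stop(sprintf(
      "scheduling conflict: generator %d has two channels in timeslot %d",
      gen[clash][1], slot[clash][1]))
  wf <- .resolve_waveforms(enabled, specs, settings, dt_us, waveforms)
  len <- vapply(wf, pulse_duration, 0)
  if (is.null(slot_duration_us))
    slot_duration_us <- max(len) + switch_time_us
  if (any(len > slot_duration_us))
    stop("a pulse is longer than the fixed slot duration")
  events <- data.frame(generator = gen, channel = ch, slot = slot,
                       start_us = slot * slot_duration_us,
                       duration_us = len)
  ord <- order(events$slot, events$generator)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, slot_duration_us = slot_duration_us,
                 window_duration_us = 8 * slot_duration_us,
                 switch_time_us = switch_time_us,
                 waveforms = stats::setNames(wf[ord], enabled[ord])),
            class = "stim_schedule")
}

.resolve_waveforms <- function(enabled, specs, settings, dt_us, waveforms) {
  if (!is.null(waveforms)) {
    if (inherits(waveforms, "current_waveform"))
      return(rep(list(waveforms), length(enabled)))
    return(lapply(enabled, function(i) {
      w <- waveforms[[i]]
      if (is.null(w)) stop(sprintf("no waveform for enabled channel %d", i))
      w
    }))
  }
  if (is.null(specs)) stop("either 'specs' or 'waveforms' is required")
  if (inherits(specs, "pulse_spec")) {
    one <- synthesize_pulse(specs, settings, dt_us)
    return(rep(list(one), length(enabled)))
  }
  lapply(enabled, function(i) {
    s <- specs[[i]]
    if (is.null(s)) stop(sprintf("no pulse spec for enabled channel %d", i))
    synthesize_pulse(s, settings, dt_us)
  })
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "<stim_schedule> %d events, slot %.4g us, window %.4g us\n",
    nrow(x$events), x$slot_duration_us, x$window_duration_us))
  invisible(x)
}

#' Maximum per-channel pulse repetition rate
#'
#' In time-division semi-parallel mode a channel can fire once per
#' stimulation window, i.e. once per `n_slots * (pulse + switch)` time.
#'
#' @param pulse_len_us Biphasic pulse length, us.
#' @param n_slots Number of timeslots (8 in the 1:8 configuration).
#' @param switch_time_us Multiplexer switching time, us.
#' @return Maximum repetition rate in Hz:
#'   `1e6 / (n_slots * (pulse_len_us + switch_time_us))`.
#' @examples
#' max_repetition_rate(400)  # ~306.5 Hz
#' @export
max_repetition_rate <- function(pulse_len_us, n_slots = 8,
                                switch_time_us = 7.8) {
  if (pulse_len_us <= 0) stop("'pulse_len_us' must be > 0")
  1e6 / (n_slots * (pulse_len_us + switch_time_us))
}

#' Export a schedule's event table to CSV
#'
#' Columns `generator`, `channel`, `slot`, `start_us`, `duration_us`.
#'
#' @param schedule A `"stim_schedule"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$events, path, row.names = FALSE)
  invisible(path)
}
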