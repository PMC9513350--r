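# Dynamic pattern-stimulation pipeline: a 64x64 binary spike-image stream
# (5 ms steps) is tiled into 64 blocks of 8x8 pixels, each block is tagged
# with a chip ID and shipped as a Reg1 frame, and the per-chip stimulus
# output is visualized on an 8x8 LED grid.  Mapping conventions (fixed and
# documented, any bijection reproduces the demonstration): blocks tile the
# frame row-major, chip_id = 8 * (row %/% 8) + (col %/% 8); within a block,
# pixel row -> generator and pixel column -> channel.

#' Construct a binary spike frame
#'
#' @param grid 64 x 64 matrix of 0/1 spike indicators.
#' @param timestamp_ms Frame timestamp, a multiple of the 5 ms step.
#' @return An object of class `"spike_frame"`.
#' @export
spike_frame <- function(grid, timestamp_ms = 0) {
  grid <- as.matrix(grid)
  if (!all(dim(grid) == c(64, 64)))
    stop("'grid' must be 64 x 64")
  if (!all(grid %in% c(0, 1)))
    stop("'grid' values must be 0 or 1")
  structure(list(grid = matrix(as.integer(grid), 64, 64),
                 timestamp_ms = timestamp_ms),
            class = "spike_frame")
}

#' @export
print.spike_frame <- function(x, ...) {
  cat(sprintf("<spike_frame> t=%g ms, %d spikes\n",
              x$timestamp_ms, sum(x$grid)))
  invisible(x)
}

# Block-mean downsampling of a square matrix to 64 x 64.
.downsample64 <- function(m) {
  if (all(dim(m) == c(64, 64))) return(m)
  if (nrow(m) %% 64 != 0 || ncol(m) %% 64 != 0)
    stop("frame dimensions must be multiples of 64")
  fr <- nrow(m) %/% 64
  fc <- ncol(m) %/% 64
  ri <- rep(seq_len(64), each = fr)
  ci <- rep(seq_len(64), each = fc)
  t(rowsum(t(rowsum(m, ri)), ci)) / (fr * fc)
}

#' Minimal transient-ON retinal stand-in
#'
#' Converts a grayscale image stream into all-or-none spike frames: a
#' pixel spikes at frame t iff its intensity increased by more than
#' `threshold` since frame t-1 (positive contrast steps only; the first
#' frame never spikes).  Frames larger than 64 x 64 are block-mean
#' downsampled first.
#'
#' @param image_stream List of numeric matrices (equal dimensions,
#'   multiples of 64).
#' @param threshold Contrast-step threshold, in intensity units.
#' @param step_ms Frame step, ms.
#' @return List of [spike_frame()]s, timestamps `0, step_ms, ...`.
#' @export
transient_on_emulator <- function(image_stream, threshold, step_ms = 5) {
  if (length(image_stream) == 0) return(list())
  small <- lapply(image_stream, .downsample64)
  out <- vector("list", length(small))
  out[[1]] <- spike_frame(matrix(0L, 64, 64), 0)
  for (t in seq_along(small)[-1]) {
    spikes <- (small[[t]] - small[[t - 1]] > threshold) * 1L
    out[[t]] <- spike_frame(spikes, (t - 1) * step_ms)
  }
  out
}

#' Section a spike frame into 64 chip-tagged 8x8 blocks
#'
#' @param frame A [spike_frame()].
#' @return List of 64 block assignments in chip-ID order 0..63, each a
#'   list with `chip_id`, `block` (8 x 8 matrix) and `origin` (zero-based
#'   top-left `(row, col)` of the block in the frame).
#' @export
section_blocks <- function(frame) {
  stopifnot(inherits(frame, "spike_frame"))
  lapply(0:63, function(id) {
    br <- id %/% 8L
    bc <- id %% 8L
    list(chip_id = id,
         block = frame$grid[br * 8L + 1:8, bc * 8L + 1:8],
         origin = c(row = br * 8L, col = bc * 8L))
  })
}

#' Reassemble 64 blocks into a spike frame
#'
#' Inverse of [section_blocks()]; `assemble_blocks(section_blocks(f))`
#' reproduces `f$grid` exactly.
#'
#' @param blocks List of 64 block assignments.
#' @param timestamp_ms Timestamp of the reassembled frame.
#' @return A [spike_frame()].
#' @export
assemble_blocks <- function(blocks, timestamp_ms = 0) {
  grid <- matrix(0L, 64, 64)
  for (b in blocks) {
    grid[b$origin[["row"]] + 1:8, b$origin[["col"]] + 1:8] <- b$block
  }
  spike_frame(grid, timestamp_ms)
}

#' Convert blocks to a chip-tagged Reg1 frame stream
#'
#' Each block becomes the STP payload of its chip: block pixel (r, c)
#' (zero-based) maps to generator r + 1, channel c + 1, i.e. flat STP
#' index `8 * r + c`.  Frames are emitted in chip-ID order, as on the
#' common bus.
#'
#' @param blocks List of 64 block assignments from [section_blocks()].
#' @return List of 64 `"bus_frame"`s of kind `"reg1"`.
#' @export
blocks_to_reg1_stream <- function(blocks) {
  lapply(blocks, function(b) {
    rf <- chip_register_file(chip_id = b$chip_id,
                             stp = as.integer(t(b$block)))
    encode_frame(rf, "reg1")
  })
}

#' Broadcast a Reg1 frame stream to a chip array
#'
#' Every frame is offered to every chip; the chip-selector logic inside
#' [decode_frame()] ensures that only the chip whose ID matches the frame
#' header latches the payload.
#'
#' @param frames List of `"bus_frame"`s.
#' @param chips List of [chip_register_file()]s (default: a fresh 64-chip
#'   array with IDs 0..63 and the demo timeslot sequence
#'   `sts = channel - 1`).
#' @return The updated list of chips.
#' @export
apply_reg1_stream <- function(frames, chips = chip_array()) {
  for (fr in frames) {
    # route on the header first; decode_frame re-checks and parses
    idx <- which(vapply(chips, function(c) c$chip_id, 0L) == fr$chip_id)
    for (i in idx) chips[[i]] <- decode_frame(fr, chips[[i]])
  }
  chips
}

#' A fresh array of module chips
#'
#' @param n_chips Number of chips, IDs 0..n_chips-1.
#' @param sts Timeslot sequence shared by all chips; the default places
#'   channel k of every generator in slot k - 1 so that all 8 channels of
#'   a generator can be enabled at once.
#' @return List of [chip_register_file()]s.
#' @export
chip_array <- function(n_chips = 64, sts = rep(0:7, times = 8)) {
  lapply(seq_len(n_chips) - 1L, function(id)
    chip_register_file(chip_id = id, sts = sts))
}

#' Render a chip's stimulus output as LED lighting patterns
#'
#' Emulates the demonstration bench where each current generator injects a
#' monophasic pulse into an LED driver: LED (generator, channel) lights
#' during its channel's slot.  Returns one 8x8 on/off grid per timeslot
#' plus their union over the stimulation window.
#'
#' @param schedule A `"stim_schedule"` for a single chip.
#' @return List with `slots` (list of 8 binary 8 x 8 matrices, rows =
#'   generators, columns = channels) and `union`.
#' @export
render_led <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  slots <- lapply(0:7, function(s) {
    g <- matrix(0L, 8, 8)
    ev <- schedule$events[schedule$events$slot == s, , drop = FALSE]
    if (nrow(ev)) g[cbind(ev$generator, ev$channel)] <- 1L
    g
  })
  union <- matrix(as.integer(Reduce(`+`, slots) > 0), 8, 8)
  list(slots = slots, union = union)
}

#' The demonstration LED drive pulse
#'
#' @param amp_ua Amplitude, uA (50 in the demo).
#' @param dur_us Duration, us (1800 in the demo).
#' @param dt_us Sample step, us.
#' @return A monophasic `"current_waveform"`.
#' @export
led_pulse <- function(amp_ua = 50, dur_us = 1800, dt_us = 1) {
  rect_waveform(amp_ua, dur_us, dt_us)
}

#' Run one spike frame through the full pattern pipeline
#'
#' Sections the frame into chip-tagged blocks, serializes them as Reg1 bus
#' frames, broadcasts the frames to a fresh 64-chip array, schedules each
#' chip's enabled channels with the LED drive pulse, renders the LED
#' grids, and reassembles the 64 lit-LED blocks into a 64x64 image.  For
#' any input frame the output equals the input: the pipeline is an exact
#' spatial identity.
#'
#' @param frame A [spike_frame()].
#' @param pulse Drive waveform, default [led_pulse()].
#' @return List with `lit` (a [spike_frame()] of lit LEDs), `frames` (the
#'   Reg1 bus frames) and `chips` (the updated chip array).
#' @export
pipeline_frame <- function(frame, pulse = led_pulse()) {
  blocks <- section_blocks(frame)
  frames <- blocks_to_reg1_stream(blocks)
  chips <- apply_reg1_stream(frames)
  lit_blocks <- lapply(chips, function(chip) {
    enabled <- sum(chip$stp) > 0
    lit <- if (enabled) {
      render_led(build_schedule(chip, waveforms = pulse))$union
    } else {
      matrix(0L, 8, 8)
    }
    id <- chip$chip_id
    list(chip_id = id, block = lit,
         origin = c(row = (id %/% 8L) * 8L, col = (id %% 8L) * 8L))
  })
  list(lit = assemble_blocks(lit_blocks, frame$timestamp_ms),
       frames = frames, chips = chips)
}

# -- portable bitmap / graymap I/O -----------------------------------------

#' Write a binary matrix as a plain PBM (P1) image
#'
#' @param mat 0/1 matrix; 1 is written as a set pixel.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pbm <- function(mat, path) {
  mat <- as.matrix(mat)
  if (!all(mat %in% c(0, 1))) stop("PBM requires 0/1 values")
  lines <- c("P1", paste(ncol(mat), nrow(mat)),
             apply(mat, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain PBM (P1) image
#'
#' @param path PBM file path.
#' @return Integer 0/1 matrix.
#' @export
read_pbm <- function(path) {
  tok <- .pnm_tokens(path, "P1")
  nc <- tok[1]
  nr <- tok[2]
  vals <- tok[-(1:2)]
  if (length(vals) != nr * nc) stop("PBM pixel count mismatch")
  matrix(as.integer(vals), nr, nc, byrow = TRUE)
}

#' Write a numeric matrix as a plain PGM (P2) image
#'
#' @param mat Matrix of non-negative intensities.
#' @param path Output path.
#' @param maxval Maximum gray value.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mat, path, maxval = 255) {
  mat <- round(as.matrix(mat))
  if (any(mat < 0) || any(mat > maxval)) stop("PGM values out of range")
  lines <- c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval),
             apply(mat, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain PGM (P2) image
#'
#' @param path PGM file path.
#' @return Numeric intensity matrix.
#' @export
read_pgm <- function(path) {
  tok <- .pnm_tokens(path, "P2")
  nc <- tok[1]
  nr <- tok[2]
  vals <- tok[-(1:3)]  # drop maxval
  if (length(vals) != nr * nc) stop("PGM pixel count mismatch")
  matrix(vals, nr, nc, byrow = TRUE)
}

.pnm_tokens <- function(path, magic) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  tok <- scan(text = paste(lines, collapse = " "), what = "character",
              quiet = TRUE)
  if (length(tok) < 3 || tok[1] != magic)
    stop(sprintf("not a plain %s file", magic))
  as.numeric(tok[-1])
}
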