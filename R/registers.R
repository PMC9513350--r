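# On-chip register memory and common-bus frame codec.
#
# One module chip carries 8 current generators x 8 output channels = 64
# stimulation channels.  Per-channel stimulus parameters live in three
# register groups, updated at decreasing frequency:
#   Reg1 - stimulation on/off position (updated every display frame)
#   Reg2 - timeslot sequence for the 8-slot multiplexer
#   Reg3 - amplitudes, reference flags, pulse-width trim, per-side settings
# Chips share a 10 Mbps serial bus; a 6-bit chip-ID header selects which
# chip latches a register-setting frame.

# Field widths of the register memory, in register-map row order.  The
# per-side fields (ma/ics/otr) are shared by the 4 generators of each side.
.reg_fields <- list(
  stp = list(n = 64L, width = 1L,  group = "reg1"),
  sts = list(n = 64L, width = 3L,  group = "reg2"),
  ap  = list(n = 64L, width = 6L,  group = "reg3"),
  cp  = list(n = 64L, width = 6L,  group = "reg3"),
  rp  = list(n = 64L, width = 1L,  group = "reg3"),
  pa  = list(n = 64L, width = 4L,  group = "reg3"),
  ma  = list(n = 2L,  width = 2L,  group = "reg3"),
  ics = list(n = 2L,  width = 2L,  group = "reg3"),
  otr = list(n = 2L,  width = 32L, group = "reg3")
)

.frame_header_bits <- 6L
# Framing bits pad the printed frame times (7.3 / 136.2 us at 10 Mbps) to
# 73 / 1362 bits; their semantics are not architecturally visible, so they
# are carried as zeros.
.frame_framing_bits <- c(reg1 = 3L, init = 4L)

#' Address of one stimulation channel
#'
#' A channel is identified by its current generator (1..8) and the output
#' channel within that generator (1..8).  The flat index
#' `(generator - 1) * 8 + (channel - 1)` (0..63) orders channels generator
#' by generator and is the serialization order of all per-channel register
#' fields.
#'
#' @param generator Current generator number, 1..8.
#' @param channel Output channel within the generator, 1..8.
#' @return An object of class `"channel_address"` with elements
#'   `generator`, `channel` and zero-based `flat`.
#' @examples
#' channel_address(1, 1)$flat  # 0
#' channel_address(8, 8)$flat  # 63
#' @export
channel_address <- function(generator, channel) {
  generator <- as.integer(generator)
  channel <- as.integer(channel)
  if (generator < 1L || generator > 8L) stop("'generator' must be in 1..8")
  if (channel < 1L || channel > 8L) stop("'channel' must be in 1..8")
  structure(
    list(generator = generator, channel = channel,
         flat = (generator - 1L) * 8L + (channel - 1L)),
    class = "channel_address"
  )
}

.check_field <- function(x, name) {
  f <- .reg_fields[[name]]
  if (length(x) != f$n)
    stop(sprintf("'%s' must have length %d", name, f$n))
  if (any(!is.finite(x)) || any(x != floor(x)))
    stop(sprintf("'%s' must hold integers", name))
  rng <- if (name == "pa") c(-7, 8) else c(0, 2^f$width - 1)
  if (any(x < rng[1]) || any(x > rng[2]))
    stop(sprintf("'%s' values must lie in %d..%.0f", name, rng[1], rng[2]))
  as.numeric(x)
}

#' Construct a chip register file
#'
#' Bit-exact image of one chip's register memory.  Per-channel fields are
#' length-64 vectors in flat-index order (see [channel_address()]); the
#' per-side fields have one entry for the left and one for the right bank
#' of four generators.
#'
#' @param chip_id 6-bit chip identifier, 0..63.
#' @param stp Stimulation on/off position, 64 x 1 bit.
#' @param sts Stimulation timeslot sequence, 64 x 3 bits (slots 0..7).
#' @param ap Anodic amplitude code, 64 x 6 bits (0..63).
#' @param cp Cathodic amplitude code magnitude, 64 x 6 bits (0..63); the
#'   cathodic sign is applied by the current generator, not stored.
#' @param rp Reference-channel flag, 64 x 1 bit; flagged channels are
#'   shorted to the reference and emit no stimulus.
#' @param pa Pulse-width adjustment code, 64 x 4 bits, signed -7..+8.
#' @param ma Maximum-amplitude range code per side, 2 x 2 bits.
#' @param ics Inrush-current-suppression setting per side, 2 x 2 bits.
#' @param otr Miscellaneous bias settings per side, 2 x 32 bits; carried
#'   as an opaque payload.
#' @return An object of class `"chip_register_file"`.
#' @seealso [register_group_sizes()], [encode_frame()], [decode_frame()]
#' @export
chip_register_file <- function(chip_id = 0,
                               stp = rep(0, 64), sts = rep(0, 64),
                               ap = rep(0, 64), cp = rep(0, 64),
                               rp = rep(0, 64), pa = rep(0, 64),
                               ma = c(0, 0), ics = c(0, 0),
                               otr = c(0, 0)) {
  chip_id <- as.integer(chip_id)
  if (chip_id < 0L || chip_id > 63L) stop("'chip_id' must be in 0..63")
  rf <- list(chip_id = chip_id)
  vals <- list(stp = stp, sts = sts, ap = ap, cp = cp, rp = rp, pa = pa,
               ma = ma, ics = ics, otr = otr)
  for (nm in names(.reg_fields)) rf[[nm]] <- .check_field(vals[[nm]], nm)
  structure(rf, class = "chip_register_file")
}

#' @export
print.chip_register_file <- function(x, ...) {
  cat(sprintf("<chip_register_file> chip_id=%d, %d channels enabled, %d reference\n",
              x$chip_id, sum(x$stp), sum(x$rp)))
  invisible(x)
}

#' Register group sizes in bits
#'
#' Sums the register-map field widths per group.  The three groups hold the
#' stimulation position (Reg1), the timeslot sequence (Reg2) and all other
#' stimulus/circuit parameters (Reg3).
#'
#' @return Named numeric vector `c(reg1 = 64, reg2 = 192, reg3 = 1160)`,
#'   computed from the field widths.
#' @examples
#' register_group_sizes()
#' @export
register_group_sizes <- function() {
  bits <- vapply(.reg_fields, function(f) as.numeric(f$n) * f$width, 0)
  grp <- vapply(.reg_fields, function(f) f$group, "")
  out <- c(tapply(bits, grp, sum))
  out[c("reg1", "reg2", "reg3")]
}

#' Frame length on the common bus
#'
#' @param kind `"reg1"` (stimulation-position update) or `"init"`
#'   (Reg2 + Reg3 initialization).
#' @return Total frame length in bits: 6-bit chip-ID header + payload +
#'   framing bits (73 for `reg1`, 1362 for `init`).
#' @export
bus_frame_length <- function(kind = c("reg1", "init")) {
  kind <- match.arg(kind)
  sizes <- register_group_sizes()
  payload <- if (kind == "reg1") sizes[["reg1"]] else
    sizes[["reg2"]] + sizes[["reg3"]]
  .frame_header_bits + payload + .frame_framing_bits[[kind]]
}

# -- bit packing ------------------------------------------------------------
# MSB-first within each value; values concatenated in field order.  Doubles
# are used so the 32-bit otr payload packs without integer overflow.

.ints_to_bits <- function(x, width) {
  out <- integer(length(x) * width)
  for (k in seq_len(width)) {
    out[(seq_along(x) - 1L) * width + k] <- floor(x / 2^(width - k)) %% 2
  }
  as.integer(out)
}

.bits_to_ints <- function(bits, width) {
  m <- matrix(as.numeric(bits), nrow = width)
  as.numeric(2^((width - 1):0) %*% m)
}

# pa codes are signed -7..+8, stored as value mod 16 (+8 -> 1000b).
.pa_encode <- function(x) x %% 16
.pa_decode <- function(x) ifelse(x > 8, x - 16, x)

.serialize_fields <- function(regfile, fields) {
  bits <- lapply(fields, function(nm) {
    v <- regfile[[nm]]
    if (nm == "pa") v <- .pa_encode(v)
    .ints_to_bits(v, .reg_fields[[nm]]$width)
  })
  unlist(bits, use.names = FALSE)
}

.deserialize_fields <- function(regfile, fields, bits) {
  pos <- 0L
  for (nm in fields) {
    f <- .reg_fields[[nm]]
    take <- f$n * f$width
    v <- .bits_to_ints(bits[pos + seq_len(take)], f$width)
    if (nm == "pa") v <- .pa_decode(v)
    regfile[[nm]] <- v
    pos <- pos + take
  }
  regfile
}

.group_fields <- function(kind) {
  if (kind == "reg1") "stp" else
    names(.reg_fields)[vapply(.reg_fields, function(f)
      f$group %in% c("reg2", "reg3"), TRUE)]
}

#' Encode a register-setting frame for the common bus
#'
#' Serializes the selected register group of one chip into a bus frame:
#' 6-bit chip-ID header, then the payload (Reg1, or Reg2 followed by Reg3),
#' then zero framing bits.  Payload bit order is fixed: channels in flat
#' index order, fields in register-map row order, each value MSB-first.
#'
#' @param regfile A [chip_register_file()].
#' @param kind `"reg1"` or `"init"` (Reg2 + Reg3).
#' @return An object of class `"bus_frame"`: list with `kind`, `chip_id`
#'   and `bits` (integer 0/1 vector of length 73 or 1362).
#' @examples
#' length(encode_frame(chip_register_file(), "reg1")$bits)  # 73
#' @export
encode_frame <- function(regfile, kind = c("reg1", "init")) {
  kind <- match.arg(kind)
  stopifnot(inherits(regfile, "chip_register_file"))
  bits <- c(.ints_to_bits(regfile$chip_id, .frame_header_bits),
            .serialize_fields(regfile, .group_fields(kind)),
            integer(.frame_framing_bits[[kind]]))
  structure(list(kind = kind, chip_id = regfile$chip_id, bits = bits),
            class = "bus_frame")
}

#' @export
print.bus_frame <- function(x, ...) {
  cat(sprintf("<bus_frame> kind=%s, chip_id=%d, %d bits\n",
              x$kind, x$chip_id, length(x$bits)))
  invisible(x)
}

#' Apply a bus frame to a chip
#'
#' Emulates the chip-selector: the target chip latches the payload only if
#' the frame's 6-bit header matches its pre-assigned chip ID; otherwise the
#' register file is returned unchanged.  `decode_frame(encode_frame(x, k), x)`
#' is the identity for any register content.
#'
#' @param frame A `"bus_frame"` from [encode_frame()] or [read_bitstream()].
#' @param target The [chip_register_file()] listening on the bus.
#' @return The updated (or untouched) register file.
#' @export
decode_frame <- function(frame, target) {
  stopifnot(inherits(frame, "bus_frame"),
            inherits(target, "chip_register_file"))
  expected <- bus_frame_length(frame$kind)
  if (length(frame$bits) != expected)
    stop(sprintf("malformed %s frame: %d bits, expected %d",
                 frame$kind, length(frame$bits), expected))
  if (any(!frame$bits %in% c(0L, 1L)))
    stop("malformed frame: bits must be 0/1")
  header <- .bits_to_ints(frame$bits[seq_len(.frame_header_bits)],
                          .frame_header_bits)
  if (header != target$chip_id) return(target)
  payload <- frame$bits[-seq_len(.frame_header_bits)]
  payload <- payload[seq_len(length(payload) - .frame_framing_bits[[frame$kind]])]
  .deserialize_fields(target, .group_fields(frame$kind), payload)
}

# -- bitstream files --------------------------------------------------------

.bits_to_hex <- function(bits) {
  pad <- (4 - length(bits) %% 4) %% 4
  bits <- c(bits, integer(pad))
  vals <- .bits_to_ints(bits, 4L)
  paste(sprintf("%x", vals), collapse = "")
}

.hex_to_bits <- function(hex, nbits) {
  vals <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  if (any(is.na(vals))) stop("invalid hex digit in bitstream")
  bits <- .ints_to_bits(vals, 4L)
  if (length(bits) < nbits) stop("bitstream line too short")
  bits[seq_len(nbits)]
}

#' Write bus frames to a hex-text bitstream file
#'
#' One frame per line as hexadecimal text (bits padded with zeros on the
#' right to whole hex digits), preceded by a one-line header naming the
#' frame kind.  All frames in one file share a kind.
#'
#' @param frames A `"bus_frame"` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bitstream <- function(frames, path) {
  if (inherits(frames, "bus_frame")) frames <- list(frames)
  kinds <- unique(vapply(frames, function(f) f$kind, ""))
  if (length(kinds) != 1L)
    stop("all frames in one bitstream file must share a kind")
  lines <- c(kinds, vapply(frames, function(f) .bits_to_hex(f$bits), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read bus frames from a hex-text bitstream file
#'
#' @param path File written by [write_bitstream()].
#' @return List of `"bus_frame"` objects.
#' @export
read_bitstream <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty bitstream file")
  kind <- match.arg(trimws(lines[1]), c("reg1", "init"))
  nbits <- bus_frame_length(kind)
  lapply(lines[-1], function(ln) {
    bits <- .hex_to_bits(trimws(ln), nbits)
    header <- .bits_to_ints(bits[seq_len(.frame_header_bits)],
                            .frame_header_bits)
    structure(list(kind = kind, chip_id = as.integer(header), bits = bits),
              class = "bus_frame")
  })
}

# -- register JSON ----------------------------------------------------------

#' Write a register file to JSON
#'
#' Field names mirror the register map (`STP`, `STS`, `AP`, `CP`, `RP`,
#' `PA`, `MA`, `ICS`, `OTR`) plus `CHIP_ID`.
#'
#' @param regfile A [chip_register_file()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_register_json <- function(regfile, path) {
  stopifnot(inherits(regfile, "chip_register_file"))
  doc <- c(list(CHIP_ID = regfile$chip_id),
           stats::setNames(lapply(names(.reg_fields), function(nm) regfile[[nm]]),
                           toupper(names(.reg_fields))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a register file from JSON
#'
#' @param path File written by [write_register_json()] (or hand-authored
#'   with the same field names; missing fields default to zero).
#' @return A [chip_register_file()].
#' @export
read_register_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list(chip_id = if (is.null(doc$CHIP_ID)) 0 else doc$CHIP_ID)
  for (nm in names(.reg_fields)) {
    v <- doc[[toupper(nm)]]
    if (!is.null(v)) args[[nm]] <- v
  }
  do.call(chip_register_file, args)
}
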