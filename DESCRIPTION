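Package: icmstim
Title: Emulator for a 64-Channel Intracortical Microstimulation Module
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Register-accurate desk-scale emulation of a multichannel
    intracortical current-stimulation ASIC and its test bench: bit-exact
    on-chip register files with a 6-bit chip-ID common-bus frame codec,
    6-bit DAC amplitude quantization and biphasic pulse synthesis with
    4-bit pulse-width trimming for charge balancing, an eight-timeslot
    time-division multiplexed output scheduler, a series-R plus parallel-RC
    model of the electrode-electrolyte interface with compliance-voltage
    clamping, multi-chip bus-timing arithmetic, a dynamic pattern-stimulation
    pipeline from binary spike-image streams to chip-tagged register updates
    and an LED-grid render, and a synthetic cortical dose-response layer
    (threshold-shifted Hill model) with voltage-sensitive-dye style movie
    generation for closed-loop testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
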