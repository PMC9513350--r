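# Randomized fixtures, built in code at test time.

random_regfile <- function(chip_id = sample(0:63, 1)) {
  chip_register_file(
    chip_id = chip_id,
    stp = sample(0:1, 64, replace = TRUE),
    sts = sample(0:7, 64, replace = TRUE),
    ap = sample(0:63, 64, replace = TRUE),
    cp = sample(0:63, 64, replace = TRUE),
    rp = sample(0:1, 64, replace = TRUE),
    pa = sample(-7:8, 64, replace = TRUE),
    ma = sample(0:3, 2, replace = TRUE),
    ics = sample(0:3, 2, replace = TRUE),
    otr = sample(0:(2^31), 2, replace = TRUE) + sample(0:1, 2, TRUE) * 2^31
  )
}

random_spike_grid <- function(p = 0.2) {
  matrix(as.integer(stats::runif(64 * 64) < p), 64, 64)
}

regfile_equal <- function(a, b) {
  fields <- c("chip_id", "stp", "sts", "ap", "cp", "rp", "pa",
              "ma", "ics", "otr")
  all(vapply(fields, function(nm) isTRUE(all.equal(a[[nm]], b[[nm]])), TRUE))
}
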