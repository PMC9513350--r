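---
title: "Emulating a 64-channel intracortical stimulation module"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a 64-channel intracortical stimulation module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmstim)
```

## What is being emulated

Intracortical microstimulation delivers biphasic current pulses of a few
tens of microamperes through microelectrodes inserted in cortex; arrays of
such stimuli are the working principle of cortical visual prostheses.
`icmstim` is a desk-scale, register-accurate software model of a
multichannel stimulation ASIC built for animal experiments of this kind,
together with the electrical and biological surroundings needed to test it
in closed loop without hardware: the electrode–electrolyte interface as an
RC circuit, and cortical excitation as a synthetic dose–response layer.

One chip carries 8 current generators with 8 output channels each
(64 channels); up to 64 chips share a common 10 Mbps register-setting bus
addressed by a 6-bit chip ID, for 4,096 channels. The emulator reproduces
the digital side bit-for-bit and the analog side with closed-form circuit
models, so every headline design number (register sizes, bus times, DAC
resolution, charge-imbalance bound, repetition-rate limit) is recomputed
rather than assumed.

## Registers and the bus codec

The register map is encoded in field widths: `stp` (on/off, 64×1 bit),
`sts` (timeslot, 64×3), `ap`/`cp` (amplitude codes, 64×6 each), `rp`
(reference flag, 64×1), `pa` (pulse-width trim, 64×4, signed −7..+8), and
per-side `ma`/`ics`/`otr` (2×2, 2×2, 2×32). `register_group_sizes()` sums
these to 64 / 192 / 1160 bits, and the two frame kinds are header (6) +
payload + framing: 73 bits for a Reg1 update, 1362 for initialization —
exactly the 7.3 µs and 136.2 µs per chip that a 10 Mbps bus implies.

Serialization order is a convention the hardware documentation leaves
open; we fix it as: channels in flat index order
`(generator − 1)·8 + (channel − 1)`, fields in register-map row order,
each value MSB-first, signed trim codes stored modulo 16, framing bits
zero. Any fixed bijection gives the required bit-exact roundtrip
(`decode_frame(encode_frame(x))` is the identity, and a frame only ever
mutates the chip whose ID matches its header).

```{r}
register_group_sizes()
c(reg1 = bus_frame_length("reg1"), init = bus_frame_length("init"))
```

## Current generation and charge accounting

The DAC resolves the selected full scale (100–400 µA in four steps) into
64 codes: 1.5625 µA per code at the ±100 µA range. Quantization rounds to
the nearest code with ties toward zero (the hardware convention is not
documented; a fixed rule keeps everything reproducible) and saturates at
code 63.

A pulse is synthesized in µA/µs units so the rectangular integral comes
out in pC. Samples hold the *mean* current over each `dt` interval, which
makes the integral of a piecewise-constant pulse exact no matter where
phase boundaries fall on the grid — important because the second-phase
trim step (1.95 µs) is not a multiple of the default `dt = 0.1` µs. The
default `dt` gives ≥ 19 samples per trim step; rise and fall are treated
as instantaneous (the silicon's ≤ 5 µs rise time is ignored).

Because both phases share one charge unit per duration, the worst net
charge a quantization mismatch of one LSB can leave behind is
`resolution × phase duration` — 156.25 pC for 0.1 ms phases at the
±100 µA range:

```{r}
s <- generator_settings(0)
res <- amplitude_resolution(s)
wf <- synthesize_pulse(pulse_spec(30, 30 + res, 100, 100), s)
charge_imbalance(wf)
```

`optimize_pw_adjust()` then plays the bench procedure: it sweeps all 16
trim codes of the second phase and keeps the one with the smallest
absolute net charge, ties broken toward code 0 (and toward the negative
code at equal magnitude, a documented convention).

## Timeslot scheduling

In time-division semi-parallel mode each generator serves its 8 channels
in 8 timeslots; a channel's `sts` code places its pulse at the start of
its slot. Slots are uniform — the longest enabled pulse plus the
multiplexer switching time (7.8 µs minimum, configurable upward) — so a
fully loaded chip with 0.4 ms pulses repeats each channel at
`1e6 / (8 × 407.8) ≈ 306.5` Hz. Two enabled channels of one generator in
the same slot is a configuration error, not a packing problem: per-slot
packing is deliberately out of scope.

## The electrode load

The interface is modelled as a series access resistance `Rs` feeding a
parallel `Rp ∥ Cp`; the generator is an ideal current source inside the
±2.42 V compliance window and clamps to the rail outside it. The system
is piecewise linear, so each sample step advances with the exact
exponential solution of whichever linear circuit is active — in
current-source mode `Vc → I·Rp` with time constant `Rp·Cp`, in clamp mode
`Vc → ±V_L·Rp/(Rs+Rp)` with `Cp·Rs·Rp/(Rs+Rp)` — which is both faster and
drift-free compared with generic ODE stepping. The clamp is hard; whether
the silicon soft-limits first is unknowable from the outside and is not
modelled.

Bench fixture loads are specified only by their impedance magnitude at
1 kHz (33.7 kΩ for a metal microelectrode model, 325 kΩ for a small-tip
one, behind ~1 kΩ series resistance). One magnitude cannot determine both
`Rp` and `Cp`, so `fit_interface_model()` fixes `Rp = 10 × |Z|(1 kHz)` —
the charge-transfer resistance dominates at DC, consistent with treating
the source as ideal below compliance — and solves `Cp` by root-finding.
The fitted values are synthetic stand-ins for unpublished component
values and are shipped as such in
`inst/extdata/bench_loads_synthetic.json`.

Shorting a channel to the reference discharges the interface through the
series path (`τ = Rs·Cp`; `Rs` is the dominant series element and the
discharge path is not otherwise specified), and the inrush model is the
contract the suppression buffer implements: `v_mismatch / Rs` without
suppression, zero with it.

## Multi-chip timing and the pattern pipeline

Chips are updated strictly sequentially on the bus, so phase times are
`n_chips × frame_bits / bitrate`; the frame-bit counts come from the
codec, not constants. A 64-chip Reg1 refresh (467.2 µs) occupies 2.3 % of
a 20 ms pattern frame and fits comfortably inside the 5 ms step of the
spike-image stream.

The dynamic-operation pipeline converts a 64×64 binary spike image into
64 chip-tagged Reg1 frames: the frame is tiled row-major into 8×8 blocks
(`chip_id = 8·(row ÷ 8) + col ÷ 8`), and within a block pixel row maps to
generator, column to channel. The physical chip↔block wiring of the
demonstration bench is not documented; any fixed bijection reproduces the
behavior, and this one is asserted everywhere. The upstream retinal
processor is replaced by a minimal transient-ON stand-in — a pixel spikes
when its intensity rises by more than a threshold between consecutive
frames — because only its output format matters here. With the LED render
(each generator drives one LED per channel with a 50 µA / 1.8 ms
monophasic pulse), the pipeline is an exact spatial identity: the union
of lit LEDs across chips equals the input spike frame, for every frame.

## The synthetic cortical response layer

Measured cortical responses to single pulses follow a sigmoidal
dose–response in charge per phase. We adopt the threshold-shifted Hill
form

$$R(q) = \frac{(q - I_{th})^N}{(q - I_{th})^N + (I_{50} - I_{th})^N},
  \quad q > I_{th}; \qquad R = 0 \text{ otherwise,}$$

because it is the simplest curve carrying exactly the three conventional
parameters — threshold charge \(I_{th}\), half-maximum charge
\(I_{50}\), steepness \(N\) — with their stated meanings; the defaults
(0.9 nC, 2.4 nC, 2.5) are typical fitted values for rat visual cortex at
0.2 ms/phase. `fit_hill()` estimates the three parameters by bounded
Levenberg–Marquardt least squares over a fixed 9-point multi-start grid
(threshold and steepness starts spanning the plausible range), making the
fit deterministic for given data; constant responses raise a classed fit
error. Charge per phase is always computed from the *quantized* amplitude
times the phase duration, tying this layer to the generator model.

`synth_vsd_movie()` renders voltage-sensitive-dye style ΔF/F movies on a
100×100 grid covering 6.25 mm (62.5 µm pitch) at 1 ms frames. Each pulse
contributes a separable term: Hill amplitude × temporal kernel × spatial
Gaussian. The kernel is an alpha function normalized to 1 at its peak
(13 ms by default, the middle of the observed 11–15 ms range) minus a
Gaussian undershoot at 100 ms (depth 0.15, width 30 ms — free choices at
realistic magnitudes, since only the undershoot's timing is reported).
The Gaussian focus starts at σ = 0.1 mm and grows 0.025 mm/ms to model
propagation; these two values were fixed once so that electrode pairs
0.6 mm apart produce two discernible activation foci in the 3–4 ms frame
while 0.3 mm pairs merge — the qualitative bipolar-stimulation contrast
made exact under defaults. Pulses arriving within 20 ms of a predecessor
are attenuated by a gain of 0.5 per predecessor in the chain — a
deliberate caricature of the inhibitory recruitment seen with sequential
stimulation (so pulse 3 of a 20 ms train lands at gain 0.25);
simultaneous pulses form one volley and share a gain. Noise is i.i.d.
Gaussian per pixel per frame, scaled by `1/sqrt(n_trials)` to mirror
trial averaging, and seeded movies are bit-reproducible.

What the generator does *not* emulate: lateral circuit activation beyond
an isotropically spreading Gaussian, extra-V1 activation, nonlinear
interactions other than the single inhibition gain, photobleaching or
heartbeat artifacts. Passing tests therefore demonstrate correctness of
the pipeline and of the fitting machinery on data with known ground
truth, not fidelity to any particular animal's cortex.

## Numerical choices and problem sizes

* Waveform step `dt = 0.1` µs (generator), 0.5 µs for long drive
  simulations; the exact-exponential stepper makes results insensitive to
  `dt` well below the interface time constants.
* Quantizer ties toward zero; trim-code ties toward 0, then negative.
* Compliance clamp tolerance: the simulated |Vout| never exceeds the
  rail by more than 1 mV (it sits exactly on it while clamped).
* Hill fit: bounds `i_th ∈ [0, max q]`, `i_50 − i_th > 0`, `n ∈
  (0.001, 50)`; 9 starts; `nls.lm` with 200 iterations.
* Test-suite problem sizes, chosen to keep the whole suite in well under
  a minute while still exercising every property at scale: 100-draw
  register roundtrips, 190 code-pair imbalance sweeps, 200-replicate
  noisy Hill recovery, 100-frame end-to-end pipeline identity, 12-pulse
  charge-accumulation trains.

## Known limitations

The serial link is modelled only as bit counts and timing (no line
coding, no clock recovery); framing-bit semantics are unknowable from the
outside and carried as zeros. The interface model is linear — no Faradaic
chemistry, no water-window limits, no waveform asymmetry between phases.
The per-channel pulse-width trim follows the register map (one 4-bit code
per channel) even though the trim circuit is described as per-generator;
the emulator applies the code of the channel being driven, which is
indistinguishable in any single-channel measurement.
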