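---
title: "Vocal-locomotor coupling from bat biologging tags: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocal-locomotor coupling from bat biologging tags: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonarwing)
```

## The problem

Echolocating bats power their calls with the same airflow that their wingbeat
cycle compresses: during commuting and prey search, calls ride the end of the
upstroke, so the sensory sampling rate is pinned to the wingbeat rate. During
prey capture the bat overrides this coupling, emitting buzzes of many faint
calls per wingbeat. `sonarwing` implements the analysis chain that quantifies
this coupling from sound-and-movement tag data: audio at 187.5 kHz (16-bit,
clip level 121 dB re 20 µPa) and heave accelerometry at 1000 Hz (±8 g), plus
a ground-truthed simulator so that every stage can be validated without
access to field recordings.

## Wingbeat phase from heave acceleration

The heave (z) axis is modelled as gravity minus a sinusoid of the wingbeat
phase,

$$a_z(t) = 9.82 - A(t)\,\sin\phi(t) \quad [\mathrm{m\,s^{-2}}],$$

with the convention that phase 0–180° (upstroke: body accelerating toward
the ground) corresponds to $a_z < 9.82$, and 180–360° (downstroke) to
$a_z > 9.82$. The constant 9.82 m s⁻² is used throughout, matching the tag
convention.

Processing steps:

1. **Low-pass filter** (`lowpass_accel()`): a 255-tap linear-phase FIR with
   a nominal 30 Hz cutoff, applied with its group delay compensated
   ("delay-free"). The design is equiripple with passband edge at 5/6 of
   the cutoff and stopband edge at twice the cutoff (25 / 60 Hz at the
   default); a windowed design at exactly 30 Hz would droop ~0.5 dB at
   25 Hz, violating the flatness the wingbeat band needs, so the equiripple
   band placement is used instead (ripple < 0.001 dB below 25 Hz, > 100 dB
   attenuation above 60 Hz).
2. **Cycle detection** (`detect_wingbeats()`): cycles start at downward
   crossings of 9.82 m s⁻² and have their midpoint at the next upward
   crossing. Crossings closer than 25 ms to the previously accepted one are
   rejected (a 20 Hz ceiling), and cycles outside 0.05–0.4 s (2.5–20 Hz)
   are discarded as implausible.
3. **Phase** (`compute_phase()`): linear interpolation in time, 0→180°
   between cycle start and midpoint, 180→360° to the cycle end. This
   crossing-interpolation construction is the one that provably satisfies
   the phase convention above on noise-free data; analytic-signal methods
   (Hilbert phase) would satisfy it only approximately. Samples outside
   detected cycles are masked.

The stroke-frequency spectrogram (`wingbeat_spectrogram()`) decimates to
100 Hz (anti-aliased) and uses a 128-sample window with 100-sample overlap;
per-frame peaks whose prominence over the frame median is under 10 dB are
flagged unreliable.

## Call detection and source levels

Audio is high-pass filtered with a causal 4-pole Butterworth at 10 kHz
(`highpass_audio()`), mirroring a physical analogue filter. The detector
(`detect_calls()`) — a surrogate for the original study's unspecified
extractor — rectifies the signal, smooths over 0.25 ms, estimates a
per-10-s-block median noise floor, and takes local envelope maxima more
than 20 dB above the floor, separated by at least 2 ms. The refractory must
stay below 4 ms so buzz II trains (4–6 ms intervals) resolve call-by-call;
`run_pipeline()` rejects configurations that violate this. Noisy epochs
(wind, conspecifics) are excluded via a caller-supplied time mask, not by
automatic discrimination.

Each call is measured over a **−6 dB window**: the span between the nearest
envelope crossings 6 dB below the call's envelope peak. Energy flux density
over that window is

$$\mathrm{EFD} = 10\log_{10}\!\Big(\frac{\sum p^2\,\Delta t}{(20\,\mu\mathrm{Pa})^2\cdot 1\,\mathrm{s}}\Big)
\quad [\mathrm{dB\ re\ 20\,\mu Pa^2 s}].$$

Whether the original window was envelope-based or cumulative-energy-based
is not documented; both are implemented behind `mode =` in
`measure_calls()`, with the envelope rule as default. Calibration is pure
arithmetic: source EFD adds a fixed **+14 dB** off-axis correction (no
head-movement model), and RMS source level adds **+25 dB**, the offset for
a fixed 3 ms call duration ($-10\log_{10}0.003 = 25.2$, printed as 25).
Events with windows truncated by the record edge or containing clipped
samples are flagged; clipped levels are lower bounds.

## Behavioural segmentation

Call-interval classes (half-open, ms): buzz II [4, 7), buzz I [7, 14),
more-than-one-per-wingbeat [14, 100), one-per-wingbeat [100, 200), one per
two [200, 400), one per three [400, 600). An alternative preset
(`interval_bins("fig4")`) uses 5–7 / 8–14 ms buzz bins; the behavioural
definition set is the default.

A **buzz** is a maximal run of ≥ 5 calls with intervals under 14 ms
(including the opening call); pauses up to 100 ms do not split a run, so
buzz I hesitations stay within one capture attempt. The terminal sub-run
under 7 ms is buzz II, and **capture time is the emission time of the last
buzz call**. A buzz-I-only run still counts as a capture attempt by default
(`require_buzzII = FALSE`). Aerial captures are distinguished from landing
or perched buzzes by requiring vigorous wingbeat cycles (amplitude above
2 m s⁻²) to cover ≥ 80 % of the half-second before the buzz through the
capture. **Commuting flight** is a buzz-free window of ≥ 100 s in which
≥ 90 % of calls fall in the wingbeat-locked classes and the median wingbeat
frequency lies in 6–8 Hz.

The **approach onset** replaces a multi-rater manual consensus with an
automated rule: the start of the earliest wingbeat cycle, within 5 s of the
capture, from which at least two calls per wingbeat are sustained through
the buzz (at least two consecutive qualifying cycles). A single
non-qualifying cycle flanked by qualifying ones does not break the run —
a wingbeat straddling a behavioural transition can catch one call — and the
rule's resolution is one wingbeat cycle. If the criterion is never met the
onset degenerates to the buzz start (a fast attack).

## Coupling metrics

Calls are joined to the cycle containing their peak time. Per-wingbeat
summed energy is the energy-domain sum of the member calls' source EFDs,
$10\log_{10}\sum_i 10^{SL_i/10}$; cycles without calls carry `NA` (never
−Inf), and the linear-domain total is conserved exactly across cycles.
Capture-aligned series index whole cycles backwards from the cycle
containing the capture (index −1). Circular statistics use the circular
median (minimiser of mean circular absolute deviation; exact candidate
search up to n = 720, 0.1° binned search above) and quartiles defined as
the 25 %/75 % cumulative-mass points of the sample unwrapped around the
median — matching the "quartile range 135–235°" style of reporting.

## The simulator and what passing tests show

`generate_flight()` integrates phase at $360 f_{wb}$ °/s per segment with
0.5 s linear frequency ramps across boundaries, then schedules calls:

* **Commute/search** (defaults): 7 Hz, one 3 ms call per wingbeat at
  82 dB EFD source level (= 107 dB re 20 µPa RMS after +25 dB), centred at
  176° with a 35° Gaussian spread. The spread drifts mildly call-to-call
  (AR(1), lag-1 correlation 0.3) so that successive intervals stay
  wingbeat-locked, as strictly coupled flight requires; white per-call
  jitter of realistic magnitude would scatter intervals out of the
  one-per-wingbeat class. The broad all-call phase quartile range seen in
  real data (≈135–235°) is a property of the behavioural mixture — commute
  plus approach plus buzz — not of commute calls alone.
* **Approach** (`plan_foraging_night()`): an early half with two loud
  calls per wingbeat (dyads spaced 180°, so intervals sit near 70 ms) and
  a late half with three faint calls per wingbeat (120° spacing, −18 dB) at
  rising wingbeat frequency. This stylised two-stage schedule produces the
  characteristic source-level drop at call intervals of several tens of ms
  and the exclusion regions (no loud calls at short intervals, no faint
  calls at one-per-wingbeat intervals). Because the schedule is discrete
  rather than a continuum, the flagged transition band on synthetic nights
  can sit slightly below the 60–70 ms reported for wild bats.
* **Buzz**: interval-driven trains, buzz I uniform in [7, 14) ms (~0.12 s)
  then buzz II uniform in [4, 6] ms (~0.05 s, ~10 calls), 30 dB below
  search level, at 13 Hz wingbeat. Interval draws continue across the
  buzz I → buzz II boundary, and ground-truth buzz labels follow the same
  interval rule the analysis uses (buzz II iff the preceding interval is
  under 7 ms), so label recovery can be exact.
* **Audio**: each call is a Hann-enveloped linear FM downsweep (80→25 kHz;
  3 ms search calls, 0.5 ms buzz calls — the buzz duration and spectral
  content are not documented for the study species and are config-exposed
  choices), scaled so the on-tag EFD equals the source level minus 14 dB,
  over Gaussian noise at a 40 dB re 20 µPa floor, clipped at 121 dB.
* **Seeding**: one master seed; accel and audio noise use derived seeds, so
  truth tables are bit-identical across runs and streams are independent.

The simulator emulates the statistical structure the analysis assumes —
sinusoidal heave, phase- or interval-locked schedules, state-dependent
levels. It does **not** emulate aerodynamics, 3-D trajectories, directional
beam patterns (the 14 dB correction is a scalar), echoes, conspecific
calls, or non-stationary noise. Passing round-trip tests therefore
demonstrates that the pipeline recovers what the model generates — timing
to sub-millisecond, levels to < 1 dB, phases to a few degrees — not that it
is robust to every artefact of field recordings.

## Problem sizes and numerical choices

The validation suite runs a compressed foraging night — 48 captures behind
110 s of commuting, ≈250 s of audio — through the full pipeline, and a
schedule-only night (48 captures separated by 170 s search legs, > 50 000
calls) for call-budget properties such as the < 2 % buzz-call fraction;
these sizes keep a complete run in minutes on one core while leaving every
per-event statistic well determined. Degenerate inputs are defined, not
errors: a resting bat yields an empty cycle table, an empty cycle table
yields a fully masked phase series, and a record with no buzzes yields zero
capture events. Ties at interval-class bin edges follow the half-open
convention ([14, 100) so a 14 ms interval is "more than one per wingbeat").

## Cross-species arithmetic

`update_metrics()` computes sensory updates per metre (rate/speed) and per
body length travelled (rate × length / speed) for commute and capture
modes; the bundled profiles cover the tagged bats (0.077 m; 7 and
150 s⁻¹; 7 and 2 m s⁻¹), sperm whales and harbor porpoises. The
allometric wingbeat frequency
$f = 5.54 - 3.068\log_{10}m - 2.857\log_{10}v$ takes mass in kilograms —
gram inputs would drive it negative for any bat — and evaluates to 7.63 Hz
for a 34 g bat at 7 m s⁻¹, slightly above the 6–7 Hz observed in
commuting flight; the formula is implemented as published and the residual
left visible rather than adjusted.

## Known limitations

* The detector is an envelope-threshold surrogate; highly overlapped calls
  (closer than ~2 ms) or calls within ~30 dB of a loud neighbour's envelope
  tail can be missed. On clean synthetic nights this affects well under 1 %
  of calls, at behavioural-state boundaries.
* Phase assignment samples the phase series at the nearest millisecond;
  at 13 Hz this contributes up to ~2.3° of quantisation.
* The level-vs-interval transition band is reported as the gap between the
  last faint and first loud occupied interval bins; with sparsely occupied
  bins the band can widen to the neighbouring bin edges.
* `flag_aerial()` infers flight from wingbeat amplitude alone; gliding
  (flight without flapping) would be labelled non-aerial.
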