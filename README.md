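# sonarwing

Analysis of vocal-locomotor coupling in echolocating bats from
sound-and-movement biologging tags.

Insect-hunting bats power their echolocation calls with the airflow of the
wingbeat cycle: while commuting or searching they emit one loud call per
one, two or three wingbeats, timed to the end of the upstroke, so their
sensory update rate is locked to their flight gait. In the final moments of
an aerial capture they override that coupling with a *buzz* — dozens of
faint calls at 4–14 ms intervals spread across the downstroke. `sonarwing`
implements the full analysis chain for quantifying this from tag data
(ultrasonic audio at 187.5 kHz plus heave accelerometry at 1000 Hz), and a
ground-truthed simulator so every stage is testable without field
recordings. It is written for movement-ecology and bioacoustics researchers
working with animal-borne tags.

## What it computes

* **Wingbeat kinematics** — delay-free 30 Hz FIR filtering, wingbeat-cycle
  detection at gravity crossings, and a continuous wingbeat phase
  $\phi \in [0, 360)$° defined so that the upstroke (0–180°) is exactly
  where heave acceleration is below 9.82 m s⁻²:
  $a_z(t) = 9.82 - A(t)\sin\phi(t)$.
* **Call detection and calibration** — 4-pole 10 kHz Butterworth high-pass,
  envelope-threshold detection, energy flux density over a −6 dB window,
  $\mathrm{EFD} = 10\log_{10}\big(\textstyle\sum p^2 \Delta t / (20\,\mu\mathrm{Pa})^2 \cdot 1\,\mathrm{s}\big)$,
  and the fixed calibration offsets: source EFD = apparent EFD + 14 dB
  (off-axis correction), RMS source level = source EFD + 25 dB (3 ms
  duration convention).
* **Behavioural segmentation** — interval classes (buzz II 4–7 ms, buzz I
  7–14 ms, …, one call per 1/2/3 wingbeats), buzz-terminated capture events
  (capture time = last buzz call), aerial-capture flags, 100 s commuting
  windows, and an automated approach-onset rule.
* **Coupling metrics** — per-call wingbeat phase, calls and summed call
  energy per wingbeat, capture-aligned series over the last ten wingbeats,
  circular phase statistics by interval class, and source level versus
  call interval.
* **Cross-species sensory flow** — updates per metre (rate/speed) and per
  body length travelled (rate·length/speed) for bats and toothed whales,
  and the allometric wingbeat frequency
  $f = 5.54 - 3.068\log_{10}(m\,[\mathrm{kg}]) - 2.857\log_{10}(v\,[\mathrm{m/s}])$.
* **Simulation** — seeded, ground-truthed tag recordings (accelerometer,
  audio, truth tables) with state-dependent wingbeat frequencies (6–13 Hz),
  phase-locked and interval-driven call schedules, and calibrated call
  levels.

## Worked example

Simulate a short foraging bout (commute, then three aerial captures) and
run the whole pipeline:

```r
library(sonarwing)

plan <- plan_foraging_night(n_captures = 3, commute_s = 15, seed = 42)
res  <- run_pipeline(plan = plan)
res
#> <tag_analysis>
#>   calls:    258
#>   cycles:   170
#>   captures: 3
#>   segments: 10

glance(res)
#>   n_calls n_cycles n_captures buzz_call_fraction median_phase_deg
#> 1     258      170          3             0.2248            174.5
#>   median_wb_freq_hz median_slow_sl_rms_db
#> 1                 7                 106.7
```

All 258 scheduled calls are detected; the bat beats its wings at 7 Hz, the
wingbeat-locked calls have a median RMS source level of ~107 dB re 20 µPa,
and the median call phase of ~175° sits at the end of the upstroke. (The
buzz-call fraction is high only because this toy bout is mostly buzzes; on
a night-length schedule it drops below 2 %.) The capture-aligned series
shows the decoupling signature — calls per wingbeat rise while the summed
energy per wingbeat falls toward the capture:

```r
tidy(res$alignment)[, c("wb_index", "mean_calls_per_wb", "mean_summed_efd_db")]
#>   wb_index mean_calls_per_wb mean_summed_efd_db
#>        -10               2.0               84.7
#>         -5               3.0               68.5
#>         -2               9.0               63.8
#>         -1               7.5               60.9

autoplot(res$alignment)       # Fig-style capture-aligned panel
autoplot(res$phase_hist)      # phase histograms by interval class
autoplot(res$level_interval)  # source level vs call interval
```

Cross-species arithmetic:

```r
update_metrics(species_profiles())
#>   species         updates_per_m_commute updates_per_bl_commute updates_per_bl_capture
#> 1 tagged_bat                       1                     0.077                   5.78
#> 2 sperm_whale                      1                    16                     200
#> 3 harbor_porpoise                 25                    37.5                   225
```

A searching bat gets one sensory update per metre flown — one per ten body
lengths — while a sperm whale searching at the same updates-per-metre gets
16 per body length, a >200-fold higher size-specific sampling rate.

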