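# svopsim

Simulation of threshold **saccadic vector optokinetic perimetry** (SVOP) —
visual-field testing in which perception of a stimulus is inferred from the
*vector* (direction and amplitude) of the subject's saccadic gaze response,
measured by an eye tracker, instead of a button press. The package is aimed
at visual psychophysicists and perimetry-algorithm developers who want a
fully inspectable, closed-loop model of such an instrument: every part of
the device that is normally hardware — the display, the tracker, and the
patient — is replaced by a testable simulation.

## What it implements

* **Test geometry and scale** — the 54-point 24-2 pattern (6° grid offset
  3° from the meridians, nasal edge at 27°, blind-spot pair flagged at
  (15°, ±3°)), and the SAP-matched perimetric decibel scale
  ΔL = (10,000/π)·10^(−dB/10) cd/m². The panel cannot display stimuli
  brighter than 14 dB (≈136.7 cd/m² including the 10 cd/m² background),
  which is why comparison thresholds are truncated at 14 dB.
* **Gaze-contingent projection** — exact flat-screen trigonometry placing
  each stimulus so it subtends the requested visual-field offset *at the
  current eye position*; head translations of ±100 mm laterally / ±150 mm
  in depth leave the subtended offset unchanged to <1e-6°. Includes a
  calibrated grey-level→luminance lookup-table model of the display.
* **Saccadic response classification** — fixation verification over a
  dwell window, velocity-plus-amplitude saccade detection, and the
  seen/unseen/invalid decision from the gaze vector (direction within 20°,
  amplitude within ±30%, 1-second unseen window by default).
* **Threshold engine** — per-location 4-2 bracketing staircases, four
  quadrant seed points at (±9°, ±9°), neighbour-propagated starting
  levels, on-screen eligibility (fixation-position dependent), and the
  v1/v2 behavioural variants (v2: 18 dB starting-level clamp, longer
  fixation dwell, waiting-time scheduling priority).
* **Synthetic observer** — hill-of-vision and glaucomatous ground-truth
  fields (nasal-step, Bjerrum-arcuate, advanced archetypes), cumulative-
  Gaussian frequency-of-seeing responses with false-positive/negative
  lapses, and 60 Hz gaze-stream synthesis with fixation jitter, saccade
  latency and landing noise, head drift and tracking dropout.
* **Analysis** — exclusion rules (incomplete gaze tests; button-response
  tests with >15% false positives), mean-sensitivity agreement,
  per-location Pearson correlation maps, test–retest repeatability, and a
  cohort driver that runs the whole validation pipeline end to end.

## A worked example

```r
library(svopsim)

pat   <- generate_pattern("24-2", "right")
set.seed(1)
truth <- make_glaucoma_field(pat, field_archetype("arcuate"))  # superior arc defect
obs   <- observer_model(truth, pat)          # default psychometric + tracker noise
sess  <- run_session(session_config(version = "v2", rng_seed = 1), obs)
sess
#> <svop_session> v2, complete, 250 presentations, 355 s
sess$field
#> <svop_field> 24-2 right eye (v2): 54/54 thresholds, complete
#>   duration: 355 s
mean_sensitivity(sess$field)     # 25.02 dB, vs 26.53 dB truth after 14 dB floor
```

The session is a genuine closed loop: each presentation synthesizes a gaze
stream from the observer model, classifies it from the saccade vector, and
feeds the decision to that location's staircase; a seen stimulus becomes
the next fixation target. The 250 presentations and 355 s above are what
the simulated test actually took; the ~1.5 dB gap to truth reflects the
2 dB bracketing quantisation plus psychometric noise. A button-response
comparator (`run_sap_like_session()`) runs the same engine without the
gaze layer, and `cohort_experiment()` drives simulated validation cohorts
through exclusions, agreement and repeatability reports.

A thin command-line wrapper is installed at
`inst/cli/svopsim.R` (subcommands `run`, `run-sap`, `make-observer`,
`cohort`, `analyze`), all of it a veneer over the functions above.

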