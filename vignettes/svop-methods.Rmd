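---
title: "Simulating gaze-driven threshold perimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gaze-driven threshold perimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svopsim)
```

## The instrument being modelled

Standard automated perimetry (SAP) maps differential light sensitivity
across the visual field: the subject fixates a central target and presses
a button when they perceive a brief peripheral stimulus. Saccadic vector
optokinetic perimetry (SVOP) replaces the button with an eye tracker.
Stimuli are drawn on a calibrated LCD panel; perception is inferred from
the *vector* of the gaze response — a saccade whose direction and
amplitude match the fixation-to-stimulus vector counts as "seen". Because
the tracker also reports the 3-D eye position, stimulus size and placement
are recomputed continuously for the actual head position, so no chin rest
is needed, and the fixation target simply becomes wherever the subject
last looked.

`svopsim` implements this instrument end to end as a simulation: the test
geometry and decibel scale, the gaze-contingent projection, the response
classifier, the 4-2 bracketing threshold engine, a synthetic
patient-plus-tracker ("observer"), and the agreement/repeatability
analyses used to validate such a device against SAP. Everything runs
closed-loop: the engine asks the observer model for gaze streams exactly
as a real device would ask a tracker.

## Test pattern and decibel scale

The 24-2 pattern has 54 locations on a 6° grid offset 3° from both
meridians, with the nasal edge of the two paracentral rows extended to
27°. The two points at (15°, ±3°) temporal straddle the physiologic blind
spot and are flagged; they are tested like any other location (their
sensitivity is genuinely zero, and their poor repeatability in real data
is an emergent behaviour, not a special case). Left-eye patterns are the
mirror image of right-eye patterns; fields are stored per eye and mirrored
only for display.

Perimetric decibels express attenuation of the conventional bowl-perimeter
maximum, a 10,000 apostilb (10,000/π ≈ 3183.1 cd/m²) increment:

$$\Delta L(\mathrm{dB}) = \frac{10{,}000}{\pi}\,10^{-\mathrm{dB}/10}
\quad [\mathrm{cd/m^2}]$$

The displayed stimulus rides on the 10 cd/m² background, so the brightest
displayable stimulus on the panel — 14 dB — has absolute luminance
`db_to_increment(14) + 10` ≈ 136.7 cd/m². This is why the instrument's
range is 14–40 dB and why comparison thresholds from a bowl perimeter are
truncated at 14 dB before any agreement statistic. Stimuli are Goldmann
III (≈0.43°, from the 4 mm² area at the 300 mm bowl radius; sizes
quadruple in area per step), 200 ms.

## Display geometry and head-position compensation

The screen is a flat panel (default 24″ 16:10, 518 × 324 mm) at z = 0;
the eye sits at (x, y, z) with z the perpendicular viewing distance
(nominal 550 mm). Angular positions use independent horizontal/vertical
(Fick-style) component angles, `atan((p - e)/z)` per axis. A stimulus
requested at offset (α, β) from the fixated point is placed where its
component angles exceed the fixation's by exactly (α, β) *for the current
eye pose*. The projection is exact trigonometry, no small-angle
approximation; the payoff is a testable contract — for any eye translation
(±100 mm laterally, ±150 mm in depth is what the tests sweep), the
re-projected stimulus subtends the requested offset to well below 1e-6°.
Circles are drawn; only the diameter (2·d·tan(θ/2) at the eye-to-point
distance d) is compensated, not the obliquity of the outline, since the
device the model follows gives no indication of ellipse correction.

The panel model carries a strictly increasing grey-to-luminance lookup
table (default: synthetic 10-bit gamma-2.2 table topping out just above
the 14 dB ceiling). Lookup is nearest-neighbour, so delivered error is at
most half the local quantisation step; requests above the table's top are
a gamut error — the physical cause of the 14 dB floor on measurable loss.

## Gaze classification

All tolerances are in degrees of visual angle and are evaluated through
the per-sample eye pose, never in raw millimetres.

* **Fixation check**: over the trailing dwell window (v1: 200 ms, v2:
  500 ms), every valid sample must lie within 2° of the target. If more
  than half the samples are invalid, the check reports a tracking-quality
  failure and the presentation is withheld.
* **Saccade detection**: inter-sample angular velocity above 100°/s at
  the 60 Hz sampling rate, *and* a movement amplitude of at least 2°
  (median pre-movement to median post-movement position). The amplitude
  criterion matters: 0.5° per-sample jitter produces >100°/s velocity
  spikes about 6% of the time at 60 Hz, and without it essentially every
  unseen trial would be misclassified. 2° sits well below the smallest
  possible stimulus offset in the 24-2 pattern (√(3²+3²) ≈ 4.24°).
  Landing is the componentwise median of the post-movement samples.
* **Decision**: *seen* iff a saccade lands inside the 1-second window
  with direction within 20° of the fixation→stimulus vector and amplitude
  within ±30%; *unseen* iff the window elapses with gaze held at
  fixation; anything else — tracking loss, a non-matching vector, gaze
  wandering off — is *invalid* and the presentation is retried. The 1 s
  unseen window is the device's stated value; the direction/amplitude/
  dwell tolerances are not published and are configurable defaults chosen
  to be loose enough for normal saccadic scatter and tight enough that a
  saccade to the wrong location can never count (the classifier's
  false-positive resistance is property-tested with random non-matching
  vectors). A corrective second saccade cannot rescue a hypometric first
  one: the decision is single-saccade.

## The 4-2 threshold engine

Each location runs a 4-2 bracketing staircase: 4 dB steps until the first
response reversal, 2 dB after, stopping at the second reversal with the
threshold taken as the last level seen (the classic full-threshold
convention; the stop-and-read-out rule is not published, and two reversals
is assumed). Levels clamp to [14, 40] dB; two consecutive unseen
responses at the 14 dB floor end the staircase there (recorded as 14 and
flagged unmeasurable if nothing was ever seen), and symmetrically at the
40 dB ceiling. The engine is verified against an independently written
brute-force replay of these rules over every response sequence to depth
12, and against a step-psychometric observer for every integer truth in
15–39 dB and every start in 18–30 dB (worst error: 1 dB — bracketing
quantisation is 2 dB).

Testing begins at four seed locations, one per quadrant at (±9°, ±9°),
started at 25 dB. A non-seed location becomes testable once a 4-neighbour
(6° along one axis) has finished, and starts at the rounded mean of its
finished neighbours' thresholds (nearest finished location if no
4-neighbour is done). Floor-censored (unmeasurable) results are excluded
from propagation unless nothing measurable has finished: a never-seen
14 dB is a censoring bound, not an estimate, and using it would bias the
start of every location adjacent to the blind spot about 1 dB low.
Version 2 additionally clamps every propagated start to ≥18 dB, so no
threshold can be decided from a single stimulus decision; v1 does not.

Scheduling is uniform-random among eligible locations with the session
seed; v2 adds a priority weight (default 0.05 per presentation waited)
that grows with time-in-queue, so chronically ineligible points — e.g.
superior-field points, which need screen area *above* the fixation point —
are pulled forward. Weight 0 reproduces v1 behaviour. A seen stimulus
becomes the next fixation target; unseen stimuli leave it in place. When
no location is eligible from the current fixation point, the engine shows
a re-centering fixation target at the screen position (searched on a
coarse 5×5 grid) that maximises the number of eligible locations — the
real device relocates fixation only on seen stimuli and publishes no
recovery rule, so some rule is required; this one is the package's
choice. Sessions end incomplete (never with an error) when fixation
checks or presentations fail more than `retry_budget` (default 40) times
consecutively.

`run_sap_like_session()` is the button-response comparator: the same
engine, seeds and propagation with the gaze layer removed, the observer's
frequency-of-seeing draw (including button false positives/negatives)
taken directly as the response. SITA-style Bayesian thresholding is
deliberately out of scope; the comparator isolates the gaze layer as the
experimental variable.

## The synthetic observer

The observer bundles a ground-truth sensitivity field with psychometric
and oculomotor noise:

* **Frequency of seeing**: p(seen) = fp + (1 − fp − fn)·Φ((t − level)/s),
  the standard cumulative-Gaussian perimetric model in dB; t is true
  sensitivity, s the slope (0 gives a deterministic step observer).
  Defaults: s = 2 dB, fp = fn = 0.03. The within-session variability of
  the modelled device is unpublished; these are stated assumptions, and
  the slope is configurable precisely because response variability grows
  in depressed regions.
* **Fields**: the normal "hill of vision" is peak − slope·eccentricity +
  N(0, 1 dB), defaults peak 31.5 dB and 0.08 dB/deg chosen so a healthy
  cohort's mean sensitivity lands in the 28–31 dB band typical of SAP
  normals; blind-spot points are 0 dB. Glaucoma archetypes superimpose a
  depression: a superior nasal step (early), a superior Bjerrum arc at
  9–21° eccentricity (arcuate, default depth 15 dB), or widespread loss
  sparing a 6° central island (advanced, 25 dB — deep enough that most
  points fall below the 14 dB display floor, as in advanced disease).
  Depressed truth may go below 14 dB; the floor applies only at
  measurement time.
* **Gaze synthesis**: 60 Hz streams; fixation-holding samples with
  angular jitter (default 0.3°, ≤0.5° being the tracker's quoted error in
  controlled conditions), slow head drift, saccade latency N(250, 50) ms,
  landing noise 0.5°, and tracking dropout (default 2%) marking samples
  invalid. With all noise at zero the synthesizer and classifier are
  exact inverses — the classifier recovers the intended decision on 100%
  of presentations, which is both a property test and the acceptance
  check for the closed loop.

## What the simulation does and does not show

Exact noiseless recovery is checked on a flat 29 dB field: 29 is
representable by the engine from the 25 dB seed start along every
propagation path, so the full loop (synthesis → classification → engine)
must return it exactly at all 52 non-blind-spot points. For arbitrary
fields even a noiseless 4-2 staircase is only accurate to its 2 dB
quantisation, and the estimate can shift by one final step when the
propagated starting level differs — which is also why two independent
noiseless sessions on the same observer are not bit-identical and
pointwise repeatability r of a noiseless cohort is high but not exactly 1.
With realistic noise (slope 2 dB, fp = fn = 3%, gaze noise 0.5°) the
median pointwise absolute error over 20 simulated observers is about
1.5 dB (the test bound is 3 dB).

The cohort driver reproduces the *machinery* of a validation study —
exclusions (incomplete gaze tests; button tests with >15% false
positives), 14 dB truncation before correlation, per-location Pearson maps
across subjects, repeat-pair repeatability — not its clinical numbers. A
simulated cohort is cleaner than recruited patients: no artefacts, no
fatigue or learning, archetypal defects, and a comparator that shares the
4-2 engine rather than being a SITA device. Agreement correlations from
the default cohort (r ≈ 0.99 on mean sensitivity) are therefore upper
bounds on what field data can show, and the package makes no claim that
they reproduce clinical values. Test durations are accumulated from
simulated event timestamps and are reported but never validated against
device times, which are hardware- and patient-dependent.

Problem sizes used by the shipped checks were chosen to keep the whole
suite interactive: depth-12 exhaustive staircase enumeration (16,384
sequences × 4 starts), 20 noisy observers for recovery, and a 24-observer
cohort (12 healthy, 12 glaucoma, half with repeats) for the analysis
pipeline. The repeat subset is stratified over both groups: a
healthy-only repeat cohort has so little between-subject variance
(~1 dB) that pointwise r would measure noise, not instrument
repeatability.

## Numerical conventions

* Starting-level means round half up (29.5 → 30), then clamp to [14, 40]
  (v2: ≥18).
* All angular math is exact trigonometry through the current eye pose;
  angular distances are Euclidean norms in component-angle space, an
  approximation below 1e-3° at the eccentricities involved.
* One RNG hierarchy: a master seed drives per-observer and per-session
  substreams (`sample.int(2^30)`), so any individual session can be
  re-run in isolation from its recorded seed; identical seeds give
  byte-identical sessions, streams and reports.
* Degenerate inputs: empty gaze streams classify as invalid; a fixation
  window with >50% dropout withholds the presentation rather than
  guessing; sessions that exhaust the retry budget return an incomplete
  result, never an exception; correlations over constant vectors are NA
  and excluded from summaries.

## A small worked example

```{r example, eval = FALSE}
pat <- generate_pattern("24-2", "right")
set.seed(1)
truth <- make_glaucoma_field(pat, field_archetype("arcuate"))
obs <- observer_model(truth, pat)
sess <- run_session(session_config(version = "v2", rng_seed = 1), obs)
sess$field
mean_sensitivity(sess$field)
```

Running the same two lines with `version = "v1"` shows the behavioural
differences: starts may fall below 18 dB, the dwell is shorter, and
scheduling has no waiting-time priority.
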