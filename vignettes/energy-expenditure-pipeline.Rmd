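---
title: "From raw acceleration to METs and device reliability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw acceleration to METs and device reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimets)
```

## The problem

Research-grade activity monitors (ActiGraph and similar) estimate
energy expenditure (EE) from tri-axial acceleration, but the vendor
pipelines are closed.  An open pipeline needs three reproducible stages:

1. **Counts** — convert raw acceleration (g) to the "activity counts"
   that published EE equations were calibrated against;
2. **METs** — evaluate published prediction equations on count epochs,
   optionally rescaled to an individual's resting metabolic rate;
3. **Reliability** — quantify whether two devices worn at the same site
   (or one device at two sites) deliver interchangeable EE estimates.

`actimets` implements all three, plus a seeded generator of synthetic
treadmill recordings shaped like the underlying protocol
(5 participants × 3 sensors × 2 configurations × 10 speeds from 1.4 to
10 km/h, 2-min bouts at 30 Hz), so that every stage can be exercised and
validated without access to recorded human data.

## Stage 1: activity counts

`counts_per_second()` implements the published ActiGraph count
replication of Brønd, Andersen & Arvidsson (2017), the same algorithm
distributed in the open `activityCounts` R package.  The chain, with all
constants embedded verbatim from that implementation
(see `count_constants()`):

1. resample to 30 Hz — linear interpolation on the timestamps; input
   already at exactly 30 Hz passes through untouched;
2. band-pass filter with the published 21-coefficient IIR (input gain
   0.965);
3. decimate to 10 Hz (every third sample);
4. clip at ±2.13 g; rectify;
5. dead-band: values below 0.068 g contribute nothing;
6. quantize: `floor(value / 0.0064)` count units;
7. sum each block of ten 10-Hz samples → integer counts per second.

Partial trailing seconds are discarded: counts are defined only on
complete 1-s windows.

**Filter initialization.**  The one place we deviate from a literal
transcription of the reference code: the IIR is started at the steady
state implied by the signal's first sample rather than at zero state.
With zero initial conditions, a device lying still at 1 g produces a
startup transient (up to ≈0.68 g after filtering) and one or two seconds
of spurious counts; with steady-state initialization a constant input
maps to an identically zero filter output, which is the behaviour a
band-pass filter is meant to deliver.  For any signal that starts at
0 g the two conventions are numerically identical, which is why our
frozen cross-implementation fixture (a 2-min, 2 Hz, 0.5 g sinusoid,
verified element-wise against an independent `scipy.signal`
implementation of the same published chain) is unaffected.

**Vector magnitude and epochs.**  `vector_magnitude_counts()` is the
per-second Euclidean norm of the three axes' counts — computed on
counts, not on raw samples.  `epoch_average()` turns a per-second series
covering a bout into counts/min (total ÷ bout minutes) or counts/10 s
(total ÷ 6 × bout minutes); for the default 2-min bout these are the ÷2
and ÷12 divisions.  `epoch_summary()` bundles the three aggregates the
equations need: `ac_vt_cpm`, `ac_vm_cpm`, `ac_vt_c10s`, with
`ac_vt_c10s == ac_vt_cpm / 6` by construction.

**Vertical axis.**  Which physical axis is "vertical" depends on how the
device is strapped to the wrist or thigh and cannot be inferred from the
data; it is therefore explicit configuration (`vertical_axis` in the
pipeline config, per placement).  The default maps both placements to
`y`, the axis that carries gravity in the synthetic generator.

## Stage 2: MET equations

Five published equations are evaluated (`met_*()`, all vectorized), each
on its calibrated count channel:

| equation | input | form |
|---|---|---|
| Freedson et al. 1998 | VT counts/min | `1.439008 + 7.95e-4·AC` |
| Crouter et al. 2010 (walk/run) | VT counts/10 s | `2.294275·exp(8.4679e-5·AC′)` |
| Santos-Lozano et al. 2013 VT (adults) | VT counts/min | `3.4002 + 5.3e-4·AC − 5.564e-2·BM + 1.2789·G` |
| Santos-Lozano et al. 2013 VM (adults) | VM counts/min | `2.8323 + 5.4e-4·AC − 5.912e-2·BM + 1.4410·G` |
| Sasaki et al. 2011 | VM counts/min | `8.63e-4·AC + 0.668876` |

`BM` is body mass in kg; `G` is the gender code, entered as the raw
integer **1 = female, 2 = male** (not a 0/1 dummy).  Two notes on the
Crouter model: it is implemented in exponential form, with the rate
constant inside `exp()` applied to the counts — at zero counts it
returns its resting coefficient 2.294275 METs, which is what a MET
equation must do.  The default rate constant is much smaller in
magnitude than the walking/running regression printed in Crouter et
al.'s own two-regression paper; we deliberately evaluate only this
single branch (no walk/run vs lifestyle branching), and the constant is
a plain function of the code should a user wish to adapt it.  The
linear equations can predict METs below zero for heavy participants at
very low counts; `compute_all()` keeps those values (they carry
information for the reliability analysis, which is shift- and
scale-tolerant) and assigns them an `NA` intensity.

**Individual correction.**  Published METs assume a resting oxygen
uptake of 3.5 mL·kg⁻¹·min⁻¹.  `corrected_mets()` rescales to an
individualized resting rate predicted by the Harris–Benedict equations
(kcal/day; `harris_benedict()`, female intercept 655.0955, male
66.4730).  The conversion chain is pure dimensional analysis:

```
RMR [mL O2/kg/min] = HB [kcal/day] × 1000 [mL/L] / (1440 [min/day] × 5 [kcal/L O2] × BM [kg])
corrected METs     = METs × 3.5 / RMR
```

A person whose predicted RMR is exactly 3.5 is the fixed point of the
correction; for everyone else it is a participant-specific multiplicative
factor, constant across counts.  Height is stored in metres and
multiplied by 100 inside the equations; users whose data is already in
centimetres pass `height_unit = "cm"`.

**Intensity.**  `classify_intensity()` uses half-open bins
`[0, 1.5)` light, `[1.5, 3)` moderate, `[3, 6)` vigorous, `≥ 6` very
vigorous.  The conventional cut-point statement ("< 6" vigorous,
"> 6" very vigorous) leaves exactly 6.0 unassigned; we assign it upward,
consistent with the other boundaries.

```{r equations}
met_freedson1998(c(0, 1000, 2000))
corrected_mets(5, age = 30, body_mass = 60, height = 1.65, gender_code = 1)
classify_intensity(c(1.0, 3.0, 6.0))
```

## Stage 3: reliability

`icc_two_way_mixed()` computes the two-way mixed, consistency-type ICC
from the mean squares of the subjects × raters ANOVA decomposition:

```
ICC(3,1) = (MS_subjects − MS_error) / (MS_subjects + (k−1)·MS_error)   # single measure
ICC(3,k) = (MS_subjects − MS_error) / MS_subjects                      # average measure
```

where `MS_error` is the residual (subject × rater interaction) mean
square.  Consistency ICC ignores systematic rater offsets — a constant
bias between two devices does not reduce it — and can be negative when
within-pair disagreement exceeds between-subject spread; negative
estimates are reported as computed, never truncated.  Both forms are
returned; table writers default to the single-measure form
(`icc_form` config), and we deliberately assert nothing about which
form any published table used.  No p-values or confidence intervals are
emitted by default; `conf_level` adds an F-distribution interval for the
single-measure form.

`cronbach_alpha_standardized()` is `k·r̄ / (1 + (k−1)·r̄)` with `r̄` the
mean pairwise **Pearson** correlation among the rater columns
("standardized items" conventionally means correlation-based alpha).
For k = 2 raters with variance-matched columns it coincides exactly with
the average-measure consistency ICC.

`agreement_table()` produces the headline speed × equation summary: ten
speed rows plus a `MEAN` row of arithmetic column means, one ICC column
per equation (five plain + five corrected) and one standardized-alpha
column per speed.  A single alpha per speed must aggregate over ten
equation scales somehow; we compute it from the mean over equations of
the between-rater Pearson correlation at that speed.  Pairing units are
participant × configuration.  Under the protocol's design the SensorID
sits at a given placement in only one configuration, so the
device-at-placement contrast has n = 5 paired bouts per speed, while
the placement contrast (ActiGraph wrist vs thigh) has n = 10.  Units
missing one rater are dropped listwise and reported in the `skipped`
attribute and the pipeline's skipped-records CSV.

## The synthetic generator

`gait_model()` + `simulate_bout()` model a treadmill bout as

```
a(t) = 1 g (gravity axis) + Σ_h A·g_axis·0.5^(h−1)·sin(2π·f·h·t + φ_h) + ε(t)
```

a harmonic series at the step frequency plus Gaussian white sensor
noise, clipped (with a warning) at the device's dynamic range (±8 g
ActiGraph, ±16 g SensorID).  Default maps, chosen once as plausible
gait-like settings and documented as configuration rather than
biomechanical claims:

* step frequency linear in speed, 1.0 Hz at 1.4 km/h → 2.0 Hz at
  10 km/h.  The cap sits deliberately below the upper edge of the count
  filter's passband: the filter's measured gain falls off sharply and
  ripples above ≈2 Hz, and a fundamental pushed to 2.5 Hz would make
  total counts *decrease* over the last speed steps, destroying the
  monotone speed→counts relationship the generator is meant to provide;
* dynamic amplitude linear in speed, 0.05 g → 1.2 g, with per-axis
  gains (0.6, 1.0, 0.3) and 3 harmonics;
* device noise SD 0.01 g (ActiGraph) / 0.02 g (SensorID);
* between-subject variability: a shared log-normal amplitude multiplier
  (SD 0.15 on the log scale) plus an independent per-placement
  multiplier (SD 0.10), and wrist amplitudes scaled by 0.8 relative to
  the thigh.  The shared component is what gives the device contrast its
  between-subject variance; the placement-specific component is what
  makes the placement contrast genuinely weaker than the device
  contrast, qualitatively matching what wear-site comparisons show.

`simulate_paired_devices()` evaluates **one** motion realization
(identical harmonic phases) on each device's time grid and adds
independent device noise afterwards — with zero noise and equal rates
the two traces are bit-identical.  `simulate_study()` enumerates the
full design; record ids follow
`t{participant}{configuration}{sensor}{speed_index}` with speed index
0–9 (so `t2130` is participant 2, configuration 1, sensor slot 3 —
the SensorID — at 1.4 km/h).  The default data-cleaning list
`default_exclusions()` removes four such records, taking the default
300-record, 600-min design to 296 records.  RNG streams are derived
hierarchically (study seed → per-record seed), so a record's realization
is stable when unrelated parts of the design change, and everything is
byte-reproducible from the design seed.

**What the generator does *not* emulate.**  Real gait is not a
3-harmonic sinusoid: no stride-to-stride timing variability, no impact
transients, no posture changes, no autocorrelated or heavy-tailed sensor
noise, no axis cross-talk from strap wobble, and the absolute count
magnitudes are not calibrated to human recordings (simulated counts per
minute run well above typical hip-worn values at matched speeds, so the
resulting METs are high).  Passing tests therefore demonstrate that the
pipeline's *mechanics* are correct — counts respond monotonically to
amplitude, variance components propagate into ICC as theory predicts,
the full chain is deterministic — not that any equation is accurate on
real data, which only a calorimetry comparison could show.

## Numerical choices and degenerate inputs

* Resampling is linear interpolation; clock jitter is tolerated, but
  non-monotone timestamps are a hard error naming the first offending
  row, and unparseable CSV values are errors, never silently dropped.
* Quantization uses `floor`, matching the reference chain; counts are
  exact integers, so cross-run comparisons can use `identical()`.
* `epoch_average()` errors when the series is shorter than the declared
  bout rather than padding or rescaling.
* ICC on an all-constant matrix is a degenerate-input error (zero total
  variance), as is a zero-variance rater column for alpha; fewer than 3
  subjects or 2 raters is a data error.
* The intensity boundary 6.0 goes to `very_vigorous`; negative METs are
  a domain error for `classify_intensity()` and an `NA` intensity inside
  `compute_all()`.

## Validation problem sizes

The shipped test-suite experiments use: the full default 300-record
design for bookkeeping and determinism checks; 10×2 matrices (25
replicates) for the ICC-vs-ANOVA oracle; n = 10 000 paired normals for
the null-ICC check; n = 200 subjects for variance-component recovery
(tolerance ±0.05) and for the three-point device-noise grid run through
the complete signal → counts → METs chain with 1-min bouts.  These sizes
were chosen to make sampling noise comfortably smaller than the
tolerances being asserted.

## Limitations

Counts are produced by a published replication of the vendor algorithm,
not by vendor firmware; agreement with a physical ActiGraph is bounded
by that replication's published accuracy.  The equations are evaluated
exactly as specified above, including a Crouter rate constant whose
provenance differs from the original two-regression publication.  The
reliability analysis quantifies *consistency* between paired sensors; it
says nothing about accuracy against indirect calorimetry, which this
package does not model.
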