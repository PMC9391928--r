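---
title: "Monitoring airborne starch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring airborne starch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerostarch)
```

## The problem

Starch granules released by grain handling (storage towers, ports, mills)
form intermittent clouds of coarse bioaerosol. A single-particle laser
spectrometer co-located with a Hirst-type volumetric trap can resolve
these clouds at one-minute resolution, but turning raw particle events
into a statement like "the storage towers 2.5 km north are the source"
requires a chain of steps: classify each >8 µm particle from its optical
signals, convert classified counts to number concentrations, calibrate the
device against the reference trap, find emission episodes, condition wind
roses on high-starch hours, and check with a transport model that
source-to-sampler travel is physically plausible. `aerostarch` implements
that chain as one seeded, testable pipeline, driven by a synthetic
campaign generator so that every stage runs and can be validated without
access to any instrument archive.

## The synthetic campaign generator

All parameter-recovery claims in this package are claims about data from
`generate_campaign()`, so its assumptions matter.

* **Particle signals.** Each class (starch, two pollen-like confusers,
  "other" by default) has a mean matrix per modality — a scattering image
  (24×40), a fluorescence spectrum (32×8) and a fluorescence lifetime
  (4×64) by default; all dimensions are configurable because instrument
  layouts differ. Class means are sums of a few smooth random bumps,
  seeded and checked for a minimum pairwise L2 separation. Events are the
  class mean plus additive Gaussian noise (sd 0.25 against peak
  amplitudes near 1) with lognormal optical diameters (starch: median
  12 µm, log-sd 0.25, so ~5% of granules fall under the 8 µm gate).
* **Emission and detection.** True emission is a Poisson count per minute
  (default: one 30-minute episode every 4 hours at 20 granules/min —
  deliberately shorter than an hour, matching the sudden-rise
  sudden-fall episode structure of field data). The device detects each
  true granule independently with probability `1/true_scaling_factor`
  (default 1/4.53), which makes the sum-ratio calibration estimator
  statistically correct on this data. The reference sampler reports the
  true hourly concentration times unbiased gamma noise (CV 0.1).
* **Wind.** A 10 Hz u/v record. During episode hours the direction is the
  planted source bearing plus one N(0, 15°) draw per hour; outside
  episodes it is uniform on [0, 360) — a neutral null for the wind-rose
  conditioning. Speeds are lognormal around 3 m/s.

What the generator does **not** emulate: correlated instrument drift,
polydisperse signal-shape dependence on diameter, mixed particle classes
within a minute whose proportions drift, calm spells, diurnal wind cycles,
or precipitation scavenging. Passing recovery tests on this data shows the
estimators are implemented correctly and are consistent under the stated
noise model; it does not certify accuracy on real instrument records,
whose class overlap is far stronger (field classification accuracies are
typically tens of percentage points lower than on clean synthetic sets).

## The classifier

The classifier is a multi-input convolutional network: one stack of
(2-D valid convolution → ReLU → 2×2 max-pool) blocks per signal modality,
features concatenated across modalities, inverted dropout (rate 0.2), one
fully connected ReLU layer (width 32) and a K-way softmax. It is trained
with minibatch Adam (batch 64, learning rate 1e-3, 15 epochs by default)
on the cross-entropy, after per-modality global standardization computed
on the training events. With the default one-block, four-channel
configuration the model has ~37k parameters and trains in well under a
minute on one CPU core for 2,000 events.

Design choices made where the architecture sketch left freedom:

* Batch normalization is omitted: at this parameter scale it buys nothing
  and costs determinism bookkeeping; the default architecture instead
  standardizes inputs once.
* The 90/10 split is stratified across **all** classes, not only starch;
  stratification is the natural extension and keeps per-class validation
  counts stable.
* Ties in the argmax resolve to the lowest class index, so predictions
  are deterministic.
* Optimizer, loss, epochs and batch size are not dictated by the
  monitoring problem; they are configuration with the defaults above.
* No class reweighting: the generator produces balanced training sets.

Training is deterministic given the seed and a fixed BLAS thread count:
initialization, the split, shuffling and dropout all draw from one seeded
stream, and `set.seed` state is restored afterwards.

## Concentrations, calibration, episodes

Counts become concentrations through the sampled volume:
`C = n / (flow × window / 1000)` m⁻³, so 20 classified starch events in
one minute at 2.8 L/min is 7,143 granules m⁻³. Hourly values are the
volume-weighted minute mean (equal to the plain mean at constant flow); a
partial trailing hour is dropped, with a message.

Calibration against the reference sampler is the sum-ratio estimator
`S = Σ reference / Σ device` over a declared set of calibration hours
(the field procedure used four selected days). Validation is the Pearson
correlation between the scaled device series and the reference over hours
**disjoint** from the calibration set — the disjointness is enforced, and
the p-value is reported but never used as a gate. On default 240-hour
campaigns the planted factor 4.53 is recovered within a few percent; the
end-to-end pipeline estimate runs slightly high because the >8 µm gate
removes a tail of true starch detections before counting (partly offset
by classifier false positives) — both the raw and scaled series are
therefore kept in the report.

Episodes are maximal runs of minutes strictly above a threshold, reported
with start, duration and peak. Mass concentration assumes spherical
granules: `M = N (π/6) d³ ρ` with density 1.5 g cm⁻³ and diameter 10 µm
by default, giving 0.008 mg m⁻³ at 10,000 granules m⁻³ (one significant
figure). Displayed concentrations are rounded to whole granules m⁻³;
internal values are never rounded. Whether a field peak value was scaled
by S before printing is ambiguous in the source material; this pipeline
applies scaling **after** aggregation and reports both series, asserting
neither reading.

## Wind and source attribution

u is eastward, v northward; the meteorological direction is the bearing
the wind blows *from*: `(270 − atan2(v, u)·180/π) mod 360`, so (0, −1)
is a northerly. Hourly direction uses the speed-weighted vector mean
(transport-relevant; unit-vector averaging would up-weight light air).
Hours with mean speed below 0.1 m/s are calm and excluded from roses.
Roses use 16 sectors of 22.5° centred on the compass points, matching the
compound directions (N-NNE, S-SSE, …) used in source surveys. The
conditioning rule is strictly more than 2 device starch counts per hour;
the time base of that rule is not standardized, and per-hour raw counts
were chosen and documented. The bearing estimate is the modal sector plus
the circular mean of contributing hourly directions; on default campaigns
the planted bearing is recovered well within half a sector (±11.25°).

## The dispersion stand-in

The transport check is a deliberately simplified Lagrangian Gaussian-puff
model, not a CALPUFF replacement: no terrain, buildings, stability
classes or three-dimensional meteorological fields. A point source at
1.5 m height with 1 m radius emits 1 g/s; each release interval (10 s)
spawns one puff whose mass is split across equal-mass bins of a lognormal
size distribution (GMD 10 µm, GSD 4 — the GSD is treated as
dimensionless, per the lognormal convention, where the source material's
"µm" unit is presumed a typo). Each bin settles at its Stokes velocity
`ρ g d²/(18 µ)` (guarded to d ≤ 100 µm); a bin deposits when its centroid
reaches the ground, so emitted mass equals airborne plus deposited mass
to machine precision at every step. Spreads grow linearly with travel
distance (σ_h = 0.1·s, σ_z = 0.05·s, plus the source radius) — chosen
over Pasquill classes for transparency; both coefficients are arguments.
Fields are sums of mass-normalized 3-D Gaussian kernels with ground
reflection, evaluated at receptor height. With a steady 5 m/s northerly
the plume centroid reaches the 2.5 km source-to-sampler distance after
exactly 500 s, and the receptor series shows the corresponding delayed
onset; because σ grows with distance, the concentration peak at the
receptor arrives within one time step of the advective travel time.

## Numerical and testing choices

* Degenerate inputs: a campaign with no emission runs end to end — the
  scaling factor is reported as `NA` (the sum-ratio is undefined on an
  all-zero device series), the episode table and rose are empty.
* Angles are folded into [0, 360) with a 1e-9-degree guard so circular
  means of wrap-around inputs (350°, 10°) return 0 rather than 360.
* Equal-mass size binning uses probability-midpoint quantiles, so the
  middle bin of an odd split sits exactly at the GMD and fractions sum to
  1 by construction; GSD = 1 collapses to a single bin.
* The event container is a plain-text directory (JSON sidecar + CSV
  matrices, numbers printed as `%.17g`) so round-trips are bit-exact and
  every artifact in a run is human-inspectable.
* Problem sizes in the test suite are the package's reference study
  conditions where the claim depends on them (240-hour campaigns,
  20 seeds, 500 events/class for classifier recovery) and reduced,
  seeded miniatures (12×16-pixel signals, 4-hour campaigns) where the
  property under test is scale-free.

## Known limitations

Classifier accuracies on synthetic data say nothing quantitative about
field accuracy; the calibration estimator assumes detection efficiency is
constant in time; the wind generator has no serial correlation beyond the
hourly episodic direction; the puff model's linear spread overestimates
near-source dilution relative to stability-resolved schemes; and the
pipeline treats the source bearing as static, whereas real attribution
must contend with multiple sources and intermittent emission activity.
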