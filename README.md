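# aerostarch

Quantifying airborne starch with a single-particle laser spectrometer —
from raw multi-modal particle events to calibrated concentrations, source
bearings and a transport check — as one seeded, fully tested R pipeline.

Grain handling (storage towers, ports, mills) intermittently releases
clouds of coarse starch granules. A laser spectrometer records, for every
particle > 8 µm in optical diameter, a scattering image, a fluorescence
spectrum and a fluorescence lifetime matrix at one-minute resolution; a
co-located Hirst-type volumetric trap (10 L min⁻¹, tape drum at
2 mm h⁻¹, 2 mm of tape per hour) provides the reference hourly record.
The package is aimed at aerobiologists and air-quality researchers who
want this analysis chain reproducible end to end:

1. **Synthetic campaign generator** — seeded particle events with
   class-separable signals, sub-hour Poisson emission episodes tied to a
   planted source bearing, a noisy reference sampler with a planted
   scaling factor, and a 10 Hz u/v wind record
   (`generate_class_templates`, `generate_particle_events`,
   `generate_campaign`).
2. **Multi-input CNN classifier** — one convolutional stack per signal
   modality, features concatenated, K-way softmax; written in base R
   (im2col convolution, backprop, Adam), trained on a stratified 90/10
   split (`build_model`, `train_classifier`, `predict`, `evaluate`).
3. **Concentrations and calibration** — counts to granules m⁻³ via
   `C = n/(flow·window/1000)`; hourly aggregation; the sum-ratio
   calibration `S = Σ reference / Σ device` over declared calibration
   hours with Pearson validation on disjoint hours; episode detection;
   mass concentration `M = N(π/6)d³ρ` for 10 µm spheres at 1.5 g cm⁻³.
4. **Wind-rose source attribution** — meteorological direction
   `(270 − atan2(v,u)·180/π) mod 360`, speed-weighted hourly vector
   averages, 16-sector roses conditioned on hours with more than 2
   device starch counts, modal sector + circular-mean bearing.
5. **Gaussian-puff dispersion stand-in** — lognormal size bins
   (GMD 10 µm, GSD 4), Stokes settling, linear-in-distance spread,
   ground reflection, exact air/ground mass bookkeeping.

`run_all()` chains every stage under one master seed and writes a
restartable set of stage outputs plus a summary JSON.

## Worked example

A 48-hour synthetic campaign with the default study conditions (four
classes, 30-minute episodes every 4 h, planted scaling factor 4.53,
planted source bearing 0° = north):

```r
library(aerostarch)
cfg <- scenario_config(duration_hours = 48, master_seed = 11)
tpl <- generate_class_templates(cfg$classes, cfg$signal_dims,
                                seed = cfg$class_template_seed)

## train the classifier on a labelled set
batch <- generate_particle_events(cfg, tpl, n_per_class = 250)
model <- build_model(classifier_config(cfg$classes, seed = 2), cfg$signal_dims)
tr <- train_classifier(model, batch)
tr$report
#> <train_report: 15 epochs, loss 0.4110 -> 0.0001, 900 train / 100 validation, accuracy 1.000>

## classify the campaign and calibrate against the reference sampler
camp  <- generate_campaign(cfg, tpl)
gated <- filter_by_diameter(camp$events, 8)          # the > 8 um gate
pred  <- predict(tr$model, gated)
n_min <- cfg$duration_hours * 60
counts <- minute_counts(gated$timestamps, pred$labels, n_min)
minute <- concentration_series(0:(n_min - 1),
                               counts_to_concentration(counts, 2.8, 1))
hourly <- aggregate_hourly(minute)
calibrate_concentrations(camp$reference$concentration_m3, hourly$values,
                         calibration_bins = 1:12)
#> <calibration: S = 4.636 over 12 bins; validation r = 0.988 (p = 3.4e-29, n = 36)>

## attribute the source from high-starch hours
hc <- as.vector(rowsum(counts, (seq_len(n_min) - 1L) %/% 60L))
rose <- build_wind_rose(hourly_vector_average(camp$wind),
                        select_high_starch_hours(hc, 2))
estimate_source_bearing(rose)
#> $modal_sector
#> [1] "N"
#> $circular_mean_deg
#> [1] 359.6825
```

The classifier separates the synthetic classes perfectly (validation
accuracy 1.000 — synthetic classes are far cleaner than field data); the
recovered scaling factor 4.636 sits a few percent above the planted 4.53
because the size gate removes a tail of true starch detections before
counting; and the circular-mean bearing 359.7° recovers the planted
northerly source to within a third of a degree. Classic worked values:

```r
round(counts_to_concentration(20, 2.8, 1))   # 7143 granules/m3 peak minute
signif(mass_concentration(10000), 1)         # 0.008 mg/m3
tape_length_for_duration(2, 24)              # 48 mm of tape per day
```

A transport check with `run_dispersion()` (steady 5 m s⁻¹ northerly,
point source 1 g s⁻¹ at 1.5 m) puts the plume centroid 2,500 m downwind
after 500 s — the source-to-sampler distance — with emitted mass equal to
airborne plus deposited mass to machine precision.

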