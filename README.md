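# antwatch

Automated quantification of red wood ant (*Formica rufa* group) activity
on a mound top, from fixed dual-sensor camera frames: a color sensor by
day, a near-infrared sensor with active illumination by night.

Red wood ant mounds sit preferentially on tectonically active,
gas-permeable faults, which makes a continuously monitored colony an
interesting long-term biosensor. This package is for researchers running
such monitoring stations: it turns a timestamped frame stream into a
calibrated scalar activity index, relates that index to an earthquake
catalog, and analyzes the spatial alignment of mound positions. Because
no public video archive exists, the package also ships a ground-truthed
synthetic scene generator, so every stage of the measurement chain is
testable offline.

## The method

At a cadence of one frame every Δt = 10 s, the raw activity index is a
masked, noise-thresholded frame difference. With D<sub>uv</sub>(t) =
|I<sub>uv</sub>(t) − I<sub>uv</sub>(t − Δt)|,

&nbsp;&nbsp;&nbsp;&nbsp;A(t) = Σ<sub>(u,v) ∈ M</sub> D<sub>uv</sub>(t) · [D<sub>uv</sub>(t) > 3σ],

where M is a binary mask covering the visible mound top and σ is the
per-sensor-mode pixel noise (MAD scale of inter-frame differences outside
the mask). Before differencing, each frame is registered onto its
predecessor by the integer translation maximizing the mean normalized
cross-correlation over interest points detected outside the mask
(compensating wind-induced camera sway). The raw index is then calibrated
onto the eight-level manual activity scale C(t) ∈ {0..7} used by human
operators — a first-order polynomial p<sub>d</sub> for the day stream, a
second-order polynomial p<sub>n</sub> for the night stream, fitted by
least squares over 2–3-week windows — and smoothed with a 10-minute
temporal median filter. Catalog utilities select earthquakes by
great-circle distance and a strict magnitude bound, extract event-locked
index windows, and flag nights whose mean index departs from a reference
baseline by more than 3 between-night standard deviations. A Hough
transform over axial azimuths summarizes preferential mound alignment
directions as circular-statistics modes (mean ± 1 SD, degrees from N).

See `vignettes/antwatch-methods.Rmd` for the full account of the model,
parameter defaults, and design decisions.

## Worked example

One synthetic day, compressed to a 60-s cadence (1,440 frames of
64×48 px), pushed through the full chain:

```r
library(antwatch)

prof  <- generate_daily_profile("M_shaped", cadence = 60)
sc    <- scene_config(n_frames = 1440, cadence = 60, n_ants = prof, seed = 1)
scene <- generate_video(sc)
scene$sequence
#> <frame_sequence> 1440 frames (48x64 px), cadence 60s
#>   modes: day=840 night=600 | dropouts: 0

series <- compute_activity_series(scene$sequence, scene$mask)
attr(series, "sigma")
#>    day  night
#> 2.9652 2.9652

win   <- schedule_manual_windows(as.Date("2010-06-01"))   # 144 windows
ann   <- generate_operator_scores(truth_categories(prof, win), seed = 2)
pairs <- pair_samples(series, ann, window_seconds = 60)
model <- fit_calibration(pairs$S_d, pairs$S_n)
model
#> <calibration_model> p_d: -0.194853 + 0.000343412*A (rms 0.553, n=83)
#>                     p_n: 0.0373802 + -0.000728239*A + 3.61778e-07*A^2 (rms 0.130, n=58)

filt <- median_filter_series(calibrate_series(model, series))
count_profile_peaks(filt, bin_minutes = 60, from_hour = 6, to_hour = 20)
#> [1] 2
```

The estimated noise scale 2.97 reflects the generator's sensor noise (sd
2 per frame, hence scale 2√2 ≈ 2.83 for a difference of two frames). The
calibration maps raw difference sums of a few thousand onto the 0–7
category scale with sub-category residuals (day RMS 0.55, night RMS
0.13), and the filtered daytime curve shows exactly the two peaks —
midday and late afternoon — that were injected. The recovered index
tracks the ground-truth ant count with Spearman rank correlation 0.948.

Catalog utilities work the same way on the bundled regional fixtures:

```r
cat1 <- read_catalog(catalog_fixture("neuwied_m2_2009_2012"))
nrow(filter_events(cat1, station = c(7.40, 50.35),
                   radius_km = 100, min_magnitude = 2.0))
#> [1] 10
```

A thin command-line front-end over the same functions lives at
`inst/cli/antwatch.R` (subcommands `synth`, `activity`, `calibrate`,
`correlate`, `lineament`, `run-all`, driven by one JSON config; see
`?run_pipeline`).

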