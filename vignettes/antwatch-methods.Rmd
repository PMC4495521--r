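---
title: "Quantifying mound-top ant activity from dual-sensor video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mound-top ant activity from dual-sensor video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antwatch)
```

## The monitoring problem

Red wood ants (*Formica rufa* group) build stationary mounds, often along
tectonically active, gas-permeable faults, which makes their colonies
attractive long-term biosensors: a fixed camera pointed at a mound top can
record the colony's activity around the clock for years. The analysis
problem is to turn such a video archive into a defensible scalar activity
index per time step — comparable to what trained human observers would
score — and then to relate that index to external event catalogs
(earthquakes) and to the spatial arrangement of mounds.

Two sensors alternate at the camera: a color sensor by day and a
near-infrared sensor with active illumination by night. The two produce
systematically different images (by night, chlorophyll-bearing grass is
bright and ants are small dark spots; by day the contrast sign flips), so
everything downstream treats the day and night streams separately.

## The activity index

At the analysis cadence of one frame every $\Delta t = 10$ s, the raw
index is a masked, noise-thresholded frame difference. For pixel $(u, v)$
at time $t$,

$$D_{uv}(t) = \lvert I_{uv}(t) - I_{uv}(t - \Delta t) \rvert,$$

and the raw activity is the sum of difference intensities that exceed
three times the pixel noise $\sigma$, over the mound region $M$ only:

$$A(t) = \sum_{(u,v) \in M} D_{uv}(t) \, [D_{uv}(t) > 3\sigma].$$

Moving ants are only a few pixels, so the well-known partial-visibility
weakness of plain frame differencing (large objects leaving ghosts) does
not arise; no background model is needed. The sum is kept as an exact
integer of 8-bit differences so tests can assert it bit-exactly. A count
mode (number of suprathreshold pixels instead of their intensity sum)
exists but is off by default: the index is defined as an intensity sum.

Three supporting choices had to be made explicit because the procedure
leaves them open:

* **Noise scale.** $\sigma$ is estimated per sensor mode as the robust MAD
  scale $1.4826 \cdot \mathrm{median}(|D|)$ of registered inter-frame
  differences over pixels *outside* the mask — the best available
  motion-free territory — pooled over up to 50 same-mode frame pairs. The
  threshold test is strict ($D > 3\sigma$), so noiseless synthetic input
  ($\sigma = 0$) admits every nonzero difference and zero-noise tests stay
  exact.
* **Registration.** Wind sways the camera slightly, so before
  differencing, each frame is registered onto its predecessor with a pure
  translation that maximizes the mean normalized cross-correlation of
  patches around interest points (local maxima of the gradient magnitude),
  detected outside the mound mask so that ant motion cannot bias the
  camera-motion estimate. Shifts are integer pixels by default — at 8-bit
  resolution sub-pixel warping buys little and integer shifts keep tests
  exact; an optional parabolic refinement of the correlation peak is
  available. A registration whose peak score falls below 0.5, or which is
  supported by fewer than 5 points, is treated as failed: the frame keeps
  its place in the time base with shift (0, 0) and the derived sample is
  flagged. Inside `compute_activity_series()` the search radius defaults
  to 5 px, which generously covers frame-to-frame sway; the single-pair
  `register_frame()` default stays at 10 px for exploratory use.
* **Sensor boundaries.** No sample is computed across a day/night sensor
  switch (the two sensors' images differ systematically), and gaps longer
  than 3 cadences are treated as dropouts that likewise yield no sample.

## Calibration against manual categories

Human operators scored one-minute windows every 10 minutes — 144 scores
per 24-h day — on eight categories: 0 (no ants on the mound top) through 6
(crowded top), plus 7 for sunbathing, a special early-spring state. Three
independent operators scored each window; the consensus $C(t)$ is their
rounded mean. The rounding rule is half-up (a tie rule had to be fixed;
means of three integers never land exactly on .5, but the rule is still
stated so the implementation is unambiguous). Category 7 is treated as an
ordinary numeric level in the regression; nothing in the data dictates a
special ordinal position for it, and this is a documented open point.

Raw activity and consensus categories meet through per-window pairing:
each annotation window contributes one pair $(\tilde A, C)$, where
$\tilde A$ is the *median* raw activity of unflagged samples inside the
window. The median is robust against occasional unregistered outliers; a
window with no usable samples contributes nothing. Each pair is assigned
to the daytime set $S_d$ or night-time set $S_n$ by the majority sensor
mode of its samples (ties toward day).

Calibration fits, by least squares (minimizing the root-mean-squared
difference between $C(t)$ and the polynomial of $A(t)$):

* $p_d$, a **first-order** polynomial, to $S_d$, and
* $p_n$, a **second-order** polynomial, to $S_n$,

over fit windows of about 2–3 weeks. The calibrated index
$p_{\mathrm{mode}}(A(t))$ is clamped to $[0, 7]$ and left continuous — it
is compared against, not snapped to, the integer manual curve. A 10-minute
temporal median filter (a centered ±5-minute window, truncated at series
edges) suppresses residual image-noise spikes. The night-time index is
known to be the weaker of the two — nocturnal brightness changes of the
mound material can bias it — and no correction for that effect is
implemented because none is defined.

## Earthquake-catalog correlation

Catalogs are plain CSVs (epicenter label, ISO date, UTC origin time with
fractional seconds, focal depth with a manual-determination flag,
magnitude, longitude, latitude). Three printed regional catalogs for the
Neuwied Basin ship with the package as fixtures (see
`catalog_fixture()`), transcribed cell for cell including the
manual-depth asterisks. Selection around a camera uses the haversine
great-circle distance on a 6371.0-km sphere (through the `geosphere`
package) and a *strict* magnitude bound (`magnitude > min_magnitude`),
matching how the printed selections are phrased. Camera coordinates are
configuration, never constants: the mound locations are withheld in the
source material, so tests and examples use nearby synthetic stations.

`extract_event_window()` re-times the calibrated index relative to an
event origin and reports the covered fraction of the requested window.
`flag_rest_suppression()` operationalizes the reported anomaly — the
normally near-zero nocturnal rest phase being replaced by activity in the
hours before an event — as a z-like displacement: the night's mean index
minus the baseline nightly mean, in units of the baseline's
between-night standard deviation, built from at least 5 reference nights;
$|z| > 3$ flags the night. This statistic is this package's own
operational definition, introduced because the source analysis describes
the suppression qualitatively without defining a test statistic. A
constant baseline (zero variance) is refused rather than flagged.

## Mound-alignment analysis

Mound coordinates are projected to a local azimuthal equidistant plane
(explicitly, even though planar treatment is standard at survey scale)
and fed to a Hough transform over axial azimuths $[0°, 180°)$ — a line's
orientation is axial, so 179° neighbors 0°. For each angle bin the
accumulator bins the signed distances $\rho$ of all points into cells of
width `rho_bin` (default 1/50 of the point-set diameter, anchored at the
smallest $\rho$ so the histogram is exactly translation- and
scale-invariant); the per-angle support is the total count in cells
holding at least `min_support` points. The default `min_support = 4` is
deliberately above the 2 points that define a line: cells of 2–3 points
arise by chance at almost every angle of a structured point set, and
admitting them floods the histogram with off-axis support, burying the
true alignment directions.

Modes are found on a circularly smoothed histogram (plateau-aware strict
local maxima; the axis is partitioned at the minima between peaks), and
each mode reports the count-weighted axial circular mean and standard
deviation via vector summation on doubled angles — testable in closed
form. The angular and radial discretization are parameters, not claims:
the source analysis does not state its bin widths.

## The synthetic-data generator

No video archive is published, so every stage is tested against
`generate_video()`: a static textured background with a central
elliptical mound region, in which small square ants (default 2×2 px,
contrast 80) perform a seeded random walk; whole-frame integer camera
jitter (default ±1 px, replicate-padded); per-mode Gaussian sensor noise
(default sd 2); a day sensor from 06:00 to 20:00 UTC rendering 3-channel
frames with bright ants on the darker mound, and a night sensor rendering
single-channel frames with dark ants on bright grass. The contrast sign
deliberately flips between modes — differencing must be, and is tested to
be, agnostic to it. Scenes default to 64×48 px at the 10-s analysis
cadence (the capture-time frame rate of the real cameras is an
acquisition detail the pipeline never sees). Every generator is a pure
function of its configuration and seed.

`generate_daily_profile()` supplies ant-count schedules: `"M_shaped"`
(the standard daily routine — rise from dawn, Gaussian peaks at 12:00 and
17:00 with amplitudes 1 and 0.85 and widths 1.8 h and 1.5 h, near-zero
nights, default 30 ants at the main peak), `"flat"`, and
`"suppressed_night"` (the M baseline with the level displaced inside a
configured window around an origin time, emulating anomalous nights).
`generate_operator_scores()` perturbs true categories by ±1 per operator
at a configurable disagreement rate (default 0.2) and recomputes the
consensus. `generate_catalog()` draws events uniform in time, uniform
over a spherical disc around the station, magnitudes uniform in range.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: photorealistic texture, moving vegetation
inside the mask, gradual dawn/dusk transitions (the sensor switches
instantaneously at the scheduled hour; transition frames in real streams
are labeled by the channel heuristic and flagged, not dropped), weather,
predators and other transient large-blob disturbances, and any real
relationship between ant behavior and earthquakes. The generator provides
ground truth for the *measurement chain*, not for the biology.

## Verification at desk scale

The headline multi-year behavioral results of the source study depend on
an unreleased video archive and are not reproducible on a desk; the test
suite therefore verifies the measurement chain property by property, at
sizes chosen to keep the default run inside a few minutes:

* the difference sum agrees bit-exactly with an independent straight-loop
  implementation on 100 random 32×32 scenes;
* integer jitter in $[-5, 5]^2$ is recovered exactly on textured frames
  over 50 seeds;
* polynomial calibration on 300 noisy pairs recovers known day/night
  coefficients within 5% relative error, with residual RMS matching a
  normal-equations oracle to $10^{-8}$;
* a full synthetic day (8,640 frames of 64×48 px, five seeds) carries an
  injected M-shaped profile through video → registration → differencing →
  calibration → median filter with mean rank correlation well above 0.8
  against ground truth, and exactly two daytime peaks.

One definition had to be added for the last check: at 10-s resolution any
noisy curve has sample-scale wiggles, so "a daytime peak" is defined on
hourly-binned means of the filtered curve (`count_profile_peaks()`) —
two strict interior local maxima of that binned curve is the M signature.

## Known limitations

* The suppression flag is a deliberately simple displacement statistic;
  it detects level shifts, not shape changes, of the nocturnal profile.
* Registration is translation-only; rotation or scale changes of the
  camera are outside its model, as is lens distortion.
* The night calibration inherits any slow brightness drift of the mound
  material; fit windows much longer than 2–3 weeks are not advisable.
* Category 7 (sunbathing) is numerically above 6 in the regression even
  though it is behaviorally a different state, not a higher crowding
  level.
* Earth-tide and weather series are consumed, if at all, as exogenous
  overlays; the package neither computes nor models them.
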