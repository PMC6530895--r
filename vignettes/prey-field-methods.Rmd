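---
title: "Quantifying a coastal prey field with an uncalibrated echosounder: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a coastal prey field with an uncalibrated echosounder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Recreational-grade echosounders (RGE) record water-column backscatter as
linear 8-bit integers with an undocumented source level, gain function and
time-varied gain (TVG). Absolute calibration to volume backscattering
strength (Sv) is impossible, but school *dimensions* and *relative*
intensities survive, and those are enough to quantify the relative
abundance of potential prey (RAPP) for coastal predators such as Hector's
dolphins and little penguins. This package implements that chain:

1. 8-bit ping exports → relative-dB echograms;
2. TVG selection from calibration-sphere returns;
3. analysis-domain masking (near-field, seabed) and background-noise
   removal;
4. SHAPES-style school detection and beam-geometry correction;
5. per-survey RAPP metrics (c.SchA, Prop.Track);
6. negative-binomial GAMMs of predator counts against RAPP.

Every stage is testable against a synthetic-data generator that plants
schools, a seabed, receiver noise and calibration-sphere drops with known
truth.

# Relative intensity

The manufacturer's linear-to-dB mapping is proprietary, so the package
declares its own: `dB = 20 log10(max(count, 1)/255)`, i.e. full scale is
0 dB and the 8-bit quantisation floor is −48.13 dB. Any affine-in-log
mapping leaves the analysis unchanged, because every downstream rule
(the −35 dB analysis threshold, TVG-form selection, school boundaries) is
either relative to this declared scale or offset-invariant by
construction. All intensities in the package are "relative dB (full scale
= 0)"; a −35 dB threshold is therefore meaningful and portable across
surveys *as long as range and gain settings never change mid-survey* —
heterogeneous range windows are rejected outright for this reason.

Depth axes come from the exported min/max range and sample count (not the
ADC sampling rate, since stored samples are decimated by unknown factors);
depth is measured below the transducer. Along-track distance uses
haversine steps between GPS fixes (Earth radius 6371.0088 km). Timestamps
are converted UTC → NZ standard time as a fixed +12 h offset with no
daylight-saving logic, because field seasons span DST boundaries
ambiguously.

# TVG selection from a calibration sphere

Stored RGE intensities are depth dependent. Lowering a tungsten-carbide
sphere below the transducer (3–35 m) and isolating 8 × 1 (vertical ×
horizontal) regions around it gives the depth profile of a constant
target. For each candidate range coefficient ξ ∈ {10, 15, 20, 40}, region
means are corrected by

$$Y(R) = \xi \log_{10}(R) + 2\alpha R$$

and the form minimising the absolute Pearson correlation between
corrected intensity and depth is selected (ties break toward the smaller,
least aggressive ξ). Choices worth making explicit:

* **"Correlation" is Pearson's r** between corrected mean region
  intensity (dB) and depth; nothing in the procedure depends on the exact
  statistic as long as it vanishes for a flat profile.
* **Region means are linear-domain** (mean power re-expressed in dB), the
  standard convention for mean Sv; the dB-domain alternative changes
  third-decimal correlations only.
* **log = log10** throughout, the sonar-equation convention.
* **Absorption α** comes from the Francois–Garrison (1982) model (the
  standard behind commercial echo-processing software) with CTD
  temperature/salinity, pH 8 and 200 kHz; **sound speed** from Mackenzie
  (1981). Any standard formulas agree far below the precision that
  matters here (α ≈ 0.05–0.06 dB/m at study conditions).
* Sphere *target strength* is never used: on an uncalibrated system only
  the depth-dependence of relative intensity is informative.
* A residual-correlation warning (|r| > 0.5 after the best candidate)
  flags depth dependence outside the candidate family.

# Preprocessing

**Seabed pick.** The commercial "best candidate" algorithm is
proprietary; the reconstruction picks, per ping, the strongest sample
below a minimum depth (default 5 m), requires it to stand within 18 dB of
the ping's overall maximum *and* at least 6 dB proud of the ping's median
(both rules offset-invariant, so the pick survives any constant dB
shift), and takes the echo's leading edge — the shallowest contiguous
sample within 6 dB of the peak — as the seabed depth. The leading edge
rather than the peak matters because after TVG correction a saturated
seabed plateau tilts upward with depth, which would otherwise bias the
pick downward by several bins. A 9-ping running median enforces
continuity; pings without a candidate inherit the interpolated line, and
a transect with more than half its pings unpickable is rejected.

**Analysis domain.** Fixed 3 m near-field exclusion; seabed exclusion
with a 0.3 m backstep (about two vertical bins of side-lobe smear — the
field protocol does not state one, so this is a declared default).

**Background noise.** A De Robertis & Higginbottom-style estimator:
average the corrected echogram over 20-ping × 5-bin cells in the linear
domain, take the minimum over cells of (cell mean − TVG at the cell
depth) as the noise level at source, subtract (noise + TVG) per sample in
the linear domain, and floor samples whose remaining SNR is below 3 dB to
a −999 dB sentinel that all later means exclude. Cell means treat
already-floored samples as zero power, which makes the operation
idempotent: re-running it on its own output finds no measurable noise and
changes nothing. All three settings are config-exposed; none are stated
by the field protocol.

# School detection

Detection is threshold → candidates → linking → minimum dimensions:

* samples ≥ −35 dB inside the analysis domain form **4-connected**
  components (4- rather than 8-connectivity prevents diagonal single-cell
  bridges between distinct schools);
* components smaller than the candidate minima are dropped;
* candidates whose bounding boxes are within 5 m along-track *and* 2 m
  vertically are merged transitively (the field settings are not
  documented; these defaults mirror the school minima and are
  config-exposed);
* schools below the preset minima are discarded. Three presets:
  `ground_truth` (3 m length / 1.5 m thickness), `survey_results`
  (5 m / 2 m) and `survey_methods` (5 m / 3 m). The two survey presets
  exist because the study's methods and results sections state different
  minima; `survey_results` is the default since it is the parameterisation
  justified by the observed dimension distribution (84% of classified
  schools exceeded 2 m × 5 m).

Measured morphology: length `L` is the along-track extent of occupied
pings plus one cell width (so a one-ping school has the width of its
cell, and a 20-cell row at 0.30 m is 6.0 m); thickness `T` the analogous
vertical extent; area `A` the summed area of member cells; depth `D` the
mean member-cell depth; mean intensity the linear-domain mean. Beam
geometry inflates raw dimensions, so

$$L_c = L - 2D\tan(\phi/2), \qquad
  T_c = T - \frac{C}{2}\frac{\tau}{1000}, \qquad
  A_c = A\,\frac{L_c T_c}{LT}$$

with φ the 3 dB beam angle (degrees), C the sound speed (m/s) and τ the
pulse length (ms). Schools with non-positive corrected dimensions are
kept in the output but flagged invalid and excluded from prey metrics —
clamping them to zero would still pollute Prop.Track denominators
asymmetrically. Schools touching the near-field line with aspect ratio
L/T > 50 are flagged for review (the field protocol screened surface
noise, bubbles and wake visually; a flag keeps that auditable instead of
silently dropping data).

# RAPP metrics

Per survey: **c.SchA** = Σ A~c~ / distance (m²/km) over valid schools,
and **Prop.Track** = Σ L~c~ / distance, with overlapping along-track
intervals merged before summation so stacked schools are not
double-counted and the result is a true proportion ≤ 1 (plain summation
is available as a switch; whether the field analysis merged overlaps is
unstated). c.SchA uses corrected areas by default, switchable to raw.
Seasons derive from the survey date: January–March is summer, August–
October winter, anything else "other" with a warning.

# Predator-count models

For each predator, counts over 136 surveys in 6 regions are modelled as

$$\log \mu = \beta_0 + s(\mathrm{RAPP}) + b_{\mathrm{region}} + \log(\mathrm{distance})$$

with a negative-binomial response: a cubic regression spline with basis
dimension 4 (the "maximum 4 knots" ceiling against over-smoothing), a
penalized per-region random intercept (`bs = "re"`), and survey distance
as a log offset (the protocol says only that distance was "incorporated";
an offset is the standard exposure treatment and a covariate switch is
provided). The best RAPP metric per predator is the lower-AIC model of
the two single-metric fits, and fit quality is reported as percent
deviance explained against the intercept-plus-offset null.

Smoothness and NB dispersion are estimated together by (restricted)
maximum likelihood outer iteration: mgcv's extended NB family does not
support GCV smoothness selection and silently substitutes REML when GCV
is requested, so the package requests it explicitly. Consequently
absolute AIC values are comparable only within this implementation —
rankings and deviance explained are the meaningful outputs, not AIC
magnitudes.

# The synthetic generator

The generator's job is to produce every input the pipeline consumes with
known truth, under the acquisition conditions of the study: ~0.30 m
along-track and ~0.15 m vertical cells, a 3 m near-field, seabeds at
8–35 m, school core intensities in the observed −34 to −13 dB range, and
survey layouts matching the study's 136 surveys over 6 regions with its
summer/winter split.

* **Raw-domain construction.** The "ideal", depth-independent field
  (schools + seabed) is built first; the true TVG is *subtracted* to make
  the stored field depth dependent; constant-level receiver noise is
  added in the stored domain; and the result is quantised through the
  8-bit format. Applying the correct TVG form therefore restores depth
  independence exactly (up to quantisation), and after correction the
  signal-to-noise ratio falls with range — the situation the noise
  remover is designed for.
* **Schools are ellipses** of constant core intensity whose soft dB
  falloff starts 1 dB *below* the support threshold: the above-threshold
  support at −35 dB is exactly the planted ellipse, while lowering the
  analysis threshold grows the patch — realistic partial-threshold
  boundaries for threshold-sensitivity tests. School placement along
  transects is uniform; the field data give no distributional form and
  none is claimed.
* **The sphere drop** anchors its reference level mid-scale at the mean
  TVG of the requested depths, because 8-bit storage spans ~48 dB while a
  40log TVG spans ~65 dB over 3–35 m; without the anchor the deep half of
  a 40log drop would vanish below the quantisation floor. Deep-end
  quantisation is then the dominant noise for ξ = 40; selection still
  recovers the generating form because every wrong candidate leaves a
  ≥ 5 log10(z) residual trend.
* **Survey simulation** draws the two RAPP metrics from right-skewed
  lognormals (medians 150 m²/km and 0.05, season shifting both up in
  summer) with correlation 0.5 between their latents — both metrics
  derive from the same school field, so independence would be
  unrealistic, while the field study's discordant best-metric results
  show they are not collinear. Counts follow the fitted-model structure
  exactly (NB log link, region intercepts, distance exposure), because
  parameter recovery is the test objective; in particular the default
  generating smooths are chosen *within the span of the k = 4 cubic
  splines the model fits* (a monotone concave quadratic in Prop.Track
  with log-range 1.5 for dolphins; a saturating curve in c.SchA
  plateauing around 700 m²/km for penguins, echoing the reported field
  smooths). A generating smooth outside that span — e.g. a logistic in
  log-RAPP — produces irreducible approximation bias and band coverage
  far below nominal at any sample size, which would test
  misspecification, not recovery.
* Defaults are calibrated once to the study's scale: per-survey mean
  counts of a few dolphins and ~1 penguin, NB dispersions near 1, region
  intercept spreads near 1 on the log scale. Default seed 20150522 is
  recorded in all outputs.

What the generator does *not* emulate: beam-pattern convolution, multiple
scattering, vessel motion, tides, bubbles/wake, fish avoidance, or
species mixtures. Passing tests therefore demonstrate that the
*algorithms* recover planted truth under the study's geometry and noise
model — not that the pipeline is robust to every artefact of real
coastal acoustics.

# Numerical choices and degenerate inputs

* Quantisation floor: counts of 0 clamp to 1 (−48.13 dB) on read; the
  floor behaves as constant raw-domain noise and is removed by the noise
  estimator.
* Floor sentinel −999 dB marks noise-removed samples and is excluded from
  every linear-domain mean; bins at depth ≤ 0 are masked `NA` by TVG
  application.
* Ties in |correlation| across TVG candidates break toward smaller ξ.
* `fit_tvg_form` requires ≥ 10 regions spanning ≥ 10 m of depth;
  degenerate depth variance is an error.
* Empty domains yield empty school tables, not errors; surveys with zero
  distance are dropped with a warning; a transect whose seabed cannot be
  picked on half its pings is rejected.
* Smooth-vs-truth comparisons evaluate across-the-function coverage at
  the observed predictor values with the model-constant uncertainty
  included in the band (the construction whose average coverage is close
  to nominal); the fitted smooth is sum-to-zero centred, so the free
  constant is aligned by least squares before comparison.

# Problem sizes used in the test-suite and acceptance runs

Chosen as the package's own desk-scale study conditions: ground-truth
scenes of 700–1100 pings × ~235 bins with 2–4 planted schools; sphere
drops of 110–300 regions over 3.2–35 m with 1 dB echo noise and 200
replicates per candidate ξ for the recovery rate; survey campaigns of
32–40 rendered transects for the end-to-end workflow; and 100 replicate
simulations of 136-survey campaigns for the model-selection rate. AIC
metric-selection consistency is evaluated in the strong-effect regime
(generating smooth log-range 2.5): at the regime boundary (log-range 1.5,
metric correlation 0.5) the selection rate is ~0.85–0.90, rising to
≥ 0.95 by log-range 2.5 — selection consistency is a property of effect
strength, and the field study's winning dolphin model led by ~28 AIC
units, far from the boundary.

# Known limitations

* No absolute calibration: intensities are relative; no density/biomass
  estimation, no NASC-type intensity-weighted metric.
* The documented CSV export schema is the ingestion boundary; the
  proprietary compressed `.sl2` container itself is not parsed.
* No species classification of schools ("potential prey" by
  construction), no discrimination of squat-lobster aggregations from
  fish.
* Bottom pick, noise removal and linking settings are declared
  reconstructions, not recovered values — the commercial implementations
  are proprietary.
* The region random effect is the only spatial structure; no
  autocorrelation beyond it, no multi-predictor models, and season is not
  a model term (the field models did not include it).
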