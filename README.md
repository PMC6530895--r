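# echoprey

Prey-field analysis from recreational-grade echosounder (RGE) data.

Small epipelagic fish — sprat, pilchard, mullet — are the prey of coastal
predators such as Hector's dolphin and little penguin, but their extreme
patchiness makes them hard to survey. Consumer echosounders detect their
schools well, yet store uncalibrated 8-bit samples with unknown gain and
time-varied-gain (TVG) functions, so none of the standard calibrated
(Sv-based) acoustic machinery applies. `echoprey` implements the analysis
chain that extracts what *does* survive the lack of calibration — school
dimensions and relative intensity — and links it to predator counts:

1. **Ingestion** — ping-level CSV exports → relative-dB echograms
   (`read_ping_csv()`, `counts_to_db()`, `pings_to_echogram()`); relative
   dB defined as `20·log10(count/255)`, full scale = 0 dB.
2. **TVG calibration** — returns from a tungsten-carbide sphere lowered
   to 3–35 m are isolated as 8×1 regions; each candidate correction
   `Y = ξ·log10(R) + 2αR` (ξ ∈ {10, 15, 20, 40}) is applied and the form
   minimising the |Pearson correlation| of corrected intensity with depth
   is selected (`fit_tvg_form()`, `apply_tvg()`). Absorption α comes from
   the Francois–Garrison model and sound speed from Mackenzie's formula
   using CTD casts (`absorption_coefficient()`, `sound_speed()`).
3. **Preprocessing** — seabed pick, 3 m near-field exclusion,
   range-dependent background-noise removal (`detect_bottom()`,
   `build_analysis_domain()`, `remove_background_noise()`).
4. **School detection** — SHAPES-style: −35 dB threshold, 4-connected
   candidates, transitive linking, minimum-dimension filtering
   (`detect_schools()`); beam-geometry corrections
   `Lc = L − 2D·tan(φ/2)`, `Tc = T − (C/2)(τ/1000)`,
   `Ac = A·(Lc·Tc)/(L·T)` (`beam_correct()`).
5. **RAPP metrics** — per-survey cumulative school area c.SchA (m²/km)
   and track proportion Prop.Track (`summarize_survey()`).
6. **Count models** — negative-binomial GAMMs
   `log μ = β₀ + s(RAPP) + b_region + log(distance)` with cubic splines
   (≤ 4 knots) and a region random effect; metrics ranked per predator by
   AIC (`fit_nb_gamm()`, `select_best_metric()`, `plot_smooth()`).

A synthetic-data generator (`synthetic_scene()`, `render_echogram()`,
`make_sphere_drop()`, `simulate_surveys()`) plants schools, seabed, noise
and sphere drops with known truth, so the entire pipeline is testable
without field data. The methods vignette
(`vignettes/prey-field-methods.Rmd`) documents the model, the defaults
and the design decisions.

## Worked example

Select the TVG form from a simulated sphere drop, then correct, detect
and beam-correct a planted school:

```r
library(echoprey)

alpha <- absorption_coefficient(ctd_cast(13, 35, pH = 8, frequency_khz = 200, depth = 10))
set.seed(42)
drop  <- make_sphere_drop(runif(120, 3.2, 35), tvg_exponent_true = 10,
                          absorption_true = alpha, noise_sd_db = 1, seed = 42)
regions <- extract_sphere_regions(pings_to_echogram(drop$records), drop$annotations)
fit <- fit_tvg_form(regions, alpha)
fit
#> <tvg_fit> selected 10log (alpha = 0.0611 dB/m, 120 regions)
#>      10      15      20      40
#> -0.0073  0.7514  0.8829  0.9414
```

The 10log (cylindrical-spreading) form flattens the sphere's intensity
against depth (|r| ≈ 0.007), while 15/20/40log all over-compensate —
exactly the diagnostic pattern expected from these instruments. The
correlation map is the full selection evidence; `apply_tvg()` then adds
`10·log10(z) + 2αz` to every sample.

```r
sc  <- synthetic_scene(schools = list(true_school(200, 10, 20, 3, core_db = -22)),
                       n_pings = 700, seabed_depth = 25, noise_floor_db = -65)
pre <- apply_tvg(pings_to_echogram(render_echogram(sc)$records), fit)
dom <- build_analysis_domain(pre, detect_bottom(pre))
schools <- detect_schools(remove_background_noise(pre, fit), dom,
                          shapes_params(preset = "ground_truth"))
round(schools[, c("L", "T", "A", "D", "mean_intensity", "Lc", "Tc", "Ac")], 2)
#>      L T     A    D mean_intensity Lc   Tc    Ac
#> 1 20.1 3 47.23 9.99         -21.87 18 2.85 40.18
```

The planted 20 m × 3 m school at 10 m depth is recovered within one cell
(L = 20.1, T = 3.00) at its planted intensity (−22 dB); the corrections
remove the beam smear (2·10·tan 6° ≈ 2.1 m) and half a pulse length
(0.15 m).

At the study scale, predator counts are modelled against the two RAPP
metrics and ranked:

```r
surveys <- simulate_surveys(n_surveys = 136, seed = 11)
ranked  <- select_best_metric(surveys, "dolphin")
ranked[[1]]
#> <nb_gamm> dolphin ~ s(prop_track) + RE(region); edf 6.7, AIC 831.2,
#>  deviance explained 37.9%, theta 1.71
attr(ranked, "delta_aic")
#> [1] 14.22019
```

Prop.Track wins the dolphin ranking by 14 AIC units and the model
explains ~38% of the deviance — the same qualitative structure the
method produces on field data, here recovered from counts the generator
drew from a known model.

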