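# dielrisk

Tools for asking how prey allocate their activity over the 24-hour cycle
when mortality risk comes from several predators *and* humans at once.
`dielrisk` links the two data streams a field study of this question
produces — camera-trap detections and radio-telemetry mortality records —
into one tested pipeline, motivated by summer white-tailed deer demography
in multi-predator forest systems: nursery groups (any deer group containing
a fawn) versus fawn-free adult deer, facing black bears, bobcats, coyotes,
wolves, and vehicle collisions.

It is written for quantitative ecologists and biostatisticians: every
user-facing function takes a data frame and returns a tibble, fitted
objects have `tidy()` / `glance()` / `autoplot()` methods, and a synthetic
data generator reproduces the statistical structure of the field data so
the whole chain is testable without any download.

## What it computes

* **Independent detections** — camera image bursts are collapsed with the
  chained 15-minute rule (same site, same species), and deer detections are
  classified nursery group / adult female / adult male from per-image count
  maxima (`collapse_detections()`, `classify_deer_group()`).
* **Diel activity densities** — von Mises kernel density estimates on the
  circle, f̂(θ) = n⁻¹ Σᵢ exp{κ cos(θ − tᵢ)}/(2π I₀(κ)), with a
  trigonometric-moment plug-in bandwidth (`fit_circular_kde()`).
* **Temporal overlap** — the coefficient Δ = ∫ min(f₁, f₂) estimated by
  Δ̂₄ (clipped density ratios at observed points; Δ̂₁ grid fallback for
  small samples), percentile-bootstrap confidence limits, and a
  pooled-randomization equality test (`estimate_delta4()`,
  `bootstrap_overlap()`, `randomization_test()`).
* **Cause-specific mortality** — the Aalen–Johansen estimator of
  cumulative incidence under competing risks with right-censoring, on a
  daily grid: CIF_k(t) = CIF_k(t−1) + S(t−1)·d_k(t)/n(t)
  (`aalen_johansen()`, `mortality_summary()`).
* **Mortality-weighted diel risk** — per-source risk weights
  w_k = CIF_k / Σ identified CIF and the combined index
  Σ_k w_k f̂_k(θ) (`compute_risk_weights()`, `compute_risk_index()`), plus
  a daily 11-day moving-window deer–carnivore overlap series
  (`moving_window_overlap()`).
* **Synthetic studies** — von Mises mixture detection generators and
  discrete-day competing-risks cohorts with embedded ground truth
  (`sim_field_scenario()`, `gen_detection_times()`,
  `gen_mortality_cohort()`).

See `vignettes/diel-risk-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate a study at 10% of full detection volume, run the whole chain, and
read the report:

```r
library(dielrisk)

bundle <- sim_field_scenario(seed = 42, scale = 0.1)
cfg    <- analysis_config(bundle$images, bundle$mortality, n_boot = 0, seed = 42)
report <- run_full_analysis(cfg)
report
#> Diel risk analysis report
#>   detections: 4648 (deer 1341, carnivores 593, humans 2714)
#>   overlap (Delta-4, nursery vs adult deer):
#>     bear    nursery 0.42  adult 0.71
#>     bobcat  nursery 0.31  adult 0.56
#>     coyote  nursery 0.40  adult 0.67
#>     wolf    nursery 0.41  adult 0.69
#>     human   nursery 0.73  adult 0.40
#>   overlap_reduction_bear_pct       41
#>   ...
#>   mean_overlap_nursery_pct         45
#>   mean_overlap_adult_pct           61
#>   fawn_total_mortality             0.170415
#>   adult_total_mortality            0.0258299
#>   mortality_ratio_fawn_adult       6.6
```

Reading it: nursery groups overlap every carnivore *less* than fawn-free
adults do (0.31–0.42 vs 0.56–0.71) and overlap humans *more* (0.73 vs
0.40) — the diurnal shift of fawn-attending deer. The fawn cohort's total
cumulative incidence (0.17, generated truth 0.16) is ~6.6× the adult one.
Single comparisons carry bootstrap confidence limits:

```r
est <- bootstrap_overlap(
  to_circular_times(report$detections, group = "nursery_group"),
  to_circular_times(report$detections, species = "coyote"),
  n_boot = 200, seed = 42)
est
#> Diel activity overlap (delta4): 0.396 [0.338, 0.439] (95% CI, B = 200; n1 = 360, n2 = 278)
```

`autoplot()` works on densities, CIF sets, risk-index curves and
moving-window series; `write_report(report, dir)` emits every table as CSV.

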