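# villimorph

Quantitative villous morphometry for environmental enteropathy studies, and
the statistical machinery of the randomised trials that use it — with a
synthetic-histology generator so that every stage of the measurement and
analysis chain can be validated against exact ground truth.

Environmental enteropathy is an asymptomatic small-bowel disorder, almost
universal in impoverished settings, whose hallmark is villous blunting.
Trials of interventions against it measure, on orientated H&E-stained
jejunal sections: villous height (VH), crypt depth (CD), villous width
(VW), and — by automatic threshold segmentation — villous perimeter (VP)
and cross-sectional area (VA), the latter two summed over the villi of a
section and normalised per 100 μm of muscularis mucosae:

    VP_per100 = Σᵢ Pᵢ / L_mm × 100        VA_per100 = Σᵢ Aᵢ / L_mm × 100

where Pᵢ is each villous contour length *excluding the basal attachment
chord*, Aᵢ the enclosed area, and L_mm the muscularis mucosae length.
Group comparisons are routed by a Shapiro-Wilk screen to pooled t tests
(normal measures) or Kruskal-Wallis with Hodges-Lehmann median-difference
intervals (skewed measures), and design calculations use the exact
non-central t distribution: with n per group, df = 2n − 2 and
ncp = δ/(σ√(2/n)), power = P(|T′| > t₁₋α/₂).

The package is written for trialists and image-analysis methodologists who
need a tested, reproducible re-implementation of this measurement scheme
rather than a vendor macro.

## What's inside

| Area | Functions |
|---|---|
| Synthetic sections with ground truth | `mucosa_spec()`, `generate_mucosa_image()`, `render_batch()` |
| Measurement engine | `auto_threshold()`, `extract_villous_contours()`, `measure_villus()`, `normalize_per_muscularis()`, `measure_landmarks()`, `assess_orientation()`, `summarize_biopsy()`, `measure_batch()` |
| Masked trial simulation | `randomize()`, `effect_spec()`, `simulate_cohort()`, `simulate_stratum()`, `lock_cohort()`, `unblind()` |
| Statistics | `shapiro_wilk()`, `two_sample_t()`, `kruskal_wallis()`, `median_difference()`, `paired_tests()`, `spearman_matrix()`, `fisher_exact_2x2()`, `percent_difference()`, `vc_ratio()`, `route_and_compare()`, `select_conservative()` |
| Power / sample size | `t_power()`, `required_n()` |
| Orchestration | `run_config()`, `run_pipeline()`, `render_report()`, `plot_mucosa()`, `autoplot()` |

A thin command-line wrapper lives at `inst/cli/villimorph.R`
(`simulate-images`, `measure`, `simulate-cohort`, `analyze`, `power`,
`run`, `report` subcommands).

## Worked example

Render a synthetic section, measure it, and compare with its analytic
ground truth:

```r
library(villimorph)

g <- generate_mucosa_image(mucosa_spec(seed = 42))
g$annotation$true_record
#>      VH    CD    VW VP_per100 VA_per100 muscularis_um adequate
#> 1   300   160   110      331.    15851.           600 TRUE

summarize_biopsy(g$image, g$annotation)
#>      VH    CD    VW VP_per100 VA_per100 muscularis_um n_villi threshold adequate
#> 1   300   160   110      333.     15819           600       3       130 TRUE
```

The measured perimeter (333.0 v. 331.2 μm/100 μm) and area (15819
v. 15851 μm²/100 μm) sit within ~0.5% of the continuous truth; VH/CD/VW
come from the landmark path and are exact here.

Simulate a masked trial under the default effect scenario, lock, unblind
and analyse:

```r
sim <- simulate_cohort(effect_spec(seed = 42))
ub  <- unblind(lock_cohort(sim$cohort), sim$code_map)
res <- route_and_compare(ub)
dplyr::filter(res, stratum == "negative", variable == "VH")
#>   stratum variable test       estimate ci_low ci_high  p_value n_mm n_placebo
#> 1 negative VH      2-tailed t     52.2   25.9    78.4 0.000421   13        12
```

A 52.2 μm villous-height advantage for the supplemented arm (95% CI
25.9–78.4 μm) in the HIV-negative stratum — the simulator's built-in effect
(56.7 μm) recovered from one trial-sized draw; the HIV-positive stratum is
simulated null. Design calculations:

```r
required_n(delta = 65, sd = 36.3, alpha = 0.05, power = 0.8)
#>       n power n_continuous   ncp    df
#> 1     6 0.798         6.03  3.10    10

t_power(15, delta = 0.20 * 236.6, sd = 36.3)
#> [1] 0.931
```

Six patients per group detect a 65 μm difference at SD 36.3 (nearest-integer
convention; `rounding = "up"` gives the strict 7 — see the methods
vignette), and 15 per group give 93% power for a 20% relative difference.

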