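---
title: "Villous morphometry and trial simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Villous morphometry and trial simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(villimorph)
```

## What this package models

Environmental enteropathy is an asymptomatic small-bowel disorder, near
universal in impoverished settings, whose cardinal histological feature is
villous blunting: shortened villi, altered crypts, reduced absorptive
surface. Quantifying it requires morphometry on orientated biopsy sections —
five measures per section, all in micrometres:

* **VH**, maximal villous height (tip to base along the axis);
* **CD**, crypt depth (mouth to base);
* **VW**, maximal villous width perpendicular to the VH axis;
* **VP**, villous perimeter — the epithelial contour length *excluding the
  basal attachment chord*, a proxy for absorptive surface area;
* **VA**, villous cross-sectional area, a proxy for villous compartment
  volume.

VP and VA are summed over the adequate villi of a section and expressed per
100 μm of muscularis mucosae, the thin muscle layer at the mucosal base
whose in-section length is the natural normalising denominator:

$$\mathrm{VP}_{/100} = \frac{\sum_i P_i}{L_{mm}} \times 100, \qquad
  \mathrm{VA}_{/100} = \frac{\sum_i A_i}{L_{mm}} \times 100.$$

Trials of interventions against enteropathy (the motivating application is
micronutrient supplementation in a masked 1:1:1:1 randomised design with
HIV strata) then compare these measures between arms. The package
implements the whole chain — synthetic ground-truth histology, the
measurement scheme, a cohort simulator, the routed statistics, and
non-central-t power calculations — so every stage can be validated against
known truth.

## The synthetic section generator

`mucosa_spec()` / `generate_mucosa_image()` render a stylised
haematoxylin-and-eosin-like cross section: a dark tissue band (intensity
60) on a bright lumen background (intensity 200), with `n_villi`
finger-like villi standing on the inter-villous plateau, narrow crypt
lumens opening between them, and a horizontal muscularis mucosae line whose
length is exactly `muscularis_length_um`. Geometry lives in micrometres (y
up, origin at the canvas bottom-left); the raster transform to pixel rows is
explicit, with a default calibration of 1 μm/pixel carried in every file
(the scale is never implicit in the image).

Two villus profiles are supported because both have closed-form oracles:

* `rect`: perimeter excluding base $2h + w$, area $wh$;
* `capped` (default): a rectangle of straight height $h - w/2$ topped by a
  semicircular cap of radius $w/2$, giving $2(h - w/2) + \pi w/2$ and
  $w(h - w/2) + \pi w^2/8$.

Rendering is binary (each pixel takes the tissue or lumen value according
to its centre), so noise-free images are exactly two-valued and trivially
separable by a global threshold; Gaussian intensity noise of SD `noise_sd`
is added on top, driven entirely by the spec's seed so identical specs give
byte-identical images. Inadequate orientation is simulated by tilting the
villi 45° from the muscularis normal — beyond the 30° tolerance the
adequacy screen uses — with the ground-truth record flagged accordingly.

The generator emulates the intensity contrast, geometry and calibration of
real digitised sections, not their texture: no nuclei, lymphocytes, stain
variation, section folds or out-of-plane structure. Passing recovery tests
therefore demonstrate that the measurement chain is unbiased on clean,
well-contrasted geometry; they do not certify performance on stained tissue
with debris and uneven illumination.

## The measurement scheme

`summarize_biopsy()` composes two paths, mirroring how a semi-automated
analyst works.

**Automatic path (VP, VA).** `auto_threshold()` picks the global grey level
maximising the between-class intensity variance on the 0–255 histogram
(Otsu's criterion), with an explicit tissue-polarity flag.
`extract_villous_contours()` then finds the villi: the top-of-tissue
elevation profile is computed per column; an initial plateau estimate (the
lower quartile of the profile) separates villus from inter-villus columns,
and the plateau is re-estimated as the median elevation over non-villus
columns. Each connected run of tissue at the row just above the plateau is
one villus; its contour is traced row by row with threshold crossings
linearly interpolated between pixel centres, giving sub-pixel polygonal
contours rather than pixel staircases (staircase perimeters are biased high
by up to ~27%, which is why level-set-style tracing matters). The base
chord is where the protrusion crosses the plateau level, and is excluded
from the perimeter: `measure_villus()` reports the shoelace area and the
closed boundary length minus the base chord. Totals are normalised per
100 μm by `normalize_per_muscularis()`.

**Landmark path (VH, CD, VW).** Real sections have these drawn by eye with
a cursor; the engine takes landmark polylines (from the JSON sidecar or any
annotation source) and measures arc length × scale. VH is the *maximum*
across the villi of a section; CD the *mean* over measured crypts (chosen
for stability; both rules are switchable via `vh_rule` / `cd_rule`).

**Orientation screen.** A section is analysable only when both villi and
crypts are present in longitudinal section; `assess_orientation()`
operationalises "longitudinal" as every villus axis within 30° of the
muscularis normal. A pure height truncation with no tilt is not detectable
from the annotation alone (the target height is unknown), a documented
limitation of the screen.

Numerical behaviour worth knowing: binary rendering plus midpoint
interpolation localises straight edges to within half a pixel, so at
1 μm/pixel VP and VA land within ~1% of the continuous truth (the suite
enforces 2%, and a 50-section recovery regression enforces slope within
[0.97, 1.03] and R² > 0.99 at noise SD 10); the measured base sits half a
pixel above the true attachment, a sub-0.5% effect that partially cancels
between perimeter and height; constant images raise an explicit "no
threshold separable" error; flat mucosa yields zero contours and zero
VP/VA, not an error.

## The cohort simulator

`effect_spec()` + `simulate_cohort()` produce a masked randomised cohort:
letters A–D assigned 1:1:1:1 (balanced within one), two letters per arm,
with the letter→arm map sealed inside an environment that only `unblind()`
reads — and `unblind()` refuses until `lock_cohort()` has marked
morphometry complete, reproducing the trial's masking discipline. HIV
status is assigned after randomisation (default prevalence 15/38); each
participant gets a pre-vaccination record and, with probability 14/38, a
correlated post-vaccination record; biopsies fail orientation
(`adequate = FALSE`) with probability 14/52. All of these defaults are the
study's own accounting.

The five measures are drawn from a Gaussian copula: latent normals with
Pearson correlation $2\sin(\pi\rho_s/6)$ chosen so the induced Spearman
correlations hit the published stratum targets (e.g. VP–VA 0.796, VH–VP
0.715 in HIV-negative patients). Margins are Gaussian for VH, CD, VA and
log-normal for VP and VW — the trial found exactly this split under
Shapiro-Wilk, and the simulator must exercise that routing. For the
log-normal margins the supplied location is the *median* (the natural
location for a skewed measure and the quantity the trial printed), with
`sdlog` set by moment matching from the supplied SD.

Default locations reproduce the printed HIV-negative contrast (VH
293.3 v. 236.6 μm; VA 27623 v. 21650 μm²/100 μm; VP medians
355.0 v. 273.7 μm/100 μm; CD 160.3 v. 151.7 μm so the V:C ratios 1.83 and
1.56 are consistent) and a null HIV-positive stratum. Only the VH SD
(36.3 μm) is published; the remaining spreads (CD 30, VP 80, VW 25,
VA 6000) were chosen once to be of the magnitude implied by the printed
confidence intervals and are exposed as configuration, never asserted as
published values. Post-vaccination records share the participant's latent
normal with correlation 0.5 and add a configurable vaccination effect
(default 0 — the vaccine had no measurable morphometric effect).

## Statistics

`route_and_compare()` analyses an unblinded cohort by intention to treat:
per HIV stratum and measure, a Shapiro-Wilk screen on arm-centred residuals
(α = 0.05) routes to either the pooled two-sample t test with its 95% CI
(Welch switchable) or to Kruskal-Wallis with a Hodges-Lehmann
median-difference estimate — the median of all pairwise between-group
differences — and its Mann-Whitney-inversion CI. Strata with fewer than two
participants per arm are skipped with a notice. No multiplicity correction
is applied by default (none was applied in the trial); `holm = TRUE` adds
one. When both pre- and post-vaccination datasets exist,
`select_conservative()` keeps, en bloc, the dataset whose effect on the
primary variable (VH) has the larger p-value, with ties resolving to pre.

Two presentation conventions are deliberate: p-values print to one
significant figure below 0.01 and two to three decimals otherwise, and
percent differences are computed as $(t - c)/c \times 100$ — an asymmetric
quantity (reversing the roles does not negate it), which the suite checks
rather than assumes away. Note that the exact two-sided Fisher p for the
trial-style 16:4 v. 11:7 split is 0.2877; tables that print such values at
two decimals can differ in the last digit depending on rounding versus
truncation.

## Power and sample size

`t_power()` is the exact non-central-t calculation: with $n$ per group,
$\mathrm{df} = 2n - 2$, noncentrality $\lambda = \delta/(\sigma\sqrt{2/n})$,
power is $P(|T'_{\mathrm{df},\lambda}| > t_{1-\alpha/2,\mathrm{df}})$; an
unequal-allocation form uses $\sigma\sqrt{1/n_1 + 1/n_2}$. `required_n()`
inverts it by continuous root-finding and then maps the continuous solution
$n^\*$ to whole patients. The default mapping is *nearest integer*, the
convention under which the motivating post-hoc calculation (δ = 65 μm,
σ = 36.3 μm, α = 0.05, power 0.8 → $n^\* = 6.026$ → 6 per group) gives its
published answer; the achieved power at the rounded n is returned alongside
so the marginal shortfall (0.798 here) is visible. `rounding = "up"` gives
the strict smallest-n-meeting-power rule (7 in that example) for users who
want the guarantee rather than the convention. The two conventions differ
only when the target power falls inside an integer gap, which is exactly
what happens in this calculation — the reason both are first-class options
rather than one being hidden.

## Pipeline and reproducibility

`run_pipeline()` chains simulate-images → measure → simulate-cohort →
analyze → report under one master seed, each stage deriving its own stream,
and writes diffable artifacts (CSV tables, JSON sidecars, a markdown
report, a CONSORT-style attrition table, and a log of every seed, threshold
and exclusion). Identical config + seed reproduce every file byte for byte;
the suite asserts this.

Problem sizes used by the test suite were chosen to make each property
decisive at interactive runtimes: 50 synthetic sections for the recovery
regression, 10⁴ draws for marginal/correlation convergence (2% and ±0.05
bands), 2000 replicates for type-I calibration (the ±1% band is about two
standard errors), 1000 replicates for the empirical-versus-predicted power
comparison, and 20000 simulated trials for the Monte-Carlo power oracle.

## Known limitations

* The renderer's realism stops at geometry + contrast; no claim is made
  about stain deconvolution, inflammation scoring or lymphocyte counting.
* Landmarks are consumed, never inferred: automatic placement of VH/CD/VW
  axes from raw pixels is out of scope, as in the semi-automated procedure
  being modelled.
* The adequacy screen detects tilt and missing structures, not pure
  truncation.
* The sealed code map is a software contract, not cryptography: it prevents
  accidental unblinding in an analysis pipeline, not adversarial access.
* Power calculations cover the two-sample t test only; the rank-based
  comparisons have no corresponding power module.
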