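---
title: "Ecoenzymatic stoichiometry and integrated soil analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecoenzymatic stoichiometry and integrated soil analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoenz)
```

## The scientific problem

Soil microbial communities secrete extracellular enzymes ("ecoenzymes") to
mine carbon, nitrogen and phosphorus from organic matter. The relative
investment into the three acquisition classes is a read-out of the
nutrient limitation the community experiences, and — combined with soil
chemistry, microbial biomass and abundance estimates — a compact description
of soil biological health. `ecoenz` implements this integrated analysis for
a three-species Agave plantation study design (five biological replicates
per species, soil and rhizosphere compartments), from raw assay readings to
multivariate inference.

## Enzyme pools and the limitation vector

The nine assayed activities are pooled into acquisition classes:

* `CE = beta-glucosidase + cellulase + xylanase - dehydrogenase` — the three
  carbon-supplying hydrolases minus the carbon-consuming oxidase. `CE` is a
  supply-minus-consumption balance and may be negative; we retain negative
  values but mark ratios and vectors as undefined rather than clamping,
  because a floor would silently convert "consumption exceeds supply" into
  "no carbon enzymes".
* `NE = urease + protease` — the two dominant nitrogen-mineralizing
  families.
* `PE = acid phosphatase` — the phosphomonoesterase assayed at the pH
  closest to these soils.

The enzymatic vector places each sample at
`x = CE/(CE + PE)`, `y = CE/(CE + NE)` in the unit square. Its length
`VL = sqrt(x^2 + y^2)` grows with relative carbon investment (carbon
limitation); its angle `VA = atan2(y, x)` in degrees discriminates
phosphorus limitation (`VA > 45`) from nitrogen limitation (`VA < 45`).
The `atan2` convention was validated against the study's printed angle for
the first species (67.231 degrees from the printed mean activities, which
`eea_summary()` reproduces to within the rounding of those inputs):

```{r}
pools <- eea_pools(data.frame(
  beta_glucosidase = 0.358, cellulase = 0.146, xylanase = 0.391,
  dehydrogenase = 2.35e-3, protease = 0.217, urease = 10.775,
  acid_phosphatase = 27.415, alkaline_phosphatase = 40.645,
  arylsulphatase = 1.764))
v <- vector_components(pools$CE, pools$NE, pools$PE)
vector_length_angle(v$x, v$y)
```

Two classification parameters are tunable. The angle threshold defaults to
45 degrees (the balanced 1:1:1 stoichiometry diagonal). The vector-length
cutoff separating a *weak* from a *strong* limitation defaults to 0.5:
field surveys of arid agricultural systems report `VL > 0.5` where
limitation is pronounced, whereas the study soils sit near 0.1. Both are
arguments of `classify_limitation()`.

### Aggregation order

Published summary tables mix two aggregation conventions: pools are sums of
group-mean activities, while ratios and vector summaries behave like means
of per-replicate values. Because ratios and `atan2` are non-linear, the two
orders differ (a Jensen gap). `summarize_group()` exposes both:
`"of_means"` derives everything from group-mean activities (used when
checking printed pools); `"per_replicate"` — the default — derives per
sample and averages, which is the convention consistent with the printed
ratio and vector-length rows. Every report states the mode used.

## Soil chemistry

`derive_chemistry()` recomputes (never trusts) the derived columns:
`TOC = OM / 1.724` (Van Bemmelen factor; it reproduces the three published
TOC values exactly), molar C:N:P ratios via atomic masses 12.011, 14.007,
30.974 (micromol per gram of soil), `SB = Ca + Mg + K + Na`,
`CEC = SB + PA`, `V% = 100 SB / CEC` and `m% = 100 Al / (SB + Al)`. The
qualitative flags use strict thresholds: slightly acidic (6.5 < pH <= 7),
organic-matter rich (OM > 30 g/kg), high TOC (> 20 g/kg), adequate P
(> 10 mg/kg), high base saturation (V% > 90). `V% + 100 PA / CEC = 100`
holds identically and is asserted as a property.

Chemistry is measured on a per-species pooled sample, so it is
group-constant: the multivariate stage broadcasts it to replicates. This is
the one place the replicate-level analysis mixes two sampling depths; we
document it rather than invent per-replicate chemistry noise.

## Microbial quantification

Four estimators convert raw enumeration observations into organisms per
gram:

* **CFU** — plain dilution-plating arithmetic with a countability flag
  (default 300 colonies) and a below-detection flag at zero.
* **MPN** — a maximum-likelihood estimator under independent Poisson
  inoculation: a tube with inoculum `v` grams is positive with probability
  `1 - exp(-lambda v)`; the score equation is solved by bracketed
  root-finding. We chose maximum likelihood over published lookup tables
  because it generalizes to any dilution design; the confidence interval
  uses a log-normal approximation with the standard error of `log10(MPN)`
  from the observed Fisher information, a simple and explicit choice
  recorded in the output metadata. The estimator is checked against a dense
  likelihood-grid search on all 64 outcomes of a 3-level x 3-tube design,
  and for scale equivariance and monotonicity.
* **TDE** — cells from bulk DNA yield at 8.14 fg DNA per cell. The same
  factor is applied to soil and rhizosphere; any eukaryotic DNA
  contribution inflates it equally.
* **EPI** — live/dead epifluorescence counts over a mosaic of 25 fields,
  scaled by filter/field area and suspension/aliquot volume. Those scaling
  constants are unpublished bench parameters; they are configuration in the
  design object (defaults: area ratio 1e4, 10 mL suspension, 10 uL
  aliquot).

## Biomass, respiration and quotients

`MBC = (C_fum - C_unfum) / kEC` and `MBN = (N_fum - N_unfum) / kEN`, with
the standard fumigation-extraction efficiencies `kEC = 0.45`,
`kEN = 0.54` as configurable defaults. Negative fluxes are flagged, not
clamped. Basal respiration converts an alkali-trap back-titration at 2 mol
NaOH per mol CO2 into micromol CO2 per gram per day. The metabolic quotient
`qCO2` divides respiration (mg CO2/g/h) by biomass carbon (g C/g); the
microbial quotient `Cmic/Corg` is the percentage of molar TOC held in
biomass. Both quotients are computed per replicate and averaged per group,
which is why group-mean quotients need not equal the quotient of group
means.

## Multivariate integration

`assemble_features()` builds the 25-variable matrix (pools, ratios, vector
summary, alkaline phosphatase and arylsulphatase activities, nine chemistry
variables, three soil elemental ratios, MR, MBC, MBN) and z-scores each
column; quantification variables are excluded by design and enter through
Spearman correlations instead. A zero-variance column (which arises in null
simulations where pooled chemistry is constant everywhere) is centred to
exact zeros rather than propagating NaN.

* **PCA** on the z-scored matrix, with a deterministic sign convention
  (largest-magnitude loading positive per axis) so runs are reproducible.
* **Per-component tests**: Shapiro-Wilk, Levene (median-centred), one-way
  ANOVA with Tukey, Kruskal-Wallis with Dunn (Bonferroni adjustment; the
  study is silent on the adjustment, so the most conservative standard
  choice is used). The parametric and non-parametric batteries are always
  reported together; Tukey is retained under non-normality when Levene
  confirms homogeneous variances.
* **k-means** (`k = 3`, 25 restarts, seeded) with purity against the
  species labels.
* **VIF screen**: iteratively drops the highest-VIF variable until all
  `VIF = 1/(1 - R^2) < 2`; ties drop the lexicographically first variable.
* **RDA** via `vegan::rda()` with seeded permutation tests (global,
  sequential per axis, sequential per term) and Ezekiel-corrected adjusted
  R-squared. The pipeline offers TOC and TN as environmental candidates by
  default; on the default design their VIF is 1.02.
* **PERMANOVA**: Euclidean pseudo-F with the `(1+b)/(1+B)` permutation
  p-value, a required seed, and an exact exhaustive mode for tiny samples
  (all label arrangements enumerated; used to verify the permutation
  machinery against enumeration). A companion dispersion test (ANOVA on
  distances to group centroids) validates the homogeneity assumption.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. Its defaults *are*
the study conditions: three species, five replicates, group means equal to
the published per-species means (one published dehydrogenase entry is
internally inconsistent with the printed across-species mean; the default
table carries the mean-consistent value). Published information stops at
means and significance calls, so the dispersion model is an assumption
surfaced in the design object: coefficient of variation 0.10 for all
replicate-level variables, truncated-at-zero normal noise for activities
and biomass/respiration targets, lognormal noise for quantification
densities with Poisson observation counts. Per-species respiration means
are back-derived from the published per-species `qCO2` and `MBC` so that
replicate-level quotients are internally consistent (their across-species
mean lands within 1.5% of the published mean respiration). Rhizosphere
quantification means equal the soil means except for the DNA-based method,
set one order of magnitude lower, so that only that method separates the
compartments — mirroring the study's observation.

With `cv = 0` every replicate equals its group mean, the dataset is fully
deterministic, and the pipeline reproduces the published worked-example
values exactly; this is the primary acceptance harness.
`null_design()` removes species effects (pooled means within compartment)
for type-I-error calibration, and `toc_gradient_data()` builds a response
matrix driven by a TOC gradient plus an unrelated predictor for
constrained-ordination power checks.

What the generator does **not** emulate: spatial autocorrelation, seasonal
dynamics, taxonomic composition, correlated replicate-level chemistry, and
any replicate dispersion structure beyond a common CV. Passing tests on
synthetic data therefore show that the estimators and inference machinery
are correct and calibrated under the stated noise model — not that the
field study's exact multivariate statistics (PCA variance fractions, RDA
partition, PERMANOVA R²) are recovered; those depend on unpublished raw
replicates and are deliberately out of scope.

## Numerical choices and problem sizes

Permutation tests default to 999 permutations with a required seed; the
pipeline derives stage seeds from its single configuration seed (`seed`,
`seed + 1`, `seed + 2`, `seed + 3` for simulation, PERMANOVA, RDA and
clustering). The MPN root-finder brackets the score equation from
`1/min(inoculum)` upward and solves to square-root machine tolerance, with
`expm1` used near zero for accuracy. Calibration simulations in the test
suite use 1,000 replicates with 199 permutations each (the permutation
p-value granularity of 1/200 is far below the 0.05 Kolmogorov band being
asserted), and the power and clustering-recovery checks use 100 seeded
runs with 999 permutations; these sizes give stable rates while keeping
the whole suite inside a couple of minutes on a single core.

## Known limitations

* Chemistry enters at pooled (group) resolution; replicate-level inference
  on chemical variables reflects the broadcast, not measurement error.
* The MPN confidence interval is a large-sample approximation; for
  extreme outcome patterns (single positive tube) coverage is approximate.
* `CE` can be negative in dehydrogenase-dominated soils, in which case the
  vector summary is undefined by construction and downstream stages carry
  flags rather than values.
* The EPI estimator treats field counts as independent Poisson draws; real
  mosaics show spatial clumping, so its dispersion is optimistic.
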