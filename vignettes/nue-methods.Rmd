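---
title: "Methods: nutrient-use-efficiency indices for two-level fertility trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient-use-efficiency indices for two-level fertility trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yamnue)
library(dplyr)
```

## The problem

White Guinea yam (*Dioscorea rotundata*) is a staple tuber crop of the West
African yam belt, increasingly grown on soils too depleted to sustain good
yields without mineral fertilizer. Genotypes differ both in how hard they are
hit by low soil NPK and in how efficiently they convert applied fertilizer
into uptake and tuber yield. Quantifying those differences takes a small set
of standard indices computed from a two-level fertility trial: a set of
genotypes grown with zero fertilizer input (non-F) and with an NPK dressing
(+F) in a split-plot randomized block design — fertility on main plots,
genotype on subplots.

`yamnue` implements the full chain from plant-level field records to those
indices, together with the classical trial statistics, and a calibrated
simulator so the whole pipeline is testable without field data.

## Data model

The unit of observation is one sampled plant, recorded as long-format rows of
plant × organ (leaf, stem, tuber): fresh weight, dry weight (g), and tissue
N/P/K concentrations (mg g⁻¹ dry matter). The reference design samples
3 plants per subplot × 4 blocks = 12 plants per genotype × treatment cell.
Validation enforces the invariants a field data set must satisfy (dry ≤ fresh,
non-negative weights, concentrations below 1000 mg g⁻¹, unique plant × organ
keys, a tuber record on every plant entering the yield analysis) and reports
every offending row by number.

Only leaf and tuber tissue is assayed in the reference design; stems carry
mass but no concentrations. Whether an unassayed organ contributes zero to
uptake or is an error is an explicit policy switch (`policy = "zero"`, the
default, or `"strict"`). We chose zero-contribution as the default because it
reproduces the published uptake scale and makes the common case run without
ceremony; `"strict"` exists for assays that are supposed to be complete.

## Derived traits and indices

Per plant:

* dry shoot weight = leaf dry + stem dry (g);
* tuber dry matter content = 100 × tuber dry / tuber fresh (%);
* total dry tuber weight = fresh tuber weight × DM/100 (g);
* nutrient uptake `U = Σ_organs dry_g × conc_mg_g / 1000` (g plant⁻¹).

Per genotype × treatment cell, plants are pooled into means (the block
structure is used only by the statistics module). With `x̄_lf`, `x̄_hf` a
genotype's cell means under non-F and +F and `Ȳ_lf`, `Ȳ_hf` the grand means:

* **Percent difference** `PD = (x̄_hf − x̄_lf)/x̄_hf × 100`;
* **Fertility intensity index** `FII = 1 − Ȳ_lf/Ȳ_hf`, the trial-wide stress
  severity;
* **Soil fertility susceptibility index**
  `SFSI = (1 − x̄_lf/x̄_hf) / FII`, so that `SFSI × FII = PD/100` exactly;
  SFSI > 1 classifies a genotype as *susceptible*, otherwise *tolerant*
  (the boundary value 1 is classified tolerant because the susceptibility
  criterion is strictly "greater than 1");
* **Apparent nutrient recovery efficiency**
  `ANR = (U_tF − U_tN)/F × 100` (%), with `F` the nutrient supplied per
  plant;
* **Physiological efficiency** `PE = (T_wF − T_wN)/(U_tF − U_tN)`
  (g dry tuber per g nutrient), `T_w` being dry tuber weight.

Two conventions deserve a note:

* **Grand means.** The default grand mean is the unweighted mean of the
  genotype means (the "mean row" of a genotype × treatment table). For
  balanced data this equals the plant-level mean; the two conventions only
  diverge with unbalanced cells, and both are available
  (`grand_means(..., method)`). Recomputing the reference trial's twelve
  PD and SFSI values from its genotype means with this convention reproduces
  every published value at the printed precision.
* **Nutrient supply per plant.** The trial states a fertilizer rate
  (kg ha⁻¹) and a planting density (plants ha⁻¹) but the division is left
  implicit; `per_plant_supply()` defines `F = rate × 1000 / density`
  (g plant⁻¹), giving 4.5, 2.5 and 3.75 g plant⁻¹ of N, P, K at the default
  90/50/75 kg ha⁻¹ and 20,000 plants ha⁻¹.

Numerical degeneracies are flagged, not silenced: PD/SFSI require a positive
+F mean and a nonzero intensity index; PE with an uptake difference inside
`eps` (default 1e-6 g — tissue-assay resolution is far coarser) returns `NA`
rather than a wild ratio or an exception, and the `NA` propagates through
reports as a flagged missing value.

ANR and PE are computed from genotype × treatment **mean** uptakes and
yields, matching the paired-environment structure of the formulas (they are
not per-plant quantities: no plant is observed under both fertility levels).
Their sampling uncertainty therefore comes from a block-level bootstrap:
blocks are resampled with replacement, cell means recomputed from the
resampled block × cell means, and all indices recomputed (default 1000
resamples, seeded). The balanced-resample grand mean is used inside the
bootstrap, where both conventions coincide.

## Trial statistics

* Per-genotype non-F vs +F contrasts use the two-sample t-test; Welch by
  default because homoscedasticity across fertility levels is not something
  the design guarantees (a pooled-variance flag exists). When both arms are
  exactly constant — which noise-free simulations legitimately produce — the
  test is resolved by convention: identical arms give t = 0, p = 1; distinct
  constant arms are perfectly separated (p = 0).
* Genotype comparisons within one fertility level use one-way ANOVA with
  Tukey HSD pairwise p-values and a compact letter display built by
  insert-and-absorb: sweep groups by descending mean (ties broken by label),
  split every letter class containing a significant pair, then absorb
  redundant subset classes. The display is consistent with its p-matrix by
  construction: genotypes sharing no letter differ at α, genotypes sharing a
  letter do not.
* Pearson correlations between genotype means carry the usual t-transform
  p-value.
* The overall genotype, treatment and interaction tests use a classical
  split-plot ANOVA: plants are first averaged to subplot means, then
  `aov(value ~ treatment * genotype + Error(block/treatment))` tests
  treatment against the block × treatment (main-plot) stratum and genotype
  and the interaction against the subplot stratum. We deliberately use the
  fully specifiable classical decomposition rather than a REML mixed model:
  with balanced data the inferential conclusions coincide, while the sums of
  squares are exactly additive and reproducible to the last bit. Averaging
  plants to subplot means keeps the subplot error from being contaminated by
  within-subplot sampling error.

## The synthetic trial generator

`simulate_trial()` emulates the reference design: 4 blocks × 2 fertility
levels (main plots) × 6 genotypes (subplots) × 3 plants. Each genotype is
parameterized by a +F base value and a responsiveness `r` per trait, so the
expected +F cell mean is the base and the expected non-F mean is
`base × (1 − r)`; the packaged defaults are calibrated so that noise-free
cell means reproduce the published genotype × treatment means exactly —
including the uptakes, for which tuber tissue concentrations are solved per
genotype × treatment given fixed leaf concentrations (30, 3 and 25 mg g⁻¹
N, P, K — typical yam foliage values) and the leaf share of shoot dry
weight.

Noise is multiplicative lognormal (weights are positive and right-skewed) at
three levels, entering as mean-one multipliers shared by all traits of the
affected unit: main plot (CV 0.10), subplot (CV 0.10) and plant (CV 0.20),
plus small independent lognormal noise on concentrations (CV 0.08) and tuber
dry matter content (CV 0.05). The per-plant totals (combined CV ≈ 0.25) give
per-cell spreads compatible with a field trial in which most non-F genotype
contrasts are not individually significant. Free parameters the reference
trial does not pin down — the 0.55 : 0.45 leaf : stem split of shoot dry
weight, leaf tissue concentrations, the 0.30/0.25 dry-matter fractions used
to back out fresh leaf/stem weights — are documented defaults, chosen once,
not fitted quantities.

What the simulator does *not* emulate: spatial field trends, emergence
failure, genotype-specific variance, measurement rounding, and any
correlation between concentration and biomass beyond the shared plot
effects. Tests that pass on simulated data therefore certify the pipeline's
arithmetic and its statistical calibration under the assumed error model —
not the field behaviour of real genotypes.

`recovery_experiment()` closes the loop: it simulates many trials, runs the
full pipeline on each, and reports bias and RMSE of SFSI, ANR and PE against
the configured truth, plus a per-replicate Spearman correlation between
estimated and true genotype SFSI ranks. Noise-free configurations recover
the truth exactly (a regression guard on the whole chain), and estimates
converge to the truth as blocks grow.

One calibration finding is worth stating plainly: at the default variance
components, a single 4-block trial recovers the full six-genotype SFSI rank
order (Spearman > 0.8) in only about three quarters of replicates (mean
Spearman ≈ 0.86). The adjacent true tuber-PD gaps are 5–7 percentage points
while each estimated PD carries a standard error of similar size, so
adjacent rank swaps are common. This is a property of the design at this
noise level, not of the estimator; the extreme genotypes separate reliably,
and the practical reading is that a 4-block trial supports contrasts between
clearly susceptible and clearly tolerant genotypes, not a full ranking.

## Problem sizes used in the test suite

The packaged checks run the power and calibration experiments at sizes
chosen to make Monte-Carlo error small relative to the margins being
asserted: 500 replicates for t-test power and for the split-plot null
calibration (Kolmogorov–Smirnov uniformity at α = 0.01), 200 replicates for
rank recovery, 100 for interaction power, 60 per arm for the
noise-monotonicity check, and 30 replicates of a 64-block trial for the
consistency check (|bias| < 0.02 on SFSI).

## Known limitations

* Stem nutrient content is unobserved in the reference design; if stems
  carry an appreciable nutrient fraction, uptakes (and hence ANR, but not
  PD/SFSI) are systematically understated under the default policy.
* ANR/PE published from unrounded field data cannot be reproduced exactly
  from printed 0.1-g uptakes; agreement is expected within a couple of
  percentage points only.
* The susceptibility classification is a point classification of the SFSI
  estimate; the bootstrap standard errors show it is fragile for genotypes
  near SFSI = 1, and the per-genotype contrast significance is carried as an
  annotation, not folded into the class.
* The split-plot ANOVA requires a complete block × treatment × genotype
  layout; missing cells are an error, never imputed.
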