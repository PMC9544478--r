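---
title: "Models and methods behind the ONSEN drought-tolerance pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ONSEN drought-tolerance pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsenfate)
library(dplyr)
```

`onsenfate` packages the computational stages of a study system in which
heat-mobilised copies of the *Arabidopsis thaliana* retrotransposon ONSEN
(AtCOPIA78) generate drought-tolerant lines, most prominently through an
exonic loss-of-function insertion in *RPI2* (ribose-5-phosphate isomerase 2,
At2G01290). The stages are: a forward-in-time simulator of the fate of such
an insertion in a selfing population under episodic drought; image-based
quantification of vital/necrotic leaf area; the insertion-catalogue
genetics; qPCR copy-number estimation; and a natural-accession association
stage. This vignette explains each model, its assumptions, the tunable
parameters, and what the synthetic-data generators do and do not emulate.

## 1. The fate simulator

### Model

A single biallelic locus in a population of `K` diploids (default
`K = 100`). The insertion allele is fully recessive (`h = 0`): only
insertion homozygotes deviate from fitness 1, with `1 + s_plus` during
drought generations (grid: +0.5, +1, +2, +5) and `1 + s_minus` otherwise
(grid: -0.1, -0.2, -0.5, -0.9). The insertion is founded as one
heterozygote, i.e. one allele in `2K = 200` genome copies (frequency
0.005). Reproduction for 50 generations with a selfing rate of 0.99:
each offspring draws parent 1 proportional to fitness, selfs with
probability 0.99, otherwise draws an independent fitness-proportional
parent 2 (with replacement — a partner can coincide with parent 1, a
standard convention that is negligible at `K = 100`), and receives one
Mendelian allele per parent.

Selection is *hard*: the next population size is
`N' = min(K, round(K * wbar))` with `wbar` the current mean fitness, so a
population of struggling homozygotes shrinks and drift strengthens.
`N' = 0` is recorded as population extinction (and counts as
non-persistence). The description "population size is a function of mean
fitness, capped at the carrying capacity" admits both `K * wbar` and
`N * wbar` scalings; we chose `K * wbar`, the simplest monotone rule in
which a fully wild-type population always sits at carrying capacity.
Rounding is IEEE half-to-even in both the C++ engine and the R oracle so
the two routes agree exactly.

Because parent picks are independent across offspring, the offspring
genotype counts are exactly `Multinomial(N', p)` with a closed-form `p`
(selfing mixture plus random-outcross term from the marginal gamete
frequency). The engine samples that multinomial directly — an exact
reformulation of the per-offspring procedure, not an approximation.

### Drought schedules

One to four drought events of two to four generations are placed "at
regular intervals". The exact placement convention is not recoverable from
the study description, so the package defines event `e` (1-indexed) to
start at generation `round(e * G / (n_events + 1))` — symmetric placement
leaving head and tail room — and rejects pathological horizons where the
blocks would overlap. Any explicit integer vector of drought generations is
accepted wherever a schedule is, so other conventions are a one-liner.
Generation indices are 1-based and drought fitness applies to reproduction
*into* a listed generation.

### Randomness and reproducibility

A root seed spawns one child seed per replicate (and per grid cell), so
`run_grid()` output is bit-identical for a given seed and independent of
chunking. Grids of persistence probability, mean final frequency and
fixation probability over the 192 default parameter combinations are the
simulator's summary product (`autoplot()` shows persistence against
`s_plus` faceted by schedule shape).

### Validation against an exact chain

For `K <= 6` the model is a small finite Markov chain; the package
enumerates it and propagates the founder distribution exactly
(`exact_chain_distribution()`), using the same reproduction rules but an
entirely independent code path (pure R, transition matrices, `dmultinom`).
Tests compare a hand-enumerated one-step distribution, and the stochastic
engine's empirical final-state distribution at 1e5 replicates
(total-variation distance below 0.01 across neutral, drought-advantage and
normal-disadvantage settings at `K` in {2, 4}). Neutral behaviour is
checked against theory: the allele frequency is a martingale (mean final
frequency 1/(2K)) and the long-run fixation probability at `K = 20`,
`G = 500` is 1/(2K).

## 2. Leaf-area phenotyping

Segmentation label images (integer codes: 0 background, 1 vital,
2 necrotic, 3 scale label) are consumed downstream of the pixel classifier,
which is out of scope here. `count_class_pixels()` is an exact histogram;
`calibrate_area()` divides by the measured scale-label pixels and
multiplies by its nominal area, which makes areas invariant to zoom changes
between imaging days — that invariance is the purpose of the in-frame
label, and the ratio convention is chosen to deliver it. The physical label
area was never published, so the default reports areas in "label units"
(`nominal_label_area = 1`).

Per-plant vitality is `100 * vital / (vital + necrotic)` — background is
excluded because it dominates the frame and carries no plant signal. A line
is called drought tolerant when the replicate mean is strictly above 50%
(ties go to non-tolerant). Plants with no leaf pixels at all are flagged
`NA` rather than 0 so that lost images and dead-and-gone plants are not
conflated; `classify_tolerant()` drops `NA` replicates listwise.

Pot weights were recorded on different days than photographs, so
`compute_water_series()` interpolates piecewise-linearly and extrapolates
linearly from the two nearest weighings at the series ends, warning when a
target day lies more than one measurement interval outside the range.
Water content is weight minus dry weight; cumulative water loss is the
first (saturated) weight minus the interpolated weight.

`fit_water_model()` regresses water loss on line, vital pixel count and
their interaction by OLS. Per-term significance uses Type-II (marginal) F
tests — the original analysis does not state the ANOVA type, and Type II is
the standard choice when interest is in main effects in the presence of a
possibly null interaction. The reduced model `water_loss ~ vital_pixels`
carries the headline message that size alone explains water use. A
perfect (zero-residual) fit leaves the F statistics undefined; the table
then reports `NA` rather than fabricating infinite statistics.

`disc_linearity_check()` reproduces the validation logic of the disc
assay: with known numbers of punched discs per class, class pixel counts
must regress linearly on disc number (slope = one disc's area, intercept
~ 0, R^2 ~ 1).

## 3. Insertion catalogue and validation genetics

The ten heat-induced ONSEN insertions of hcLine31 ship as a TSV fixture
transcribed from the published catalogue; coordinates use the printed
abbreviated span style (`149387-91`), which the parser expands by prefix
substitution and the writer re-abbreviates (keeping at least two end
digits, as printed) so round trips are cell-for-cell. Spans wider than
10 bp are rejected: a TIP span is a target-site, not a gene.

The candidate filter encodes the published reasoning: a uniformly tolerant
line implies a homozygous causal mutation, and a knock-out implies an
exonic location — `context == "Exon" & zygosity == "homozygous"` reduces
the 10 insertions to 3 candidates (*AT1G58602*, *AT2G01290*, *AT5G03435*).

Genotyping gels are encoded by `call_zygosity_from_bands()`: a short
elongation time means the flanking-primer PCR only amplifies the empty
site, so (wt+, ins-) is wild type, (wt+, ins+) heterozygous, (wt-, ins+)
insertion homozygote, (wt-, ins-) a failed reaction.
`expected_f2_survival()` enumerates F2 genotypes under the recessive
single-locus model: 25% survivors for hcLine31 x wild type, 100% for the
allelism cross hcLine31 x *rpi2-1* (both alleles are loss-of-function at
the same locus), 0% for wild type x wild type.

## 4. qPCR copy number

`fold_change_ddct()` implements the delta-delta-Ct method with
amplification efficiency fixed at 2 (no standard curve was reported):
technical replicates are averaged per gene, `dCt = Ct_target - Ct_ref`,
`ddCt` is taken against the control sample, and `fold = 2^-ddCt`.
Replicate SDs combine in quadrature through both differences; the fold SD
uses the delta method (`fold * ln 2 * sd_ddct`). `copies_from_fold()`
multiplies by the wild-type baseline, which defaults to 8 ONSEN copies —
a value implied by the published arithmetic (8-fold = ~64 copies) rather
than measured, which is why it is an explicit argument.

## 5. Natural-accession association

Dosages (0/1/2 alternate-allele counts) come from GT-only VCFs via `vcfR`;
multiallelic sites are skipped. The published filters are reproduced:
minor allele frequency strictly above 0.3, and removal of related
ecotypes. Kinship uses the KING-robust within-family estimator (the
`vcftools --relatedness2` statistic),
`k = (N_het,het - 2 N_opposing_hom) / (N_het,i + N_het,j)` over
pairwise-complete sites, which is exactly 0.5 for duplicated genotypes.
Since "keep only ecotypes with k < 0.5" does not specify *which* member of
a related pair to drop, pruning is greedy on the number of violating
partners with a deterministic lexicographic tie-break, so duplicate
clusters collapse to one representative.

The association model is
`aridity = mu + beta * dosage + u_group + e` with a single admixture-group
random intercept. It is fitted by maximum likelihood (not REML): the
variance ratio `lambda = sigma2_g / sigma2_e` is profiled in one
dimension, and at each `lambda` the fixed effects are generalized least
squares. With one grouping factor, a within/between rotation makes the GLS
weights diagonal (within-group deviations have unit weight; the group-mean
component of group `g` has variance `sigma2_e (1 + lambda n_g)`), so each
profile evaluation is a cheap weighted regression and the boundary
`sigma2_g = 0` is checked explicitly (where the fit collapses to OLS). The
fit agrees with `lme4::lmer(..., REML = FALSE)` to numerical precision —
lme4 serves as an independent cross-check in the test suite, never as the
implementation. Wald p-values are reported; with hundreds of ecotypes the
normal approximation is adequate, and the null type-I error is verified by
simulation (3-7% at alpha = 0.05).

"Variance explained" is not defined in the source analysis; the package
defines it as the fixed-effect share of total model variance,
`VE = 100 * beta^2 Var(g) / (beta^2 Var(g) + sigma2_g + sigma2_e)`. The
plug-in estimator is mildly biased upward (it adds `Var(beta_hat)` through
`beta_hat^2`, and with few groups `sigma2_g` is estimated with large
variance); at the study scale (596 ecotypes, 9 groups) the bias is a few
tenths of a percentage point, well inside the recovery tolerance used in
the acceptance checks. The aridity response is treated as an opaque
per-ecotype value: the source is internally inconsistent about whether the
summer window is May-August or April-August, so window construction is the
caller's concern.

LD between SNPs is the composite measure: squared Pearson correlation of
dosage vectors over pairwise-complete ecotypes, invariant to allele
relabeling.

## 6. Synthetic data: what it does and does not emulate

Every consumer stage has a generator with machine-readable ground truth,
all bit-deterministic under a seed:

- `synth_segmentation_image()`: non-overlapping discs (rejection-sampled
  in normalised coordinates, so zoom changes rescale the same layout) plus
  a rectangular scale label; optional vital/necrotic class-flip noise
  emulating classifier confusion. It does *not* render plants — rosette
  shape, soil texture and lighting are irrelevant to the downstream
  arithmetic, which only sees label counts.
- `synth_weight_series()`: daily loss `a + b * size + N(0, sigma)`
  accumulated from a saturated weight with a dry-weight floor. Defaults
  (a = 5 g/day, b = 0.004 g/day per vital pixel, sigma = 1 g, 320 g
  saturated, 100 g dry, weighing days 1/8/15/22/27) are chosen to sit at
  the scale of a small pot drying over four weeks; the real record's
  weather-driven day-to-day correlation is not modelled.
- `synth_tip_table()`: catalogue rows with an exon-bias knob mirroring
  ONSEN's insertion preference for transcribed regions.
- `synth_genotype_aridity()`: Hardy-Weinberg dosages at chosen mafs,
  group-structured response, one causal SNP whose effect is solved from a
  target variance-explained, optional duplicate clusters. Real panels add
  LD structure and maf-structure correlation that the generator omits, so
  passing recovery tests demonstrate estimator correctness under the
  model, not robustness to confounding beyond the group effect.
- `synth_qpcr_plate()`: Ct values with planted folds and replicate noise.

## 7. Problem sizes and numerical choices

The validation and acceptance runs use: 50 000 replicates for the neutral
martingale (and 20 000 at `K = 20`, `G = 500` for fixation), 1e5
replicates per setting for oracle equivalence, 1e4 replicates per cell for
monotonicity (compared with a 99% CI slack on adjacent differences —
persistence differences between neighbouring cells can be genuinely tiny),
500 simulations for water-model coverage, and 200 recovery + 1000 null
simulations for the mixed model. These sizes put Monte-Carlo error well
below each check's tolerance while keeping the whole suite in the
minutes range on one core.

Other numerical conventions: profile search over `log lambda` in
[-25, 15] with an explicit boundary check at zero; `optimize()` tolerance
1e-9; multinomial sampling through R's RNG in both R and C++ so seeds
behave identically; kinship entries with a zero denominator (no
heterozygous sites in either member) are `NA`, never 0.

## 8. Known limitations

- The simulator is single-locus by design: no linked selection, mutation,
  migration or recurrent transposition. It asks only how an existing
  insertion fares.
- `N' = K * wbar` vs `N' = N * wbar` is a genuine ambiguity of the hard-
  selection description; results for the study grid are not sensitive to
  the choice in the regimes reported, but the alternative is not
  implemented.
- The tolerance classifier and candidate filter are faithful to the
  published decision rules, including their sharp edges (strict 50%
  threshold, exon-only context).
- The LMM's Wald inference is asymptotic; for very small panels a
  likelihood-ratio or permutation test would be preferable.
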