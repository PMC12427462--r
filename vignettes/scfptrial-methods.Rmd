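---
title: "Methods: microbiome and palatability analytics for an SCFP feeding trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiome and palatability analytics for an SCFP feeding trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfptrial)
```

## The study design this package models

`scfptrial` implements the analysis chain of a longitudinal feline feeding
trial of a *Saccharomyces cerevisiae* fermentation product (SCFP), a dried
postbiotic. Sixty-three cats are randomised to three arms of 21 — a control
kibble (CD) and the same diet supplying roughly 150 or 300 mg SCFP per kg
body weight (T150, T300) — with fecal shotgun-metagenome profiles at days
0, 21 and 42. The daily food offer is set from the maintenance energy
requirement, 100 x (BW kg)^0.67 kcal/day (`ration_kcal()`). Around the
microbiome chain sit two self-contained analytic blocks: a two-bowl
palatability battery on a separate 20-cat panel and an apparent total tract
digestibility (ATTD) calculation.

The package takes as inputs the *tabular* products of the sequencing
workflow — Bracken-style taxon count tables and genome annotation tables
(EC numbers, KEGG KOs and pathways, CAZy families) — never reads or
alignments. Everything downstream of those tables is implemented here.

## Butyrate-producer screening

Species are screened for butyrate-production potential by completeness of
three routes to butyryl-CoA in their genome annotations
(`butyrate_pathway_catalog()`):

* **acetyl-CoA route** — the route is called present when both terminal
  enzymes are found: crotonyl-CoA reductase (EC 1.3.1.86) and
  trans-2-enoyl-CoA reductase (EC 1.3.1.44). Biochemically the two ECs
  describe alternative final reductions, so `classify_genome()` also
  offers `acetyl_rule = "either"`; the stricter both-enzymes reading is the
  default because the screening rule is stated as requiring the last two
  enzymes of the pathway.
* **glutarate route** — all of EC 2.8.3.12 and 4.1.1.70.
* **4-aminobutyrate route** — all of EC 1.1.1.6, 4.2.1.120 and 5.3.3.3.

A species is a likely producer when *any* genome assigned to it completes
any route (`classify_species()`); species with no annotated genome are
called `none` so that downstream subsetting has total coverage. The
terminal-reaction KOs — buk (K00929), ptb (K00634), atoD (K01034) — are
deliberately not part of the species rule: they define the KO feature
subset used for the KO-level differential abundance.

## Abundance-weighted functional potential

`compile_potential()` builds per-sample functional profiles: every species
whose relative abundance in that sample exceeds 1e-4 contributes that
relative abundance to each KO/pathway/CAZy family carried by any of its
genomes (`species_feature_union()`). Three choices deserve note:

* the inclusion threshold is applied **per sample** — membership in the
  community is a sample-level condition, so a species can contribute in one
  sample and not another;
* weights are raw relative abundances with **no re-closure** after the
  threshold cut; the excluded mass is below 1e-4 per species, so values are
  bounded by 1 and the distortion is negligible, but this is a documented
  divergence risk against workflows that renormalise;
* presence is binary — gene copy number is ignored.

## Compositional preprocessing and diversity

Rare taxa are removed when their **mean** relative abundance across samples
falls below 1e-5 (`filter_rare_taxa()`). The mean basis is a choice: a
per-sample or maximum basis is offered, but the mean is order-independent
and the most common convention. Filtering operates on raw counts;
rarefaction (`rarefy()`, multivariate hypergeometric subsampling to the
minimum per-sample depth by default, single seeded draw) is applied only
for alpha diversity, where unequal sequencing depth would otherwise
masquerade as diversity differences. Beta diversity instead uses the
centered log-ratio transform (`clr_transform()`, pseudocount 0.5 added to
all counts — a common compositional default, configurable), Euclidean
(Aitchison) distances, and centered PCA whose full-dimensional coordinates
preserve those distances exactly.

`permanova()` implements the permutational multivariate ANOVA directly:
Gower double-centering of the squared distance matrix, sequential (Type I)
sums of squares in the order the terms are given — the convention of
`vegan::adonis2`, against which the partition is cross-checked in the test
suite — and p-values of the form (1 + exceedances) / (1 + permutations).
Permutations are free by default, mirroring the study's usage with
repeated measures pooled; a `strata` argument restricts shuffles to within
cat when a conservative repeated-measures analysis is wanted.

## Longitudinal differential abundance

The statistical engine codes dose (0/150/300) and time (day 0/21/42) with
orthonormal polynomial contrasts (`polynomial_contrasts()`; a binary
CD-vs-pooled-SCFP coding is the alternative) and fits, per feature, a
linear mixed model with treatment, timepoint and their interaction as
fixed effects and a random intercept per cat, optionally adjusted for sex
(`fit_feature_models()`; fitting is delegated to lme4/lmerTest via a
prototype fit that is refit per feature). From each fit the per-arm linear
time trend is extracted as a contrast of fixed effects and reported **per
timepoint step**, so a planted slope of b CLR units per step is estimated
as b.

`differential_abundance()` wraps the chain in the LinDA spirit: CLR
transform, per-feature mixed models, then a compositional bias correction —
under CLR a community-wide compositional shift adds the *same* offset to
every feature's coefficient, so the offset is estimated as the median of
the per-feature coefficients (assuming most features are null) and
subtracted before the test statistics are recomputed and BH-adjusted
within term. The published LinDA package's mode-based kernel estimate and
its exact Satterthwaite bookkeeping are not replicated bit-for-bit; the
median is the default here (a kernel-mode option exists) because it is
robust and has no bandwidth parameter. Degrees of freedom are
Satterthwaite by default, with a fast residual-df option
(`df_method = "residual"`) used in the large simulation studies, where
n - p is large enough that the two are practically indistinguishable.

For count outcomes observed at two focal days,
`timepoint_ratio_contrast()` fits a log-link mixed model (Poisson, or
Gaussian on logs) and extracts day-42:day-0 ratios per group on the
response scale (ratio < 1: higher at day 0), plus pairwise and polynomial
dose contrasts on the log-ratios. For continuous fecal-chemistry-style
outcomes the package's convention is to log-transform when |skewness| > 1,
an explicit, testable rule standing in for the usual informal
"considerable deviation from normality".

## Palatability analytics

The two-bowl battery (`palatability_report()`) reproduces the trial's
printed worked examples exactly, which pinned down two conventions:

* the consumption ratio reports the larger-consumed diet first
  (`consumption_summary()`), with 2:1 the inclusive clear-preference
  criterion (`clear_preference()`);
* the first-choice chi-square (`first_choice_test()`) expects
  `n_cats * n_days / 2` choices per diet, df = 1, no continuity
  correction — abstentions do **not** reduce the expectation. This is the
  only convention under which all nine printed daily/overall p-values
  (e.g. counts 14 vs 5 with one abstention giving X² = 4.1, p = 0.043)
  reproduce, and it was frozen before implementation.

Per-cat intake ratios pool grams over days; the signed-rank validation and
the paired daily t-test are delegated to the standard stats routines with
the pairing and stratification assembled here. Acceptability (intake /
offered) is modelled on the logit scale with a per-cat random intercept
(`acceptance_model()`), reporting odds ratios of acceptance against
control. `attd()` applies the digestibility formula
(intake − fecal output) / intake x 100 and flags negative values.

## The synthetic cohort

Because the trial's raw sequence data are not deposited, `generate_trial()`
produces a full synthetic bundle with the statistical structure the
analyses assume; its defaults are the study conditions (63 cats in 3 arms,
3 timepoints, 560 species / 198 genera, depth uniform on
89,217–1,527,695 reads, 38 F / 25 M, 30 producer species, a 20-cat
palatability panel with 100 g bowls).

* **Composition.** Species base abundances are log-normal (sigma = 1.5);
  each cat receives persistent log-abundance offsets (sigma = 0.5) and
  each sample day-to-day jitter (sigma = 0.3); counts are multinomial at
  the drawn depth. These noise scales are calibration choices producing
  realistic between-cat separation in ordinations, not reported values.
* **Planted Shannon decline.** The control arm's diversity decline is a
  progressive power tilt p_i ∝ p_i^(1+εt), with ε solved per cat so that
  the expected ordinary-least-squares Shannon slope over the three equally
  spaced timepoints equals −0.07 per step (with equally spaced steps the
  OLS slope is (H(2) − H(0))/2, so one root-find per cat makes the
  expectation exact). The tilt is a mechanism choice: the decline is
  reported in the source only as a fitted linear trend.
* **Planted producer trends.** Five producer species in T300 get log-fold
  trends of ±0.4 per step (3 down, 2 up, mirroring the reported pattern of
  three decreasing and two increasing producers). The magnitude is a
  calibration choice — no effect sizes are reported — picked once as a
  strong-but-realistic shift; the trend taxa are drawn from the more
  abundant producers so that trends are identifiable at the simulated
  depths.
* **Annotations.** Every producer species carries one complete route in
  exactly one of its 1–3 genomes (exercising the any-genome rule), 15% of
  non-producers carry an incomplete route subset (exercising the
  completeness rules), and background features avoid all catalog ECs.
* **Palatability.** Consumption shares are Beta draws whose logit mean is
  shifted by the preference effect (default 0.8 in favour of the
  supplemented bowl against control, 0 between the two supplemented
  diets), with a per-cat taste effect and a small abstention probability
  (0.025) so the expected-count convention is exercised. With the effect
  at 0, shares centre on 1:1 and first choices are Binomial(n, 1/2).

What the generator does *not* emulate: taxonomic misclassification,
phylogenetic correlation among species, zero-inflation beyond multinomial
sampling, bowl-position effects, or any real fecal chemistry. Passing
tests therefore demonstrate that the chain recovers what it is pointed at
under its own assumptions, not that those assumptions hold in real feline
metagenomes.

## Validation studies and problem sizes

Three simulation studies double as acceptance evidence, with sizes chosen
to keep a full run in minutes:

* `simulate_permanova_type1()`: 500 null replicates of 30 samples x 50
  taxa — rejection at alpha 0.05 should sit in [0.03, 0.07];
* `simulate_da_recovery()`: 50 reduced cohorts (10 cats/arm, 200 species,
  20 producers) run end-to-end from annotations to BH-adjusted per-arm
  trends — sensitivity for the planted taxa at q < 0.05 should be at
  least 0.8 with at most 10% of null producers flagged;
* `simulate_shannon_trend_recovery()`: 200 reduced cohorts — the mean
  fitted CD slope should land within ±0.02 of the planted −0.07 while the
  supplemented arms' slope distributions straddle zero. Slopes here are
  computed on raw counts: depth is drawn independently of timepoint, so
  the small finite-depth bias of the plug-in Shannon estimator cancels
  from the slope.

## Numerical conventions and edge cases

* Canonical ordering of samples and taxa is lexicographic; writers emit
  byte-stable TSV.
* Missing values are not permitted in count tables — no imputation rule is
  defined anywhere in the chain.
* The rarity and inclusion thresholds are strict where stated as
  "less/higher than": a species exactly at 1e-4 is excluded from
  functional potential.
* A paired t-test on zero-variance differences is reported as degenerate
  (p = 1 for identical columns, p = 0 for a constant nonzero difference)
  rather than erroring mid-report.
* `bias_correct()` declines to correct fewer than 5 features (warning),
  since a location estimate over a handful of coefficients is
  meaningless.
* Genus-level analyses can either re-read a genus table or aggregate the
  species table (`aggregate_taxa()`); both entry points exist because the
  provenance of the study's genus tables is ambiguous.

## A small worked example

```{r example, eval = FALSE}
cfg <- reduced_cohort_config()
bundle <- generate_trial(cfg, seed = 1)

calls <- classify_species(bundle$annotations)
producers <- producer_subset(bundle$abundance, calls)

da <- differential_abundance(producers, bundle$design)
head(da[da$term == "time_linear@T300" & da$q_value < 0.05, ])

rep_ <- palatability_report(
  subset(bundle$palatability, diet_a == "CD" & diet_b == "T300"))
rep_$consumption$ratio
```

## Known limitations

The PERMANOVA permutes freely across repeated measures by default (as the
study's analysis appears to); the LinDA approximation differs from the
published package in its bias-location estimator and df details; the
acceptance model treats offered grams as binomial weights, a pragmatic
quasi-likelihood reading of a proportion outcome; and none of the
reported Shannon/PERMANOVA/differential-abundance *values* from the
original cohort are reproducible without the undeposited raw data — the
package's claims about those stages rest on the property-based validation
above.
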