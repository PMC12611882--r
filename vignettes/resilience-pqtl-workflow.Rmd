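---
title: "From contextual fear memory to protein modules: the resqtl methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From contextual fear memory to protein modules: the resqtl methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

resqtl quantifies cognitive resilience in recombinant inbred backcross (RIX)
mouse panels -- F1 crosses in which each animal carries either a paternal B
(C57BL/6J) or D (DBA/2J) allele at every locus over a fixed maternal
background, with roughly half the litter carrying a dominant familial-AD
transgene -- and traces that resilience to genetically regulated protein
modules in the frontal cortex proteome. This vignette explains the models,
the tunable parameters, the synthetic cohort the package validates itself
against, and the numerical choices that a user of the results should know
about.

## The quantitative resilience trait

Contextual fear memory (CFM) is the percent of a test session an animal
spends freezing, in [0, 100]. Transgene carriers (AD) freeze less than
their non-transgenic (Ntg) littermates, but how much less depends on
genetic background. The trait of interest is the deviation of each AD
animal from the expectation set by its own strain's Ntg baseline:

1. average CFM per strain in the Ntg group;
2. regress individual AD CFM values on their strain's Ntg mean, weighting
   each animal by `1/n_s`, where `n_s` is the number of AD animals in its
   strain;
3. z-score the residuals over all included AD animals.

The `1/n_s` weights are not a stylistic choice: they make the individual-
level objective separate into a within-strain constant plus the
strain-mean sum of squares, so the fitted slope and intercept are
*exactly* those of the unweighted regression of AD strain means on Ntg
strain means. That equivalence is asserted to `1e-10` in the test suite
and is the property that lets per-animal residuals and strain-mean
regression coexist in one fit. Strains without an Ntg baseline are
dropped with a warning rather than imputed; z-scores use the sample
standard deviation.

```{r}
library(resqtl)
res <- resilience_scores(phenotypes)   # tibble: animal, strain, group, cfm
glance(res)                            # slope, intercept, R^2, h2, h2_rix
```

## Heritability

Heritability is the one-way ANOVA sum-of-squares ratio
`h2 = SS_strain / (SS_strain + SS_residual)` over strains with at least
two animals, and its strain-mean (replicate-adjusted) form
`h2_rix = h2 / (h2 + (1 - h2)/n)` with `n` the average replicate count.
`h2_rix` equals `h2` at `n = 1`, is monotone in both arguments, and tends
to 1 as replicates accumulate, because strain means average away
environmental noise. At `h2 = 0.26` and `n = 7` the formula gives 0.71.
The sums of squares are computed by group arithmetic -- algebraically
identical to `anova(aov(y ~ strain))`, which the tests assert, but linear
in the number of animals so that panels with thousands of strains (used
in the convergence checks) remain instantaneous.

## pQTL scan, cis/trans, haplotype blocks

Genotypes are coded 0 for homozygous B/B and 1 for heterozygous B/D --
the only two states a backcross panel can show. For every protein x
marker pair the scan fits the simple additive regression of strain-level
log2 abundance (animals averaged per strain) on the code over
pairwise-complete strains, and reports the two-sided t p-value. Proteins
must be observed in at least 10 strains (`filter_min_strains`).
Benjamini-Hochberg q-values are computed jointly across the whole test
matrix through the single shared `adjust_bh()` routine; per-protein
adjustment is available as a flag. A protein's peak is its minimum-p
marker, ties broken by chromosome then position. Records are `cis` when
the marker lies within 5 Mb of the encoding gene's interval on the same
chromosome, `trans` otherwise (including any other chromosome). No
kinship or mixed-model correction is applied; the panel is treated as
exchangeable strains, and covariates are out of scope because the
analyzed cohort is single-sex and single-age.

Linkage disequilibrium between markers is the squared Pearson correlation
of code vectors. A haplotype block is the set of candidate markers whose
r^2 with a peak reaches a threshold (default 1.00, compared with `1e-12`
slack so exact complete linkage is matched despite floating arithmetic);
the block interval spans the member positions.

## Differential expression

Two designs. `trait_association()` regresses strain-level abundance on
the per-strain resilience trait; when chained after the scan, the BH
universe is the pQTL-significant proteins -- the set actually
interrogated. `stratified_de()` contrasts B/B against B/D strains at a
chosen marker; the log2 fold change is oriented B/B minus B/D, so
positive values mean higher abundance in the resilient-genotype strains.
Its moderated t shrinks each protein's pooled variance toward a scaled
inverse-chi-square prior whose degrees of freedom and scale are
moment-matched to the spread of the per-protein sample variances
(`var(s^2)/mean(s^2)^2 = 2(d + d0 - 2)/(d(d0 - 4))`, solved for `d0`);
the moderated variance is the convex combination
`(d0 s0^2 + d s^2)/(d0 + d)` with `d + d0` reference degrees of freedom.
When the sample variances are all equal the prior degrees of freedom go
to infinity sensibly and the moderated t equals the ordinary t, which is
also available via `moderated = FALSE`.

## Module PCA and mediation

Correlated module proteins cannot enter one regression side by side; the
package refuses that design and instead summarizes the module by
principal components of the z-scored strain x protein matrix. The PC1
sign is fixed so its mean loading is positive. For an equicorrelated
module the population PC1 variance fraction is
`(1 + (m - 1) rho)/m` -- 53% at `m = 8`, `rho = 0.463`.

`mediate()` implements the classic three-regression decomposition with X
the genotype code at a haplotype SNP, M a module principal component, and
Y the strain-mean resilience: `a` (X on M), `b` and `c'` (M and X
jointly on Y), `c` (total), with indirect effect `a * b` and the exact
identity `c = c' + a * b` on complete cases. Uncertainty comes from a
stratified case-resampling bootstrap: strains are resampled within
genotype group so X stays polymorphic in every replicate; the interval is
bias-corrected and accelerated (acceleration from a leave-one-strain-out
jackknife), reducing exactly to the percentile interval when bias and
acceleration vanish; the two-sided sign p-value is floored at
`1/(n_boot + 1)`. Missing strains are dropped and counted (`n`,
`n_dropped`) rather than handled by a likelihood machinery the rest of
the package does not use; this is a deliberate, documented simplification.
A degenerate bootstrap falls back to the percentile interval with a
warning.

## TF motif integration

Binding sites arrive as 4-column BED (`chr start end TF:accession`),
0-based half-open; genotype markers are 1-based. The conversion -- a SNP
at `bp` lies in `[start, end)` iff `start <= bp - 1 < end` -- is fixed in
`snps_in_sites()` and nowhere else, and is checked against an exhaustive
double loop. TF abundance tracks are correlated with the trait (Pearson r,
raw p reported first as is conventional for small candidate sets, BH q
alongside), and trait-on-TF regressions can be stratified by genotype
group, omitting groups with fewer than three strains. The shipped
`inst/extdata/*_synthetic.*` files encode a *synthetic* toy geometry for
the candidate regulatory SNP inside an Nr1d1-motif site on the chromosome
1 interval; they are coordinates invented for testing, not database
exports.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it plants a known causal
structure and records it, so every downstream stage can be audited for
parameter recovery. The structure is:

* a block of `block_markers` (default 10) perfectly linked markers on
  chromosome 1, inside a fixed GRCm39-style interval; all other markers
  follow a per-chromosome two-state Markov chain with switch probability
  `recomb_prob` (default 0.1), strains independent. Every marker is
  guaranteed polymorphic, and no non-block marker may be identical to or
  the exact complement of the block pattern (either would be r^2 = 1), so
  block extraction recovers exactly the planted members;
* a module latent `L = a x + noise` driven by the standardized block
  code; `module_size` proteins loading at +/- sqrt(module_rho) on `L`
  (one negative member);
* the trait deviation `D = c' x + b M + noise`, where `M` is the
  *realized* signed-mean signal of the module proteins. Driving the trait
  through the realized proteins rather than the unobservable latent is
  what makes full mediation recoverable: PC1 then measures the true
  mediator, instead of a noisy proxy whose measurement error would leak
  indirect effect into the direct path;
* a ninth trait-associated protein loading negatively on the module
  signal whose own, stronger planted driver sits on a different
  chromosome -- so the truth table lists nine associated proteins, seven
  positive and two negative, one of them trans;
* null proteins, a subset with strong cis drivers at random markers; and
  26 TF tracks, the first with a planted marginal trait correlation
  (default 0.55), the second tracking the trait only within B/B strains
  (within-group R^2 0.53).

Per-animal phenotypes add within-strain Gaussian noise and clamp to
[0, 100]; replicate counts are uniform on `replicates_range` (default
2-17). All randomness descends from one integer seed through a labelled
substream rule (`substream_seed`), so any stage reruns identically in
isolation.

### Calibration conventions

Two generator parameters name the value an *estimator* should recover,
not a raw variance component, because the corresponding estimators are
biased at panel scale:

* `h2_strain` is the expected ANOVA SS fraction. The naive plan -- set
  the between-strain variance share to `h2_strain` -- fails because
  `E[SS_strain]` picks up `(s - 1) sigma_e^2`; at 7 replicates a planted
  0.26 share would be estimated near 0.36. The generator therefore
  inverts the estimator's expectation and plants
  `sigma_s^2/sigma_e^2 = [h s (n - 1)/((1 - h)(s - 1)) - 1]/n`.
* `baseline_r2` is the expected *observed* strain-mean regression R^2.
  Observed strain means carry noise `sigma_w^2/n_s` on both axes
  (attenuating R^2) while finite-panel least squares inflates it by about
  `(1 - rho^2)/(s - 1)`; both corrections are inverted in closed form,
  and the Ntg-mean noise that leaks into the residuals through the fitted
  slope is added back into the within-strain calibration so measured
  heritability stays unbiased.

Convergence checks (the SS fraction within 0.01 of target on a
10,000-strain panel) and the averaged-seed checks in the acceptance suite
pin these calibrations down.

### Default effect sizes, and one deliberate departure

The defaults describe a strong, fully mediated genetic signal:
`snp_module_effect = 0.97`, `module_trait_effect = 0.97`,
`snp_direct_effect = 0`, cis null effects 0.9. They are deliberately near
the feasibility boundary because the per-protein SNP correlation of a
module protein is bounded by `sqrt(module_rho)`, and clearing a
genome-wide BH threshold at 49 strains with comfortable margin requires
most of that ceiling. Relatedly, the default `module_rho` is 0.55 rather
than the 0.463 that yields a 53% PC1 share: a locus whose per-protein
p-values reach ~1e-9 at 30 strains implies per-protein SNP correlations
around 0.85, and no joint linear model can combine those with pairwise
protein correlations of 0.463 (the shared-factor bound forces pairwise
correlation at or above the squared SNP correlation). The two published
features are mutually inconsistent at desk scale, so the default cohort
favors recoverability of the planted module, while the PC1 benchmark is
always evaluated at `module_rho = 0.463`, where it belongs.

### What the generator does not emulate

Gaussian noise everywhere (freezing percentages are clamped, not
logit-modelled); no meiotic map or funnel pedigree, so LD decays
geometrically rather than by genetic distance; no sex or age structure
(the emulated cohort is 6-month-old females); missingness is absent by
default rather than following an instrument-driven pattern; peptide
intensities share a protein profile plus fixed ionization offsets, with
batch shifts that are exactly additive in log2. Passing tests therefore
certify the statistical machinery on data whose assumptions are known to
hold -- they do not certify robustness to the violations real cortex
data can show.

## Problem sizes and runtime choices

The validation suite runs cohorts of 49 strains with a 19 x 12 marker
panel and ~155 proteins (the full chain in about 2 s), 100-200 seed
averages for the calibrated-recovery checks, a 10,000-strain panel for
the heritability convergence check, and 500 synthetic panels for
bootstrap-coverage calibration (nominal 95% intervals, 1000 replicates
each). These sizes were chosen so that each check pins its quantity to
within its stated tolerance while the whole suite stays comfortably
interactive.

## Pipeline orchestration

`run_pipeline()` wires the stages simulate -> normalize -> resilience ->
scan -> associate -> mediate -> motif, failing fast (naming the stage)
when an upstream output is missing. The resilience locus is defined
operationally as the modal peak marker among trait-associated proteins,
expanded to its complete-LD block; the mediation module is the
trait-associated proteins whose peaks fall inside that block. Because
this is a discovery rule, a strongly trait-correlated protein can
legitimately join the module even though it was not planted there --
discovery on FDR-controlled sets admits the occasional extra member by
design, which is also why the validation asserts that the planted module
is contained in the recovered one rather than equal to it. Reports carry
a manifest (package version, seed, configuration hash) and are
byte-identical under identical configuration and seed.
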