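---
title: "Low-pass imputation and haplotype consistency: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-pass imputation and haplotype consistency: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowpasshap)
```

## What the package evaluates

Low-pass whole-genome sequencing (depths of roughly 0.5-4X) recovers
genotypes by imputing against a phased reference haplotype panel. Per-marker
quantities — genotype concordance, dosage accuracy, single-marker
association — are known to survive this procedure well. Haplotype-level
quantities are a different matter: phasing decisions made by the imputation
engine can differ between sequencing depths of the *same* libraries, so any
statistic built on phased haplotypes (extended haplotype homozygosity,
XP-EHH selection scans, haplotype counting) inherits that instability.
`lowpasshap` is a desk-scale, fully synthetic re-implementation of that
evaluation: it generates a panel and a cohort with known truth, sequences
them *in silico* across a depth grid, imputes, and measures both the
per-marker and the haplotype-level consequences.

Everything is driven by one `ExperimentConfig` (see `default_config()`);
`run_experiment()` executes the whole workflow deterministically for a seed.

## The synthetic data generator

**Panel.** `simulate_panel()` uses a founder-mosaic model rather than a
coalescent: each breed has a founder haplotype derived from one ancestral
0/1 string by independent flips at rate `founder_div` (default 0.15); each
panel haplotype walks along the chromosome copying its breed founder,
switching to a random founder at `recomb_switch_rate` per bp, with private
flips at `mutation_rate`. This produces the two features the downstream
analyses actually consume — long shared haplotype tracts and a spread of
allele frequencies with breed structure — without attempting realistic
genealogies. Positions are uniform on a single chromosome (default 20 Mb,
5000 sites, so ~4 kb marker spacing). Multi-chromosome studies are a loop
over configs.

**Panels for imputation.** From a 9-breed master panel (16 haplotypes per
breed), `subset_panel()` builds the three analogues used throughout: a
24-diploid "full" panel containing all 8 target-breed diploids, a
12-diploid target-enriched "panel1", and a 12-diploid target-depleted
"panel2" (at most 1 target diploid, at most 2 per other breed). These sizes
were chosen once as the desk-scale regime for the exact K^2-state
imputation HMM; the 2:1 full:subset ratio mirrors the idea of a large
diverse panel against small curated subsets.

**Cohort.** `simulate_cohort()` builds 30 individuals (6 cases) whose
truth haplotypes are mosaics of the *target-breed* panel haplotypes
(`mosaic_switch_rate`, default 2e-6 per bp, i.e. ~500 kb tracts) plus
private flips at `private_allele_rate` (default 0.02). Private flips are
recorded in `private_mask`: they are the alleles the panel has never seen,
and the imputation engine is expected to pull them toward the panel
frequency — the central caveat the evaluation is built around. The causal
site is drawn among sites with panel MAF in [0.15, 0.35]: common enough to
be imputable, rare enough that 6/30 recessive homozygotes is attainable.
Case genotypes are overwritten (not rejection-sampled) so the case count is
exact and deterministic. Cases additionally carry two copies of a single
donor panel haplotype across a `sweep_bp` (default 1 Mb) window around the
locus: a fully penetrant recessive colour locus in a selected breed implies
exactly this local haplotype homozygosity, and without it no haplotype-based
statistic could possibly detect the locus.

**Sequencing.** `simulate_pileup()` draws per-cell depths
`Poisson(lambda * region_multiplier * indiv_multiplier)` and alternate reads
`Binomial(d, q_g)` with `q_g = (g/2)(1-eps) + (1-g/2) eps` (one symmetric
error parameter, default 0.001; no base-quality spread, no read-length
correlation). The depth grid is 0.9 / 3.8 / 9.6 / 17.4 / 43.5X. The 9.6X
and 17.4X datasets are produced by `thin_pileup()` — independent binomial
read thinning of the 43.5X pileup at the depth ratio (0.40 for 17.4X) —
because those datasets were down-sampled alignments of the same run; 0.9X
and 3.8X are fresh Poisson draws, as independent resequencing runs of the
same libraries. Three 400-kb segments at multiplier 0.3 (renormalised to
chromosome mean 1) emulate hard-to-map regions with depressed coverage;
they are the planted signal for the depth-deviation diagnostics.

Default generator rates were fixed once, after calibrating that the default
simulation displays the qualitative structure the analyses assume —
clearly degraded 0.9X performance, a detectable sweep (an excess of
significant negative XP-EHH Z-scores), a median of ~3 distinct
cross-depth haplotypes per region under missing-restricted counting, and a
5% upper count tail around 8 without the restriction — and were not
revisited afterwards.

What the generator does **not** emulate: alignment and mapping error,
base-quality variation, INDELs and multi-allelic sites, linked read
sampling (depths are site-independent given the multipliers), genotyping
error in the panel itself, and real genealogies. Passing tests therefore
demonstrate the *pipeline's* behaviour under controlled structure, not
field performance on real cohorts.

## Genotype likelihoods and naive calls

`pileup_to_gl()` evaluates `L(g) ∝ (1-q_g)^a q_g^b` in log space and
normalises; zero-depth cells are exactly uniform. `naive_calls()` (the
pre-imputation callset; at 43.5X it is the validation standard for all
concordance) takes the per-cell argmax with ties broken toward the
reference — deterministic, and only relevant for zero-information cells,
which the depth filter masks anyway. Per-depth minimum call depths follow
the evaluation design: 1, 2, 5, 10 for 0.9 / 3.8 / 9.6 / 17.4X (and 10 at
43.5X).

## The imputation engine

`impute_phase()` is an exact diploid Li-Stephens hidden Markov model over
ordered pairs (j, k) of panel haplotypes. Transitions factorise per
haplotype: switch probability `rho_m = 1 - exp(-recomb_rate * ne_scale *
delta_bp)` with the switch landing uniformly on the panel; emissions are
`sum_g GL[m, g] P(g | alleles of j, k copied with error theta)`. The
forward-backward pass runs in O(K^2) per site via row/column sums and is
rescaled per site, so 5000-site chromosomes are far from underflow. A
brute-force path-enumeration oracle pins the implementation down to 1e-10
for K <= 4, M <= 4.

Design choices, all config-exposed:

* **Exact HMM, not sampling.** Production imputation engines iterate
  stochastic haplotype sampling for speed at K in the thousands; at desk
  scale (K <= 512) the exact HMM is tractable, testable against
  enumeration, and deterministic. The price is that the stochastic
  phase-jitter of real engines is *understated*; the switch-error injection
  utilities exist to reintroduce it on demand.
* **Phasing.** Genotypes are the argmax of the genotype posterior (so GP,
  DS and the hard calls never disagree); heterozygote orientation comes
  from the Viterbi ordered-pair path, with the ordered-state posterior as
  tie-break when the Viterbi state copies equal alleles. Phasing is
  therefore bit-reproducible run to run.
* **Parameters.** `recomb_rate` defaults to 1e-8 per bp (a standard
  mammalian per-generation rate) with `ne_scale = 50` multiplying the
  distance — together an effective switch intensity of ~5e-7 per bp,
  comparable to the cohort mosaic scale. `mismatch_theta` defaults to the
  Watterson-style `lambda / (2 (lambda + K))` with
  `lambda = 1 / sum_{k<K} 1/k`. The real engine's internal
  parameterisation is not public in the evaluation being emulated; these
  are stand-ins and nothing downstream is sensitive to factors of a few.
* **Chunking.** 20-Mb chunks with 250-kb overlap; each site's posterior
  comes from the chunk owning its midpoint, and haplotype labels are
  ligated across chunks by matching the two possible label orientations
  over the overlap. On the default single-chromosome config this is a
  single chunk; the multi-chunk path is exercised by tests.
* **INFO.** `info_score()` is the IMPUTE-style ratio of observed dosage
  variance to its binomial expectation, defined as 1 for monomorphic
  posteriors and clamped to [0, 1].

Masking (`mask_low_gp()`, GP < 0.95) marks cells missing for genotype-level
analyses but *retains* the phased alleles: phased output carries an allele
at every site, which is what haplotype-level consumers read.

## Concordance metrics

All rates are computed over comparable cells only (non-missing on both
sides, depth filter, and — when the truth callset carries posteriors — a
0.9999 truth-certainty filter, which is a no-op for simulated truth).
Undefined rates are flagged `NA`, never silently 0. Non-reference
discordance excludes concordant homozygous-reference pairs from the
denominator. MAF bins default to edges (0, 0.001, 0.005, 0.01, 0.05, 0.1,
0.2, 0.5] — the evaluation bins "by allele frequency" without printing
edges, so these are a conventional choice. Haplotype discordance compares
same-labelled haplotypes exactly as emitted (split-and-compare); an
optimal re-pairing mode exists but is off by default because the literal
procedure is what the evaluation used. Switch error is the fraction of
consecutive truth-heterozygous site pairs (restricted to sites the test
callset also calls heterozygous) whose relative phase disagrees.

## Association and selection scans

`lmm_assoc()` is an EMMAX-style mixed model: one REML fit of
`y = W a + u + e`, `u ~ N(0, sigma_g^2 K)` under the null via the
eigendecomposition of the centred GRM, then per-site GLS Wald tests with a
t reference on `n - c - 1` degrees of freedom (which keeps the 30-sample
null calibrated; the asymptotic normal would not be). The binary phenotype
is analysed as quantitative, as the reference implementation's LMM does.
Sites are tested on imputed dosage by default — the dosage uses more of the
imputation output than hard calls; a hard-call mode is a one-liner via
`hard_calls()`. Forcing `sigma_g^2 = 0` reduces the scan to OLS exactly,
which is the closed-form limit the tests check.

`xpehh_scan()` computes EHH as the probability that two random haplotypes
of a population are identical over the span from the core (core site
included; EHH of the empty span is 1), truncates at the first EHH below
0.05, integrates over *physical* distance (no genetic map exists here) with
linear interpolation to the exact cutoff crossing (truncation mode
switchable), and takes `ln(iHH_A / iHH_B)` at every core with pooled MAF >=
0.05. Standardisation is genome-wide (not frequency-binned — the binned
variant is a documented alternative) with the population (n-denominator)
standard deviation, so Z has mean 0, sd 1 exactly. Fixation in the case
population B drives Z negative. Cores at the chromosome edge contribute a
one-sided integral and are flagged rather than dropped.

## Haplotype-consistency diagnostics

Regions are fixed-variant-count windows (default 100 consecutive sites)
with uniformly sampled starts — the evaluation's region size distribution
implies variant-indexed sampling. For each region and individual, the
2 x n_depths phased strings are collected and distinct strings counted.
If imputation and phasing were consistent across depths the count is 1
(all homozygous) or 2; a single-variant genotype difference in one depth
makes 3. (A pure phase flip at one heterozygous site makes the count 2 or
4, never 3, because both labelled strings change; the counting tests
enumerate this.)

Two counting modes exist because missing-data handling is genuinely open:
restricting to positions non-missing in every depth (`respect_missing =
TRUE`, the conservative default of the operation) or counting the retained
phase at all positions (`FALSE`). The pipeline's diagnostics use the
latter: phased VCFs carry an allele everywhere, and the restriction mode
systematically *removes* the discrepant sites in depressed-coverage
regions — under it, planted low-coverage segments show *lower* counts,
inverting the phenomenon being studied, whereas the retained-phase mode
reproduces it (flagged regions concentrate in the planted segments).

The regional depth-deviation test is a paired two-sided Wilcoxon
signed-rank on per-individual (region mean depth, chromosome mean depth)
pairs: zeros dropped (Pratt mode available), average ranks for ties, the
exact conditional distribution by dynamic programming up to n = 30 non-zero
pairs and a tie-corrected, continuity-corrected normal approximation
beyond. All-zero differences give p = 1 by convention. Window metrics are
computed in 1-Mb windows with windows outside the (0.01, 0.99) quantile
band of window mean depth dropped, and median region haplotype counts are
rounded up before the p-on-haplotypes regression.

## Problem sizes and determinism

The shipped defaults are desk-scale: one 20-Mb chromosome with 5000 sites,
a 24-diploid full panel, N = 30, five depths, three panels, 2000 regions
(the operation's own default of 10,000 regions reflects a genome-scale run;
2000 matches a single 20-Mb chromosome), 1-Mb windows. A full
`run_experiment()` takes a few minutes on one CPU; the test suite runs its
cross-depth properties on 10 seeds of the default simulation. Every random
stage derives its seed deterministically from the config seed, so reports
are bit-identical across runs — including the Viterbi phasing, whose
tie-breaks are fixed (prefer staying, then a haplotype-B switch, then
haplotype-A, then both).

## Known limitations

* Desk-scale panels cannot reproduce published genome-scale magnitudes
  (e.g. exact r^2-by-depth medians or raw counts of significant scores);
  the package's claims are orderings, calibrations and mechanism checks,
  which is also how its acceptance checks are framed.
* A fully penetrant recessive phenotype leaves essentially no residual at
  the causal site once its dosage is measured well, so the top-depth Wald
  p there can underflow to astronomically small values. With only ~5000
  sites, that single point gives the Pearson correlation of `-log10(p)`
  vectors across depths large seed-to-seed swings; the *ordering*
  (0.9X tracks the top depth worse than 3.8X and above) is the stable,
  tested property.
* Deterministic phasing understates real engines' stochastic phase
  variability; cross-depth inconsistency here is driven by data, not
  algorithmic randomness. The switch-error injection utility quantifies
  the consequence of the missing variability.
* The error model is a single symmetric epsilon; there is no
  mapping-quality or BAQ modelling, so "hard-to-map" regions exist only
  through the depth multipliers.
* The exact HMM is O(K^2 M) per individual; it is intended for panels of
  tens to a few hundred haplotypes, with a hard cap at K = 512.
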