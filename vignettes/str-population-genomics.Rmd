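---
title: "STR population genomics with strpopgen: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STR population genomics with strpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpopgen)
```

# The setting

Short tandem repeats mutate predominantly by slippage, adding or
removing whole repeat units. Two consequences drive everything in this
package. First, allele *length* is an ordered, quantitative character:
two alleles one unit apart are more closely related than two alleles
ten units apart, and statistics that exploit this (Rst, the stepwise
distance Dxy, dosage) extract more signal than treating each length as
an unordered category. Second, loci are deeply multiallelic, so
SNP-style 0/1/2 codings do not apply directly; PCA needs the
indicator-matrix expansion and diversity needs frequency-spectrum
statistics (PIC, Shannon's H′).

The pipeline takes per-sample diploid allele-length calls (a
lobSTR-style VCF with `MOTIF`/`END` INFO keys and a `GB` deviation
field, or matrices built in code), a sample-to-population map with
optional per-population environment values, SNP dosages for
comparison, and BED interval sets for genomic context.

# Models and estimators

## Rst

For two groups at one locus,
$$R_{st} = \frac{S_t - S_w}{S_t},$$
where $S_w$ averages over the two groups the mean squared
allele-length difference and $S_t$ is the same mean over the pooled
alleles. We define the mean over **all ordered allele pairs**
(equivalently, twice the population variance of allele length). This
choice is deliberate: with means over distinct unordered pairs only,
two groups sharing an identical allele multiset would produce
$S_w > S_t$ and hence a spuriously negative Rst, because the
within-group pair set excludes proportionally more self-comparisons
than the pooled set. Under the ordered-pair definition the
shared-multiset case gives exactly 0 and complete fixation for
different lengths exactly 1, which is what a fixation index should do.
Remaining ambiguities are exposed as flags on `rst()`:

* `within_individual` (default `TRUE`): whether the two alleles of one
  individual form a valid within-group pair.
* `weighted` (default `FALSE`): $S_w$ averages the two group means
  with equal weight; the alternative weights by pair count.
* `units`: bp (default) or repeat units — Rst itself is invariant to
  this per-locus rescaling, only the reported $S_w$/$S_t$ change.

A monomorphic pooled sample ($S_t = 0$) leaves Rst undefined; such
loci are excluded from the genome-wide Z-transformation and cannot be
flagged significant. Significance is rank-based: the top 5‰ of defined
Rst values (k = ⌈0.005 n⌉, ties at the cut broken by genomic order for
determinism), then significant loci within 5 kb (start-to-start by
default; `measure = "end"` gives end-to-start) chain into candidate
differentiated regions.

## Dxy and the neighbour-joining tree

$$D_{xy} = \frac{1}{4N} \sum_{\mathrm{loci}} \sum_{i,j \in \{1,2\}}
  |C_{Ai} - C_{Bj}|$$
with $C$ the repeat count (allele length / unit length, real-valued so
imperfect repeats pass through unchanged) and $N$ the number of loci
non-missing in *both* samples of the pair (pairwise-complete, the
standard treatment when missingness is unmodelled). Loci enter after
an informativeness screen on the major allele frequency. A literal
minimum threshold of 0.05 on the major allele is near-tautological for
realistic allele counts, so the default screen instead prunes
near-fixed loci (major allele frequency ≤ 0.95) and both knobs
(`major_freq_min`, `major_freq_max`) are exposed; monomorphic loci
contribute nothing to the numerator but would inflate $N$, and the
default screen removes them.

Trees are classical Saitou–Nei neighbour joining computed by
`ape::nj()` on the Dxy matrix; branch lengths may be negative as in
the classical algorithm (`clamp_negative` truncates). The package
builds only the repeat-count distance tree; a separate
standard-genetic-distance tree is out of scope.

## Indicator encoding and PCA

A locus with $n$ observed alleles contributes $n-1$ columns: alleles
are ranked by descending cohort frequency (ties by ascending length),
the most frequent allele is the dropped reference, and entries are
per-sample copy counts (0/1/2), so a biallelic STR reduces exactly to
minor-allele dosage. Missing genotypes are mean-imputed per column
before centring — the usual smartPCA-style preprocessing; `impute =
FALSE` keeps `NA`s. PCA itself is an SVD of the column-centred matrix
(unit-variance scaling optional), eigenvalues reported on the sample
covariance scale, with the sign convention that each component's
largest-magnitude score is positive so results are reproducible across
BLAS implementations and sample orderings.

## Environmental association

Per locus, ordinary least squares of the environment on dosage with
the first three genotype PCs as covariates, mirroring the direction a
field study would use when the environment is recorded per population
(`direction = "dosage"` swaps response and predictor; without
covariates the t-test p is identical either way). The dosage
coefficient's two-sided t-test p-value is reported; loci with fewer
than `n_min = 20` called samples or zero dosage variance are marked
untestable rather than fitted unstably. The Bonferroni threshold
defaults to alpha divided by (testable loci × variables) — with 0.05
and 600,000 tests, 8.33 × 10⁻⁸ — and a per-variable count is a
one-line change in `bonferroni_threshold()`. Significance is strict
(`p < threshold`).

Two caveats are inherent to the design, not implementation details:

* **Pseudo-replication.** The environment is constant within a
  population while regression runs over samples. When population
  structure is not fully captured by the covariates, the per-sample
  t-test is anti-conservative; in simulations with eight diverged
  populations and three PCs we measure inflation well above nominal.
  The calibration study therefore uses layouts where the covariates
  can span the between-population space (see below). Interpreting
  p-values from such scans on real cohorts warrants the same caution.
* **Attenuation.** A planted effect acts on the population-mean
  dosage, but the regression uses individual dosages (population mean
  plus within-population deviation), a classic errors-in-variables
  setting: estimated coefficients are biased toward zero even while
  detection power is essentially 1. The acceptance script reports the
  recovered median coefficient alongside the detection rate.

## Genomic context

Feature intervals are 0-based half-open in files and in the
`feature_set` container (BED convention), loci 1-based inclusive (VCF
convention); conversions happen only at the container boundary, and
overlap queries run through `GenomicRanges`. Each locus gets the
single highest-precedence overlapping class (default CDS > 5′UTR >
3′UTR > H3K4me3 > H3K27ac > intron > intergenic; ≥ 1 bp overlap).
Enrichment is reported both ways the field quotes it: the odds ratio
of the 2×2 table and the density fold (class rate over genome-wide
rate), with a Pearson chi-squared test without continuity correction
(Yates by flag) — large STR catalogues make the large-sample test
appropriate, and a zero margin marks the record untestable. TSS
profiles use the locus midpoint, distance signed by gene strand so
upstream is negative, binned counts normalised per bp per locus.
Hotspots tile chromosomes in 1-Mb windows, assign loci by start
coordinate, keep terminal partial windows (flagged) but exclude them
from the genome-wide mean/SD, and flag counts strictly above
mean + 2 SD, so a flat genome yields no hotspots.

## STR versus SNP signals

SNP differentiation uses the Hudson Fst estimator from the two
groups' sample allele frequencies, Z-transformed genome-wide exactly
like Rst, so Z-vs-Z is scale-compatible; association mode compares
−log₁₀ p from the identical OLS design run on SNP dosages
(`dosage_assoc()`). Windows are centred on the STR start, ±100 kb by
default; an STR is "stronger" only when its signal strictly exceeds
the maximum SNP signal, and the flag is undefined when no SNP lies in
the window.

# The simulator: what it emulates and what it does not

`simulate_str_cohort()` is a forward-time Wright–Fisher simulator
under the strict symmetric single-step mutation model: each allele
gains or loses one repeat unit with probability `mutation_rate` per
generation, reflecting at one repeat. A shared ancestral pool evolves
for `burnin_generations` (default 200) so standing variation exists at
the split, then each of `n_populations` evolves independently for
`divergence_generations` (a star phylogeny — no migration, no nested
splits). Diploids are drawn from the final pools, missing calls
injected per genotype, and one master seed drives fixed per-stage
child seeds so cohort, environment, features and SNPs can be
regenerated independently.

Default study conditions (chosen once as a realistic
moderately-diverged livestock-style cohort, and used by the test
suite): 8 populations × 15 diploids, 200 loci cycling 2–6 bp motifs at
10 ancestral repeats (well under the 80 bp calling limit), mutation
rate 10⁻³ per allele per generation, 500 generations of divergence at
diploid size 50, 2% missing calls, a 2 × 10 Mb genome. Environment
values are built per population as
Σ effect × population-mean dosage + N(0, `env_noise_sd`), every sample
inheriting its population's value — deliberately reproducing the
population-level assignment and its pseudo-replication caveat.
`simulate_features()` places non-overlapping intervals per class and
can force a stated fraction of a locus subset inside one class so
enrichment is detectable by construction; `simulate_snps()` draws
Balding–Nichols diverged frequencies and binomial dosages.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: mutation-rate heterogeneity
across loci and length dependence, multi-step and biased mutations,
range constraints beyond the lower reflecting boundary, interrupted or
imperfect repeat structure, linkage and recombination, migration and
admixture, nested population histories, genotyping error and allelic
dropout (missingness is injected completely at random), and reference
bias. Results on real cohorts inherit none of the calibration
guarantees measured under this model.

# Validation studies and problem sizes

The suite's heavier studies, all seeded and sized to run comfortably
on one CPU:

* *Rst oracle*: 200 random two-group cohorts (≤ 6 diploids per group)
  against exhaustive ordered-pair enumeration at 10⁻¹² tolerance, plus
  the exact fixation (1) and shared-multiset (0) fixtures.
* *Tree recovery*: 200 random 5–8-taxon trees; neighbour joining on
  their additive (cophenetic) matrices must recover every topology
  (Robinson–Foulds 0).
* *Scan calibration*: 20 seeds × 500 loci. The null uses a panmictic
  cohort (zero divergence, 400 burn-in generations) with four
  population labels, so the three PC covariates can span the full
  between-population space, and applies the ≤ 0.95 major-allele
  screen; the empirical type-I error at α = 0.05 must sit inside its
  binomial 99% interval. With five or more diverged populations, or
  without covariates, the same scan is measurably anti-conservative —
  that is the design caveat above, demonstrated by the
  covariate-reduces-false-positives property test rather than hidden
  by the calibration study's layout.
* *Power*: 20 seeds of the 8-population default with a planted effect
  of 1.5 environment units per bp and noise SD 0.1; the planted locus
  must fall below the Bonferroni threshold in ≥ 90% of seeds.
* *Differentiation monotonicity*: mean Rst at 50 vs 2,000 generations
  of divergence (2 × 30 diploids, 200 dinucleotide loci, 10 seeds)
  must rank correctly in every seed or by paired Wilcoxon p < 0.01.
* *Enrichment recovery*: trinucleotide loci forced into CDS intervals
  at fraction 0.5 against a ~8% CDS genome fraction, implying a
  density fold near 3; the recovered median over 10 seeds must lie in
  [2, 4].

`scripts/acceptance.R` re-runs scaled versions of these studies from a
single command-line seed and writes every quantity as JSON.

# Numerical conventions, degenerate inputs, limitations

* Percentiles for the expansion score use linear interpolation between
  order statistics (R's default type 7); the test suite pins this
  against an explicit order-statistic oracle. The score is invariant
  to sample relabelling and to rescaling lengths and unit together;
  the expanded flag is inclusive at 10.
* PIC uses the Botstein form; Shannon's H′ uses natural log with a
  `base` argument. Polymorphism defaults to ≥ 2 distinct observed
  alleles (`min_alleles = 3` for the stricter reading). Diversity
  panels stratify by population by default with a pooled option.
* All-missing loci yield empty spectra and `NA` statistics; a fully
  monomorphic cohort flows through `rst_scan()`, `top_permille()` and
  `merge_cdr()` producing empty results, while `z_transform()` refuses
  a zero-variance or all-undefined scan with an explicit error.
* He/Ho ratios are infinite for a fully heterozygous sample and `NaN`
  when a sample has no called loci — flagged, not silently dropped.
* NJ tie behaviour and PCA sign are fixed as described so identical
  inputs give identical outputs across platforms.
* Loci are validated once at construction: motif 2–6 bp over ACGT,
  reference length equal to the span and ≤ 80 bp, overlapping loci
  dropped keeping the first in genomic order, with a dropped-record
  count attached. Motifs are kept strand-as-reported.
* Known limitations: no mixed-model association (kinship random
  effects), no permutation p-values for Rst (rank cutoffs only, as in
  the scan design), no bootstrap support on trees, no reverse-
  complement motif canonicalisation, and the simulator limits listed
  above.
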