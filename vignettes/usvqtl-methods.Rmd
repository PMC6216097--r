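---
title: "Methods: heritability and QTL mapping of infant vocalization traits"
author: "usvqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heritability and QTL mapping of infant vocalization traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvqtl)
```

## The designs and what they identify

The package analyzes infant ultrasonic vocalization (USV) traits — number,
duration, mean peak frequency, and mean peak amplitude of calls, plus counts
of ten call-type syllables — in two complementary mouse designs.

**The recombinant inbred (RI) panel.** Strains descended from two inbred
parents (coded `B` and `D`), each strain a fixed homozygous mosaic of the
two parental genomes. Because every genome can be resampled, the panel
supports both broad-sense heritability of individuals and the heritability
of *strain means*, and it is the design used for QTL mapping.

**The reciprocal diallel cross.** The two parental strains and their
reciprocal F1 hybrids (`B6D2F1`: B6 dam; `D2B6F1`: D2 dam). Reciprocal F1
females inherit identical nuclear genomes, so any systematic difference
between them must come from the parents — maternal environment or genomic
imprinting — rather than from the alleles the pups carry. This is the
design used for the parent-of-origin test.

## Heritability estimators

`variance_partition()` fits a fixed-effects linear model with the caller's
terms in the caller's order and reports *sequential* (type-I) sums of
squares, so each term is adjusted only for those before it. For the diallel
reproduction the conventional order is strain, litter, sex, age, weight,
then interactions. Fractions of the total sum of squares sum to one,
including the residual.

Three heritability quantities are computed:

* **h² (full model)** — the strain fraction from the full sequential model
  on diallel data. With only four genotype groups this conflates additive
  and dominance variance; the package reports it without claiming
  additivity.
* **H² (strain only)** — `broad_h2()`: the strain fraction of total SS from
  a strain-only model, the broad-sense heritability of individuals in the
  RI panel.
* **HRIx̄² = Va/(Va + Ve/n)** — `hri2()`: the heritability of strain means,
  where `Va` is the between-strain variance component, `Ve` the
  within-strain variance, and `n` the number of within-line replicates.
  Resampling the same genome `n` times shrinks the environmental term, so
  HRIx̄² exceeds the individual-level ratio and approaches 1 as `n` grows.

`broad_h2()` extracts `Va` and `Ve` from the ANOVA mean squares by the
balanced-design moment estimator, `Va = (MS_strain − MS_within)/n̄` with
`n̄` the mean per-strain record count for unbalanced data, floored at zero.
The SS-ratio H² is biased slightly upward at finite replication (about
+0.04 at 41 strains × 8 pups for a true fraction of 0.6); the moment
components behind HRIx̄² are unbiased, which the recovery tests exploit.

Confidence intervals come from `subsample_ci()`: the statistic is
recomputed on repeated 95% subsets of the records drawn without
replacement, and the 2.5th/97.5th percentiles of the resampled values are
reported. (The source material is ambiguous about whether one or both
tails were recorded; this package always returns and labels both
percentiles.) Per-day estimates are merged by `combine_across_days()`, the
inverse-squared-standard-error weighted mean.

`trait_diagnostics()` supports the "one big locus or many small ones"
question: it standardizes strain means, returns normal-probability-plot
coordinates, and reports the largest successive gap between sorted
z-scores — a crude bimodality indicator, since a single large-effect
biallelic locus splits strain means into two modes.

## The QTL scan

Mapping operates on per-strain trait means (`strain_means()`), optionally
winsorized first: `winsorize_means()` converts the means to z-scores and
replaces any value with |z| above 2.5 by the nearest retained value on the
same side, logging each change. Replacement is applied on both sides: the
documented worked example in the source data raises a low value, so a
one-sided reading would not reproduce it.

`expected_dosages()` codes `B` as −1 and `D` as +1 and fills a pseudomarker
grid (default 1 cM) with the conditional expectation of the allele given
the nearest informative flanking markers. Recombination between adjacent
positions uses the Haldane map function expanded for sib-mated RI lines,
`R = 4r/(1+6r)`. Between concordant flanks the expectation is taken as the
flanking code itself — the double-exchange configuration is not
entertained, which keeps genotyped-equivalent positions at exactly ±1 —
and between discordant flanks the single exchange is placed left or right
with odds `(1−R_L)R_R : R_L(1−R_R)`, so the midpoint of a discordant pair
scores 0. Heterozygous and unknown calls are treated as missing and
mean-imputed per position. Plain linear interpolation is available via
`interpolate = TRUE` for comparison with systems whose method is unstated.

`hk_scan()` is Haley-Knott regression: at every position an
intercept-plus-slope least-squares fit of strain means on dosage, scored by
`LRS = N ln(RSS0/RSS1)` and converted to LOD by dividing by 4.61. The
additive coefficient is the slope under ±1 coding, i.e. half the D-minus-B
class difference. Degenerate positions (constant dosage) score 0, and RSS1
is floored at `RSS0 × 1e-10` so perfect fits yield a large finite score.

Genome-wide significance is calibrated by `permutation_thresholds()`:
strain means are permuted across strains (the mapping unit is the strain,
so individual-level permutation is not offered), the genome-wide maximum
LRS recorded per permutation (default 5,000), and the 95th and 37th
percentiles of that null distribution returned as the significant
(p < 0.05) and suggestive (p < 0.63, about one false QTL per scan)
thresholds.

`lod_support_interval()` reports the 1.5-LOD support interval: the
outermost contiguous positions whose LOD stays within 1.5 of the peak,
truncated at chromosome ends, in Mb. `bootstrap_peaks()` resamples strains
with replacement (default 2,000 resamples) and tallies where the
genome-wide peak lands; ties go to the lowest coordinate.
`peak_report()` turns a scan plus thresholds into a peak table: contiguous
supra-suggestive runs are peaks, sibling peaks on one chromosome are
separated by dips below the suggestive line, and for sibling pairs the
report counts strains carrying opposite parental alleles at the two peak
markers — the haplotype argument for two linked QTLs rather than one —
and flags overlapping support intervals, leaving the one-versus-two
question to the reader.

**Kinship correction.** RI strains generated at different epochs are
unequally related, which inflates single-marker statistics.
`kinship_matrix()` builds the centered genotype cross-product relatedness
(rescaled to unit mean diagonal), and `kinship_lmm_scan()` fits
`y = μ + xβ + u + e` with `cov(u) ∝ K`: the variance ratio
`δ = σe²/σg²` is estimated once under the null by restricted likelihood on
the spectral decomposition of `K` (one-dimensional search on log δ over
[ln 1e-5, ln 1e5]), and every position is then tested by generalized least
squares with those weights held fixed — the usual
"population parameters previously determined" approximation; exact
per-position re-estimation is available behind `refit = TRUE`. With
`K ∝ I` the scan reduces exactly to `hk_scan()`.

## Candidate-gene triage

`interval_candidates()` selects genes overlapping a support interval (any
overlap, closed endpoints — stated explicitly because boundary genes
matter in practice), optionally restricted to genes carrying a coding
variant (nsSNP or InDel). `evidence_rank()` groups candidates by how many
of three curated evidence lists they appear in — cis-eQTL for the gene's
own transcript, expression correlation with the mapped trait, and prior
phenotype associations — with the all-three tier as the top candidates.
Evidence flags are curated inputs; no databases are queried. The packaged
tables `chr2_candidates.tsv` and `chr8_candidates.tsv` encode the
published lists for the two fine-mapped loci (symbols and flags as
published; Mb coordinates are approximate placements within each
interval).

## The synthetic-data generator

`simulate_ri_genotypes()` draws each strain's chromosome as a two-state
Markov chain: the first marker is either parental allele with probability
½ and adjacent markers disagree with probability `4r/(1+6r)` on the
Haldane `r` implied by the cM gap. No heterozygous or unknown calls are
emitted (real files may contain them; the reader handles those). Autosomal
inheritance only.

`simulate_ri_phenotypes()` composes each pup × day value as grand mean +
additive QTL effects + polygenic strain deviate + litter deviate +
maternal (dam) deviate + fixed day shift + residual, with component
variances scaled so the realized fractions match the configuration in
expectation, and QTL fractions nested inside the strain-level (genetic)
fraction. Defaults mirror the study conditions: 41-strain panels are
typical downstream, 4 litters × 2 pups per strain (within the reported
range of 2–5 litters and > 310 pups over 41 strains), recording days 7–9,
variance fractions 0.6 strain / 0.2 litter / 0.2 residual (strain
fractions of 0.3–0.7 and litter contributions of 10–51% are the reported
range), day shifts worth about 1% of variance, and no sex effect (none was
detected in the quantitative traits). Within-pup day-to-day correlation
defaults to 0 with a `pup_day_cor` knob, since no value is reported.
Maternal effects are modelled at the litter level (each litter has one
dam), so in the RI design they are empirically confounded with litter
effects; they are kept as a separate knob for completeness and default
to 0.

`simulate_diallel()` gives both reciprocal F1 groups one shared genetic
value, adds the dam-strain maternal deviation, and adds a parent-of-origin
deviation with opposite sign in the two reciprocal groups, so the expected
reciprocal-F1 difference is twice the sum of the maternal contrast and the
parent-of-origin deviation. Defaults are 6 litters × 5 pups per group
(matching the reported group sizes of 24–30), amplitude-like strain means
(−36/−23/−39 dB) and an 8 dB residual SD chosen to reproduce the reported
standard errors of about 1.5–2 dB at n ≈ 30. Sexes alternate within
litters. `simulate_calltype_counts()` is a plain multinomial draw over the
ten syllable categories.

What the generator does *not* emulate: acoustic waveforms, amplitude
clipping of loud calls (noted in the source data but uncorrected there and
here), X/Y and mitochondrial inheritance, day-by-strain interactions, and
non-normal trait distributions. Passing tests therefore demonstrate that
the estimators recover the variance structure and loci they were designed
for — not that real recordings satisfy these assumptions.

## Numerical choices and problem sizes

* LRS-to-LOD conversion uses the conventional constant 4.61 exactly.
* Permutation thresholds default to 5,000 permutations; bootstrap
  histograms to 2,000 resamples; subsample CIs accept any iteration count
  ≥ 100 (the checks here use 1,000; the original analysis used 100,000,
  which changes only the Monte-Carlo error of the percentile estimates).
* Power simulations (`power_by_simulation()`) model strain means directly:
  the planted QTL carries `qtl_fraction` of the genetic variance, and the
  remaining genetic variance is drawn as an unlinked strain deviate (an
  infinitesimal-model reading; for detection of the planted locus an
  unlinked polygenic term and measurement noise are interchangeable). The
  nested permutation thresholds inside power loops use 500 permutations
  per panel — the threshold estimate is unbiased, and its extra noise is
  absorbed into the Monte-Carlo error — while standalone thresholds keep
  the 5,000 default. The threshold rule behind the published power figures
  is not recoverable from the available material, so the policy
  (significant / suggestive / pointwise) is an explicit argument.
* Validation problem sizes were fixed in advance at the study scale:
  41-strain panels, 200-replicate recovery and calibration runs, 1,000
  markers for null-calibration scans, a planted QTL at 40% of strain-mean
  variance (with HRIx̄² = 0.8: polygenic 40%, noise 20%) for
  interval-coverage checks, and 400 null diallels for test-size checks.
* Ties at the scan maximum resolve to the lowest-coordinate position, so
  bootstrap histograms and peak reports are deterministic given the data.
* `winsorize_means()` requires at least 3 strains and errors on zero
  variance; `hk_scan()` requires at least 4 complete strains;
  `kinship_lmm_scan()` rejects asymmetric or indefinite kinship matrices
  (eigenvalues below −1e-6 of the spectral radius).

## Known limitations

* The moment estimator for `Va` uses the mean per-strain count for
  unbalanced designs; strongly unbalanced panels would warrant the
  unweighted-means correction or REML, which is out of scope here.
* The diallel "h²" from four genotype groups is not a narrow-sense
  estimate in the strict additive sense.
* The mixed-model scan reuses the null variance ratio across positions;
  for very strong QTLs the per-position `refit = TRUE` path is more
  accurate and proportionally slower.
* Evidence flags for triage are curated inputs; the package deliberately
  does not recompute eQTLs or trait correlations from expression matrices.
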