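# usvqtl

Quantitative-genetic analysis of mouse infant ultrasonic vocalizations
(USVs) — the isolation calls pups emit on postnatal days 7–9 — for two
complementary designs:

* a **recombinant inbred (RI) panel** (BXD-style strains descended from
  C57BL/6J and DBA/2J), used to estimate heritability and map quantitative
  trait loci (QTLs) for call number, duration, mean peak frequency, and
  mean peak amplitude; and
* a **reciprocal diallel cross** (B6, D2, and the reciprocal F1 hybrids),
  used to separate genetic from maternal and parent-of-origin
  contributions, since reciprocal F1 females carry identical nuclear
  genomes.

It is aimed at behavioral geneticists working with RI strain means and
diallel pup data who want the full pipeline — variance partitioning,
permutation-calibrated genome scans, and candidate triage — as plain,
testable R functions.

## What it computes

**Heritability.** Sequential ANOVA variance partitions
(`variance_partition`), broad-sense H² as the strain fraction of total sum
of squares (`broad_h2`), and the heritability of strain means

    HRIx̄² = Va / (Va + Ve / n)

(`hri2`), with `Va` the between-strain variance component, `Ve` the
within-strain variance, and `n` the number of within-line replicates.
Empirical 95% intervals recompute the estimator on repeated 95% subsets of
the pups (`subsample_ci`); per-day estimates merge by inverse-squared-error
weighting (`combine_across_days`); `power_by_simulation` estimates the
power to detect a locus carrying a given fraction of the genetic variance.

**QTL mapping on strain means.** Winsorization of outlying means beyond
|z| = 2.5 (`winsorize_means`), expected allele dosages at markers and
pseudomarkers using the sib-mating RI expansion R = 4r/(1+6r)
(`expected_dosages`), Haley-Knott regression scans scored as
LRS = N·ln(RSS₀/RSS₁) with LOD = LRS/4.61 (`hk_scan`), genome-wide
significant (p < 0.05) and suggestive (p < 0.63) thresholds from 5,000
phenotype permutations (`permutation_thresholds`), 1.5-LOD support
intervals (`lod_support_interval`), 2,000-resample bootstrap peak
histograms (`bootstrap_peaks`), a kinship-adjusted mixed-model scan via
spectral decomposition (`kinship_matrix`, `kinship_lmm_scan`), and a peak
report that separates sibling peaks and counts discordant-allele strains
between them (`peak_report`).

**Diallel analysis.** Kruskal–Wallis / pairwise Wilcoxon / Tukey group
comparisons (`group_comparison`), the reciprocal-F1 parent-of-origin rank
test with effect direction (`parent_of_origin_test`), per-subject
call-type percentage profiles averaged as mean-of-ratios
(`calltype_profile`), and vocal-organ volumes from serial-section areas
(`section_volume`).

**Candidate triage.** Genes overlapping a support interval, optionally
restricted to carriers of coding variants (`interval_candidates`), ranked
by membership in three evidence lists — cis-eQTL, trait-correlated
expression, prior phenotype — with the all-three tier as the top
candidates (`evidence_rank`).

**Synthetic data.** Generators for RI genotype mosaics, structured
phenotypes (strain/QTL/litter/maternal/residual variance components over
three recording days), reciprocal diallel families, and multinomial
call-type counts (`simulate_ri_genotypes`, `simulate_ri_phenotypes`,
`simulate_diallel`, `simulate_calltype_counts`), plus readers/writers for
the GeneNetwork `.geno` dialect and tabular phenotype, strain-mean, and
scan files (`read_geno`, `read_phenotypes`, `strain_means`, `write_scan`,
...).

## Worked example

Simulate a 41-strain panel with a QTL on chromosome 2 carrying 60% of the
genetic variance, estimate heritability, and map the locus:

```r
library(usvqtl)
map  <- sim_map(n_chr = 5, markers_per_chr = 25, length_cM = 60)
geno <- simulate_ri_genotypes(41, map, seed = 11)
pups <- simulate_ri_phenotypes(geno, sim_config(qtl_spec = c(c2_m13 = 0.6),
                                                seed = 12))

h7 <- broad_h2(pups, "amplitude_db", day = 7)
h7
#> H2_strain_only = 0.625  (day 7 )
#>   Va = 0.525, Ve = 0.383, n = 8.00
hri2(h7$Va, h7$Ve, h7$n)
#> [1] 0.916

means <- winsorize_means(strain_means(pups, "amplitude_db", day = 7))
dos   <- expected_dosages(geno, step = 1)
scan  <- hk_scan(dos, means)
th    <- permutation_thresholds(dos, means, n_perm = 5000, seed = 13)
th
#> genome-wide thresholds (5,000 permutations):
#>   significant (p<0.05): LRS 13.20 / LOD 2.86
#>   suggestive (p<0.63): LRS 6.42 / LOD 1.39
peak_report(scan, th, geno)
#> QTL peaks (suggestive or better):
#>   chr marker cM Mb   LRS   LOD significant ci_lo_mb ci_hi_mb ...
#> 1   2 c2_m13 30 60 33.73 7.317        TRUE       56       62 ...
```

The panel was built with variance fractions 0.6 strain / 0.2 litter / 0.2
residual, so H² ≈ 0.62 and HRIx̄² ≈ 0.92 at 8 pups per strain are the
expected recoveries; the scan finds the planted marker `c2_m13`
genome-wide significant (LOD 7.3 against a significance line of 2.9) with
a 1.5-LOD support interval of 56–62 Mb around it.

Candidate triage on the packaged evidence tables for the two fine-mapped
amplitude/frequency loci:

```r
genes <- read_gene_table(usv_example("chr8_candidates.tsv"))
evidence_rank(interval_candidates(genes, "8", c(3.5, 16.7),
                                  require_coding_variant = TRUE))
#> evidence tiers (number of lists a gene appears in):
#>   tier 3: 3 gene(s) [Arhgef10, Csmd1, Dlgap2]
#>   ...
```

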