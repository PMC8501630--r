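# cnacomplexity

Downstream analysis of allele-specific copy number profiles of tumor
genomes.

Tools such as ASCAT turn SNP-array (or sequencing) data into a segmentation
of each tumor genome: ordered segments, each with integer copy numbers for
the two alleles, plus estimates of tumor ploidy and aberrant cell fraction.
`cnacomplexity` is everything that comes after that step for a cohort of
tumors:

* **Ploidy and aberration calls.** Tumor ploidy is the length-weighted
  median total copy number across the genome; a segment with total copy
  number `c` is a *gain* when `c > P + δ` and a *loss* when `c < P − δ`
  (default `δ = 0`, the strict rule).
* **Recurrent aberrant regions.** Per-position gain/loss frequencies across
  samples, and maximal regions aberrant in at least a proportion `p` of the
  samples (default `p = 0.30`), annotated with overlapping genes and
  cytobands.
* **Eight genomic-complexity indices**, genome-wide and per chromosome arm
  (8 × 43 = 344 arm-wise scores per tumor with the packaged 43-arm layout).
  For a region with clipped segments *i = 1..n* (lengths `L_i`, totals
  `c_i`, alleles `a_i ≥ b_i`, covered length `W`, regional weighted median
  `m`, genome ploidy `P`, focal cap `w0 = 3 Mb`):

  | index | meaning | formula |
  |---|---|---|
  | `var`  | variation vs regional median | `(1/W) Σ L_i·abs(c_i − m)` |
  | `steep`| steep copy transitions | `(1/W) Σ_adj abs(Δc)·min(L_j, L_{j+1}, w0)` |
  | `curv` | oscillation (focal complex events) | `(1/W) Σ_int e_j·min(L_j, w0)`, `e_j` the strict local-extremum magnitude |
  | `dev`  | deviation from ploidy | `(1/W) Σ L_i·abs(c_i − P)` |
  | `gain` | gain magnitude×width | `(1/W) Σ L_i·max(0, c_i − P)` |
  | `loss` | loss magnitude×width | `(1/W) Σ L_i·max(0, P − c_i)` |
  | `loh`  | allelic skew with one allele lost | `(1/W) Σ_{b_i=0, c_i≥1} L_i·(a_i − b_i)` |
  | `asym` | allelic skew with both alleles kept | `(1/W) Σ_{b_i≥1} L_i·(a_i − b_i)` |

  `dev = gain + loss` holds identically; `loh` and `asym` use the
  allele-specific values, the rest the totals.
* **Stratified comparisons.** Welch t-tests (Wilcoxon rank-sum when
  Shapiro–Wilk rejects normality at α = 0.01 in either group) of the scores
  between two sample strata (e.g. TP53 mutated vs wildtype), with optional
  residualization on covariates (ploidy, aberrant cell fraction) and
  Bonferroni correction over the score family.
* **Cis-gene integration.** A gene is a *cis-gene* when the Pearson
  correlation between its total copy number (segment at the gene midpoint)
  and its log2 expression exceeds 0.4 **and** at least one of two t-tests
  (loss vs normal, normal vs gain; `δ = 0.5` grouping) has P < 0.05 — a
  deliberately liberal, uncorrected criterion. The smaller P is rescaled to
  `Z = −Φ⁻¹(P)` for display (P = 0.05 ↦ Z = 1.64). Fisher one-sided
  enrichment with Benjamini–Hochberg correction runs over user-supplied GMT
  gene sets.
* **Synthetic cohorts.** A generator emulates segmentation output: a
  multimodal ploidy mixture (modes at 2, 3.5 and 5.5 copies), whole-arm
  gains/losses, focal and focal-complex oscillating events, LOH and allelic
  asymmetry at configurable Poisson rates, plus matched expression with
  known cis effects — and emits the full ground truth for every cohort.

## Worked example

```r
library(cnacomplexity)

layout <- default_layout()                       # 43 chromosome arms
ann    <- simulate_annotation(layout, n_genes = 300, seed = 2)
cohort <- generate_cohort(layout, demo_group_specs(n = 20), ann, seed = 42)

cohort$profiles[[1]]
#> sample_profile TP53mut_01: 111 segments, ploidy=3.498, acf=0.571

round(score_genome_wide(cohort$profiles[[1]])[, -1:-2], 3)
#>     var steep  curv   dev gain  loss   loh  asym
#> 1 0.842  0.07 0.037 0.842 0.67 0.172 0.865 0.553
```

This near-triploid tumor deviates from its ploidy over most of the genome
(`dev` 0.84, mostly `gain`), carries massive LOH (0.87 copy·fraction) and
some focal complexity (`steep`/`curv`).

```r
track   <- aberration_frequency(cohort$profiles)
regions <- annotate_regions(recurrent_regions(track, p = 0.30), ann)
head(regions[, c("chrom", "start", "end", "direction", "peak_freq", "genes")], 3)
#>   chrom     start       end direction peak_freq             genes
#> 1  chr4 174509272 187922040      gain       0.3 G0096,G0097,G0098
#> 2  chr5  23430270  23662770      gain       0.3
#> 3  chr5  25393632  26051677      gain       0.3             G0100

scores <- score_cohort(cohort$profiles, "genome")
covs   <- data.frame(sample = cohort$metadata$sample,
                     ploidy = as.numeric(cohort$metadata$ploidy),
                     acf    = as.numeric(cohort$metadata$acf))
groups <- setNames(cohort$metadata$TP53, cohort$metadata$sample)
compare_groups(adjust_scores(scores, covs), groups)[, c("index", "test", "p_bonferroni", "significant")]
#>   index     test p_bonferroni significant
#> 1   var        t     5.56e-04        TRUE
#> 2 steep        t     4.49e-09        TRUE
#> 3  curv        t     1.31e-07        TRUE
#> 4   dev        t     5.56e-04        TRUE
#> 5  gain wilcoxon     3.93e-01       FALSE
#> 6  loss        t     5.01e-01       FALSE
#> 7   loh        t     1.54e-02        TRUE
#> 8  asym wilcoxon     1.56e-01       FALSE
```

At n = 20 per group the high-burden ("mutated") stratum separates on five
of the eight genome-wide indices after ploidy/cellularity adjustment and
Bonferroni correction over the family of 8.

```r
cis <- call_cis_genes(cohort$expression, cohort$profiles, ann, regions = regions)
sum(cis$cis)
#> [1] 34
head(cis[cis$cis, c("gene", "n", "r", "min_p", "z")], 3)
#>     gene  n     r   min_p    z
#> 7  G0007 40 0.648 0.00179 2.91
#> 21 G0021 40 0.557 0.01057 2.31
#> 22 G0022 40 0.569 0.01330 2.22
```

34 of 300 genes pass the compound cis criterion; with the cohort's true
`cis_fraction = 0.2` and effect β = 1, most carry a genuine effect. The
whole chain can also be driven from files with
`run_pipeline(pipeline_config(...))`, which writes one TSV per stage plus a
run manifest.

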