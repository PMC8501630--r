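---
title: "Complexity scoring and cis-expression integration for allele-specific copy number profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity scoring and cis-expression integration for allele-specific copy number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnacomplexity)
```

## The analysis model

`cnacomplexity` operates strictly downstream of allele-specific copy number
segmentation. Its input world is the one a tool like ASCAT emits: for every
tumor, an ordered list of genomic segments each carrying two non-negative
integer copy numbers (major allele `a ≥` minor allele `b`), plus optional
real-valued estimates of tumor ploidy and aberrant cell fraction. Raw array
or sequencing signal, normalization and the segmentation itself are out of
scope; segments are taken at face value. Segments need not tile the genome —
uncovered bases are treated as missing, never as copy-neutral.

Internal coordinates are 1-based inclusive throughout (the segment-table
convention). BED annotation input is 0-based half-open and converted at the
boundary, so a BED row `chr1 0 100 GENE1` becomes the internal interval
1–100.

### Two notions of ploidy

The package distinguishes two quantities that are often conflated:

* the **calling ploidy**: the length-weighted *median* total copy number of
  the sample's segments — the smallest total `v` such that segments with
  total `≤ v` cover at least half the covered genome. On integer segment
  data this is an integer, which is what makes the strict gain/loss rule
  (`c > P` / `c < P`) meaningful: with any non-integer reference every
  integer segment would be aberrant and the "normal" class would be empty.
  `call_profile()`, the recurrence stage and the cis grouping all use this
  measure.
* the **supplied ploidy**: the upstream tool's own real-valued estimate
  (carried in the segment table), which behaves like a length-weighted mean
  and is the right covariate and reporting quantity. `compute_ploidy()`
  returns it when present (with the computed median attached as an
  attribute), and `adjust_scores()` consumes it.

The weighted median uses the **lower-median tie rule** (smallest value whose
cumulative length reaches `W/2`): deterministic, and integer on integer
input. A 50/50 split between totals 2 and 4 therefore yields ploidy 2, not
3.

### Aberration calls and recurrent regions

A segment with total `c` is a *gain* when `c > P + δ`, a *loss* when
`c < P − δ`, *normal* otherwise. The default `δ = 0` is the strict rule used
for recurrence; equality is not "exceeding". The three labels partition the
segments for every `δ`, and growing `δ` can only move calls toward normal.

Across a cohort the genome is cut into atomic intervals by the union of all
samples' breakpoints (`GenomicRanges::disjoin`). Gain and loss frequencies
at an interval are computed **over the samples covering it**, not over the
whole cohort, so sparsely covered regions are not artificially diluted; the
per-interval denominator `n` is reported so users can filter. Maximal runs
of adjacent atomic intervals with frequency `≥ p` (inclusive threshold,
default `p = 0.30`) become recurrent aberrant regions, separately per
direction, with no minimum width. Gene and cytoband annotation requires at
least 1 bp of true overlap; an abutting gene is not listed.

### The eight complexity indices

For a region R the clipped, ordered segments *i = 1..n* (lengths `L_i`,
totals `c_i`, covered length `W = Σ L_i`, regional weighted median `m`,
genome calling-ploidy `P`) are compressed into eight non-negative,
dimensionless-copy scores — `var`, `steep`, `curv`, `dev`, `gain`, `loss`,
`loh`, `asym` (formula table in the README). The first six use total copy
numbers; `loh` and `asym` use the allele-specific values. Each score couples
the *magnitude* of an aberration with the *width* of genome it affects.

The quantitative form of each index involves choices this package fixes and
documents:

* **Breakpoint weighting and the focal cap.** Each copy transition
  contributes its magnitude `|Δc|` times the narrower flanking width, capped
  at `w0` (default 3 Mb, the focal scale; a `score_config()` parameter). The
  cap makes a narrow shift count fully while a breakpoint between two huge
  segments contributes at most `w0`, so `steep`/`curv` respond to focal
  complexity rather than to arm-level architecture. Consequence worth
  knowing: while `var`, `dev`, `gain`, `loss`, `loh` and `asym` are exactly
  invariant under a uniform rescaling of all lengths, `steep` and `curv` are
  invariant only while the capped widths stay below `w0` — the cap is an
  absolute physical scale, deliberately not rescaled.
* **Merging.** Adjacent segments with identical `(a, b)` are merged before
  scoring, so splitting a segment into equivalent halves never changes any
  score and breakpoint terms reflect true copy transitions. Adjacency means
  consecutive segments on the same chromosome; marker-sparse gaps (e.g.
  centromeres) do not break adjacency, matching how segmented data are
  produced.
* **Oscillation.** `curv` scores interior segments that are strict local
  extrema of the total-copy sequence, by the distance to the nearer
  neighbor level. A plateau is not an extremum; a lone whole-arm gain moves
  `dev`/`gain` but not `curv`.
* **LOH vs asymmetry.** `loh` counts skew `a − b` only where the minor
  allele is completely lost (`b = 0`) with at least one copy retained;
  homozygous deletions (`c = 0`) contribute to `loss`, not to `loh` —
  nothing is retained there. `asym` counts skew where both alleles survive
  (`b ≥ 1`). Copy-neutral LOH is thus visible to `loh` alone, and
  `dev = gain + loss` holds identically (positive/negative part
  decomposition), which the tests assert everywhere.
* **Degenerate regions.** A region with zero covered length yields eight
  missing values, never zeros — an uncovered arm is unknown, not quiet.

Scores are computed genome-wide (8 per tumor) and per arm of a
`genome_layout` (8 × 43 = 344 per tumor with the packaged layout). The
packaged layout is an hg19-style cytoband-derived arm table — 24
chromosomes × 2 arms minus the five acrocentric p arms (13p, 14p, 15p, 21p,
22p) = 43 arms. No genome build is implied by the method itself; users can
supply any 4-column arm table or UCSC cytoband file. Raw scores are emitted
with no variance stabilization or rank transform.

### Group comparisons

Scores are compared between exactly two strata with a Welch t-test, replaced
by the Wilcoxon rank-sum test when a Shapiro–Wilk test rejects normality at
α = 0.01 in either group — an explicit operationalization of "strong
deviation from normality"; near-constant groups also fall back to Wilcoxon.
Welch rather than pooled-variance because strata in practice are very
unbalanced (e.g. 20 mutated vs 134 wildtype). The Bonferroni family is
every score tested in the mode — 8 genome-wide, 8 × arms arm-wise — and
significance means adjusted P < α (default 0.05); `−log10 P` is also emitted
for display. Groups smaller than 3 are skipped with a warning.

Covariate adjustment (`adjust_scores()`) replaces each score column, within
each region, by residuals of an ordinary least-squares fit on the covariates
plus intercept (typically supplied ploidy and aberrant cell fraction).
Linear residualization is the package's documented choice of adjustment;
constant covariates are dropped with a warning, samples with missing
covariates excluded with a message.

### Cis-genes, Z-scores, enrichment

Per gene, the total copy number of the segment containing the **gene
midpoint** is paired with the gene's log2 expression in each sample (the
midpoint rule resolves genes spanning breakpoints deterministically).
Samples are grouped gain/loss/normal at the gene with `δ = 0.5` around the
calling ploidy — with `δ = 0` and any real-valued reference there would be
no normal class for the t-tests to compare against. A gene is *cis* when
Pearson `r > 0.4` **and** at least one of loss-vs-normal / normal-vs-gain
Welch t-tests has P < 0.05, each t-test requiring ≥ 3 samples per arm (a
test that cannot run contributes no P; the gene can still qualify through
the other). No multiplicity correction is applied — the criterion is
intentionally liberal. The smaller P is rescaled to `Z = −Φ⁻¹(P)` (strictly
decreasing, antisymmetric; Z > 1.64 iff P < 0.05) purely for display.
Raw total copy number, not a log-ratio, enters the correlation. Genes with
constant copy number have undefined `r` and are never cis.

Enrichment of the cis list in user-supplied GMT gene sets uses the
one-sided Fisher exact test on the (in set) × (cis) table over the analyzed
universe, with Benjamini–Hochberg correction across sets.

## The synthetic-data generator

`generate_profile()`/`generate_cohort()` emulate the *post-segmentation*
interface, not the array: integer allele-specific segments tiling the
layout's arms (autosomes + X by default), with

* a **ploidy mixture** (defaults: modes at 2, 3.5 and 5.5 copies with
  weights 0.6/0.3/0.1, echoing the multimodal ploidy distributions seen in
  lung-cancer cohorts). The drawn target `T` sets each arm's baseline total
  to `⌊T⌋` or `⌊T⌋+1` (probability = the fractional part), split as evenly
  as possible between alleles, so the emitted length-weighted-mean ploidy
  clusters at the mixture modes within ±0.25;
* Poisson-count events composed sequentially with alleles floored at 0:
  whole-arm ±1 gains/losses, focal ±1 events (0.5–10 Mb), focal-complex
  events of k alternating +1/−1 sub-segments (k in 3–7), LOH (minor allele
  to zero, copy-neutral with probability 0.5) and allelic asymmetry (+1
  major copy where the minor allele is retained); event placement is
  uniform within a uniformly chosen arm, clipped at arm boundaries;
* matched expression `μ_g + β_g (c_gs − P_s) + N(0, σ)` with `μ_g ~ N(7,
  1)`, `β_g = β` for a random `cis_fraction` of genes and 0 otherwise;
* a full truth table (every injected event, every true cis gene with its
  β, the noise SD and the seed). All randomness flows from one seed;
  rerunning is byte-identical, and emitted tables pass the package's own
  reader validation.

The demo configuration (`demo_group_specs()`) contrasts a high-burden,
ploidy-shifted stratum (labelled TP53-mutated; arm/focal/complex/LOH/asym
rates 12/8/4/5/4 per genome) with a quieter near-diploid stratum (rates
4/2.5/1/1.5/1.2) at 30 samples per group — roughly threefold rate contrasts,
the regime in which mutation-stratified cohorts separate on complexity
scores. Aberrant cell fractions are drawn from a Beta(5.3, 4.7) (mean
≈ 0.53).

**What the generator does not emulate** — and hence what green tests do and
do not show about real data: no tumor purity or subclonality (integer states
only), no marker noise or segmentation error, no GC waves, no distance decay
or co-occurrence structure between events, no expression covariance beyond
the cis effect, uniform event placement instead of fragile-site or
selection-driven hotspots. Results on synthetic cohorts validate the
pipeline's arithmetic and statistical behavior, not biological discovery
performance.

## Simulation designs used by the test suite

Problem sizes were chosen so the entire suite runs comfortably on a laptop
while keeping estimates stable:

* **Oracle equivalence.** All eight scores and the weighted-median ploidy
  are checked against an independent per-base implementation (expand the
  genome to single bases, run-length encode, apply the definitions
  directly) on 50 random tiling profiles of ≤ 10⁴ bases each, at `w0 = 50`
  bases.
* **Cis recovery.** 10 cohorts of 100 diploid-baseline samples × 1,000
  genes, 200 of them with β = 1 at noise SD 0.3 — with the default event
  rates this puts the per-gene population correlation near 0.8. Measured:
  sensitivity ≥ 0.90, false-positive rate ≤ 0.02 (observed in practice:
  ≈ 1.0 and ≈ 0).
* **Comparison validity.** 1,000 null families (both groups N(0,1), n =
  30/group, 8 scores): family-wise error after Bonferroni ≤ 0.07. Power: a
  2-SD shift on all 8 scores at n = 30/group is detected on all 8 after
  correction.
* **Enrichment.** Fisher P equals an explicit hypergeometric tail sum
  (`choose()` arithmetic, not `fisher.test`) on a deterministic grid of
  tables with universes 10–200, plus the BH step-up worked example
  (0.01, 0.02, 0.04) → (0.03, 0.03, 0.04).

## Known limitations

* The quantitative index formulas realize their verbal definitions but are
  this package's own fixing; other implementations of the same ideas may
  scale differently, so compare absolute score values only within one
  implementation.
* `steep`/`curv` are not invariant under genome rescaling once flank widths
  exceed the cap (see above).
* Frequency tracks use covering-sample denominators; cohorts with very
  heterogeneous coverage should inspect the reported `n` per interval.
* The midpoint rule assigns one segment per gene; genes straddling a
  breakpoint inherit the midpoint side only.
* Multi-group (> 2) comparisons and GISTIC-style significance models for
  recurrence are intentionally absent.
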