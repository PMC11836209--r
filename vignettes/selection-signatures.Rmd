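---
title: "Within-population selection-signature scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-population selection-signature scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

`ovisweep` scans a single population genotyped on a medium-density SNP array
for footprints of recent selection, and summarizes its genetic diversity and
genomic inbreeding. Two complementary within-population statistics are
implemented from first principles:

* the **integrated haplotype score (iHS)**, which contrasts the decay of
  extended haplotype homozygosity (EHH) around the ancestral and the derived
  allele of each SNP in phased haplotypes. A recent incomplete sweep leaves
  the swept allele on unusually long shared haplotypes, so its integrated
  EHH is inflated relative to the alternative allele;
* **runs of homozygosity (ROH)**, contiguous homozygous stretches arising
  from autozygosity. Their incidence across individuals ("ROH islands")
  marks regions dragged to homozygosity in a substantial part of the
  population, and their summed length per individual gives the genomic
  inbreeding coefficient F_ROH.

Everything else in the pipeline — file IO, quality control, diversity
statistics, inbreeding coefficients, window tiling, interval overlap — is
the standard machinery those statistics need, exposed as plain functions so
each stage can be tested against independent oracles.

## The model, stage by stage

### Quality control

Filters are applied in a fixed order: non-autosomal loci out (default
autosome set `1:26`, the sheep karyotype); samples with genotyping rate
below 90%; SNPs with call rate below 90% (on the retained samples); SNPs
with minor allele frequency below 0.05 (on non-missing calls of the
retained samples). The order matters only in edge cases, but fixing it
makes the removal ledger additive and reproducible; sample-level filtering
precedes frequency-dependent SNP filtering, as PLINK does by convention.
MAF is always computed from non-missing genotypes.

### Diversity statistics

Per SNP: minor allele frequency (binned into the seven classes
`[0,0.01]`, `(0.01,0.05]`, ..., `(0.4,0.5]`), observed heterozygosity
`Ho = n_het / n`, and expected heterozygosity with the small-sample
correction `He = 2p(1-p) * n/(n-1)`. The correction is not universal in the
literature; it is adopted here because it makes `He` an unbiased estimator
and keeps the expected-homozygosity term of `F_HOM` consistent with PLINK's
`--het`. The proportion of polymorphic SNPs `P_N` counts MAF strictly above
0.05. Pairwise identity-by-state sharing uses loci complete in both
individuals (pairwise deletion), `D_ST = (IBS2 + 0.5 IBS1)/N`, distance
`D = 1 - D_ST`. All "mean ± SD" summaries use the sample SD.

### ROH detection

The scanner is the sliding-window method: a window of `min_snps` SNPs moves
one SNP at a time; a window is homozygous ("hit") if it contains at most 1
heterozygous and 2 missing calls. Each SNP's hit proportion is the fraction
of windows covering it that are hits; SNPs above the 0.05 proportion
threshold are run candidates (the threshold is the conventional default of
sliding-window ROH tools and is configurable). Maximal candidate stretches
are split at inter-SNP gaps above 1 Mb and retained if they hold at least
`min_snps` SNPs, span at least 1 Mb, and have at least 1 SNP per 100 kb.
Heterozygous or missing calls inside a run are allowed exactly insofar as
the per-window rule admits them; runs are never merged across a gap.

`min_snps` is not a free constant: it comes from the false-positive bound
`L = ln(a/(n_s n_i)) / ln(1 - het)` — the smallest run length whose
expected number of chance occurrences among `n_s` SNPs in `n_i` individuals
at mean heterozygosity `het` stays below `a`. The result is rounded *up*:
for a 45,943-SNP, 514-individual dataset at `het = 0.388` the bound is
40.68, so 41 SNPs. Rounding to nearest would give the same integer here,
but only the ceiling preserves the bound in general.

Run length is `end - start + 1` with closed SNP-position endpoints; the
five reporting classes are half-open `[1,5)`, `[5,10)`, `[10,20)`,
`[20,40)`, `[40,Inf)` Mb, so every run falls in exactly one class.
`F_ROH` divides each individual's summed run length by the SNP-covered
genome length (per-chromosome span between first and last SNP, summed).
ROH islands are maximal stretches of consecutive SNPs whose run incidence
reaches the population threshold, 10% inclusive ("at least 10%").

### EHH, iHH and iHS

For a focal SNP and allele, EHH at flanking SNP `x` is the probability that
two carrier haplotypes drawn without replacement are identical at every SNP
between the focal SNP and `x`; the implementation groups carrier haplotypes
incrementally (groups can only split while moving outward, so every curve
is non-increasing by construction). Curves are followed until EHH drops
below 0.05 — that boundary point is kept — and integrated over physical bp
by the trapezoid rule, both sides summed. No genetic map is assumed;
physical distance is the natural scale for array data without a pedigree
map. A SNP whose curve is cut by a chromosome end while EHH is still above
0.10 is flagged unreliable and excluded, as border truncation biases the
integral.

The unstandardized score is `ln(iHH_A / iHH_D)`. Because its distribution
depends strongly on the derived allele frequency, standardization is done
within derived-frequency bins of width 0.05 (bins with fewer than 10 SNPs
are merged with a neighbour): within each bin the score is centered and
scaled to SD 1. A plain global standardization is a special case
(`bin_width = 1`) but is not the default, since it confounds frequency with
signal. Extreme SNPs are `|iHS| > 3.2`, a strict inequality.

Ancestral states are unknown in sheep, so two assignment strategies are
provided: the major allele as ancestral (ties at frequency 0.5 resolve
deterministically to allele 0), and repeated random assignment. The
integrated EHH areas per allele do not depend on the assignment, so they
are computed once; each random replicate only relabels alleles (a sign flip
of the unstandardized score) and re-standardizes. How repeated random
assignments should be combined into one callable track is not settled
usage; this package reports the per-SNP mean of `|iHS|` across replicates,
flags extremes on that mean, and reports a Spearman rank correlation
against the major-allele mode so the user can verify that the two
strategies agree before trusting either.

### Region calling and annotation

The genome is tiled into non-overlapping 500-kb windows anchored at
position 1 of each chromosome (deterministic, assembly-aligned tiling; a
SNP at position 500,000 belongs to window 1, at 500,001 to window 2). A
window is under selection if it holds at least 10 scored SNPs of which at
least 5 are extreme; "10 SNPs" is read as a minimum, since fixed windows on
an array hold variable SNP counts. Adjacent called windows merge into one
region — observed multi-window signatures make clear that merging is the
intended behaviour. Method agreement is assessed by 1-bp-minimum interval
intersection between iHS regions and ROH islands. Annotation against a
user-supplied BED file converts BED's 0-based half-open coordinates to the
package's 1-based closed convention on read (and back on write); an
interval that merely abuts a region does not annotate it.

## The synthetic cohort: what it emulates, what it does not

Real genotypes for this kind of study are typically not redistributable, so
the package ships a simulator that gives every stage a parameter-recovery
test with known truth.

* **Neutral background**: per-SNP target frequencies from a U-shaped
  Beta(0.45, 0.45) spectrum (array-like after ascertainment, floored at the
  configured MAF), and local LD from a two-pool Markov mosaic — each
  haplotype switches between two latent parent pools with probability
  `1 - exp(-rate * gap)` per adjacent-SNP interval, and the pools differ in
  allele frequency. This reproduces a realistic frequency spectrum and
  short-range LD cheaply; it does not model deep coalescent genealogies,
  demography, or recombination hotspots.
* **Sweeps**: a donor haplotype is copied into a chosen fraction of
  haplotypes over a flank, with copy fidelity decaying linearly from 1 at
  the focal SNP to 0 at the flank edge — the simplest shape that yields the
  EHH decay a real sweep shows. The focal column is overwritten so that
  exactly `round(freq * n_haplotypes)` haplotypes carry the swept allele,
  making the truth record exact (background carriers would otherwise blur
  the planted frequency).
* **Autozygosity**: within a planted tract the second haplotype of an
  individual is replaced by the first, forcing homozygosity; missing calls
  are injected only into genotypes (never haplotypes — the iHS path assumes
  complete phased input, as phasing/imputation is an upstream concern) and
  by default spare tract cells so the planted truth is not eroded.

Passing recovery tests on this simulator demonstrates that the statistics
and their calling rules behave as specified under controlled conditions; it
does not demonstrate robustness to phasing error, array ascertainment bias,
population structure, or demographic confounding, all of which a real
analysis must consider separately.

## Problem sizes and numerical choices in the shipped checks

The test-suite simulations use cohorts the package can analyze in seconds
while keeping every constraint active: oracle equivalence for EHH on
fixtures of up to 20 haplotypes by 50 SNPs (where brute-force pairwise
comparison is exact and cheap), ROH oracle equivalence on chromosomes of up
to 300 SNPs, neutral iHS calibration on 5 cohorts of 200 haplotypes by
5,000 SNPs, sweep recovery on 100-individual cohorts with a 2-Mb-flank
sweep at frequency 0.5, and inbreeding recovery on 48 individuals at
planted autozygosity levels 0–30%. The analysis workflow under `analysis/`
uses 120 individuals and 3,000 SNPs per 100-Mb chromosome (~33 kb spacing,
so a 500-kb window holds ~15 SNPs, comparable to the per-window SNP counts
reported for 50K arrays).

Degenerate inputs are handled explicitly rather than silently: monomorphic
SNPs have no derived allele and are never scored; SNPs with fewer than two
carriers of an allele, or with zero integrated area, are excluded;
standardization fails loudly if a bin has zero variance; QC errors out if a
filter empties the dataset; pairs with no shared complete loci and
individuals whose `F_HOM` denominator vanishes are reported missing with a
warning.

## Known limitations

* iHS requires phased, complete haplotypes; phasing and imputation are
  preconditions, not package features.
* Physical distance only; if a genetic map exists, bp-based integration
  ignores recombination-rate variation.
* The ROH scanner implements the sliding-window family only; the
  consecutive-runs algorithm is out of scope.
* Single-population statistics only: no F_ST, XP-EHH, or other
  cross-population contrasts.
* Interval annotation is a generic BED overlap; database lookups (QTL,
  gene ontology enrichment) are left to external tools.
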