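---
title: "Methods: detecting photoperiod-driven selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting photoperiod-driven selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoclines)
```

This vignette documents the models, parameter choices and numerical
conventions behind `photoclines`, and what its synthetic benchmarks do and
do not establish about real data.

## The design

The hypothesis under test is environmental: as populations settled at
higher latitudes, the growing seasonal swing in day length
(Δphotoperiod) selected for alleles — particularly in circadian-clock
biology — whose frequencies should therefore form clines that track
Δphotoperiod rather than geography per se. The pipeline has three
independent lines of evidence:

1. a **frequency–environment correlation scan** (Kendall τ against
   Δphotoperiod with MAF-binned empirical ranks),
2. **population differentiation** (pairwise Weir–Cockerham F_ST ranks:
   high between Δphotoperiod-contrasted pairs, low between
   Δphotoperiod-matched but geographically distant pairs), and
3. **haplotype sweep signatures** at the candidate SNPs (DIND and lnRsb).

Every statistic is converted to an *empirical percentile rank* against a
genome-wide (or region-wide) background rather than to a parametric
p-value. The rationale: demography — drift, bottlenecks, serial founder
effects — moves the whole genome, while selection is locus-specific, so a
locus in the extreme tail of the empirical distribution is the signal of
interest, and panel-wide ascertainment biases largely cancel.

## Day length

`day_length()` uses the standard sunrise equation with geometric horizon:
declination δ = −23.44°·cos(360°·(d+10)/365) on day d, hour angle
cos ω = −tan φ · tan δ, day length 2ω/15 hours, clamped to 0 or 24 h
inside the polar circles. We deliberately omit atmospheric refraction and
twilight corrections: Δphotoperiod enters only a *rank* correlation, and
any day-length model monotone in |latitude| produces identical ranks. A
365-day year is used; the extremes are solstice-driven, so leap-day
handling is immaterial. When a population's location is a latitude range,
the caller supplies the midpoint.

## The correlation scan

For each SNP, `env_scan()` computes Kendall τ-b between the allele-b
frequency across populations and Δphotoperiod, with the two-sided
p-value from the tie-adjusted normal approximation of the concordance
statistic (`stats::cor.test`, `exact = FALSE`). The normal approximation,
not exact enumeration, is the right regime here: with ~52 populations,
low-MAF SNPs produce many tied frequencies. Because allele labels are
arbitrary, the sign of τ is meaningless and all downstream ranking uses
|τ|.

`maf_binned_rank()` then places each SNP in a right-open average-MAF bin
of width 0.01 (MAF is the unweighted across-population mean frequency,
folded) and assigns the mid-rank percentile of |τ| within the bin:
(number strictly below + half the ties, self included) / bin size. The
mid-rank convention makes the 0.95 gate reproducible and symmetric: a
strict maximum among n distinct values gets (n − 0.5)/n, a fully tied bin
gets 0.5 everywhere. A consequence worth noting: the gate `rank > 0.95`
is *unreachable* in bins with fewer than 10 SNPs, so the scan needs
genome-scale input (or pooling) — on a 400-SNP panel most bins are too
small, which is visible as depressed recall in small demonstrations.
Single-SNP bins are set to rank 0.5 with a warning rather than dropped.

`call_significant()` applies the published dual gate: Bonferroni
p < 0.05 over the number of SNPs analyzed AND τ rank > 0.95 (strict, as
printed). The two gates are complementary: Bonferroni alone is blind to
demography; the rank alone admits SNPs whose correlation is weak in
absolute terms.

## Resampling enrichment

`gene_set_resample()` draws m genes at random from the universe of genes
covered by ≥ 1 scanned SNP and counts genes with ≥ 1 SNP passing the dual
gate, applying the Bonferroni correction *per drawn set* (each draw has
its own SNP count), exactly mirroring the treatment of the observed set.
The empirical probability uses the (count + 1)/(reps + 1) estimator —
never 0, at most 1/10001 away from the raw proportion at the default
10,000 replicates. `snp_matched_gene_resample()` additionally matches
each target gene's SNP count (exact where possible, else nearest within a
factor-two window, never the target gene itself), controlling for large
genes being easier to hit. `excess_test()` compares a significant count
against the 5% gate mass with a two-sided Fisher exact test on
\[observed, rest; round(0.05·n), rest\] plus a one-sided binomial
cross-check; the 2×2 construction is our fixed convention, so Fisher
p-values are comparable across runs of this package but not digit-for-
digit with other implementations of the same idea.

## Differentiation

`wc_fst()` implements the Weir & Cockerham (1984) two-population θ̂ =
a/(a+b+c) from genotype counts, with *observed* heterozygosity entering
the c component. Negative estimates are retained: clamping at zero would
destroy the low tail, and the low tail is evidence here (distant
populations under the same photoperiod regime should show *unusually low*
differentiation at selected loci). Ranks use 50 equal-width average-MAF
classes on \[0, 0.5\] with the same mid-rank convention; the per-class
95th percentile is reported alongside. Pairs with fewer than 2 genotyped
individuals on either side are excluded, not guessed.

## Haplotype tests

**DIND.** For a focal SNP with known ancestral state, iπ_A and iπ_D are
the mean pairwise haplotype differences among ancestral- and
derived-allele carriers over a window of 40 flanking *variants* (20 per
side — variant-counted, not distance-counted, so the window adapts to
local SNP density; edges truncate with a flag). A sweep on the derived
allele drives iπ_D toward 0 and the ratio up. Ratios with iπ_D = 0 are
set to the dataset-wide maximum finite value + 20 — above everything,
still on the scale. Significance is the DAF-class-wise (100 classes)
95th percentile of a large background scan; classes dominated by capped
values (low DAF) have no usable percentile and are reported as
not-evaluable, which reproduces the empirical DAF floor seen in real
panels.

**EHHS / iES / lnRsb.** EHHS at site s relative to a focal SNP is the
probability that two haplotypes drawn *without replacement* are identical
over the whole interval — Σ n_h(n_h−1)/(n(n−1)) over haplotype classes —
normalized to 1 at the focal site and truncated below 0.05 (points under
the floor are dropped). iES is the trapezoid integral of the two-sided
curve over physical position. lnRsb = ln(iES_pop1/iES_pop2) is computed
for every SNP within 100 kb of a candidate (200-kb regions), then
median-centered across the pooled region SNPs; significance is the
mid-rank percentile ≥ 0.95 in that pooled empirical distribution, one
tail, in the direction of extended homozygosity in population 1. We
center by the median and rank empirically rather than fitting a normal:
the region-wide distribution is asymmetric near sweeps, and
median-centering removes the population-pair offset (drift moves *all*
log-ratios) while leaving the tail intact — both the raw and centered
values are returned. Swapping the populations flips signs and mirrors
ranks exactly. Haplotypes are required phased and complete; panels built
from VCF drop unphased input with an error rather than imputing.

## The synthetic-data generator

The generator reproduces the *design* of a worldwide diversity panel, not
any particular organism's history. Defaults are the package's study
conditions, fixed once:

| parameter | default | meaning |
|---|---|---|
| `n_pops` | 52 | populations on a latitude chain |
| `latitude_range` | 0–70° | spans Δphotoperiod 0–24 h |
| `drift_scale` | 0.002/° | Balding–Nichols F grows away from the equatorial origin, to F ≈ 0.14 — a human-scale out-of-Africa differentiation gradient |
| `frac_selected` | 5% | SNPs carrying a cline |
| `cline_strength` | 0.15 logit/h | gives mean |τ| ≈ 0.58 across 52 populations, i.e. clines strong enough that \|τ\| ≥ 0.5 |
| `n_individuals` | 25 | diploids genotyped per population |
| `n_haplotypes` | 100 | per panel |
| `region_kb`, `mutation_density` | 200 kb, 1/kb | one 200-site region per panel |
| `recomb_decay` | 50 kb | founder-mosaic segment scale and sweep-copy fidelity: a hard-sweep haplotype length |
| `sweep_daf` | 0.6 | derived frequency at planted sweeps |
| `n_founders`, `private_mut` | 6, 0.005 | background haplotype diversity |

Frequencies follow Balding–Nichols: p_k ~ Beta around the ancestral
frequency (Uniform(0.05, 0.95)) with F_k proportional to latitude
distance from the origin; selected SNPs shift the Beta mean on the logit
scale by `cline_strength` × Δphotoperiod_k with a random sign. The origin
population (F = 0) reproduces its mean exactly. Haplotype panels are
founder mosaics with exponential segment lengths plus private mutations;
a planted sweep overwrites carriers with a single core haplotype whose
copy fidelity decays as exp(−d/`recomb_decay`). Setting `n_founders = 1`
with `private_mut = 0` yields the fully monomorphic degenerate panel
(EHHS ≡ 1, DIND not computable) used to test degenerate-input handling;
this is the generator's zero-diversity limit, reached through founder
diversity rather than through the site count, which must stay ≥ 2 for a
panel to exist.

What the generator does *not* emulate: linkage between scan SNPs (the
frequency table draws SNPs independently), ascertainment bias, admixture,
longitude structure, and realistic recombination maps. Passing tests
therefore establish that the statistics are correctly computed and
calibrated under their own null, and that the pipeline recovers signals
of the stated strength — not that real human panels would yield any
particular count.

## Numerical conventions and degenerate inputs

* Mid-rank percentiles everywhere; ranks live in (0, 1), never exactly 0
  or 1.
* Missing frequency cells drop a population from that SNP's statistics;
  SNPs testable in < 3 populations or with constant values are flagged
  (`status`), never silently dropped.
* Multi-allelic VCF records are skipped with a warning at ingest.
* LD collapsing (`collapse_by_ld`, r² ≥ 0.4) is a single greedy pass in
  genomic order; when a candidate conflicts with exactly one retained
  SNP, a seeded coin flip decides which survives, so the retained set is
  random-but-reproducible and always passes the pairwise r² < 0.4 audit.
  The 500-bp upstream window of SNP–gene assignment is strand-aware
  (\[TSS−500, TSS−1\] on +, mirrored on −) — the conservative reading of
  "upstream" — and coordinates are 1-based inclusive throughout (VCF
  convention).
* Frequency tables round-trip through TSV bit-exactly (17 significant
  digits on write).
* All stochastic operations take explicit seeds and restore the caller's
  RNG state; identical seeds give bit-identical results.

## Problem sizes used in the checks

The packaged test-and-acceptance runs use 10,000-SNP neutral panels for
rank calibration (bins of ~200 SNPs), 6,000-SNP panels for cline
recovery, and 50 seeded replicates for each haplotype-test power
estimate, with the DIND background built from 10 neutral 200-site
panels. These sizes put every MAF/DAF class comfortably above the
granularity limits discussed earlier while keeping a full run at a few
minutes on one CPU.

## Known limitations

* The Fisher 2×2 convention in `excess_test()` (and the ±1-corrected
  empirical p) are package conventions; other implementations of the
  same tests can differ in the third digit.
* Gate counting on *printed* (rounded) percentile ranks, as in the
  bundled worked-example tables, is inclusive (≥ 0.95, ≤ 0.05), because
  a rank printed as 0.950 sat at or above the gate before rounding;
  `count_extreme()` on continuous ranks keeps the strict gates.
* DIND requires ancestral polarization; SNPs with unknown ancestral
  state must be resolved upstream (outgroup comparison is out of scope).
* lnRsb ranks are region-relative: a region saturated by a very wide
  sweep dilutes its own focal rank. The 200-kb default leaves enough
  neutral flank at the simulated sweep widths.
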