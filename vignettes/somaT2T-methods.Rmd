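---
title: "somaT2T: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somaT2T: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaT2T)
```

somaT2T implements the downstream computations that sit on top of a
donor-specific diploid assembly (DSA) of a paired tumor/normal sample:
haploid copy-number profiling, a somatic SNV/DNV filter cascade,
mutational-spectrum analysis with sequence-composition normalization,
centromere dip region (CDR) detection, telomere variant repeat (TVR)
analysis, and haplotype-selective chromatin accessibility. Everything
upstream — assembly, alignment, phasing, variant calling, repeat annotation —
is treated as input. A synthetic-data module generates all of those inputs
with the statistical structure the analyses assume, so the whole pipeline is
testable at desk scale. This vignette records the models, the tunable
parameters, and the design choices that were genuinely open.

## Haploid copy number (hCN)

In a tumor that has undergone whole-genome duplication, base-level coverage
is multimodal: the global maximum of the histogram sits on the duplicated
(2n) segments and a second, lower-coverage peak marks haploid (1n) coverage.
`find_coverage_modes()` locates both on a smoothed histogram. The histogram
rule is ours: bins of `binwidth` (default 1x), a running-mean smooth
(5 bins), and two guards against noise — a secondary mode must reach
`min_peak_frac` (10%) of the primary peak height and be separated from it by
a valley below `valley_frac` (80%) of the lower peak. Monotone shoulders and
tail noise fail the valley test.

The per-window ratio is

$$\log_2\!\frac{T_w / T_{1n}}{N_w / N_{1n}}$$

with the tumor constant $T_{1n}$ the haploid coverage mode and the normal
constant $N_{1n}$ chosen so that the normal term is ~1 for a
copy-number-neutral window. With per-haplotype window depths (reads
partitioned between the two assembly haplotypes) that constant is half the
diploid coverage mode; with diploid-total window depths, as produced by
`simulate_coverage()`, it is the diploid mode itself. `log2_hcn_ratio()`
takes both constants explicitly, `run_pipeline()` passes the diploid mode,
and the distinction matters because the classification thresholds below
assume the ratio is $\approx \log_2(\mathrm{hCN})$. Ratios below −1.5 are
capped at −1.5 and zero-coverage normal windows are masked.

Segmentation is recursive binary segmentation with a permutation test: at
each step the split maximizing the pooled two-sample t statistic (leftmost
on ties) is accepted if its within-segment permutation p-value is below
`alpha` (default 1e-4 with `nperm = 10000`; note the smallest attainable p
is $1/(nperm+1)$, so `nperm` must exceed $1/\alpha - 1$ — the function warns
otherwise). Segments keep at least `min_width = 5` windows of 100 kb.
Before segmentation, single-window outliers (deviating more than 4 trimmed
SDs, trim 0.025, from their 10-window neighbourhood median) are shrunk to
the median ± 2 trimmed SDs. This outlier rule is an approximation of the
smoothing conventionally applied before circular binary segmentation, with
all parameters exposed; the split search itself is cross-checked in the test
suite against an exhaustive-split oracle on profiles of up to 20 windows.

Segments are classified by median ratio against the breakpoint vector
(−0.415, 0.585, 1.322, 1.848, 2.263) into DEL, hCN = 1..4 and amplified.
Two of these are the $\log_2(n + 0.5)$ midpoints (0.585, 1.322); the
remaining three depart from that formula (which would give −1.000, 1.807,
2.170). `hcn_thresholds("printed")` (the default) uses the conventional
table verbatim; `hcn_thresholds("formula")` recomputes all five
self-consistently. The altered-genome fraction counts base pairs whose
state differs from the neutral state, hCN = 1 by default (the haploid
baseline of a genome-duplicated tumor); the neutral state is an argument.

## Somatic SNV/DNV filter cascade

The cascade runs replicate intersection → normal-evidence filter → deleted
segments → cross-haplotype resolution → density filter; each stage only
removes or annotates calls. Choices worth recording:

* **Normal evidence.** "At most one alternate read in the normal"
  (`max_alt_reads = 1`): two or more normal alt reads mark germline variants
  or shared artifacts.
* **Cross-haplotype duplicates.** The same variant called at homologous
  positions on both haplotypes is resolved by a two-sided Fisher's exact
  test on alt/ref counts per haplotype (p < 0.01 assigns to the haplotype
  with the higher alt fraction), with a second-tier read source retried
  before flagging a record ambiguous. Sidedness is not dictated by the
  procedure itself; two-sided is assumed.
* **Density filter.** 1 kb windows at 500 bp steps; windows with ≥ 3 calls
  are merged, and a merged region's calls are discarded if ≥ 3 of them have
  VAF < 0.75 *or* the median call depth falls below
  $\mu - 3\sqrt{\mu}$ with $\mu = 61.5$ (the haploid coverage; the Poisson
  SD is $\sqrt{\mu}$, so the default cut is ≈ 38.0). The two rules fire
  independently, and a triggering region drops *all* of its calls
  (`drop_all = TRUE`); dropping only the sub-threshold calls is available
  behind the flag, since the prose rule is ambiguous on this point.
* **DNVs.** Runs of calls at consecutive positions are clustered;
  even-sized clusters are paired, and a pair becomes a DNV only if both
  calls are fixed (VAF ≥ 0.9) on the same haplotype or share a phase set on
  the same haplotype. Odd clusters are flagged for review. Read-backed
  phasing is not re-implemented; phase-set identity stands in for it.
* **hVAF.** The default definition is the haplotype-restricted VAF (alt
  reads over reads assigned to that haplotype), which makes a variant on 2
  of 4 copies of a duplicated haplotype read ~0.5; `hvaf(method =
  "vaf_times_hcn")` provides the alternative scaling definition.

## Mutational spectra

SBS-96 classes follow the conventional pyrimidine-centered order
(C>A, C>G, C>T, T>A, T>C, T>G × 5'/3' context); purine-reference calls are
reverse-complemented, making classification strand-involutive. DBS-78
doublet classes are generated programmatically with reverse-complement
collapsing of the palindromic references.

**3-mer normalization.** Counts are rescaled by the ratio of genome-wide to
region-specific canonical 3-mer frequencies, then globally rescaled to
preserve the total, then rounded to integers. Rounding is half-away-from-
zero (a documented choice; no rule is canonical), so the total is preserved
within 0.5 per class (≤ 48 over 96 classes). A region frequency of zero for
a class with nonzero count is an error naming the class. K-mer counting
collapses both strands onto the 32 canonical pyrimidine-centered 3-mers.

**Predicted mutability** of a region is
$\sum_c f_c \, e_{k(c)}$ — the reference (non-repeat) spectrum fraction of
each class times the region's enrichment of that class's 3-mer — i.e. the
expected relative mutation rate of the region from sequence composition
alone; it equals 1 under uniform enrichment.

**Signature fitting** is non-negative least squares (Lawson–Hanson via
`pracma::lsqnonneg`) of the normalized counts against a fixed
column-stochastic signature matrix; fitting on counts vs fractions only
changes the exposure scale, not the reported fractions. The shipped matrix
(`synthetic_signatures()`) is *synthetic*: deterministic mechanism-inspired
shapes (UV dipyrimidine C>T, NpCpG clock-like, TpC-focused, flat
backgrounds) under the conventional names of the melanoma-associated set.
It carries no external catalogue data and is intended for testing and
simulation; users with the reference catalogue can pass their own matrix.

**AMSD.** The aggregate mutation spectrum distance between two spectra is
the cosine distance of their fraction vectors; the null pools all mutations
and re-draws two multinomial spectra of the original sizes, and the p-value
is +1-corrected so its floor is $1/(n_{perm}+1)$. Calibration, measured in
the test suite at 150 mutations per spectrum: the decision tails are
conservative-to-nominal ($P(p \le 0.01) \approx 0.008$,
$P(p \le 0.05) \approx 0.06$) while the mid-range is mildly inflated
($P(p \le 0.5) \approx 0.58$) — a property of the pooled-multinomial null
itself, worth knowing when interpreting non-extreme p-values.

## Per-class rates and the breakpoint test

`rate_by_class()` resolves overlapping annotations by a fixed priority —
kinetochore classes (CDR, non-CDR-HOR), then satellite subclasses, then
other repeats, then non-repeat — both for call assignment and for the bp
denominators (higher-priority classes claim the shared bp). The priority is
a documented choice. The two-proportion Z-test is the pooled-variance
closed form. The breakpoint–CDR permutation test places the observed number
of breakpoints uniformly and independently over the placement space (e.g.
all alpha-satellite HOR bp) in each of `n_iter` iterations (default 1e5)
and reports the +1-corrected fraction of iterations with ≥ `min_overlap`
(default 2) breakpoints inside CDRs. Placement granularity (per-bp
independent uniform) is our decision; because placements are genuinely
drawn, the binomial closed form remains an independent oracle in tests.

## CDR detection

Alpha-satellite arrays are merged across gaps ≤ 10 kb and filtered to
≥ 100 kb. The bulk caller bins methylation at 1 kb, z-scores each array
against its own mean and *population* SD, flags bins with z < −1.5, flips
runs of ≤ 5 kb flanked on both sides by the opposite state (low runs first,
then high runs; the pass order is exposed because it is not dictated
anywhere), and keeps surviving low runs at least 50 kb from both array
ends. The run-flipping is a projection (applying it twice changes
nothing), which the suite asserts. Bins with no CpG coverage are excluded
from the mean/SD and cannot become CDR bins. The per-molecule caller runs
the same algorithm per read with the read's own bins as reference; reads
spanning < 2 bins or with zero internal contrast (e.g. a read entirely
inside a dip) yield nothing — a structural limit of read-internal
z-scoring, not a bug — and the edge rule is applied against the *array*
ends (applying it to read ends would erase all calls at typical read
lengths). CDR comparison reports per-chromosome changes in size-weighted
center of mass, total bp and count, with the cohort fraction shifted beyond
a threshold (default 100 kb).

## Telomere TVR analysis

Reads are oriented to the G-strand by majority vote between TTAGGG and
CCCTAA counts (ties flagged). The telomeric portion (distal to the provided
subtelomere/telomere junction offset) is partitioned exactly into canonical
runs — maximal tandem runs of ≥ 2 exact copies of the canonical hexamer —
and TVR bases (everything else). The ≥ 2-copy rule means singleton hexamers
inside degenerate sequence count as TVR context; a ≥ 1-copy alternative is
available (`min_copies`). Junction detection itself is out of scope: the
boundary offset is an input (synthetic or precomputed).

The consensus profile is the per-offset fraction of covering reads whose
base is a TVR base, boxcar-smoothed over 25 bp; peaks are local maxima
above `min_peak_frac = 0.25` separated by ≥ 50 bp (both exposed — no
published values exist; planted peaks in the tests sit well above the
threshold). Restructuring is called when a normal-only peak lies distal to
a shared peak (matching tolerance 50 bp, twice the smoothing window): the
most proximal lost peak is the distal boundary (minimum chew-back) and the
most distal shared peak proximal to it is the proximal limit (maximum
chew-back). The attrition/extension summary uses the proximal limit as the
minimum retained length and mean tumor telomere length minus that limit as
the telomerase extension; negative extensions flag internal-deletion
candidates.

## Haplotype-selective accessibility

Per peak, Fisher's exact test on accessible/inaccessible × haplotype fiber
counts with Benjamini–Hochberg correction (selective iff q < 0.05). Peaks
without two-haplotype contrast — zero fibers or zero copy number on either
haplotype (LOH) — are excluded. Selective peaks partition by priority:
somatic-variant-explained, germline-het-explained, imprinted, unexplained.
The additive copy-number expectation splits each peak's accessible fibers
in the hCN1:hCN2 ratio; the reported correlation is Pearson on
accessible-fiber counts (mirroring the natural axes; a log option would be
a trivial extension). The boundary-distance analysis compares cumulative
fractions of unexplained vs background peaks within increasing distances of
an hCN state change, with a bootstrap band (1,000 resamples of the
unexplained set) on the difference curve — the band is an addition, since
the comparison is otherwise shown without uncertainty. The background peak
set is an explicit input.

## The synthetic-data module

The generator's defaults are the study conditions the analyses assume:

* **Composition**: satellites 4.27% of the genome (alpha-satellite 1.77%,
  HSat2 1.0%, HSat3 0.9%, HSat1A/B 0.3% each), interspersed repeats ~40%.
  Satellite sequence is tandem monomer (171 bp alpha-like, 26 bp
  HSat2/3-like, 42 bp HSat1-like) with 2% per-copy divergence — realistic
  k-mer structure without real sequence.
* **Rates**: anchored at HSat2 = 6.1e-5 SNVs/bp, 7.78× the non-repeat
  baseline, a 5.05× spread across satellite families, and pooled satellite
  and repeat enrichments of 3.79× and 1.4×. Only the anchors are published;
  the remaining class rates were interpolated once so the pooled rates
  reproduce the anchors exactly at the default composition, and are not
  revisited.
* **Spectrum**: 72% of mass on C>T at dipyrimidines. Mutation *positions*
  are drawn proportionally to each site's total spectrum mass within a
  block (class totals stay binomial at the class rate), then the alternate
  allele is drawn conditionally on the trinucleotide. Uniform positions
  would dilute the realized spectrum by context availability and break the
  UV-dominated structure the spectrum analyses assume.
* **Coverage**: normal 176× (unimodal diploid), tumor haploid coverage
  61.5×; default karyotype has 78% of the genome off the hCN = 1 baseline.
* **Methylation**: baseline fraction 0.85 (SD 0.05) with planted 60 kb
  dips at 0.45 in arrays ≥ 200 kb; molecules carry binary per-CpG calls at
  the local mean.
* **Telomeres**: 6 kb germline telomeres with a fixed TVR layout
  (12 bp TVR blocks placed out of frame with the hexamer), attrition to
  1.4 kb retained plus 2.3 kb extension in restructured tumors — tumor
  telomeres end up 2.3 kb shorter on average. Half the reads are stored
  reverse-complemented to exercise strand handling.
* **Determinism**: one global seed; each generator draws from its own
  derived stream, so adding a generator does not perturb the others.

What the generator does *not* emulate: read-level sequencing error
profiles, alignment and mapping artifacts (beyond planted low-VAF
clusters), subclonal structure by default (a subclonal VAF mixture is
behind a flag), replication timing, and real satellite higher-order
structure. Green tests therefore demonstrate correctness of the
*computations* under the assumed statistical structure, not robustness to
every failure mode of real sequencing data.

## Problem sizes

The test suite runs module tests on genomes of 0.3–1 Mb and the
rate-recovery checks on a 20 Mb genome at the published per-class rates
(with repeat fractions enlarged to 65% so every class carries enough bp for
a meaningful binomial band); recovery is asserted within 3σ sampling error.
The acceptance script simulates a 12 Mb genome with the published rate
*ratios* and absolute rates scaled ×160, chosen a priori so the pooled fold
estimates carry ≈ 2% sampling SD (≈ 4,000–19,000 calls per pooled class).
Segmentation tests use 10,000 permutations at α = 1e-4, matching the
default operating point. The statistical property suites (Fisher vs
enumeration, split oracle, AMSD and Monte Carlo calibration, planted-dip
and restructuring recovery) complete in a few minutes on one CPU.

## Known limitations

* The segmentation is recursive (not circular) binary segmentation; on
  profiles whose change is a single interior island shorter than
  `min_width`, a circular variant would differ.
* Single-molecule CDR calling requires within-read contrast and dense CpG
  calls; shallow dips (< ~2 read-internal SDs) are invisible per molecule
  even when the bulk caller finds them.
* The two-tier cross-haplotype test treats tiers as independent retries;
  no multiplicity adjustment is applied across tiers.
* `find_coverage_modes()` assumes the haploid mode is below the primary
  mode; a tumor whose 1n state dominates the genome would present the
  reverse geometry and should be normalized with explicit constants.
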