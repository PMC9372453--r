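---
title: "Comparing genome size and composition with binned k-mer spectra"
author: "kmerdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing genome size and composition with binned k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerdiff)
```

## The model

`kmerdiff` treats a shotgun sequencing dataset as a multiset of canonical
k-mers (default k = 21, the lexicographic minimum of each window and its
reverse complement). Two complementary summaries are used throughout:

* the **k-mer dump** — the sorted table of k-mers and multiplicities,
  identity-aware, supporting set algebra (organelle subtraction, repeat
  extraction) and database-style joins between samples;
* the **k-mer spectrum** — the histogram n(m) of distinct k-mers per
  multiplicity level m, identity-free, supporting genome-size estimation
  and copy-number scaling.

For a diploid sequenced at monoploid k-mer coverage c, heterozygous
k-mers concentrate near multiplicity c, homozygous ones near 2c, and a
repeat with C copies per haplotype (homozygous) near 2Cc. Dividing
multiplicities by c therefore converts the x-axis to genomic **copy
number at the diploid level**: heterozygous sequence at 1, homozygous
single-copy at 2, a C-copy-per-haplotype repeat at 2C. This factor of two
matters when reading difference graphs: a repeat "at x = 3000" carries
1500 copies per haplotype.

### Genome-size estimation

With organellar k-mers removed, the 2C genome size is

$$\mathrm{GS}_{2C} = \frac{1}{c}\sum_{m \ge c/2} m\, n(m),$$

i.e. every retained k-mer occurrence contributes 1/c of a genomic
position. The m < c/2 cutoff removes the low-multiplicity
error/contamination peak. The analogous binned form replaces m/c by each
bin's expected copy number and is used for difference graphs. Conversion
to picograms uses 1 pg = 978 Mbp and 1C = 2C/2; polyploids are out of
scope.

Two boundary conventions coexist deliberately: the size estimator keeps
m ≥ c/2, while binning discards scaled values ≤ 0.5. The one-point
discrepancy (a level at exactly c/2) is preserved per procedure because
each rule is stated that way for its own step.

### Copy-number bins

Bins are geometric, (0.5·1.1^i, 0.5·1.1^(i+1)] for i = 0, 1, …, so each
upper limit is 10% above its lower limit: (0.5, 0.55], (0.55, 0.605], …,
with bin 39 = (20.57, 22.63]. The scheme is shared across samples, so a
bin index means the same copy-number range everywhere; the number of bins
is data-driven, ending at the bin of the highest-copy k-mer observed. The
"expected copy number" representative of a bin is the geometric mean
√(lower·upper), consistent with geometric growth; the arithmetic midpoint
differs by < 0.12% at 10% growth and is available via
`bin_scheme(representative = "midpoint")`. Bin-boundary assignment uses a
small relative tolerance (1e-9) so values lying exactly on an upper bound
fall into that bin despite floating-point log arithmetic.

### Comparisons

A **difference graph** multiplies per-bin count differences by the bin
representative to get base-pair contributions; its total equals the
difference of binned genome sizes exactly, and the graph is antisymmetric
under argument swap. Cumulative series are ordered by ascending bin
(increasing repetitiveness). A **joint spectrum** is a full outer join of
two dumps on the k-mer column with per-axis scaling and binning; a k-mer
absent from one dump, or scaled ≤ 0.5 there, is assigned to a reserved
"absent" class (index −1) on that axis so presence/absence variation stays
visible (an inner-join mode restricts to shared k-mers). Axis marginals
(absent class dropped) reproduce each sample's binned spectrum, which the
tests exploit as a consistency check.

**Repeat attribution** restricts both dumps to k-mers unique to one repeat
family before joining or summing. Only family-unique k-mers are counted
(uniqueness enforced globally across families), so family contributions
are disjoint, additive, bounded by the whole-genome estimate — and
systematically conservative. For tandem repeats, supplying the monomer
*doubled* head-to-tail as the family reference captures the
junction-spanning k-mers of real arrays.

**Distances**: Manhattan is the sum of absolute per-bin count differences;
Gower is specialised to quantitative per-bin counts as the mean of
absolute differences divided by the across-cohort per-bin range (zero-range
bins skipped), hence bounded in [0, 1]. Cohort ANOVA is delegated to
`stats::aov`; the permutation check reports add-one exceedance p-values
(1 + #{perm ≥ obs})/(1 + n_perm), which cannot reach zero.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 21 | k-mer length; odd, ≤ 31, so no k-mer is its own reverse complement |
| `min_count` | 2 (reads), 1 (assemblies) | dump threshold; removes most singleton error k-mers |
| `coverage` | — | monoploid peak multiplicity; scale factor for copy number |
| `origin`, `growth` | 0.5, 1.10 | bin scheme; ≤ origin is discarded as contaminant |
| breakpoints | 10, 10², …, 10⁶ | coarse copy-number ranges for composition summaries |
| `n_perm` | 999 | label permutations for the cohort check |

The monoploid coverage is the one parameter with real leverage. The
built-in `find_monoploid_peak()` is a deliberately simple detector:
moving-average smoothing (window 3) on a contiguous multiplicity grid,
the first local minimum taken as the error trough, then the tallest
smoothed local maximum inside the search window, ties broken toward lower
multiplicity. It returns an integer multiplicity, so it quantizes the true
peak position with up to ±0.5/c relative error (~2% at c ≈ 23). Dedicated
spectrum-fitting tools estimate fractional coverages by mixture models;
when such an estimate exists it should be passed directly (`--coverage`
in the CLI), and the detector treated as a cross-check. Mixture-model
fitting of heterozygosity or peak widths is intentionally out of scope.

## The synthetic-data generator

`simulate_genome()` emits a diploid whose haplotype B is haplotype A with
i.i.d. substitutions at the heterozygosity rate — substitution-only, so
coordinates are shared and every segment is traceable. Haplotype A is a
random single-copy backbone with diverged TE copies inserted at random
positions, then a tandem satellite array and a tandem rDNA-like block; an
independent organellar sequence is sequenced at a depth multiplier.
`simulate_reads()` draws uniform read starts from both haplotypes, flips
strands at random, and applies i.i.d. substitution errors;
`make_pair()` derives a second genome by adding/removing whole repeat
copies (homozygously, at matching coordinates), recording the exact
planted 2C difference. All randomness flows from explicit seeds and global
RNG state is restored afterwards.

Defaults describe one fixed desk-scale study condition: 1 Mbp single-copy
backbone per haplotype, heterozygosity 0.5% (mid-range for the kind of
outbreeding diploid cohort this method targets, where fitted values span
roughly 0.1–1.4%), a 145-nt satellite at 3000 copies per haplotype, a
4-kb TE at 60 copies with 2% divergence, a 2-kb rDNA-like unit at 150
copies, and a 50-kb organelle at 20× relative depth; reads are 150 bp
single-end at 30× per haplotype with 0.5% error. `coverage` means **base**
coverage; the monoploid k-mer peak then sits at
coverage·(L−k+1)/L·(1−e)^k (`expected_kmer_coverage()`), e.g. 23.4 for
the defaults — tests assert the detector lands within ±1 of that value
rather than at the nominal 30.

What the generator does *not* emulate: indels (k-mer identity methods are
insensitive to them at this scale), PCR duplicates, GC bias,
quality-score structure, and the broadened, platform-dependent peak
widths seen in real spectra. Passing tests therefore demonstrate
correctness of the arithmetic and recovery under idealised Poisson-like
sampling, not robustness to library-preparation artefacts.

## Numerical behaviour and known limitations

* **Estimator bias at high copy number.** A k-mer from a repeat at very
  high copy number has single-substitution error variants that recur often
  enough to pass the m ≥ c/2 cutoff, so error mass that the monoploid-peak
  normalisation assumes lost is partly recovered for the repeat fraction.
  At 0.5% error and ~50% repeat content this inflates 2C estimates by
  ~3–4%; combined with integer peak quantization the end-to-end error can
  brush 5%. With a fitted (fractional) coverage the recovery stays within
  5% of truth in the packaged simulations; the tests document both
  effects. Real datasets share this behaviour — which is one reason the
  published workflow fits coverage with a dedicated tool rather than an
  argmax.
* **Genome size in bp equals retained k-mer mass over c**; the (k−1)
  per-contig undercount is ignored as negligible at genome scale.
* Counting is exact (hash table, 2-bit packed, 62 bits at k = 31), not
  sketched; datasets must fit in memory. ~150 Mbp of reads with 0.5%
  error needs roughly 1–2 GB during counting.
* Windows containing any non-ACGT base are skipped whole, matching
  standard counter behaviour on trimmed reads.
* Strand-collapsed (canonical) counting is assumed; `canonical = FALSE`
  preserves forward-strand counting for databases built that way.
* The permutation check permutes labels uniformly; with tiny cohorts the
  permutation distribution is coarse and the add-one p-value floor
  (1/(n_perm+1)) dominates.
* No tree building, no repeat clustering/annotation, no ploidy or
  heterozygosity inference: those belong to dedicated tools; this package
  consumes their outputs (fitted coverages, repeat family references).

## Problem sizes used in the packaged checks

Unit tests run on toy sequences and random dumps (≤ 10⁴ entries). The
end-to-end recovery simulations use a ~3.95 Mbp 2C genome pair (defaults
above) and a ~1.4 Mbp 2C pair for the planted-3000-copy step signature,
both at 30× per haplotype — large enough that satellite, rDNA and TE
fractions are each resolved by hundreds of distinct k-mers, small enough
to run in minutes on one core.
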