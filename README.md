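# kmerdiff

Reference-free comparison of genome size and genome composition between
individuals, from shotgun sequencing reads alone.

Genome assemblies under-represent exactly the sequences that make genomes
differ in size — satellites, rDNA arrays, transposable elements — and
low-pass "genome skimming" misses the single-copy fraction. `kmerdiff`
works instead on uncropped k-mer spectra of moderately high-coverage reads:
it estimates each individual's diploid (2C) genome size, rescales every
spectrum to genomic copy number, bins the copy numbers geometrically so
whole genomes become comparable vectors of a few hundred numbers, and then
locates which copy-number classes — and which specific repeat families —
drive the size differences between samples. It is aimed at population and
comparative genomicists working on organisms without reference assemblies.

## The method

For a sample sequenced at monoploid k-mer coverage *c* (the multiplicity of
the "haploid" spectrum peak formed by heterozygous k-mers), with *n(m)*
distinct k-mers at multiplicity *m* and organellar k-mers subtracted:

* **Genome size.** The spectrum below *m* = *c*/2 (the contamination/error
  peak) is discarded, and

  GS(2C) = Σ<sub>m ≥ c/2</sub> m · n(m) / c   [bp],

  converted to picograms as 1C pg = GS(2C) / 2 / 978 Mbp.

* **Copy-number binning.** Scaled multiplicities *m*/*c* (≡ genomic copy
  number: heterozygous k-mers at 1, homozygous at 2) are assigned to
  geometric bins (0.5·1.1<sup>i</sup>, 0.5·1.1<sup>i+1</sup>], each upper
  limit 10% above its lower limit; values ≤ 0.5 are discarded as likely
  contaminants. Binning after scaling makes bin *i* mean the same copy
  number range in every sample.

* **Difference graphs.** Per-bin count differences between two samples,
  multiplied by the bin's expected copy number √(lower·upper), give each
  copy-number class's contribution (bp) to the total 2C difference; the
  cumulative series shows a step wherever a repeat's abundance differs.

* **Joint k-mer spectra.** A database-style join of two k-mer dumps on the
  k-mer column, binned per axis, yields a matrix of k-mer counts over
  copy-number bin pairs — off-diagonal mass is copy-number divergence,
  visible down to single k-mer families.

* **Repeat attribution.** K-mers unique to each repeat family restrict the
  same genome-size arithmetic to one family at a time, quantifying how much
  of a pairwise size difference each family explains.

* **Cohort statistics.** One-way ANOVA partitions per-sample 2C sizes by
  species (with a label-permutation check), and Manhattan/Gower distances
  over binned spectra support clustering and alignment-free phylogenetics.

A synthetic-data module simulates diploid genomes with tunable
heterozygosity, a tandem satellite, a dispersed TE family, an rDNA-like
block and an organellar contaminant, plus error-bearing shotgun reads and
exact truth tables, so the whole pipeline is testable without downloads.

## Worked example

```r
library(kmerdiff)

spec  <- genome_spec(unique_len = 2e5, satellite = c(145, 600),
                     te = c(4000, 12, 0.02), rdna = c(2000, 30),
                     organelle = c(50000, 20), seed = 7)
g     <- simulate_genome(spec)
reads <- simulate_reads(g, read_spec(coverage = 30, error_rate = 0.005,
                                     seed = 7))
dump  <- count_kmers(reads, k = 21, min_count = 2)
nuc   <- kmer_subtract(dump, count_reference_kmers(g$organelle, k = 21))
s     <- spectrum_of(nuc)
peak  <- find_monoploid_peak(s, 12, 35)
estimate_genome_size(s, peak)
#> 2C genome size: 0.82 Mbp (1C = 0.00 pg) at coverage 23

g$truth$size_2c
#> [1] 790000

b <- scale_and_bin(s, peak)
range_summary(b)[1:4, c("range", "bp")]
#>        range       bp
#> 1     (0,10] 479588.0
#> 2   (10,100] 174755.2
#> 3 (100,1000]      0.0
#> 4 (1000,10000] 171333.3
```

The estimate (823 kbp) sits within ~4% of the simulated truth (790 kbp);
the detected peak 23 matches the expected monoploid k-mer coverage
30 · (150−21+1)/150 · 0.995²¹ ≈ 23.4. The coarse range summary shows the
single-copy fraction in (0,10], the TE/rDNA mass in (10,100] and the
600-copy-per-haplotype satellite in (1000,10000] — at diploid copy number
~1200 — exactly where the difference graphs would localise a change.

Cohort statistics work directly on published per-sample values:

```r
gs <- c(999.98, 989.23, 1055.93, 1227.92, 1126.64, 1096.44, 1104.84)
sp <- c("An", "An", "Vi", "Ro", "Ri", "Ri", "Ri")
anova_partition(gs, sp)
#> $F [1] 72.42784  ... $variance_explained [1] 0.9863812  $p [1] 0.002687048
```

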