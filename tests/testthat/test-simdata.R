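# small genome used across simulator tests
tiny_spec <- function(seed = 1, het = 0.005) {
  genome_spec(unique_len = 5e4, heterozygosity = het,
              satellite = c(145, 200), te = c(2000, 5, 0.02),
              rdna = c(1000, 20), organelle = c(20000, 10), seed = seed)
}

test_that("genome simulation is deterministic and internally consistent", {
  g1 <- simulate_genome(tiny_spec())
  g2 <- simulate_genome(tiny_spec())
  expect_identical(g1$haplotypes, g2$haplotypes)
  expect_identical(g1$organelle, g2$organelle)
  g3 <- simulate_genome(tiny_spec(seed = 2))
  expect_false(identical(g1$haplotypes, g3$haplotypes))

  expect_equal(g1$truth$size_1c, nchar(g1$haplotypes[["A"]]))
  expect_equal(g1$truth$size_2c, sum(nchar(g1$haplotypes)))
  expect_equal(sum(g1$truth$families$bp_1c), g1$truth$size_1c)
  fams <- g1$truth$families
  expect_equal(fams$copies[fams$family == "satellite"], 200)
  expect_equal(fams$unit_len[fams$family == "satellite"], 145)
  # segment coordinates tile the haplotype exactly
  expect_equal(g1$segments$start[1], 1)
  expect_equal(g1$segments$end[nrow(g1$segments)], g1$truth$size_1c)
  expect_true(all(g1$segments$start[-1] == head(g1$segments$end, -1) + 1))
})

test_that("truth distinct-k-mer counts match counting on the emitted FASTA", {
  g <- simulate_genome(tiny_spec(), k = 21)
  for (f in unique(g$segments$family)) {
    seg <- g$segments[g$segments$family == f, ]
    pieces <- c(substring(g$haplotypes[["A"]], seg$start, seg$end),
                substring(g$haplotypes[["B"]], seg$start, seg$end))
    expect_equal(
      length(count_reference_kmers(pieces, k = 21)$kmer),
      g$truth$families$distinct_kmers[g$truth$families$family == f],
      info = f)
  }
})

test_that("zero heterozygosity gives identical haplotypes", {
  g <- simulate_genome(tiny_spec(het = 0))
  expect_identical(g$haplotypes[["A"]], g$haplotypes[["B"]])
  g5 <- simulate_genome(tiny_spec(het = 0.05))
  mism <- mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                      strsplit(b, "")[[1]]),
                 g5$haplotypes[["A"]], g5$haplotypes[["B"]])
  expect_equal(unname(mism) / nchar(g5$haplotypes[["A"]]), 0.05,
               tolerance = 0.05)
})

test_that("read simulation hits its coverage target deterministically", {
  g <- simulate_genome(tiny_spec())
  rs <- read_spec(coverage = 8, read_length = 100, error_rate = 0.002,
                  seed = 5)
  r1 <- simulate_reads(g, rs)
  r2 <- simulate_reads(g, rs)
  expect_identical(r1, r2)
  expect_true(all(nchar(r1) == 100))
  nuclear <- sum(nchar(r1[grepl("^[AB]_", names(r1))]))
  expect_equal(nuclear / g$truth$size_2c, 8, tolerance = 0.01)
  organelle <- sum(nchar(r1[grepl("^organelle", names(r1))]))
  expect_equal(organelle / nchar(g$organelle), 8 * 10, tolerance = 0.01)
  # near-zero coverage: near-empty output, no error
  expect_lt(length(simulate_reads(g, read_spec(coverage = 0.001,
                                               seed = 1))), 30)
  # read length longer than the organelle is rejected
  expect_error(simulate_reads(g, read_spec(coverage = 1,
                                           read_length = 30000, seed = 1)),
               "length")
  # paired mode emits /1 and /2 mates of equal number
  rp <- simulate_reads(g, read_spec(coverage = 2, paired = TRUE, seed = 3))
  expect_equal(sum(grepl("/1$", names(rp))), sum(grepl("/2$", names(rp))))
})

test_that("error-free reads put the monoploid peak at the expected level", {
  g <- simulate_genome(tiny_spec(het = 0.01))
  rs <- read_spec(coverage = 30, read_length = 150, error_rate = 0,
                  seed = 11)
  dump <- count_kmers(simulate_reads(g, rs), k = 21, min_count = 2)
  nuc <- kmer_subtract(dump, count_reference_kmers(g$organelle, k = 21))
  s <- spectrum_of(nuc)
  cexp <- expected_kmer_coverage(rs, 21)   # 30 * 130/150 = 26
  peak <- find_monoploid_peak(s, 0.5 * cexp, 1.5 * cexp)
  expect_lte(abs(peak - cexp), 2)
})

test_that("make_pair plants exact whole-copy differences", {
  sp <- tiny_spec()
  p0 <- make_pair(sp, delta = c())
  expect_identical(p0$a$haplotypes, p0$b$haplotypes)
  expect_equal(p0$planted_diff_2c_bp, 0)

  p <- make_pair(sp, delta = c(satellite = 50))
  expect_equal(p$planted_diff_2c_bp, 2 * 50 * 145)
  fams <- p$b$truth$families
  expect_equal(fams$copies[fams$family == "satellite"], 250)

  pm <- make_pair(sp, delta = c(satellite = -50, rDNA = 5, TE = 2))
  expect_equal(pm$planted_diff_2c_bp,
               2 * (-50 * 145 + 5 * 1000 + 2 * 2000))
  expect_error(make_pair(sp, delta = c(satellite = -1000)), "remove")
  expect_error(make_pair(sp, delta = c(nope = 1)), "delta")
  # base genome is untouched outside the edited family blocks
  expect_identical(p$a$haplotypes, simulate_genome(sp)$haplotypes)
})
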