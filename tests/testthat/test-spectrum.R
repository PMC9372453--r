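test_that("monoploid peak detection finds the tallest post-trough maximum", {
  # error slope, then peaks at m = 10 (taller) and m = 20
  m <- 1:30
  y <- 1e5 * exp(-m) + 5000 * dnorm(m, 10, 2) + 3000 * dnorm(m, 20, 2)
  s <- kmer_spectrum(m, y)
  expect_equal(find_monoploid_peak(s, 2, 30), 10)
  # restricting the search window selects the other peak
  expect_equal(find_monoploid_peak(s, 15, 30), 20)
  # pure error: monotonically decreasing, no peak
  s_err <- kmer_spectrum(1:20, 1e5 * exp(-(1:20)))
  expect_error(find_monoploid_peak(s_err, 2, 20), "manual|manually")
  expect_error(find_monoploid_peak(kmer_spectrum(), 2, 20), "empty")
  expect_error(find_monoploid_peak(s, 10, 5), "search_min")
})

test_that("genome-size arithmetic follows the spectrum-sum rule", {
  s <- kmer_spectrum(c(10, 20), c(100, 450))
  expect_equal(estimate_genome_size(s, 10)$gs_2c_bp, 1000)
  # cutoff at c/2 removes the low-multiplicity contamination peak
  s <- kmer_spectrum(c(4, 10), c(1e6, 100))
  expect_equal(estimate_genome_size(s, 10)$gs_2c_bp, 100)
  # boundary: m = c/2 is kept (>= rule)
  s <- kmer_spectrum(c(5, 10), c(10, 100))
  expect_equal(estimate_genome_size(s, 10)$gs_2c_bp, (5 * 10 + 10 * 100) / 10)
  expect_warning(est <- estimate_genome_size(kmer_spectrum(2, 5), 100),
                 "cutoff")
  expect_equal(est$gs_2c_bp, 0)
  expect_error(estimate_genome_size(kmer_spectrum(2, 5), -1), "positive")
})

test_that("pg conversion uses 1 pg = 978 Mbp and halves to 1C", {
  expect_equal(round(mbp_to_pg_1c(999.98), 2), 0.51)
  expect_equal(round(mbp_to_pg_1c(1227.92), 2), 0.63)
  expect_equal(mbp_to_pg_1c(1956), 1)
  expect_equal(mbp_to_pg_1c(0), 0)
  expect_error(mbp_to_pg_1c(-1), ">= 0")
})

test_that("bin boundaries follow the geometric closed form", {
  expect_true(is.na(bin_index(0.5)))   # equal to origin: discarded
  expect_equal(bin_index(0.55), 0L)
  expect_equal(bin_index(0.550001), 1L)
  expect_equal(bin_index(22.0), 39L)
  expect_error(bin_index(0), "> 0")
  expect_equal(round(bin_lower(39), 2), 20.57)
  expect_equal(round(bin_upper(39), 2), 22.63)
  expect_equal(bin_upper(0:50), 0.5 * 1.1^(1:51))
  # a value exactly on an upper bound belongs to that bin
  for (i in c(0L, 5L, 17L, 39L))
    expect_equal(bin_index(bin_upper(i)), i)
  # representative lies inside its bin; geometric vs midpoint agree closely
  sch_mid <- bin_scheme(representative = "midpoint")
  r_geo <- bin_representative(0:60)
  r_mid <- bin_representative(0:60, sch_mid)
  expect_true(all(r_geo > bin_lower(0:60) & r_geo <= bin_upper(0:60)))
  expect_true(all(abs(r_geo - r_mid) / r_mid < 0.0012))
})

test_that("scaling and binning place counts in the right copy-number bins", {
  s <- kmer_spectrum(10, 100)
  b <- scale_and_bin(s, 10)
  expect_equal(b$bin, 7L)  # 0.5 * 1.1^7 = 0.974 < 1 <= 1.072
  expect_equal(b$count, 100)
  # scaled exactly 0.5: discarded
  b <- scale_and_bin(kmer_spectrum(5, 50), 10)
  expect_equal(length(b$bin), 0L)
  # scale invariance: multiplying multiplicities and coverage together
  s <- kmer_spectrum(c(6, 12, 60), c(10, 20, 5))
  b1 <- scale_and_bin(s, 6)
  b2 <- scale_and_bin(kmer_spectrum(c(6, 12, 60) * 5, c(10, 20, 5)), 30)
  expect_equal(b1$bin, b2$bin)
  expect_equal(b1$count, b2$count)
  for (m in c(7, 23, 100))
    expect_equal(scale_and_bin(kmer_spectrum(m, 9), m)$bin, 7L)
})

test_that("binned genome size weights counts by expected copy number", {
  expect_equal(binned_genome_size(binned_spectrum()), 0)
  b <- binned_spectrum(7L, 100)
  expect_equal(binned_genome_size(b),
               100 * sqrt(bin_lower(7) * bin_upper(7)))
  expect_equal(round(binned_genome_size(b), 1), 102.2)
})

test_that("range summary partitions the binned mass exactly", {
  b <- scale_and_bin(kmer_spectrum(10, 1000), 10)
  rs <- range_summary(b)
  expect_equal(rs$bp[1], binned_genome_size(b))  # all mass in (0, 10]
  expect_equal(sum(rs$bp), binned_genome_size(b))
  set.seed(5)
  for (i in 1:10) {
    b <- rand_binned(max_bin = 120)
    rs <- range_summary(b)
    expect_equal(sum(rs$bp), binned_genome_size(b))
  }
  # a repeat at copy number ~5000 lands in the (1000, 10000] range
  b <- scale_and_bin(kmer_spectrum(c(30, 150000), c(1000, 145)), 30)
  rs <- range_summary(b)
  expect_equal(rs$bp[rs$lower == 1000],
               145 * bin_representative(bin_index(5000)))
  expect_error(range_summary(b, c(10, 10)), "increasing")
})

test_that("idealized diploid spectra recover G1 + 2 G2", {
  # heterozygous k-mers at Poisson(c), homozygous at Poisson(2c)
  for (c_cov in c(20, 30, 50)) {
    g1 <- 5e4; g2 <- 4e5
    m <- 1:(6 * c_cov)
    n <- g1 * dpois(m, c_cov) + g2 * dpois(m, 2 * c_cov)
    est <- estimate_genome_size(kmer_spectrum(m, n), c_cov)
    expect_lt(abs(est$gs_2c_bp - (g1 + 2 * g2)) / (g1 + 2 * g2), 0.02)
  }
})

test_that("binning does not bias the genome-size inference", {
  set.seed(17)
  for (i in 1:50) {
    c_cov <- sample(20:60, 1)
    g1 <- runif(1, 1e4, 1e5); g2 <- runif(1, 1e5, 1e6)
    m <- 1:(6 * c_cov)
    n <- g1 * dpois(m, c_cov) + g2 * dpois(m, 2 * c_cov)
    # add a few high-copy repeat levels
    reps <- sample(10:5000, 5)
    m <- c(m, reps * c_cov)
    n <- c(n, runif(5, 10, 200))
    o <- order(m); m <- m[o]; n <- n[o]
    keep <- !duplicated(m)
    s <- kmer_spectrum(m[keep], n[keep])
    unbinned <- estimate_genome_size(s, c_cov)$gs_2c_bp
    binned <- binned_genome_size(scale_and_bin(s, c_cov))
    expect_lt(abs(binned - unbinned) / unbinned, 0.05)
  }
})
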