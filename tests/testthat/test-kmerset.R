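test_that("canonical counting matches hand-enumerated examples", {
  d <- count_kmers("ACGTACGT", k = 3, min_count = 1)
  expect_equal(d$kmer, c("ACG", "GTA"))
  expect_equal(d$count, c(4, 2))

  d <- count_kmers("AAA", k = 3, min_count = 1)
  expect_equal(d$kmer, "AAA")
  expect_equal(d$count, 1)

  # windows overlapping the N are skipped entirely
  d <- count_kmers("ACGNACG", k = 3, min_count = 1)
  expect_equal(d$kmer, "ACG")
  expect_equal(d$count, 2)

  # forward-strand (non-canonical) mode keeps k-mers as written
  d <- count_kmers("ACGT", k = 3, min_count = 1, canonical = FALSE)
  expect_equal(d$kmer, c("ACG", "CGT"))
})

test_that("degenerate inputs give empty dumps and invalid k is rejected", {
  expect_equal(length(count_kmers(character(), k = 21, min_count = 1)), 0L)
  expect_equal(length(count_kmers("ACGT", k = 21, min_count = 1)), 0L)
  expect_error(count_kmers("ACGT", k = 4), "odd")
  expect_error(count_kmers("ACGT", k = 33), "odd|31")
  expect_error(count_kmers("ACGT", k = 3, min_count = 0), "min_count")
})

test_that("counting equals the brute-force oracle on random sequences", {
  set.seed(42)
  for (k in c(3, 5, 21)) {
    for (rep in 1:25) {
      seqs <- replicate(sample(1:4, 1),
                        rand_seq(sample(50:400, 1), n_rate = 0.02))
      for (mc in c(1L, 2L)) {
        got <- count_kmers(seqs, k = k, min_count = mc)
        want <- oracle_count(seqs, k, min_count = mc)
        expect_identical(got$kmer, want$kmer)
        expect_equal(got$count, want$count)
      }
      # conservation: total multiplicity equals the number of valid windows
      got1 <- count_kmers(seqs, k = k, min_count = 1)
      expect_equal(sum(got1$count),
                   sum(oracle_count(seqs, k, min_count = 1)$count))
    }
  }
})

test_that("reference counting keeps multiplicity-1 k-mers", {
  seqs <- c("ACGTACGT", rand_seq(60))
  ref <- count_reference_kmers(seqs, k = 21)
  expect_identical(ref, count_kmers(seqs, k = 21, min_count = 1))
  one <- count_reference_kmers(rand_seq(21), k = 21)
  expect_equal(length(one), 1L)
  expect_equal(one$count, 1)
})

test_that("subtract and intersect partition a dump", {
  a <- kmer_dump(c("ACG", "GTA"), c(4, 2))
  b <- kmer_dump("GTA", 1)
  expect_equal(kmer_subtract(a, b)$kmer, "ACG")
  expect_equal(kmer_subtract(a, kmer_dump(k = 3))$kmer, a$kmer)
  expect_equal(length(kmer_subtract(a, a)), 0L)
  expect_error(kmer_subtract(a, kmer_dump("ACGTA", 1)), "mismatch")

  expect_equal(kmer_intersect(a, "ACG")$count, 4)
  expect_equal(length(kmer_intersect(a, character())), 0L)
  expect_identical(kmer_intersect(a, a$kmer), a)
  expect_error(kmer_intersect(a, "ACGTA"), "length")

  set.seed(7)
  big <- rand_dump(200)
  keys <- sample(big$kmer, 80)
  inter <- kmer_intersect(big, keys)
  rest <- kmer_subtract(big, kmer_dump(sort(keys), rep(1, 80), k = big$k))
  expect_equal(sort(c(inter$kmer, rest$kmer)), big$kmer)
  expect_equal(sum(inter$count) + sum(rest$count), sum(big$count))
})

test_that("group-unique k-mer sets are disjoint subsets of their groups", {
  db <- unique_to_group(list(G1 = "AAAA", G2 = "CCCC"), k = 3)
  expect_equal(db$groups$G1, "AAA")
  expect_equal(db$groups$G2, "CCC")  # canonical of CCC is min(CCC, GGG)

  db <- unique_to_group(list(G1 = "AAAA", G2 = "AAAA"), k = 3)
  expect_equal(lengths(db$groups), c(G1 = 0L, G2 = 0L))

  single <- unique_to_group(list(only = "ACGTACGT"), k = 3)
  expect_equal(single$groups$only, c("ACG", "GTA"))

  expect_error(unique_to_group(setNames(list("AAAA", "CCCC"),
                                        c("g", "g")), k = 3), "unique")

  set.seed(11)
  groups <- replicate(4, rand_seq(300), simplify = FALSE)
  names(groups) <- paste0("G", 1:4)
  db <- unique_to_group(groups, k = 5)
  all_unique <- unlist(db$groups)
  expect_equal(anyDuplicated(all_unique), 0L)
  for (g in names(groups)) {
    full <- count_reference_kmers(groups[[g]], k = 5)$kmer
    expect_true(all(db$groups[[g]] %in% full))
  }
})

test_that("spectrum_of tallies dump multiplicities", {
  s <- spectrum_of(kmer_dump(c("ACG", "GTA"), c(4, 2)))
  expect_equal(s$multiplicity, c(2, 4))
  expect_equal(s$count, c(1, 1))
  expect_equal(length(spectrum_of(kmer_dump(k = 21))$count), 0L)
  s <- spectrum_of(kmer_dump(c("AAA", "AAC", "AAG"), c(2, 2, 2)))
  expect_equal(s$multiplicity, 2)
  expect_equal(s$count, 3)
  set.seed(3)
  d <- rand_dump(150)
  expect_equal(sum(spectrum_of(d)$count), length(d))
})
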