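# Brute-force k-mer counting oracle, independent of the package's counter:
# lists every window, canonicalizes by explicit reverse-complement string
# comparison, and tallies with table().

oracle_revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

oracle_count <- function(seqs, k, min_count = 1L, canonical = TRUE) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (canonical) {
    rc <- oracle_revcomp(wins)
    wins <- ifelse(wins <= rc, wins, rc)
  }
  tab <- table(wins)
  tab <- tab[tab >= min_count]
  list(kmer = names(tab), count = as.numeric(tab))  # table() sorts keys
}

rand_seq <- function(len, n_rate = 0) {
  paste(sample(c("A", "C", "G", "T",
                 if (n_rate > 0) "N"),
               len, replace = TRUE,
               prob = c(rep((1 - n_rate) / 4, 4),
                        if (n_rate > 0) n_rate)),
        collapse = "")
}

# random k-mer dump over a small universe, for join/marginal properties
rand_dump <- function(n, k = 5, max_count = 60) {
  universe <- oracle_count(rand_seq(4^k), k)$kmer
  keys <- sort(sample(universe, min(n, length(universe))))
  kmer_dump(keys, sample(max_count, length(keys), replace = TRUE), k = k)
}

# random binned spectrum on a shared scheme
rand_binned <- function(scheme = bin_scheme(), max_bin = 60) {
  bins <- sort(sample(0:max_bin, sample(5:25, 1)))
  binned_spectrum(bins, sample(1000, length(bins), replace = TRUE),
                  scheme = scheme, coverage = 30)
}

table1_gs <- c(An1 = 999.98, An2 = 989.23, Vi = 1055.93, Ro = 1227.92,
               Ri1 = 1126.64, Ri2 = 1096.44, Ri3 = 1104.84)
table1_species <- c("An", "An", "Vi", "Ro", "Ri", "Ri", "Ri")
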