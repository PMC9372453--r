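#' k-mer dump objects
#'
#' A k-mer dump is the identity-aware representation of a sequencing dataset:
#' a table of canonical k-mers and their multiplicities, sorted
#' lexicographically by k-mer (A < C < G < T), mirroring the two-column text
#' dumps written by standard k-mer counters.
#'
#' @param kmer character vector of k-mers (upper-case ACGT), strictly
#'   increasing lexicographically.
#' @param count numeric vector of multiplicities (>= 1), same length.
#' @param k k-mer length; inferred from `kmer` when missing and the dump is
#'   non-empty.
#' @param min_count the minimum-count threshold the dump was built with.
#' @return An object of class `kmer_dump` with elements `k`, `kmer`, `count`
#'   and `min_count`.
#' @seealso [count_kmers()], [read_kmer_dump()]
#' @export
kmer_dump <- function(kmer = character(), count = numeric(), k = NULL,
                      min_count = 1L) {
  kmer <- as.character(kmer)
  count <- as.numeric(count)
  if (length(kmer) != length(count))
    stop("kmer and count must have the same length")
  if (is.null(k)) {
    if (length(kmer) == 0)
      stop("k must be given for an empty dump")
    k <- nchar(kmer[1L])
  }
  k <- as.integer(k)
  if (length(kmer)) {
    if (any(nchar(kmer) != k))
      stop("all k-mers must have length k = ", k)
    if (is.unsorted(kmer, strictly = TRUE))
      stop("k-mers must be strictly increasing (sorted, unique)")
    if (any(count < 1))
      stop("multiplicities must be >= 1")
  }
  structure(list(k = k, kmer = kmer, count = count,
                 min_count = as.integer(min_count)),
            class = "kmer_dump")
}

#' @export
print.kmer_dump <- function(x, ...) {
  cat("k-mer dump: ", length(x$kmer), " distinct ", x$k, "-mers, ",
      format(sum(x$count), big.mark = ","), " total occurrences",
      " (min count ", x$min_count, ")\n", sep = "")
  if (length(x$kmer)) {
    n <- min(5L, length(x$kmer))
    cat(paste0("  ", x$kmer[seq_len(n)], "\t", x$count[seq_len(n)]),
        sep = "\n")
    if (length(x$kmer) > n) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.kmer_dump <- function(x) length(x$kmer)

check_k <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k > 31 || k %% 2 == 0)
    stop("k must be a single odd integer between 1 and 31")
  as.integer(k)
}

as_sequence_chr <- function(sequences) {
  if (methods::is(sequences, "XStringSet")) sequences <- as.character(sequences)
  as.character(sequences)
}

#' Count canonical k-mers in sequences
#'
#' Counts every window of `k` consecutive unambiguous bases across a
#' collection of sequences. Each window contributes one count to its
#' canonical form, the lexicographic minimum of the window and its reverse
#' complement (strand-collapsed counting); windows containing any non-ACGT
#' symbol are skipped entirely. Entries below `min_count` are removed, which
#' with the default `min_count = 2` discards most sequencing-error k-mers as
#' standard counters do on read data.
#'
#' @param sequences character vector or `Biostrings::XStringSet` of DNA
#'   sequences (reads or assembled sequence).
#' @param k k-mer length; odd, between 1 and 31. Default 21.
#' @param min_count drop k-mers seen fewer than this many times. Default 2,
#'   appropriate for read data; use [count_reference_kmers()] for assemblies.
#' @param canonical collapse each k-mer with its reverse complement
#'   (default). `FALSE` counts forward-strand k-mers as written.
#' @return A [kmer_dump()].
#' @examples
#' count_kmers("ACGTACGT", k = 3, min_count = 1)
#' @export
count_kmers <- function(sequences, k = 21L, min_count = 2L, canonical = TRUE) {
  k <- check_k(k)
  if (min_count < 1) stop("min_count must be >= 1")
  sequences <- as_sequence_chr(sequences)
  res <- cpp_count_kmers(sequences, k, as.integer(min_count),
                         isTRUE(canonical))
  kmer_dump(res$kmer, res$count, k = k, min_count = min_count)
}

#' Count k-mers in a reference assembly
#'
#' Identical to [count_kmers()] with `min_count` forced to 1: in an assembled
#' sequence (for example an organellar genome used for k-mer subtraction)
#' most k-mers legitimately occur once and must be retained.
#'
#' @inheritParams count_kmers
#' @return A [kmer_dump()].
#' @export
count_reference_kmers <- function(sequences, k = 21L, canonical = TRUE) {
  count_kmers(sequences, k = k, min_count = 1L, canonical = canonical)
}

#' Set algebra on k-mer dumps
#'
#' `kmer_subtract()` removes from `a` every k-mer present in `b` (used to
#' strip organellar k-mers from a sample database); `kmer_intersect()`
#' restricts `a` to a given key set (used to pull out repeat-family k-mers).
#' Multiplicities of the surviving entries are unchanged.
#'
#' @param a a [kmer_dump()].
#' @param b a [kmer_dump()] whose k-mers are removed from `a`.
#' @return A [kmer_dump()] with `a`'s `k` and `min_count`.
#' @export
kmer_subtract <- function(a, b) {
  stopifnot(inherits(a, "kmer_dump"), inherits(b, "kmer_dump"))
  if (a$k != b$k) stop("k mismatch: ", a$k, " vs ", b$k)
  keep <- !(a$kmer %in% b$kmer)
  kmer_dump(a$kmer[keep], a$count[keep], k = a$k, min_count = a$min_count)
}

#' @rdname kmer_subtract
#' @param keys character vector of k-mers (or a `kmer_dump`) to keep.
#' @export
kmer_intersect <- function(a, keys) {
  stopifnot(inherits(a, "kmer_dump"))
  if (inherits(keys, "kmer_dump")) keys <- keys$kmer
  keys <- as.character(keys)
  if (length(keys) && any(nchar(keys) != a$k))
    stop("key length does not match dump k = ", a$k)
  keep <- a$kmer %in% keys
  kmer_dump(a$kmer[keep], a$count[keep], k = a$k, min_count = a$min_count)
}

#' Group-unique k-mer sets (repeat k-mer database)
#'
#' For a named list of per-group sequence collections (for example one
#' repeat-family consensus or read set per group), extracts for each group
#' the canonical k-mers that occur in that group and in no other group.
#' Uniqueness is global, so the resulting sets are pairwise disjoint and a
#' k-mer can be attributed to at most one repeat family.
#'
#' @param groups named list; each element a character vector or `XStringSet`
#'   of sequences. Names are the group labels and must be unique.
#' @param k k-mer length (odd, 1-31).
#' @param canonical see [count_kmers()].
#' @return An object of class `repeat_kmer_db`: list with `k` and `groups`,
#'   a named list of sorted k-mer character vectors.
#' @export
unique_to_group <- function(groups, k = 21L, canonical = TRUE) {
  k <- check_k(k)
  if (length(groups) < 1) stop("at least one group is required")
  labels <- names(groups)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels))
    stop("groups must have unique, non-empty names")
  per_group <- lapply(groups, function(s)
    count_reference_kmers(as_sequence_chr(s), k = k, canonical = canonical)$kmer)
  all_kmers <- unlist(per_group, use.names = FALSE)
  shared <- unique(all_kmers[duplicated(all_kmers)])
  sets <- lapply(per_group, function(km) km[!(km %in% shared)])
  names(sets) <- labels
  structure(list(k = k, groups = sets), class = "repeat_kmer_db")
}

#' @export
print.repeat_kmer_db <- function(x, ...) {
  cat("repeat k-mer database: ", length(x$groups), " groups, k = ", x$k,
      "\n", sep = "")
  sizes <- vapply(x$groups, length, integer(1))
  for (i in seq_along(sizes))
    cat("  ", names(sizes)[i], ": ", sizes[i], " unique k-mers\n", sep = "")
  invisible(x)
}

#' k-mer spectrum of a dump
#'
#' Tallies a dump into its identity-free counterpart: for each multiplicity
#' level m, the number of distinct k-mers observed m times.
#'
#' @param a a [kmer_dump()].
#' @return A [kmer_spectrum()].
#' @export
spectrum_of <- function(a) {
  stopifnot(inherits(a, "kmer_dump"))
  if (!length(a$count)) return(kmer_spectrum(numeric(), numeric(), k = a$k))
  tab <- table(a$count)
  m <- as.numeric(names(tab))
  o <- order(m)
  kmer_spectrum(m[o], as.numeric(tab)[o], k = a$k)
}
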