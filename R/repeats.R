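#' Per-repeat-family contribution to a sample's genome size
#'
#' Restricts a sample's k-mer dump to each repeat family's family-unique
#' k-mers (see [unique_to_group()]) and applies the genome-size arithmetic
#' to the subset: multiplicities at or above half the monoploid coverage are
#' summed and divided by the coverage, giving the base pairs that family
#' contributes to the sample's 2C genome. Because family k-mer sets are
#' pairwise disjoint, contributions are additive and each is bounded by the
#' whole-genome estimate. Only family-unique k-mers are counted, so
#' contributions are, if anything, underestimates.
#'
#' @param sample a [kmer_dump()] for the sample (organelles subtracted).
#' @param db a `repeat_kmer_db` from [unique_to_group()] or
#'   [read_repeat_db()].
#' @param coverage the sample's monoploid peak multiplicity (> 0).
#' @param genome_size optional whole-genome `genome_size_estimate` (or 2C bp
#'   number) used for the `genome_proportion` column; computed from `sample`
#'   when missing.
#' @return A data.frame with one row per family: `group`, `bp`, `mbp`,
#'   `genome_proportion`.
#' @export
repeat_contribution <- function(sample, db, coverage, genome_size = NULL) {
  stopifnot(inherits(sample, "kmer_dump"), inherits(db, "repeat_kmer_db"))
  if (sample$k != db$k) stop("k mismatch: ", sample$k, " vs ", db$k)
  if (coverage <= 0) stop("coverage must be > 0")
  if (is.null(genome_size))
    genome_size <- estimate_genome_size(spectrum_of(sample), coverage)
  gs_bp <- if (inherits(genome_size, "genome_size_estimate"))
    genome_size$gs_2c_bp else as.numeric(genome_size)
  bp <- vapply(db$groups, function(keys) {
    sub <- kmer_intersect(sample, keys)
    keep <- sub$count >= coverage / 2
    sum(sub$count[keep]) / coverage
  }, numeric(1))
  data.frame(group = names(db$groups), bp = unname(bp), mbp = unname(bp) / 1e6,
             genome_proportion = if (gs_bp > 0) unname(bp) / gs_bp else
               NA_real_,
             stringsAsFactors = FALSE)
}

#' Fraction of a pairwise genome-size difference explained by repeats
#'
#' Sums the per-family contribution differences between two samples and
#' divides by the total pairwise 2C difference. The result may exceed 1
#' when repeat-associated k-mer variation overshoots the overall
#' genome-size difference (the balance then lies in low-copy sequence
#' moving the other way).
#'
#' @param pair_diff_bp total 2C genome-size difference (bp), non-zero.
#' @param repeat_diffs named numeric vector of per-family bp differences,
#'   oriented the same way as `pair_diff_bp`.
#' @return A single number; `NA` with a warning when `pair_diff_bp` is 0.
#' @export
explained_fraction <- function(pair_diff_bp, repeat_diffs) {
  if (length(pair_diff_bp) != 1)
    stop("pair_diff_bp must be a single number")
  if (pair_diff_bp == 0) {
    warning("total genome-size difference is zero; fraction undefined")
    return(NA_real_)
  }
  sum(repeat_diffs) / pair_diff_bp
}

#' Joint k-mer spectrum restricted to one repeat family
#'
#' Computes [joint_spectrum()] after restricting both dumps to a family's
#' (family-unique) k-mer set, exposing where that family's k-mers sit in
#' copy-number space in each sample. Copy-number change in the family shows
#' as compact off-diagonal mass.
#'
#' @param sample,reference [kmer_dump()] objects with equal `k`.
#' @param keys character vector of the family's k-mers (one element of a
#'   `repeat_kmer_db`'s `groups`).
#' @param coverage_sample,coverage_reference monoploid peak multiplicities.
#' @inheritParams joint_spectrum
#' @return A `joint_spectrum` (sample on axis A, reference on axis B).
#' @export
repeat_joint_spectrum <- function(sample, reference, keys, coverage_sample,
                                  coverage_reference, scheme = bin_scheme(),
                                  join = c("outer", "inner"),
                                  label_sample = "sample",
                                  label_reference = "reference") {
  joint_spectrum(kmer_intersect(sample, keys),
                 kmer_intersect(reference, keys),
                 coverage_sample, coverage_reference, scheme = scheme,
                 join = join, label_a = label_sample,
                 label_b = label_reference)
}
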