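#' Geometric copy-number bin scheme
#'
#' Shared copy-number classes for comparing coverage-scaled spectra between
#' samples: bin i (i = 0, 1, ...) covers the half-open interval
#' `(origin * growth^i, origin * growth^(i+1)]`. With the defaults
#' (origin 0.5, growth 1.10) each bin's upper limit is 10% larger than its
#' lower limit, bin 0 is (0.5, 0.55] and bin 39 is (20.57, 22.63]. Scaled
#' multiplicities at or below `origin` are treated as likely contaminants
#' and discarded by [bin_index()].
#'
#' @param origin lower bound of bin 0 (default 0.5).
#' @param growth per-bin growth factor (> 1; default 1.10).
#' @param representative how the expected copy number of k-mers in a bin is
#'   summarised: `"geometric"` (default; geometric mean of the bounds,
#'   consistent with geometric bin growth) or `"midpoint"` (arithmetic mean;
#'   differs by < 0.12% at 10% growth).
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme <- function(origin = 0.5, growth = 1.10,
                       representative = c("geometric", "midpoint")) {
  if (origin <= 0) stop("origin must be > 0")
  if (growth <= 1) stop("growth must be > 1")
  representative <- match.arg(representative)
  structure(list(origin = origin, growth = growth,
                 representative = representative),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf(
    "copy-number bin scheme: bin i = (%g*%g^i, %g*%g^(i+1)], e.g. (%.3g, %.3g], (%.3g, %.3g], ...\n",
    x$origin, x$growth, x$origin, x$growth,
    bin_lower(0, x), bin_upper(0, x), bin_lower(1, x), bin_upper(1, x)))
  invisible(x)
}

same_scheme <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$growth, b$growth)) &&
    a$representative == b$representative
}

#' @rdname bin_scheme
#' @param i bin index (vector of integers >= 0).
#' @param scheme a `bin_scheme`.
#' @export
bin_lower <- function(i, scheme = bin_scheme()) scheme$origin * scheme$growth^i

#' @rdname bin_scheme
#' @export
bin_upper <- function(i, scheme = bin_scheme()) {
  scheme$origin * scheme$growth^(i + 1)
}

#' @rdname bin_scheme
#' @export
bin_representative <- function(i, scheme = bin_scheme()) {
  lo <- bin_lower(i, scheme)
  up <- bin_upper(i, scheme)
  if (scheme$representative == "geometric") sqrt(lo * up) else (lo + up) / 2
}

#' Map scaled multiplicities to copy-number bins
#'
#' Returns the bin index i with
#' `origin * growth^i < value <= origin * growth^(i+1)`, or `NA` for values
#' at or below `origin`, which are discarded as likely contaminants.
#' Boundary values are resolved with a small relative tolerance so that a
#' value exactly equal to a bin's upper limit falls in that bin.
#'
#' @param value positive scaled multiplicities (copy numbers).
#' @param scheme a [bin_scheme()].
#' @return Integer bin indices (>= 0), `NA` where discarded.
#' @examples
#' bin_index(c(0.5, 0.55, 0.550001, 22))  # NA, 0, 1, 39
#' @export
bin_index <- function(value, scheme = bin_scheme()) {
  if (any(value <= 0)) stop("scaled multiplicities must be > 0")
  x <- log(value / scheme$origin) / log(scheme$growth)
  i <- as.integer(ceiling(x - 1e-9) - 1)
  i[value <= scheme$origin] <- NA_integer_
  i
}

#' Scale a spectrum to copy-number units and bin it
#'
#' Divides every multiplicity by the monoploid peak multiplicity `coverage`,
#' placing heterozygous k-mers at copy number 1 and homozygous at 2, then
#' assigns each level's distinct-k-mer count to its geometric copy-number
#' bin. Scaled values at or below the scheme origin are discarded. Because
#' binning happens after scaling, a bin index means the same genomic copy
#' number range in every sample, making binned spectra directly comparable.
#'
#' @param s a [kmer_spectrum()].
#' @param coverage monoploid peak multiplicity used for scaling (> 0).
#' @param scheme a [bin_scheme()].
#' @return An object of class `binned_spectrum`: list with `scheme`, `bin`
#'   (sorted integer indices), `count` (distinct k-mers per bin) and
#'   `coverage`. The highest bin present is the one holding the
#'   highest-copy-number k-mer observed.
#' @export
scale_and_bin <- function(s, coverage, scheme = bin_scheme()) {
  stopifnot(inherits(s, "kmer_spectrum"))
  if (!is.numeric(coverage) || length(coverage) != 1 || coverage <= 0)
    stop("coverage must be a single positive number")
  idx <- bin_index(s$multiplicity / coverage, scheme)
  keep <- !is.na(idx)
  agg <- tapply(s$count[keep], idx[keep], sum)
  binned_spectrum(bin = as.integer(names(agg)), count = as.numeric(agg),
                  scheme = scheme, coverage = coverage)
}

#' @rdname scale_and_bin
#' @param bin,count parallel vectors of bin indices and k-mer counts.
#' @export
binned_spectrum <- function(bin = integer(), count = numeric(),
                            scheme = bin_scheme(), coverage = NA_real_) {
  bin <- as.integer(bin)
  count <- as.numeric(count)
  if (length(bin) != length(count))
    stop("bin and count must have the same length")
  o <- order(bin)
  bin <- bin[o]; count <- count[o]
  if (length(bin)) {
    if (any(bin < 0)) stop("bin indices must be >= 0")
    if (anyDuplicated(bin)) stop("bin indices must be unique")
    if (any(count < 0)) stop("counts must be >= 0")
  }
  structure(list(scheme = scheme, bin = bin, count = count,
                 coverage = coverage),
            class = "binned_spectrum")
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat("binned k-mer spectrum: ", format(sum(x$count), big.mark = ","),
      " k-mers in ", length(x$bin), " occupied copy-number bins",
      if (length(x$bin)) paste0(" (max bin ", max(x$bin), ", copy number <= ",
                                signif(bin_upper(max(x$bin), x$scheme), 4), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Genome size implied by a binned spectrum
#'
#' Sums, over occupied bins, the k-mer count times the bin's expected copy
#' number (the representative of [bin_scheme()]), analogous to computing the
#' genome size from an unbinned spectrum. Used to verify that binning does
#' not bias genome-size inferences and as the weighting behind
#' [diff_graph()].
#'
#' @param b a `binned_spectrum`.
#' @return Genome size in bp (2C when the source spectrum was a diploid's).
#' @export
binned_genome_size <- function(b) {
  stopifnot(inherits(b, "binned_spectrum"))
  sum(b$count * bin_representative(b$bin, b$scheme))
}

#' Aggregate a binned spectrum into coarse copy-number ranges
#'
#' Collapses bins into half-open copy-number ranges (default boundaries 10,
#' 100, ..., 1e6 plus a final open-ended range) to show which broad
#' repetitiveness classes hold the genome's mass. A bin is assigned to the
#' range containing its representative copy number; values are k-mer counts
#' times representative copy number, i.e. base pairs, and sum exactly to
#' [binned_genome_size()].
#'
#' @param b a `binned_spectrum`.
#' @param breakpoints strictly increasing range boundaries.
#' @return A data.frame with columns `range`, `lower`, `upper` and `bp`.
#' @export
range_summary <- function(b, breakpoints = c(10, 100, 1e3, 1e4, 1e5, 1e6)) {
  stopifnot(inherits(b, "binned_spectrum"))
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  lower <- c(0, breakpoints)
  upper <- c(breakpoints, Inf)
  rep_cn <- bin_representative(b$bin, b$scheme)
  bp <- b$count * rep_cn
  grp <- findInterval(rep_cn, lower, left.open = TRUE, rightmost.closed = FALSE)
  total <- vapply(seq_along(lower), function(g) sum(bp[grp == g]), numeric(1))
  data.frame(range = paste0("(", format(lower, scientific = FALSE,
                                        trim = TRUE), ",",
                            format(upper, scientific = FALSE, trim = TRUE),
                            "]"),
             lower = lower, upper = upper, bp = total,
             stringsAsFactors = FALSE)
}
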