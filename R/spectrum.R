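#' k-mer spectrum objects
#'
#' A k-mer spectrum is the histogram of a sequencing dataset's k-mer
#' multiplicities: for each multiplicity level m (x-axis), the number of
#' distinct k-mers observed m times (y-axis). For a diploid, heterozygous
#' k-mers pile up at the per-haplotype ("monoploid") coverage and homozygous
#' k-mers at twice that; repeats extend the spectrum to arbitrarily high
#' multiplicities, so spectra here are kept uncropped.
#'
#' @param multiplicity numeric vector of multiplicity levels (integers >= 1),
#'   strictly increasing.
#' @param count numeric vector of distinct-k-mer counts (>= 0), same length.
#' @param k the k-mer length the spectrum was built with.
#' @return An object of class `kmer_spectrum` with elements `k`,
#'   `multiplicity` and `count`.
#' @seealso [spectrum_of()], [read_spectrum()]
#' @export
kmer_spectrum <- function(multiplicity = numeric(), count = numeric(),
                          k = 21L) {
  multiplicity <- as.numeric(multiplicity)
  count <- as.numeric(count)
  if (length(multiplicity) != length(count))
    stop("multiplicity and count must have the same length")
  if (length(multiplicity)) {
    if (any(multiplicity < 1) || any(multiplicity != floor(multiplicity)))
      stop("multiplicities must be integers >= 1")
    if (is.unsorted(multiplicity, strictly = TRUE))
      stop("multiplicities must be strictly increasing")
    if (any(count < 0)) stop("counts must be >= 0")
  }
  structure(list(k = as.integer(k), multiplicity = multiplicity,
                 count = count),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("k-mer spectrum (k = ", x$k, "): ",
      format(sum(x$count), big.mark = ","), " distinct k-mers over ",
      length(x$multiplicity), " multiplicity levels",
      if (length(x$multiplicity))
        paste0(" [", min(x$multiplicity), ", ", max(x$multiplicity), "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom graphics plot
plot.kmer_spectrum <- function(x, log = "xy", xlab = "multiplicity",
                               ylab = "distinct k-mers", type = "l", ...) {
  keep <- x$count > 0
  plot(x$multiplicity[keep], x$count[keep], log = log, xlab = xlab,
       ylab = ylab, type = type, ...)
  invisible(x)
}

#' Locate the monoploid coverage peak of a spectrum
#'
#' A simple detector for the multiplicity of the monoploid ("haploid") k-mer
#' peak -- the peak formed by heterozygous k-mers, whose multiplicity equals
#' the per-haplotype sequencing coverage in k-mer terms. Counts are smoothed
#' with a centred moving average (window 3) on a contiguous multiplicity
#' grid; the first local minimum marks the end of the sequencing-error
#' slope, and the tallest smoothed local maximum after it within
#' `[search_min, search_max]` is returned. Ties break toward the lower
#' multiplicity. Dedicated spectrum-fitting tools estimate this quantity by
#' mixture models; when one has been run, pass its value downstream instead
#' of calling this detector.
#'
#' @param s a [kmer_spectrum()].
#' @param search_min,search_max multiplicity range searched for the peak.
#' @return The peak multiplicity (a single number > 0).
#' @export
find_monoploid_peak <- function(s, search_min = 2, search_max = Inf) {
  stopifnot(inherits(s, "kmer_spectrum"))
  if (!length(s$multiplicity)) stop("spectrum is empty")
  if (search_min >= search_max) stop("search_min must be < search_max")
  # fill the multiplicity grid so neighbours are adjacent levels
  m_grid <- seq(min(s$multiplicity), max(s$multiplicity))
  y <- numeric(length(m_grid))
  y[match(s$multiplicity, m_grid)] <- s$count
  n <- length(y)
  sm <- y
  if (n >= 3)
    sm[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
  # first local minimum = error trough (interior point, strict on the right)
  trough <- 0L
  for (i in seq_len(n - 2L) + 1L) {
    if (sm[i] <= sm[i - 1] && sm[i] < sm[i + 1]) { trough <- i; break }
  }
  is_max <- rep(FALSE, n)
  if (n >= 3) {
    for (i in seq_len(n - 2L) + 1L)
      is_max[i] <- sm[i] >= sm[i - 1] && sm[i] > sm[i + 1]
  }
  cand <- which(is_max & seq_len(n) > trough &
                  m_grid >= search_min & m_grid <= search_max)
  if (!length(cand))
    stop("no monoploid peak found in [", search_min, ", ", search_max,
         "]; supply the coverage manually")
  best <- cand[which.max(sm[cand])]  # which.max takes the first = lower m
  m_grid[best]
}

#' Estimate diploid (2C) genome size from an uncropped spectrum
#'
#' Given the monoploid peak multiplicity c, the portion of the spectrum with
#' multiplicity below c/2 -- largely the contamination/error peak -- is
#' discarded; for the remaining levels, multiplicity times count is summed
#' and divided by c:
#' \deqn{GS_{2C} = \sum_{m \ge c/2} m\, n(m) / c.}
#' Each retained k-mer occurrence then contributes 1/c of a genomic position,
#' so the result is in base pairs per diploid (2C) genome. Organellar k-mers
#' are expected to have been subtracted beforehand (see [kmer_subtract()]).
#'
#' @param s a [kmer_spectrum()].
#' @param coverage the monoploid peak multiplicity c (> 0), from
#'   [find_monoploid_peak()] or an external spectrum fitter.
#' @return An object of class `genome_size_estimate`: list with `gs_2c_bp`,
#'   `gs_2c_mbp`, `gs_1c_pg` (1 pg = 978 Mbp), `coverage` and `cutoff`.
#' @examples
#' s <- kmer_spectrum(c(10, 20), c(100, 450))
#' estimate_genome_size(s, coverage = 10)$gs_2c_bp  # 1000
#' @export
estimate_genome_size <- function(s, coverage) {
  stopifnot(inherits(s, "kmer_spectrum"))
  if (!is.numeric(coverage) || length(coverage) != 1 || coverage <= 0)
    stop("coverage must be a single positive number")
  cutoff <- coverage / 2
  keep <- s$multiplicity >= cutoff
  if (!any(keep)) {
    warning("spectrum is empty after the multiplicity >= c/2 cutoff")
    gs <- 0
  } else {
    gs <- sum(s$multiplicity[keep] * s$count[keep]) / coverage
  }
  structure(list(gs_2c_bp = gs, gs_2c_mbp = gs / 1e6,
                 gs_1c_pg = mbp_to_pg_1c(gs / 1e6),
                 coverage = coverage, cutoff = cutoff),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("2C genome size: %.2f Mbp (1C = %.2f pg) at coverage %g\n",
              x$gs_2c_mbp, x$gs_1c_pg, x$coverage))
  invisible(x)
}

#' Convert a diploid genome size in Mbp to 1C picograms
#'
#' Uses the standard conversion 1 pg = 978 Mbp and halves the diploid (2C)
#' value to a monoploid (1C) DNA amount.
#'
#' @param gs_2c_mbp diploid genome size in Mbp (>= 0).
#' @return 1C genome size in picograms.
#' @examples
#' mbp_to_pg_1c(1956)  # exactly 1 pg
#' @export
mbp_to_pg_1c <- function(gs_2c_mbp) {
  if (any(gs_2c_mbp < 0)) stop("genome size must be >= 0")
  gs_2c_mbp / 2 / 978
}

#' Pairwise 2C genome-size difference
#'
#' @param a,b `genome_size_estimate` objects or plain numbers on a common
#'   scale (bp or Mbp).
#' @return `a - b` on that scale (Mbp when both inputs are Mbp).
#' @export
total_gs_difference <- function(a, b) {
  val <- function(x) if (inherits(x, "genome_size_estimate")) x$gs_2c_bp else x
  val(a) - val(b)
}
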