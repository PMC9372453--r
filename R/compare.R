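#' Per-bin k-mer difference graph between two samples
#'
#' For each copy-number bin the difference in distinct-k-mer counts between
#' two binned spectra is multiplied by the bin's expected copy number,
#' giving the bin's contribution to the genome-size difference in base
#' pairs; summing over bins yields the total 2C difference, analogous to
#' computing a genome size from a spectrum. The cumulative series, ordered
#' by ascending bin (increasing repetitiveness), makes visible which
#' copy-number classes drive the total: a step ("slope") at some copy
#' number marks a repeat whose abundance differs between the samples.
#'
#' @param a,b `binned_spectrum` objects scaled to copy-number units and
#'   binned with the same [bin_scheme()]. The comparison is `a - b`
#'   (e.g. sample minus reference).
#' @return An object of class `diff_graph`: list with `scheme`, a `table`
#'   data.frame (`bin`, `lower`, `upper`, `representative`, `count_diff`,
#'   `bp_diff`, `cumulative_bp` over the union of occupied bins) and
#'   `total_bp`. Swapping the arguments negates every field.
#' @export
diff_graph <- function(a, b) {
  stopifnot(inherits(a, "binned_spectrum"), inherits(b, "binned_spectrum"))
  if (!same_scheme(a$scheme, b$scheme))
    stop("binned spectra use different bin schemes")
  bins <- sort(union(a$bin, b$bin))
  ca <- numeric(length(bins)); cb <- numeric(length(bins))
  ca[match(a$bin, bins)] <- a$count
  cb[match(b$bin, bins)] <- b$count
  rep_cn <- bin_representative(bins, a$scheme)
  count_diff <- ca - cb
  bp_diff <- count_diff * rep_cn
  tab <- data.frame(bin = bins,
                    lower = bin_lower(bins, a$scheme),
                    upper = bin_upper(bins, a$scheme),
                    representative = rep_cn,
                    count_diff = count_diff,
                    bp_diff = bp_diff,
                    cumulative_bp = cumsum(bp_diff))
  structure(list(scheme = a$scheme, table = tab, total_bp = sum(bp_diff)),
            class = "diff_graph")
}

#' @export
print.diff_graph <- function(x, ...) {
  cat(sprintf("k-mer difference graph: %d bins, total 2C difference %.3f Mbp\n",
              nrow(x$table), x$total_bp / 1e6))
  invisible(x)
}

#' @export
#' @importFrom graphics abline plot
plot.diff_graph <- function(x, xlab = "genomic copy number",
                            ylab = "cumulative difference (bp)", type = "s",
                            log = "x", ...) {
  plot(x$table$representative, x$table$cumulative_bp, type = type, log = log,
       xlab = xlab, ylab = ylab, ...)
  abline(h = x$total_bp, col = "grey")
  invisible(x)
}

ABSENT_BIN <- -1L

#' Binned joint k-mer spectrum of two samples
#'
#' Joins two k-mer dumps on the k-mer column (a database-style join, so the
#' comparison is aware of sequence identity), scales each side's
#' multiplicity by its own monoploid coverage, bins both with a shared
#' scheme, and counts how many k-mers fall in each pair of bins. Mass on the
#' diagonal marks k-mers with equal copy number in both samples;
#' off-diagonal mass marks copy-number divergence. With the default outer
#' join, a k-mer missing from one dump -- or scaled at or below the
#' scheme origin there and hence discarded -- is recorded against the
#' reserved "absent" index (-1) on that axis, so presence/absence variation
#' stays visible; `join = "inner"` keeps only k-mers present in both dumps.
#'
#' @param a,b [kmer_dump()] objects with equal `k`.
#' @param coverage_a,coverage_b monoploid peak multiplicities (> 0).
#' @param scheme a [bin_scheme()].
#' @param join `"outer"` (default) or `"inner"`.
#' @param label_a,label_b sample identifiers carried into the result.
#' @return An object of class `joint_spectrum`: list with `scheme`, `cells`
#'   (data.frame `bin_a`, `bin_b`, `count`; absent = -1), `labels` and
#'   `coverages`. See [as.matrix.joint_spectrum()] and [joint_marginals()].
#' @export
joint_spectrum <- function(a, b, coverage_a, coverage_b,
                           scheme = bin_scheme(),
                           join = c("outer", "inner"),
                           label_a = "A", label_b = "B") {
  stopifnot(inherits(a, "kmer_dump"), inherits(b, "kmer_dump"))
  if (a$k != b$k) stop("k mismatch: ", a$k, " vs ", b$k)
  if (coverage_a <= 0 || coverage_b <= 0) stop("coverages must be > 0")
  join <- match.arg(join)

  pos <- match(a$kmer, b$kmer)
  in_both <- !is.na(pos)
  bin_of <- function(count, coverage) {
    idx <- bin_index(count / coverage, scheme)
    idx[is.na(idx)] <- ABSENT_BIN  # discarded (<= origin) counts as absent
    idx
  }
  bins_a <- bin_of(a$count, coverage_a)
  bins_b_for_a <- rep(ABSENT_BIN, length(a$kmer))
  bins_b_for_a[in_both] <- bin_of(b$count[pos[in_both]], coverage_b)
  if (join == "inner") {
    ia <- bins_a[in_both]
    ib <- bins_b_for_a[in_both]
  } else {
    only_b <- !(b$kmer %in% a$kmer)
    ia <- c(bins_a, rep(ABSENT_BIN, sum(only_b)))
    ib <- c(bins_b_for_a, bin_of(b$count[only_b], coverage_b))
  }
  keep <- !(ia == ABSENT_BIN & ib == ABSENT_BIN)  # doubly-absent is no k-mer
  ia <- ia[keep]; ib <- ib[keep]
  cells <- data.frame(bin_a = integer(), bin_b = integer(), count = numeric())
  if (length(ia)) {
    key <- paste(ia, ib)
    agg <- tapply(rep(1, length(ia)), key, sum)
    parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
    cells <- data.frame(bin_a = as.integer(parts[, 1]),
                        bin_b = as.integer(parts[, 2]),
                        count = as.numeric(agg))
    cells <- cells[order(cells$bin_a, cells$bin_b), , drop = FALSE]
    rownames(cells) <- NULL
  }
  structure(list(scheme = scheme, cells = cells,
                 labels = c(label_a, label_b),
                 coverages = c(coverage_a, coverage_b), join = join),
            class = "joint_spectrum")
}

#' @export
print.joint_spectrum <- function(x, ...) {
  cat(sprintf(
    "joint k-mer spectrum (%s vs %s, %s join): %s k-mers in %d occupied cells\n",
    x$labels[1], x$labels[2], x$join,
    format(sum(x$cells$count), big.mark = ","), nrow(x$cells)))
  invisible(x)
}

#' Dense matrix view of a joint spectrum
#'
#' @param x a `joint_spectrum`.
#' @param ... unused.
#' @return A numeric matrix; rows are sample A's bins, columns sample B's,
#'   with dimnames giving bin indices ("absent" for the reserved class).
#' @export
as.matrix.joint_spectrum <- function(x, ...) {
  if (!nrow(x$cells)) return(matrix(numeric(), 0, 0))
  ra <- sort(unique(x$cells$bin_a))
  rb <- sort(unique(x$cells$bin_b))
  m <- matrix(0, length(ra), length(rb),
              dimnames = list(ifelse(ra == ABSENT_BIN, "absent", ra),
                              ifelse(rb == ABSENT_BIN, "absent", rb)))
  m[cbind(match(x$cells$bin_a, ra), match(x$cells$bin_b, rb))] <- x$cells$count
  m
}

#' Marginal binned spectra of a joint spectrum
#'
#' Sums a joint spectrum over one axis at a time, dropping each axis's own
#' absent class, and returns the two implied binned spectra. For an
#' outer-join spectrum these reproduce exactly what [scale_and_bin()] gives
#' for each sample's dump, which makes this a consistency check on the join.
#'
#' @param j a `joint_spectrum`.
#' @return A list of two `binned_spectrum` objects named by sample label.
#' @export
joint_marginals <- function(j) {
  stopifnot(inherits(j, "joint_spectrum"))
  marg <- function(bins) {
    keep <- bins != ABSENT_BIN
    if (!any(keep)) return(list(bin = integer(), count = numeric()))
    agg <- tapply(j$cells$count[keep], bins[keep], sum)
    list(bin = as.integer(names(agg)), count = as.numeric(agg))
  }
  ma <- marg(j$cells$bin_a)
  mb <- marg(j$cells$bin_b)
  out <- list(binned_spectrum(ma$bin, ma$count, j$scheme, j$coverages[1]),
              binned_spectrum(mb$bin, mb$count, j$scheme, j$coverages[2]))
  names(out) <- j$labels
  out
}

#' Sample distance matrix from binned spectra
#'
#' Converts per-bin k-mer count differences into pairwise distances over a
#' cohort, for clustering or phylogeny-style analyses. `"manhattan"` is the
#' sum over bins of absolute count differences. `"gower"` is Gower's
#' coefficient restricted to quantitative variables: the mean over bins of
#' absolute differences divided by the across-cohort range of that bin's
#' counts (bins with zero range are skipped), so distances lie in [0, 1].
#' Bins occupied in at least one sample participate; a bin missing from a
#' sample counts as 0 k-mers there.
#'
#' @param samples list (optionally named) of `binned_spectrum` objects
#'   sharing one bin scheme; length >= 2.
#' @param metric `"manhattan"` or `"gower"`.
#' @return A symmetric numeric matrix with zero diagonal and sample labels
#'   as dimnames.
#' @export
distance_matrix <- function(samples, metric = c("manhattan", "gower")) {
  metric <- match.arg(metric)
  if (length(samples) < 2) stop("at least two samples are required")
  lapply(samples, function(s) stopifnot(inherits(s, "binned_spectrum")))
  scheme <- samples[[1]]$scheme
  for (s in samples[-1])
    if (!same_scheme(scheme, s$scheme))
      stop("all samples must share one bin scheme")
  labels <- names(samples)
  if (is.null(labels)) labels <- paste0("S", seq_along(samples))
  bins <- sort(unique(unlist(lapply(samples, `[[`, "bin"))))
  counts <- vapply(samples, function(s) {
    v <- numeric(length(bins)); v[match(s$bin, bins)] <- s$count; v
  }, numeric(length(bins)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(bins))
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  rng <- apply(counts, 1, function(r) diff(range(r)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ad <- abs(counts[, i] - counts[, j])
    d[i, j] <- d[j, i] <- switch(metric,
      manhattan = sum(ad),
      gower = if (any(rng > 0)) mean(ad[rng > 0] / rng[rng > 0]) else 0)
  }
  d
}
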