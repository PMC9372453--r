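#' Specification of a synthetic diploid genome
#'
#' Parameters for [simulate_genome()]. The emitted genome is a diploid with
#' two haplotypes differing by i.i.d. substitutions at the heterozygosity
#' rate, a single-copy backbone, a dispersed TE family with per-copy
#' divergence, a tandem satellite array, a tandem high-copy rDNA-like
#' block, and an unlinked organellar contaminant sequenced at elevated
#' depth. Defaults describe a desk-scale genome whose spectrum shows the
#' features the analysis relies on: a monoploid and a diploid peak, a
#' multi-thousand-copy tandem repeat, and an organellar peak well above the
#' nuclear copy numbers.
#'
#' @param unique_len bp of single-copy backbone per haplotype.
#' @param heterozygosity per-site substitution probability between the two
#'   haplotypes, in [0, 1).
#' @param satellite `c(unit_len, copies)`: tandem satellite monomer length
#'   (default 145 nt) and array copies per haplotype.
#' @param te `c(unit_len, copies, divergence)`: dispersed element length,
#'   copy count, and per-copy divergence from the family consensus.
#' @param rdna `c(unit_len, copies)`: tandem rDNA-like unit and copy count.
#' @param organelle `c(len, depth)`: organellar contaminant length and its
#'   sequencing-depth multiplier relative to one nuclear haplotype.
#' @param seed integer seed; the same spec yields byte-identical genomes.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(unique_len = 1e6, heterozygosity = 0.005,
                        satellite = c(unit_len = 145, copies = 3000),
                        te = c(unit_len = 4000, copies = 60,
                               divergence = 0.02),
                        rdna = c(unit_len = 2000, copies = 150),
                        organelle = c(len = 50000, depth = 20),
                        seed = 1L) {
  spec <- list(unique_len = as.numeric(unique_len),
               heterozygosity = as.numeric(heterozygosity),
               satellite = c(unit_len = unname(satellite[1]),
                             copies = unname(satellite[2])),
               te = c(unit_len = unname(te[1]), copies = unname(te[2]),
                      divergence = unname(te[3])),
               rdna = c(unit_len = unname(rdna[1]),
                        copies = unname(rdna[2])),
               organelle = c(len = unname(organelle[1]),
                             depth = unname(organelle[2])),
               seed = as.integer(seed))
  lens <- c(spec$unique_len, spec$satellite["unit_len"], spec$te["unit_len"],
            spec$rdna["unit_len"], spec$organelle["len"])
  if (any(lens <= 31)) stop("all unit lengths must exceed 31 bp (max k)")
  if (spec$heterozygosity < 0 || spec$heterozygosity >= 1)
    stop("heterozygosity must be in [0, 1)")
  if (spec$te["divergence"] < 0 || spec$te["divergence"] >= 1)
    stop("TE divergence must be in [0, 1)")
  if (any(c(spec$satellite["copies"], spec$te["copies"],
            spec$rdna["copies"]) < 0))
    stop("copy numbers must be >= 0")
  structure(spec, class = "genome_spec")
}

#' Specification of a synthetic shotgun sequencing run
#'
#' @param coverage target base coverage per haplotype (> 0).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability, in [0, 0.1].
#' @param paired emit read pairs from opposite fragment ends (pairing is
#'   cosmetic for k-mer counting; default single-end).
#' @param seed integer seed.
#' @return An object of class `read_spec`.
#' @export
read_spec <- function(coverage = 30, read_length = 150L, error_rate = 0.005,
                      paired = FALSE, seed = 1L) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  structure(list(coverage = coverage, read_length = as.integer(read_length),
                 error_rate = error_rate, paired = isTRUE(paired),
                 seed = as.integer(seed)),
            class = "read_spec")
}

#' Expected k-mer coverage of the monoploid peak
#'
#' Converts base coverage to the expected multiplicity of the monoploid
#' k-mer peak: each read of length L yields L - k + 1 windows, and a window
#' survives error-free with probability (1 - e)^k, so
#' `coverage * (L - k + 1) / L * (1 - e)^k`.
#'
#' @param spec a [read_spec()].
#' @param k k-mer length.
#' @return Expected monoploid peak multiplicity.
#' @export
expected_kmer_coverage <- function(spec, k = 21L) {
  stopifnot(inherits(spec, "read_spec"))
  spec$coverage * (spec$read_length - k + 1) / spec$read_length *
    (1 - spec$error_rate)^k
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_sequences <- function(x, rate) {
  if (rate <= 0) return(x)
  cpp_apply_substitutions(x, rate)
}

# assemble a haplotype-part list into genome structures
parts_to_genome <- function(parts, spec, organelle, k) {
  seq_a <- vapply(parts, `[[`, "", "a")
  seq_b <- vapply(parts, `[[`, "", "b")
  fam <- vapply(parts, `[[`, "", "family")
  len <- nchar(seq_a)
  end <- cumsum(len)
  segments <- data.frame(family = fam, start = c(1, head(end, -1) + 1),
                         end = end, stringsAsFactors = FALSE)
  hap_a <- paste(seq_a, collapse = "")
  hap_b <- paste(seq_b, collapse = "")
  fam_levels <- c("unique", "TE", "satellite", "rDNA")
  fam_levels <- fam_levels[fam_levels %in% fam]
  fam_tab <- do.call(rbind, lapply(fam_levels, function(f) {
    sel <- fam == f
    distinct <- length(count_reference_kmers(c(seq_a[sel], seq_b[sel]),
                                             k = k)$kmer)
    unit <- switch(f, unique = spec$unique_len,
                   TE = spec$te[["unit_len"]],
                   satellite = spec$satellite[["unit_len"]],
                   rDNA = spec$rdna[["unit_len"]])
    copies <- switch(f, unique = 1,
                     TE = sum(sel),
                     satellite = sum(nchar(seq_a[sel])) /
                       spec$satellite[["unit_len"]],
                     rDNA = sum(nchar(seq_a[sel])) / spec$rdna[["unit_len"]])
    data.frame(family = f, unit_len = unit, copies = copies,
               bp_1c = sum(nchar(seq_a[sel])), distinct_kmers = distinct,
               stringsAsFactors = FALSE)
  }))
  truth <- list(size_1c = nchar(hap_a),
                size_2c = nchar(hap_a) + nchar(hap_b),
                k = as.integer(k), families = fam_tab)
  structure(list(haplotypes = c(A = hap_a, B = hap_b),
                 organelle = organelle, spec = spec, parts = parts,
                 segments = segments, truth = truth),
            class = "sim_genome")
}

#' Simulate a diploid genome with known repeat architecture
#'
#' Builds haplotype A from a random single-copy backbone with diverged TE
#' copies inserted at random positions, followed by a tandem satellite
#' array and a tandem rDNA-like block; haplotype B is haplotype A with
#' i.i.d. substitutions at the heterozygosity rate (substitution-only, so
#' coordinates are shared). An independent organellar contaminant sequence
#' is emitted alongside. The returned truth table records exact 1C/2C
#' sizes and, per repeat family, unit length, copy number, and the number
#' of distinct canonical k-mers in the family's emitted sequence across
#' both haplotypes.
#'
#' @param spec a [genome_spec()].
#' @param k k-mer length used for the truth table's distinct-k-mer counts.
#' @return An object of class `sim_genome`: list with `haplotypes` (named
#'   character vector A/B), `organelle`, `spec`, `segments` (family
#'   coordinates, valid for both haplotypes), `consensus` sequences per
#'   repeat family, and `truth`.
#' @export
simulate_genome <- function(spec, k = 21L) {
  stopifnot(inherits(spec, "genome_spec"))
  k <- check_k(k)
  with_seed(spec$seed, {
    te_n <- spec$te[["copies"]]
    te_cons <- random_dna(spec$te[["unit_len"]])
    sat_mono <- random_dna(spec$satellite[["unit_len"]])
    rdna_unit <- random_dna(spec$rdna[["unit_len"]])
    backbone <- random_dna(spec$unique_len)
    # split the backbone at TE insertion points
    cuts <- if (te_n > 0)
      sort(sample(spec$unique_len - 1, min(te_n, spec$unique_len - 1)))
    else integer()
    bounds <- c(0, cuts, spec$unique_len)
    uniq_parts <- substring(backbone, head(bounds, -1) + 1, bounds[-1])
    te_copies <- if (te_n > 0)
      mutate_sequences(rep(te_cons, te_n), spec$te[["divergence"]])
    else character()
    ord_a <- character(0)
    fams <- character(0)
    for (i in seq_along(uniq_parts)) {
      ord_a <- c(ord_a, uniq_parts[i])
      fams <- c(fams, "unique")
      if (i <= length(te_copies)) {
        ord_a <- c(ord_a, te_copies[i])
        fams <- c(fams, "TE")
      }
    }
    if (spec$satellite[["copies"]] > 0) {
      ord_a <- c(ord_a, strrep(sat_mono, spec$satellite[["copies"]]))
      fams <- c(fams, "satellite")
    }
    if (spec$rdna[["copies"]] > 0) {
      ord_a <- c(ord_a, strrep(rdna_unit, spec$rdna[["copies"]]))
      fams <- c(fams, "rDNA")
    }
    ord_b <- mutate_sequences(ord_a, spec$heterozygosity)
    parts <- Map(function(f, a, b) list(family = f, a = a, b = b),
                 fams, ord_a, ord_b)
    names(parts) <- NULL
    organelle <- random_dna(spec$organelle[["len"]])
    g <- parts_to_genome(parts, spec, organelle, k)
    g$consensus <- c(TE = te_cons, satellite = sat_mono, rDNA = rdna_unit)
    g
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(
    "simulated diploid genome: 1C = %s bp (2C = %s bp), organelle %s bp\n",
    format(x$truth$size_1c, big.mark = ","),
    format(x$truth$size_2c, big.mark = ","),
    format(nchar(x$organelle), big.mark = ",")))
  print(x$truth$families, row.names = FALSE)
  invisible(x)
}

#' Simulate shotgun reads from a synthetic genome
#'
#' Draws reads with uniform start positions from both haplotypes at the
#' target per-haplotype coverage and from the organellar contaminant at
#' `coverage * depth` (its relative-depth multiplier), flips each read to
#' the reverse strand with probability 1/2, and applies per-base
#' substitution errors. With `paired = TRUE` reads are emitted as /1, /2
#' mates from the two ends of fragments of length `2 * read_length + 100`.
#'
#' @param genome a `sim_genome` (or any list with `haplotypes` and
#'   optionally `organelle` character elements).
#' @param spec a [read_spec()].
#' @return Named character vector of reads. Identical spec and genome give
#'   byte-identical output.
#' @export
simulate_reads <- function(genome, spec) {
  stopifnot(inherits(spec, "read_spec"))
  rl <- spec$read_length
  sources <- c(as.list(genome$haplotypes),
               if (!is.null(genome$organelle) &&
                   nchar(genome$organelle) > 0)
                 list(organelle = genome$organelle))
  depth <- c(rep(spec$coverage, length(genome$haplotypes)),
             if (length(sources) > length(genome$haplotypes))
               spec$coverage * genome$spec$organelle[["depth"]])
  with_seed(spec$seed, {
    frag_len <- if (spec$paired) 2L * rl + 100L else rl
    reads <- unlist(lapply(seq_along(sources), function(i) {
      s <- sources[[i]]
      len <- nchar(s)
      if (len < frag_len)
        stop("read/fragment length (", frag_len,
             ") exceeds sequence length (", len, ")")
      n_frag <- round(depth[i] * len / (if (spec$paired) 2 * rl else rl))
      if (n_frag < 1) return(character())
      starts <- sample.int(len - frag_len + 1L, n_frag, replace = TRUE)
      if (spec$paired) {
        r1 <- substring(s, starts, starts + rl - 1L)
        r2 <- revcomp(substring(s, starts + frag_len - rl,
                                starts + frag_len - 1L))
        out <- c(r1, r2)
        names(out) <- c(paste0(names(sources)[i], "_", seq_len(n_frag),
                               "/1"),
                        paste0(names(sources)[i], "_", seq_len(n_frag),
                               "/2"))
      } else {
        out <- substring(s, starts, starts + rl - 1L)
        names(out) <- paste0(names(sources)[i], "_", seq_len(n_frag))
      }
      out
    }))
    if (!length(reads)) return(character())
    flip <- runif(length(reads)) < 0.5
    reads[flip] <- revcomp(reads[flip])
    nm <- names(reads)
    reads <- mutate_sequences(reads, spec$error_rate)
    names(reads) <- nm
    reads
  })
}

revcomp <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a second genome by editing whole repeat copies
#'
#' Creates the two-sample scenario where one genome carries additional (or
#' fewer) copies of specific repeat families: the second genome is the
#' first with whole copies added to or removed from the family blocks, on
#' both haplotypes at matching positions (added copies are identical
#' between haplotypes, i.e. homozygous). Tandem families (`satellite`,
#' `rDNA`) grow or shrink at the array end; added `TE` copies are appended
#' as new diverged insertions after the last TE segment.
#'
#' @param spec a [genome_spec()] for the base genome.
#' @param delta named numeric vector of copy-number edits, names among
#'   `"satellite"`, `"rDNA"`, `"TE"` (e.g. `c(satellite = -500)`). Removing
#'   more copies than exist is an error.
#' @param k k-mer length for the truth tables.
#' @return List with `a` and `b` (`sim_genome` objects; `b` carries the
#'   edits), `delta`, and `planted_diff_2c_bp`, the exact planted 2C size
#'   difference `b - a` in bp.
#' @export
make_pair <- function(spec, delta = numeric(), k = 21L) {
  g_a <- simulate_genome(spec, k = k)
  if (length(delta)) {
    bad <- setdiff(names(delta), c("satellite", "rDNA", "TE"))
    if (length(bad) || is.null(names(delta)))
      stop("delta names must be among satellite, rDNA, TE")
  }
  parts <- g_a$parts
  fams <- vapply(parts, `[[`, "", "family")
  with_seed(spec$seed + 1000L, {
    for (f in names(delta)) {
      d <- delta[[f]]
      if (d == 0) next
      unit <- switch(f, satellite = spec$satellite[["unit_len"]],
                     rDNA = spec$rdna[["unit_len"]],
                     TE = spec$te[["unit_len"]])
      if (f %in% c("satellite", "rDNA")) {
        i <- which(fams == f)
        if (length(i) != 1) stop("family ", f, " not present in the genome")
        have <- nchar(parts[[i]]$a) / unit
        if (d < 0 && -d > have)
          stop("cannot remove ", -d, " copies of ", f, "; only ", have,
               " exist")
        mono <- substr(parts[[i]]$a, 1, unit)
        if (d > 0) {
          add <- strrep(mono, d)
          parts[[i]]$a <- paste0(parts[[i]]$a, add)
          parts[[i]]$b <- paste0(parts[[i]]$b, add)
        } else {
          keep <- nchar(parts[[i]]$a) + d * unit
          parts[[i]]$a <- substr(parts[[i]]$a, 1, keep)
          parts[[i]]$b <- substr(parts[[i]]$b, 1, keep)
          if (keep == 0) { parts[[i]] <- NULL; fams <- fams[-i] }
        }
      } else {  # TE
        i_te <- which(fams == "TE")
        if (d < 0) {
          if (-d > length(i_te))
            stop("cannot remove ", -d, " TE copies; only ", length(i_te),
                 " exist")
          drop <- tail(i_te, -d)
          parts <- parts[-drop]
          fams <- fams[-drop]
        } else {
          new_copies <- mutate_sequences(
            rep(g_a$consensus[["TE"]], d), spec$te[["divergence"]])
          at <- if (length(i_te)) max(i_te) else
            max(which(fams == "unique"))
          new_parts <- lapply(new_copies, function(s)
            list(family = "TE", a = s, b = s))
          parts <- append(parts, new_parts, after = at)
          fams <- c(fams[seq_len(at)], rep("TE", d),
                    fams[-seq_len(at)])
        }
      }
    }
  })
  g_b <- parts_to_genome(parts, spec, g_a$organelle, k)
  g_b$consensus <- g_a$consensus
  list(a = g_a, b = g_b, delta = delta,
       planted_diff_2c_bp = g_b$truth$size_2c - g_a$truth$size_2c)
}

#' Write a simulated genome (and optionally reads) to standard files
#'
#' Emits `<prefix>_hapA.fasta`, `<prefix>_hapB.fasta`,
#' `<prefix>_organelle.fasta` and `<prefix>_truth.tsv`; when `reads` is
#' given, also `<prefix>_reads.fastq`.
#'
#' @param genome a `sim_genome`.
#' @param prefix output path prefix.
#' @param reads optional read vector from [simulate_reads()].
#' @return Character vector of the files written, invisibly.
#' @export
write_sim_genome <- function(genome, prefix, reads = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  files <- c(hapA = paste0(prefix, "_hapA.fasta"),
             hapB = paste0(prefix, "_hapB.fasta"),
             organelle = paste0(prefix, "_organelle.fasta"),
             truth = paste0(prefix, "_truth.tsv"))
  write_fasta(c(hapA = genome$haplotypes[["A"]]), files["hapA"])
  write_fasta(c(hapB = genome$haplotypes[["B"]]), files["hapB"])
  write_fasta(c(organelle = genome$organelle), files["organelle"])
  tr <- genome$truth$families
  tr$size_1c <- genome$truth$size_1c
  tr$size_2c <- genome$truth$size_2c
  write.table(tr, files["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(reads)) {
    files <- c(files, reads = paste0(prefix, "_reads.fastq"))
    write_fastq(reads, files["reads"])
  }
  invisible(files)
}
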