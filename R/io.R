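#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()`; the format is taken
#' from the file extension (`.fq`/`.fastq`, optionally `.gz`, selects FASTQ)
#' unless given. FASTQ qualities are ignored.
#'
#' @param path file path (plain or gzip-compressed).
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return A named character vector of sequences.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param sequences named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly. FASTQ records get uniform placeholder
#'   qualities ("I"), since downstream k-mer counting is quality-blind.
#' @rdname read_sequences
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_sequences
#' @export
write_fastq <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(x))) names(x) <- paste0("read", seq_along(x))
  quals <- Biostrings::BStringSet(vapply(width_chr(sequences), function(w)
    strrep("I", w), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

width_chr <- function(x) nchar(as.character(x))

#' k-mer dump files
#'
#' Two-column text files, one record per line, `KMER<TAB>COUNT`, sorted
#' ascending by k-mer, no header -- the text-dump dialect of the standard
#' k-mer counters, so dumps produced by external tools can be read directly.
#'
#' @param path file path.
#' @param min_count threshold to record on the object (the file itself does
#'   not carry it).
#' @return `read_kmer_dump()` a [kmer_dump()]; `write_kmer_dump()` `path`,
#'   invisibly. A write followed by a read reproduces the dump exactly.
#' @export
read_kmer_dump <- function(path, min_count = 1L) {
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE,
               colClasses = c("character", "numeric"),
               col.names = c("kmer", "count"), quote = ""),
    error = function(e) data.frame(kmer = character(), count = numeric()))
  kmer_dump(tab$kmer, tab$count, k = if (nrow(tab)) NULL else 21L,
            min_count = min_count)
}

#' @rdname read_kmer_dump
#' @param x a [kmer_dump()] (write) .
#' @export
write_kmer_dump <- function(x, path) {
  stopifnot(inherits(x, "kmer_dump"))
  writeLines(if (length(x$kmer))
    paste0(x$kmer, "\t", format(x$count, scientific = FALSE, trim = TRUE))
    else character(), path)
  invisible(path)
}

#' k-mer histogram (spectrum) files
#'
#' Two-column text files `MULTIPLICITY<TAB>COUNT`, ascending multiplicity,
#' no header, as written by the standard counters' histogram commands.
#' Zero-count rows are accepted on read and omitted on write.
#'
#' @param path file path.
#' @param k k-mer length to record on the object.
#' @return `read_spectrum()` a [kmer_spectrum()]; `write_spectrum()` `path`,
#'   invisibly.
#' @export
read_spectrum <- function(path, k = 21L) {
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE,
               colClasses = c("numeric", "numeric"),
               col.names = c("multiplicity", "count")),
    error = function(e) data.frame(multiplicity = numeric(),
                                   count = numeric()))
  keep <- tab$count > 0
  kmer_spectrum(tab$multiplicity[keep], tab$count[keep], k = k)
}

#' @rdname read_spectrum
#' @param x a [kmer_spectrum()].
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "kmer_spectrum"))
  keep <- x$count > 0
  writeLines(paste0(format(x$multiplicity[keep], scientific = FALSE,
                           trim = TRUE), "\t",
                    format(x$count[keep], scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Binned-spectrum TSV files
#'
#' Self-describing per-bin tables with explicit numeric bounds: columns
#' `bin_index`, `lower_bound`, `upper_bound`, `representative_cn`,
#' `kmer_count`, with a header line.
#'
#' @param b a `binned_spectrum`.
#' @param path file path.
#' @param scheme,coverage used by `read_binned_spectrum()` to rebuild the
#'   object (the file stores bounds, not the scheme parameters).
#' @return `write_binned_spectrum()` `path` invisibly;
#'   `read_binned_spectrum()` a `binned_spectrum`.
#' @export
write_binned_spectrum <- function(b, path) {
  stopifnot(inherits(b, "binned_spectrum"))
  tab <- data.frame(bin_index = b$bin,
                    lower_bound = bin_lower(b$bin, b$scheme),
                    upper_bound = bin_upper(b$bin, b$scheme),
                    representative_cn = bin_representative(b$bin, b$scheme),
                    kmer_count = b$count)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binned_spectrum
#' @export
read_binned_spectrum <- function(path, scheme = bin_scheme(),
                                 coverage = NA_real_) {
  tab <- read.table(path, sep = "\t", header = TRUE)
  binned_spectrum(tab$bin_index, tab$kmer_count, scheme = scheme,
                  coverage = coverage)
}

#' Difference-graph TSV files
#'
#' Columns `bin_index`, `lower`, `upper`, `representative_cn`, `count_diff`,
#' `bp_diff`, `cumulative_bp`, with a header line.
#'
#' @param d a `diff_graph`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_diff_graph <- function(d, path) {
  stopifnot(inherits(d, "diff_graph"))
  tab <- d$table
  names(tab) <- c("bin_index", "lower", "upper", "representative_cn",
                  "count_diff", "bp_diff", "cumulative_bp")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Joint-spectrum files
#'
#' The sparse form is a three-column table (`count`, `bin_a`, `bin_b`) with
#' a header; the reserved absent class is encoded as -1. `matrix_path`
#' optionally also writes the dense matrix as TSV with bin labels.
#'
#' @param j a `joint_spectrum`.
#' @param path sparse three-column output path.
#' @param matrix_path optional dense-matrix output path.
#' @return `write_joint_spectrum()` `path` invisibly;
#'   `read_joint_spectrum()` a `joint_spectrum` (scheme, labels and
#'   coverages must be re-supplied; the file stores only the cells).
#' @export
write_joint_spectrum <- function(j, path, matrix_path = NULL) {
  stopifnot(inherits(j, "joint_spectrum"))
  tab <- data.frame(count = j$cells$count, bin_a = j$cells$bin_a,
                    bin_b = j$cells$bin_b)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path)) {
    m <- as.matrix(j)
    write.table(data.frame(bin_a = rownames(m), m, check.names = FALSE),
                matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_joint_spectrum
#' @inheritParams joint_spectrum
#' @export
read_joint_spectrum <- function(path, scheme = bin_scheme(), coverage_a = NA,
                                coverage_b = NA, label_a = "A",
                                label_b = "B", join = "outer") {
  tab <- read.table(path, sep = "\t", header = TRUE)
  cells <- data.frame(bin_a = as.integer(tab$bin_a),
                      bin_b = as.integer(tab$bin_b),
                      count = as.numeric(tab$count))
  cells <- cells[order(cells$bin_a, cells$bin_b), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(scheme = scheme, cells = cells,
                 labels = c(label_a, label_b),
                 coverages = c(coverage_a, coverage_b), join = join),
            class = "joint_spectrum")
}

#' Distance-matrix files
#'
#' Square TSV with a header row and a leading label column; `format =
#' "phylip"` writes the square PHYLIP dialect (sample count on the first
#' line) instead.
#'
#' @param d a symmetric matrix from [distance_matrix()].
#' @param path file path.
#' @param format `"tsv"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(data.frame(sample = rownames(d), d, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(format(nrow(d)),
               vapply(seq_len(nrow(d)), function(i)
                 paste(c(rownames(d)[i], format(d[i, ], digits = 10)),
                       collapse = "\t"), character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Read a repeat-family k-mer database from FASTA input
#'
#' Accepts either a directory of FASTA files (one family per file, filename
#' without extension = family label) or a single multi-FASTA whose headers
#' carry the family label as a prefix (`label#anything` or `label` alone).
#' Family-unique k-mers are then extracted with [unique_to_group()].
#'
#' @param path directory or multi-FASTA file.
#' @param k k-mer length.
#' @param sep header prefix separator for the multi-FASTA form.
#' @return A `repeat_kmer_db`.
#' @export
read_repeat_db <- function(path, k = 21L, sep = "#") {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files found in ", path)
    groups <- lapply(files, read_sequences)
    names(groups) <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(files))
  } else {
    seqs <- read_sequences(path)
    labels <- vapply(strsplit(names(seqs), sep, fixed = TRUE), `[`, "",
                     1)
    labels <- sub("\\s.*$", "", labels)
    groups <- split(unname(seqs), labels)
  }
  unique_to_group(groups, k = k)
}
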