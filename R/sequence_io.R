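#' @importFrom Biostrings readBStringSet readDNAStringSet DNAString DNAStringSet
#'   reverseComplement matchPattern neditStartingAt writeXStringSet
#' @importFrom IRanges IRanges start end width reduce findOverlaps
#' @importFrom GenomicRanges GRanges seqnames strand
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and converts T to U. The package stores every small-RNA
#' sequence in RNA form; DNA-form references (as printed in most genome
#' resources) are normalized on input so that comparisons are alphabet-safe.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over A/C/G/U (plus any non-standard characters,
#'   which downstream validators reject).
#' @export
normalize_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Convert an RNA-form sequence to DNA form (U to T)
#' @param x character vector.
#' @return character vector over A/C/G/T.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

is_valid_rna <- function(x) {
  !grepl("[^ACGU]", x)
}

#' Collapse raw small-RNA reads into a unique-sequence count table
#'
#' Identical sequences are merged with summed counts; reads outside the
#' configured length window are discarded. Reads containing non-nucleotide
#' characters are rejected with a warning rather than aborting the run.
#' The default window of 18-30 nt is the analysis range of typical plant
#' small-RNA libraries; `length_preset = "gel"` switches to the 16-30 nt
#' gel-purification range.
#'
#' @param records character vector of raw read sequences (T or U form).
#' @param label single string naming the library (e.g. "seed").
#' @param min_len,max_len integer length bounds in nt (inclusive).
#' @param length_preset either "analysis" (18-30) or "gel" (16-30); ignored
#'   when `min_len`/`max_len` are given explicitly.
#' @return a `ReadLibrary` object: list with `label`, `reads` (data.frame of
#'   `sequence`, `length`, `count`, sorted by sequence), `total_reads`,
#'   `unique_reads`.
#' @export
collapse_reads <- function(records, label, min_len = NULL, max_len = NULL,
                           length_preset = c("analysis", "gel")) {
  length_preset <- match.arg(length_preset)
  bounds <- if (length_preset == "gel") c(16L, 30L) else c(18L, 30L)
  if (is.null(min_len)) min_len <- bounds[1]
  if (is.null(max_len)) max_len <- bounds[2]
  stopifnot(is.character(label), length(label) == 1L, min_len <= max_len)

  records <- normalize_rna(records)
  bad <- !is_valid_rna(records)
  if (any(bad)) {
    warning(sprintf("rejected %d read(s) with non-nucleotide characters", sum(bad)))
    records <- records[!bad]
  }
  len <- nchar(records)
  records <- records[len >= min_len & len <= max_len]

  if (length(records) == 0L) {
    reads <- data.frame(sequence = character(), length = integer(),
                        count = integer(), stringsAsFactors = FALSE)
  } else {
    tab <- table(records)
    reads <- data.frame(sequence = names(tab),
                        length = nchar(names(tab)),
                        count = as.integer(tab),
                        stringsAsFactors = FALSE)
    reads <- reads[order(reads$sequence), , drop = FALSE]
    rownames(reads) <- NULL
  }
  new_read_library(label, reads)
}

new_read_library <- function(label, reads) {
  structure(
    list(label = label,
         reads = reads,
         total_reads = sum(reads$count),
         unique_reads = nrow(reads)),
    class = "ReadLibrary"
  )
}

#' @export
print.ReadLibrary <- function(x, ...) {
  cat(sprintf("ReadLibrary '%s': %d unique reads, %d total reads\n",
              x$label, x$unique_reads, x$total_reads))
  invisible(x)
}

#' Build a ReadLibrary directly from a sequence/count table
#'
#' @param sequences character vector of unique read sequences.
#' @param counts integer vector of per-sequence counts (same length).
#' @param label library label.
#' @return a `ReadLibrary`.
#' @export
read_library <- function(sequences, counts, label) {
  stopifnot(length(sequences) == length(counts), all(counts >= 0))
  sequences <- normalize_rna(sequences)
  if (anyDuplicated(sequences)) {
    counts <- as.integer(tapply(counts, sequences, sum))
    sequences <- sort(unique(sequences))
  }
  stopifnot(all(is_valid_rna(sequences)))
  reads <- data.frame(sequence = sequences, length = nchar(sequences),
                      count = as.integer(counts), stringsAsFactors = FALSE)
  reads <- reads[order(reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  new_read_library(label, reads)
}

#' Length profile of a read library
#'
#' Computes, per read length, the fraction of total reads and the fraction of
#' unique sequences of that length. Seed-type plant libraries typically peak
#' at 24 nt (the heterochromatic siRNA class) while leaf libraries peak at
#' 21 nt (the canonical miRNA length).
#'
#' @param lib a `ReadLibrary`.
#' @return data.frame with columns `length`, `total_fraction`,
#'   `unique_fraction`, sorted by length.
#' @export
length_distribution <- function(lib) {
  stopifnot(inherits(lib, "ReadLibrary"))
  if (lib$unique_reads == 0L)
    stop("length_distribution: empty library, fractions undefined")
  tot <- tapply(lib$reads$count, lib$reads$length, sum)
  uni <- table(lib$reads$length)
  data.frame(length = as.integer(names(tot)),
             total_fraction = as.numeric(tot) / lib$total_reads,
             unique_fraction = as.integer(uni) / lib$unique_reads,
             row.names = NULL)
}

## ---- file formats -----------------------------------------------------

#' Read a FASTA file
#' @param path file path.
#' @param rna normalize sequences to the RNA alphabet (default TRUE).
#' @return named character vector (names = record ids up to first whitespace).
#' @export
read_fasta <- function(path, rna = TRUE) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (rna) seqs <- normalize_rna(seqs)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' Quality strings are validated for length agreement with the read and then
#' discarded; the pipeline works on collapsed counts, not per-base qualities.
#'
#' @param path file path.
#' @param rna normalize to RNA alphabet.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path, rna = TRUE) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("read_fastq: %s: truncated record near line %d",
                 path, length(lines)))
  i <- seq(1L, length(lines), by = 4L)
  if (any(substr(lines[i], 1L, 1L) != "@"))
    stop(sprintf("read_fastq: %s: malformed header at line %d",
                 path, i[which(substr(lines[i], 1L, 1L) != "@")[1]]))
  seqs <- lines[i + 1L]
  qual <- lines[i + 3L]
  bad <- nchar(seqs) != nchar(qual)
  if (any(bad))
    stop(sprintf("read_fastq: %s: quality/sequence length mismatch at line %d",
                 path, i[which(bad)[1]] + 3L))
  if (rna) seqs <- normalize_rna(seqs)
  seqs
}

#' Read a collapsed FASTA read library (">id_x<count>" dialect)
#'
#' Headers of the form `>seq_<n>_x<count>` carry the read count of each
#' unique sequence.
#'
#' @param path file path.
#' @param label library label for the returned object.
#' @return a `ReadLibrary`.
#' @export
read_collapsed_fasta <- function(path, label) {
  seqs <- read_fasta(path, rna = TRUE)
  m <- regmatches(names(seqs), regexpr("_x([0-9]+)$", names(seqs)))
  if (length(m) != length(seqs))
    stop("read_collapsed_fasta: header(s) lack the _x<count> suffix")
  counts <- as.integer(sub("^_x", "", m))
  read_library(unname(seqs), counts, label)
}

#' Write a ReadLibrary as collapsed FASTA
#' @param lib a `ReadLibrary`.
#' @param path output path.
#' @export
write_collapsed_fasta <- function(lib, path) {
  stopifnot(inherits(lib, "ReadLibrary"))
  ids <- sprintf("seq_%d_x%d", seq_len(nrow(lib$reads)), lib$reads$count)
  seqs <- lib$reads$sequence
  names(seqs) <- ids
  write_fasta(seqs, path)
}

#' Read a GFF3 annotation file
#'
#' Thin wrapper over [rtracklayer::import.gff3]; intervals stay in the GFF3
#' 1-based closed convention used throughout the package.
#'
#' @param path file path.
#' @return a `GRanges` with at least a `type` metadata column.
#' @export
read_gff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Write tabular results as a TSV report
#'
#' UTF-8, tab-delimited, header row, no quoting, NA rendered as "NA".
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a genome from FASTA as a DNAStringSet
#' @param path file path.
#' @return `DNAStringSet` named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("read_genome: duplicate chromosome names")
  if (any(Biostrings::width(g) == 0L)) stop("read_genome: empty chromosome")
  g
}
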