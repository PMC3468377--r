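## Annotation-category classification of small RNA reads.
##
## Every unique read is assigned to exactly one category by a fixed
## precedence order. RNA classes (rRNA, tRNA, snRNA, snoRNA, siRNA) match by
## substring-or-equality against a reference set (degradation fragments of
## structural RNAs are substrings of the full-length molecule); known
## mature/star miRNAs match by exact full-length equality (they are defined
## molecules, and substring matching would conflate isomiRs); exon/intron
## assignment requires a genomic hit overlapping a feature interval.

DEFAULT_PRECEDENCE <- c("mature miRNA", "mature star", "rRNA", "tRNA",
                        "snRNA", "snoRNA", "siRNA", "exon", "intron",
                        "other sRNAs")

#' Bundle category references into an AnnotationSet
#'
#' @param references named list of character vectors of reference sequences;
#'   recognized names: `mature`, `star`, `rrna`, `trna`, `snrna`, `snorna`,
#'   `sirna`. Missing categories are treated as empty.
#' @param gene_models optional `GRanges` of gene models with a `type`
#'   metadata column containing `gene` and `exon` rows (GFF3 convention);
#'   intron intervals are derived as gene minus exon.
#' @param precedence character vector giving the assignment order; must end
#'   with "other sRNAs".
#' @return an `AnnotationSet` object.
#' @export
annotation_set <- function(references = list(), gene_models = NULL,
                           precedence = DEFAULT_PRECEDENCE) {
  stopifnot(precedence[length(precedence)] == "other sRNAs",
            !anyDuplicated(precedence))
  refs <- lapply(references, normalize_rna)
  feats <- if (!is.null(gene_models)) gene_features(gene_models) else NULL
  structure(list(references = refs, features = feats, precedence = precedence),
            class = "AnnotationSet")
}

## Split gene models into exon and intron GRanges.
gene_features <- function(gene_models) {
  stopifnot(methods::is(gene_models, "GRanges"))
  type <- as.character(gene_models$type)
  exons <- gene_models[type == "exon"]
  genes <- gene_models[type == "gene"]
  introns <- GenomicRanges::setdiff(
    GenomicRanges::reduce(genes, ignore.strand = TRUE),
    GenomicRanges::reduce(exons, ignore.strand = TRUE),
    ignore.strand = TRUE)
  list(exon = exons, intron = introns,
       gene = GenomicRanges::reduce(genes, ignore.strand = TRUE))
}

## Match reads (RNA form) against one reference category. Substring-or-equal
## on either strand of the reference; `exact` switches to full-length
## equality (mature/star categories).
match_reference <- function(sequences, refs, exact = FALSE) {
  if (length(refs) == 0L || length(sequences) == 0L)
    return(logical(length(sequences)))
  refs <- normalize_rna(refs)
  if (exact) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::RNAStringSet(refs)))
    return(sequences %in% c(refs, rc))
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAStringSet(refs)))
  subject <- paste(c(refs, rc), collapse = "NNNN")
  vapply(sequences, function(s) grepl(s, subject, fixed = TRUE), logical(1),
         USE.NAMES = FALSE)
}

#' Classify every read of a library into annotation categories
#'
#' @param lib a `ReadLibrary`.
#' @param ann an `AnnotationSet`.
#' @param genome_hits optional data.frame of genomic hits as returned by
#'   [map_reads()] (used for the exon/intron categories; reads without hits
#'   can never be exonic/intronic).
#' @return character vector of category labels, parallel to `lib$reads`.
#' @export
classify_reads <- function(lib, ann, genome_hits = NULL) {
  stopifnot(inherits(lib, "ReadLibrary"), inherits(ann, "AnnotationSet"))
  seqs <- lib$reads$sequence
  n <- length(seqs)
  assigned <- rep(NA_character_, n)

  ref_key <- c("mature miRNA" = "mature", "mature star" = "star",
               "rRNA" = "rrna", "tRNA" = "trna", "snRNA" = "snrna",
               "snoRNA" = "snorna", "siRNA" = "sirna")

  overlap_category <- function(feature_type) {
    hit_overlap <- logical(n)
    if (is.null(genome_hits) || is.null(ann$features) ||
        nrow(genome_hits) == 0L)
      return(hit_overlap)
    feats <- ann$features[[feature_type]]
    if (length(feats) == 0L) return(hit_overlap)
    gr <- GenomicRanges::GRanges(
      genome_hits$chrom,
      IRanges::IRanges(genome_hits$start, genome_hits$end))
    ov <- GenomicRanges::findOverlaps(gr, feats, minoverlap = 1L,
                                      ignore.strand = TRUE)
    hit_seqs <- unique(genome_hits$sequence[S4Vectors::queryHits(ov)])
    seqs %in% hit_seqs
  }

  for (cat in ann$precedence) {
    todo <- is.na(assigned)
    if (!any(todo)) break
    if (cat == "other sRNAs") {
      assigned[todo] <- cat
    } else if (cat %in% names(ref_key)) {
      refs <- ann$references[[ref_key[[cat]]]]
      hit <- match_reference(seqs[todo], refs,
                             exact = cat %in% c("mature miRNA", "mature star"))
      assigned[todo][hit] <- cat
    } else if (cat %in% c("exon", "intron")) {
      hit <- overlap_category(cat)
      assigned[todo][hit[todo]] <- cat
    } else {
      stop(sprintf("unknown category in precedence: %s", cat))
    }
  }
  assigned
}

#' Summarize a library into a category table
#'
#' Produces the per-category accounting of unique and total reads, with
#' fractions of the library totals. Every read lands in exactly one
#' category, so the rows sum to the library totals.
#'
#' @param lib a `ReadLibrary`.
#' @param ann an `AnnotationSet`.
#' @param genome_hits optional hits data.frame (see [classify_reads()]).
#' @return data.frame with columns `category`, `unique_reads`, `total_reads`,
#'   `unique_fraction`, `total_fraction`, one row per precedence category
#'   (including empty ones) plus a "Total" row.
#' @export
summarize_classification <- function(lib, ann, genome_hits = NULL) {
  if (lib$unique_reads == 0L) stop("summarize_classification: empty library")
  cls <- classify_reads(lib, ann, genome_hits)
  cats <- ann$precedence
  uni <- vapply(cats, function(cc) sum(cls == cc), integer(1))
  tot <- vapply(cats, function(cc) sum(lib$reads$count[cls == cc]), integer(1))
  out <- data.frame(category = c(cats, "Total"),
                    unique_reads = c(uni, lib$unique_reads),
                    total_reads = c(tot, lib$total_reads),
                    stringsAsFactors = FALSE)
  out$unique_fraction <- out$unique_reads / lib$unique_reads
  out$total_fraction <- out$total_reads / lib$total_reads
  rownames(out) <- NULL
  out
}
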