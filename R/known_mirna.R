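## Conserved (known) miRNA identification and quantification.
##
## A known miRNA is present in a library iff some read equals its mature
## sequence exactly, full length ("perfect match"); isomiRs shifted by even
## one nucleotide do not count. Abundances are normalized as reads per
## million of the library's total clean reads.

#' Identify conserved miRNAs by perfect match
#'
#' @param lib a `ReadLibrary`.
#' @param known data.frame with columns `name`, `mature` and optionally
#'   `star`, `precursor` (sequences, T or U form).
#' @return data.frame `name`, `mature`, `count`, `rpm` with one row per known
#'   miRNA detected (count > 0). Duplicate mature sequences under different
#'   names each receive the read's count, with a warning.
#' @export
identify_conserved <- function(lib, known) {
  stopifnot(inherits(lib, "ReadLibrary"),
            all(c("name", "mature") %in% names(known)))
  mature <- normalize_rna(known$mature)
  if (anyDuplicated(mature))
    warning("duplicate mature sequences under different names; counts assigned to all")
  idx <- match(mature, lib$reads$sequence)
  count <- ifelse(is.na(idx), 0L, lib$reads$count[idx])
  out <- data.frame(name = known$name, mature = mature,
                    count = as.integer(count), stringsAsFactors = FALSE)
  out <- out[out$count > 0L, , drop = FALSE]
  out$rpm <- rpm(out$count, lib$total_reads)
  rownames(out) <- NULL
  out
}

#' Reads-per-million normalization
#'
#' @param count read count(s).
#' @param library_total total clean reads of the library (> 0).
#' @return count / library_total * 1e6.
#' @export
rpm <- function(count, library_total) {
  if (any(library_total == 0)) stop("rpm: library_total must be > 0")
  count / library_total * 1e6
}

#' Compare conserved-miRNA results between two libraries
#'
#' Joins the two result tables on miRNA name and flags each miRNA as
#' specific to one library or shared; miRNAs absent from both are dropped.
#'
#' @param a,b results from [identify_conserved()] on two libraries; the two
#'   must derive from the same known reference (names are the join key).
#' @param epsilon pseudo-count added to both RPM values before computing the
#'   fold difference (default 0; with the default, fold is Inf/NaN for
#'   library-specific miRNAs).
#' @return data.frame `name`, `count_a`, `count_b`, `rpm_a`, `rpm_b`,
#'   `specificity` ("a-only", "b-only", "shared"), `fold_a_vs_b`.
#' @export
compare_libraries <- function(a, b, epsilon = 0) {
  nm <- sort(union(a$name, b$name))
  ia <- match(nm, a$name); ib <- match(nm, b$name)
  ca <- ifelse(is.na(ia), 0L, a$count[ia])
  cb <- ifelse(is.na(ib), 0L, b$count[ib])
  ra <- ifelse(is.na(ia), 0, a$rpm[ia])
  rb <- ifelse(is.na(ib), 0, b$rpm[ib])
  keep <- ca > 0L | cb > 0L
  spec <- ifelse(ca > 0L & cb == 0L, "a-only",
                 ifelse(cb > 0L & ca == 0L, "b-only", "shared"))
  data.frame(name = nm, count_a = ca, count_b = cb,
             rpm_a = ra, rpm_b = rb, specificity = spec,
             fold_a_vs_b = (ra + epsilon) / (rb + epsilon),
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

#' Mature versus star abundance of one known miRNA
#'
#' Occasionally the star strand of a duplex accumulates beyond the mature
#' strand; the returned flag marks those cases.
#'
#' @param known one-row data.frame (or list) with `mature` and optionally
#'   `star` and `precursor` sequences. When `star` is missing but a
#'   `precursor` is available, the star is derived from the folded precursor
#'   via [find_star()].
#' @param lib a `ReadLibrary`.
#' @return list with `mature_count`, `star_count` (NA when no star sequence
#'   is available or derivable) and `star_exceeds_mature` (NA when the star
#'   count is missing).
#' @export
star_abundance <- function(known, lib) {
  stopifnot(inherits(lib, "ReadLibrary"))
  mature <- normalize_rna(known$mature)
  star <- if (!is.null(known$star) && !is.na(known$star))
    normalize_rna(known$star) else NA_character_
  if (is.na(star) && !is.null(known$precursor) && !is.na(known$precursor)) {
    prec <- normalize_rna(known$precursor)
    cand <- hairpin_candidate(prec)
    if (!is.null(cand)) {
      pos <- regexpr(mature, prec, fixed = TRUE)
      if (pos > 0L) {
        st <- find_star(cand, c(pos, pos + nchar(mature) - 1L))
        if (!is.null(st)) star <- st$sequence
      }
    }
  }
  lookup <- function(s) {
    i <- match(s, lib$reads$sequence)
    if (is.na(i)) 0L else lib$reads$count[i]
  }
  mc <- lookup(mature)
  sc <- if (is.na(star)) NA_integer_ else lookup(star)
  list(mature_count = mc, star_count = sc,
       star_exceeds_mature = if (is.na(sc)) NA else sc > mc)
}
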