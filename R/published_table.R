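#' Load the bundled table of published novel maize miRNAs
#'
#' The package ships the printed summary table of 54 novel maize miRNAs
#' (mature sequence, length, per-library abundance, precursor genomic
#' context, cross-species conservation) from the seed/leaf small-RNA study
#' the pipeline re-implements. It serves as an in-package reference set for
#' family grouping, context tallies and nucleotide-composition summaries.
#'
#' @return data.frame with columns `mirna`, `sequence` (DNA form as
#'   printed), `length`, `abundance_seed`, `abundance_leaf`, `position`,
#'   `conservation`.
#' @export
published_novel_mirnas <- function() {
  path <- system.file("extdata", "novel_mirnas_published.tsv",
                      package = "srnapipe", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Summaries of a novel-miRNA table
#'
#' Computes the headline descriptive statistics of a novel-miRNA set: the
#' number of loci, the number of families under single-linkage grouping
#' (equal length, Hamming distance at most 1), the genomic-context tally
#' and the fraction of matures whose 5' nucleotide is U.
#'
#' @param tab data.frame with columns `sequence` and `position` (as returned
#'   by [published_novel_mirnas()], or a [discover()] result renamed
#'   accordingly).
#' @return list with `n_mirnas`, `n_families`, `position_tally` (named
#'   integer vector), `fraction_start_u`.
#' @export
novel_mirna_summary <- function(tab) {
  stopifnot(all(c("sequence", "position") %in% names(tab)))
  seqs <- normalize_rna(tab$sequence)
  fam <- group_families(seqs)
  tally <- table(tab$position)
  list(n_mirnas = nrow(tab),
       n_families = length(unique(fam)),
       position_tally = stats::setNames(as.integer(tally), names(tally)),
       fraction_start_u = mean(substr(seqs, 1, 1) == "U"))
}
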