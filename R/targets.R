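## miRNA target prediction with positional mismatch rules and a duplex
## MFE-ratio criterion.
##
## The model is gapless: a binding site has the same length as the miRNA and
## positions are indexed 1..L from the miRNA 5' end, so miRNA position i
## faces site position L-i+1 (antiparallel). G:U wobbles are tracked
## separately but count as mismatches for every positional rule; they still
## contribute wobble stacking energy in the duplex MFE.

COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Evaluate a miRNA:site duplex positionally
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site binding-site sequence on the transcript, 5'->3', same length.
#' @return a `DuplexEvaluation` list: `states` (per miRNA position 1..L:
#'   "match", "wobble" or "mismatch"), `mismatch_total` (wobbles included),
#'   `wobble_total`, `max_consecutive_mismatches_2_12`,
#'   `positions_10_11_clean`, and `basic_positional_pass` (the three
#'   positional criteria combined; the MFE-ratio criterion is evaluated
#'   separately).
#' @export
evaluate_duplex <- function(mirna, site) {
  mirna <- normalize_rna(mirna); site <- normalize_rna(site)
  L <- nchar(mirna)
  if (nchar(site) != L) stop("evaluate_duplex: site length must equal miRNA length")
  mi <- strsplit(mirna, "")[[1]]
  ## miRNA position i faces site position L-i+1
  tg <- rev(strsplit(site, "")[[1]])
  match_wc <- COMPLEMENT[mi] == tg
  wobble <- (mi == "G" & tg == "U") | (mi == "U" & tg == "G")
  states <- ifelse(match_wc, "match", ifelse(wobble, "wobble", "mismatch"))
  is_mm <- states != "match"

  run_2_12 <- max_run(is_mm[2:min(12L, L)])
  ev <- list(
    mirna = mirna, site = site, states = states,
    mismatch_total = sum(is_mm),
    wobble_total = sum(states == "wobble"),
    max_consecutive_mismatches_2_12 = run_2_12,
    positions_10_11_clean = !any(is_mm[10:11]),
    basic_positional_pass = sum(is_mm) <= 3L && !any(is_mm[10:11]) &&
      run_2_12 <= 2L
  )
  class(ev) <- "DuplexEvaluation"
  ev
}

max_run <- function(x) {
  best <- 0L; run <- 0L
  for (v in x) { run <- if (v) run + 1L else 0L; best <- max(best, run) }
  best
}

#' Duplex MFE ratio against the perfect complement
#'
#' Ratio of the hybridization MFE of miRNA:site to that of the miRNA with
#' its exact reverse complement; 1 for a perfect site, smaller for impaired
#' sites, clamped at 0 when the site does not hybridize at negative energy.
#'
#' @param mirna,site sequences, 5'->3' (vectors of equal length are
#'   processed in batch).
#' @return numeric vector of ratios.
#' @export
mfe_ratio <- function(mirna, site) {
  mirna <- normalize_rna(mirna); site <- normalize_rna(site)
  perfect <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAStringSet(mirna)))
  e_perfect <- duplex_energy(mirna, perfect)
  if (any(e_perfect >= 0))
    stop("mfe_ratio: perfect-duplex energy is non-negative")
  e_site <- duplex_energy(mirna, site)
  pmax(0, e_site / e_perfect)
}

#' Predict targets of a miRNA over a transcript set
#'
#' Slides a window of the miRNA's length along each transcript and reports
#' every window satisfying all four basic criteria: at most 3 mismatches,
#' no mismatch at miRNA position 10 or 11, no more than 2 consecutive
#' mismatches within positions 2-12, and duplex MFE ratio greater than
#' `min_ratio`. The positional rules are screened vectorially; duplex
#' energies are computed only for windows that survive them. The strict
#' subset flag additionally requires zero mismatches at positions 2-12 and
#' no two adjacent mismatches anywhere.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcripts named character vector of transcript sequences.
#' @param max_mismatch,min_ratio basic-criteria thresholds (defaults 3 and
#'   0.75, strict >).
#' @return data.frame `transcript`, `start`, `end` (1-based inclusive site
#'   interval on the transcript), `mismatches`, `wobbles`, `ratio`,
#'   `strict_pass`.
#' @export
predict_targets <- function(mirna, transcripts, max_mismatch = 3L,
                            min_ratio = 0.75) {
  stopifnot(length(transcripts) > 0L, !is.null(names(transcripts)))
  mirna <- normalize_rna(mirna)
  L <- nchar(mirna)
  mi <- strsplit(mirna, "")[[1]]
  comp <- COMPLEMENT[mi]

  rows <- list()
  for (tx in names(transcripts)) {
    tseq <- normalize_rna(transcripts[[tx]])
    n <- nchar(tseq)
    if (n < L) next
    tch <- strsplit(tseq, "")[[1]]
    nwin <- n - L + 1L
    ## state matrices: row = miRNA position i, column = window start s;
    ## miRNA position i faces transcript position s + L - i
    is_mm <- matrix(FALSE, nrow = L, ncol = nwin)
    for (i in seq_len(L)) {
      faced <- tch[(L - i + 1L):(n - i + 1L)]
      is_mm[i, ] <- faced != comp[i]
    }
    mm_tot <- colSums(is_mm)
    keep <- which(mm_tot <= max_mismatch)
    if (length(keep) == 0L) next
    for (s in keep) {
      ev <- evaluate_duplex(mirna, substr(tseq, s, s + L - 1L))
      if (!ev$basic_positional_pass) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = tx, start = s, end = s + L - 1L,
        mismatches = ev$mismatch_total, wobbles = ev$wobble_total,
        strict_pass = strict_filter(ev), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(transcript = character(), start = integer(),
                      end = integer(), mismatches = integer(),
                      wobbles = integer(), ratio = numeric(),
                      strict_pass = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  sites <- substr(transcripts[out$transcript], out$start, out$end)
  out$ratio <- mfe_ratio(rep(mirna, nrow(out)), unname(sites))
  out <- out[out$ratio > min_ratio, , drop = FALSE]
  out <- out[order(out$transcript, out$start),
             c("transcript", "start", "end", "mismatches", "wobbles",
               "ratio", "strict_pass")]
  rownames(out) <- NULL
  out
}

#' Strict secondary filter on a duplex evaluation
#'
#' TRUE iff the duplex has zero mismatches at miRNA positions 2-12 and no
#' two adjacent mismatch positions anywhere along the duplex.
#'
#' @param ev a `DuplexEvaluation` from [evaluate_duplex()].
#' @return logical.
#' @export
strict_filter <- function(ev) {
  stopifnot(inherits(ev, "DuplexEvaluation"))
  is_mm <- ev$states != "match"
  L <- length(is_mm)
  no_2_12 <- !any(is_mm[2:min(12L, L)])
  no_adjacent <- max_run(is_mm) <= 1L
  no_2_12 && no_adjacent
}
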