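## Cross-species conservation scan: near-matches of a mature miRNA in a
## foreign genome, asymmetric flanking windows covering both possible
## precursor placements, inverted-repeat detection, and re-application of
## the pre-miRNA criteria (single hairpin, MFEI, mature on one arm).

#' Find near-matches of a miRNA in a genome
#'
#' All gapless occurrences with at most `max_mm` substitutions, both strands.
#'
#' @param mirna mature sequence (T or U form).
#' @param genome `DNAStringSet`.
#' @param max_mm maximum substitutions (default 4).
#' @return data.frame `chrom`, `start`, `end`, `strand`, `mismatches`.
#' @export
find_near_matches <- function(mirna, genome, max_mm = 4L) {
  lib <- read_library(mirna, 1L, "query")
  hits <- map_reads(lib, genome, max_mismatch = max_mm)
  hits[, c("chrom", "start", "end", "strand", "mismatches")]
}

#' Extract the two asymmetric precursor windows around a hit
#'
#' A mature miRNA can sit on either arm of its precursor, so the windows
#' extend 50 nt one way and 250 nt the other relative to the match
#' boundaries (offsets applied upstream of the match start and downstream
#' of the match end on the genomic plus strand, mirrored for minus-strand
#' hits). Windows are clipped at chromosome ends and returned 5'->3' on the
#' hit's strand.
#'
#' @param hit one row from [find_near_matches()].
#' @param genome `DNAStringSet`.
#' @param short_flank,long_flank flank lengths in nt (defaults 50 / 250).
#' @return list of two lists, each with `gstart`, `gend` (genomic, 1-based
#'   closed), `sequence` (RNA form, hit strand), and `match_start`,
#'   `match_end` (position of the matched mature within the window
#'   sequence).
#' @export
extract_windows <- function(hit, genome, short_flank = 50L, long_flank = 250L) {
  chrom_len <- Biostrings::width(genome[names(genome) == hit$chrom])
  mk <- function(up, down) {
    gstart <- max(1L, hit$start - up)
    gend <- min(chrom_len, hit$end + down)
    if (gstart > chrom_len || gend < 1L) return(NULL)
    seq_dna <- as.character(Biostrings::subseq(genome[[hit$chrom]], gstart, gend))
    if (hit$strand == "-") {
      seq_dna <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq_dna)))
      ms <- gend - hit$end + 1L
    } else {
      ms <- hit$start - gstart + 1L
    }
    list(gstart = gstart, gend = gend, sequence = normalize_rna(seq_dna),
         match_start = ms, match_end = ms + (hit$end - hit$start))
  }
  ## on the hit's strand the two placements are 5' arm (short upstream
  ## flank, long downstream) and 3' arm (long upstream, short downstream);
  ## for minus-strand hits the genomic offsets mirror automatically
  if (hit$strand == "+") {
    wins <- list(mk(short_flank, long_flank), mk(long_flank, short_flank))
  } else {
    wins <- list(mk(long_flank, short_flank), mk(short_flank, long_flank))
  }
  Filter(Negate(is.null), wins)
}

#' Detect inverted repeats within a window
#'
#' Aligns the window locally against its own reverse complement
#' (match +3, mismatch -3, gap open -12, gap extend -2) and reduces the
#' alignment to non-crossing arm pairs. Multiple inverted repeats are found
#' by recursing into the flanks of each accepted repeat.
#'
#' @param window nucleotide sequence.
#' @param min_arm minimum arm length in aligned base pairs (default 15).
#' @param min_identity minimum fraction of complementary pairs (default 0.7).
#' @param min_score minimum arm score, computed einverted-style as
#'   match/mismatch points over the paired positions (default 50, i.e. a
#'   17-bp perfect arm); random sequence rarely reaches it.
#' @param scores named numeric vector `match`, `mismatch`, `gap_open`,
#'   `gap_ext`.
#' @return data.frame `arm1_start`, `arm1_end`, `arm2_start`, `arm2_end`,
#'   `loop_length`, `identity`, `score`, sorted by score (descending).
#' @export
find_inverted_repeats <- function(window, min_arm = 15L, min_identity = 0.7,
                                  min_score = 50,
                                  scores = c(match = 3, mismatch = -3,
                                             gap_open = 12, gap_ext = 2)) {
  window <- rna_to_dna(normalize_rna(window))
  n <- nchar(window)
  empty <- data.frame(arm1_start = integer(), arm1_end = integer(),
                      arm2_start = integer(), arm2_end = integer(),
                      loop_length = integer(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < 2L * min_arm + 3L) return(empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scores[["match"]], mismatch = scores[["mismatch"]],
    baseOnly = TRUE)

  scan <- function(lo, hi) {
    if (hi - lo + 1L < 2L * min_arm + 3L) return(NULL)
    sub <- substr(window, lo, hi)
    m <- hi - lo + 1L
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sub), Biostrings::DNAString(rc), type = "local",
      substitutionMatrix = mat, gapOpening = scores[["gap_open"]],
      gapExtension = scores[["gap_ext"]])
    if (Biostrings::score(al) <= 0) return(NULL)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    i <- IRanges::start(Biostrings::pattern(al)) - 1L
    j <- IRanges::start(Biostrings::subject(al)) - 1L
    pairs <- matrix(integer(0), ncol = 2L); comp <- logical(0)
    for (k in seq_along(pa)) {
      if (pa[k] != "-") i <- i + 1L
      if (sa[k] != "-") j <- j + 1L
      if (pa[k] != "-" && sa[k] != "-") {
        q <- m - j + 1L                       # subject pos -> window pos
        pairs <- rbind(pairs, c(min(i, q), max(i, q)))
        ## subject is the reverse complement, so an alignment match already
        ## means window[i] and window[q] are complementary
        comp[nrow(pairs)] <- pa[k] == sa[k]
      }
    }
    ## deduplicate mirror pairs and drop self/crossing pairs
    keep <- pairs[, 1] < pairs[, 2]
    pairs <- pairs[keep, , drop = FALSE]; comp <- comp[keep]
    if (nrow(pairs) == 0L) return(NULL)
    dup <- duplicated(pairs)
    pairs <- pairs[!dup, , drop = FALSE]; comp <- comp[!dup]
    if (nrow(pairs) < min_arm) return(NULL)
    a1 <- range(pairs[, 1]); a2 <- range(pairs[, 2])
    if (a1[2] >= a2[1]) return(NULL)          # crossing arms
    ident <- mean(comp)
    ## arm score on the deduplicated pair set (the raw alignment score
    ## double-counts palindromic alignments that cross their own centre)
    arm_score <- scores[["match"]] * sum(comp) +
      scores[["mismatch"]] * sum(!comp)
    res <- NULL
    if (nrow(pairs) >= min_arm && ident >= min_identity &&
        arm_score >= min_score) {
      res <- data.frame(
        arm1_start = lo + a1[1] - 1L, arm1_end = lo + a1[2] - 1L,
        arm2_start = lo + a2[1] - 1L, arm2_end = lo + a2[2] - 1L,
        loop_length = a2[1] - a1[2] - 1L, identity = ident,
        score = arm_score, stringsAsFactors = FALSE)
    }
    ## recurse into the flanks for further repeats
    left <- scan(lo, lo + a1[1] - 2L)
    right <- scan(lo + a2[2], hi)
    rbind(res, left, right)
  }
  out <- scan(1L, n)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Evaluate a near-match hit for conservation
#'
#' A hit is conserved when one of its windows contains an inverted repeat
#' and, after precursor excision around the matched mature, folds into a
#' single stem-loop with MFEI above `mfei_min` and with the matched mature
#' lying wholly on one arm (no loop overlap).
#'
#' @param hit one row from [find_near_matches()].
#' @param genome foreign genome `DNAStringSet`.
#' @param species label for the report.
#' @param mfei_min MFEI threshold (strict >, default 0.85).
#' @param min_arm,min_identity thresholds for [find_inverted_repeats()].
#' @return list (`ConservationHit`): `species`, `chrom`, `start`, `strand`,
#'   `mismatches`, `windows` (list), `candidate` (best `HairpinCandidate`
#'   or NULL), `conserved`.
#' @export
evaluate_conserved <- function(hit, genome, species = "foreign",
                               mfei_min = 0.85, min_arm = 15L,
                               min_identity = 0.7) {
  windows <- extract_windows(hit, genome)
  best <- NULL
  conserved <- FALSE
  for (w in windows) {
    irs <- find_inverted_repeats(w$sequence, min_arm, min_identity)
    if (nrow(irs) == 0L) next
    wf <- fold(w$sequence)
    unit <- excise_unit(wf$structure, w$match_start, w$match_end)
    if (is.null(unit)) next
    unit[1] <- max(1L, unit[1] - 5L)
    unit[2] <- min(nchar(w$sequence), unit[2] + 5L)
    cand <- hairpin_candidate(substr(w$sequence, unit[1], unit[2]))
    if (is.null(cand)) next
    ms <- w$match_start - unit[1] + 1L
    me <- w$match_end - unit[1] + 1L
    if (ms < 1L || me > cand$length) next
    on_arm <- (ms >= cand$arm5[1] && me <= cand$arm5[2]) ||
      (ms >= cand$arm3[1] && me <= cand$arm3[2])
    no_loop <- !(ms <= cand$loop[2] && me >= cand$loop[1])
    if (cand$mfei > mfei_min && on_arm && no_loop) {
      best <- cand
      conserved <- TRUE
      break
    }
    if (is.null(best)) best <- cand
  }
  structure(list(species = species, chrom = hit$chrom, start = hit$start,
                 strand = hit$strand, mismatches = hit$mismatches,
                 windows = windows, candidate = best, conserved = conserved),
            class = "ConservationHit")
}

#' Scan a foreign genome for conservation of a set of matures
#'
#' @param matures named character vector of mature sequences.
#' @param genome foreign genome `DNAStringSet`.
#' @param species label.
#' @param max_mm mismatch tolerance for the initial scan (default 4).
#' @param mfei_min MFEI threshold.
#' @return data.frame `mirna`, `species`, `chrom`, `start`, `strand`,
#'   `mismatches`, `conserved` (one row per near-match hit; miRNAs without
#'   hits are absent).
#' @export
scan_conservation <- function(matures, genome, species = "foreign",
                              max_mm = 4L, mfei_min = 0.85) {
  stopifnot(!is.null(names(matures)))
  rows <- list()
  for (nm in names(matures)) {
    hits <- find_near_matches(matures[[nm]], genome, max_mm)
    for (i in seq_len(nrow(hits))) {
      ch <- evaluate_conserved(hits[i, ], genome, species, mfei_min)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = nm, species = species, chrom = ch$chrom, start = ch$start,
        strand = ch$strand, mismatches = ch$mismatches,
        conserved = ch$conserved, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(mirna = character(), species = character(),
                      chrom = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      conserved = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
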