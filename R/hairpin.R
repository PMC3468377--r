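## Novel miRNA discovery: genome mapping, read clustering, precursor
## excision and folding, MFEI / loop / repeat / abundance filters, star
## calling, genomic-context annotation and family grouping.

#' Default configuration of the discovery pipeline
#'
#' @return named list of tunable parameters: `max_mismatch` (genome mapping),
#'   `merge_gap` (cluster merging, nt), `window_pad` / `window_pad_retry` /
#'   `window_cap` (candidate window extraction, nt), `min_precursor_len`,
#'   `excise_margin` (unpaired residues kept around the excised stem-loop),
#'   `mfei_min`, `mature_len_min` / `mature_len_max`, `min_count`,
#'   `star_max_unpaired`, repeat-filter thresholds (`repeat_entropy_min`,
#'   `repeat_tandem_units`, `repeat_tandem_max_period`).
#' @export
discovery_config <- function() {
  list(max_mismatch = 1L,
       merge_gap = 200L,
       window_pad = 150L,
       window_pad_retry = 75L,
       window_cap = 400L,
       min_precursor_len = 40L,
       excise_margin = 5L,
       mfei_min = 0.85,
       mature_len_min = 20L,
       mature_len_max = 22L,
       min_count = 5L,
       star_max_unpaired = 0.5,
       repeat_entropy_min = 3.0,
       repeat_tandem_units = 9L,
       repeat_tandem_max_period = 6L)
}

#' Map library reads to a genome with bounded mismatches
#'
#' Reports all occurrences of each read on both strands with at most
#' `max_mismatch` substitutions (no indels). A read may hit many loci;
#' unmapped reads simply produce no rows.
#'
#' @param lib a `ReadLibrary`.
#' @param genome `DNAStringSet` named by chromosome.
#' @param max_mismatch maximum substitutions per hit (default 1).
#' @return data.frame `sequence`, `count`, `chrom`, `start`, `end` (1-based
#'   closed genomic interval), `strand`, `mismatches`.
#' @export
map_reads <- function(lib, genome, max_mismatch = 1L) {
  stopifnot(inherits(lib, "ReadLibrary"))
  out <- vector("list", 2L * lib$unique_reads * length(genome))
  k <- 0L
  for (r in seq_len(lib$unique_reads)) {
    seq_rna <- lib$reads$sequence[r]
    cnt <- lib$reads$count[r]
    pat_fwd <- Biostrings::DNAString(rna_to_dna(seq_rna))
    pat_rev <- Biostrings::reverseComplement(pat_fwd)
    for (ch in names(genome)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") pat_fwd else pat_rev
        m <- Biostrings::matchPattern(pat, genome[[ch]],
                                      max.mismatch = max_mismatch)
        if (length(m) == 0L) next
        mm <- Biostrings::neditStartingAt(pat, genome[[ch]],
                                          starting.at = IRanges::start(m))
        k <- k + 1L
        out[[k]] <- data.frame(
          sequence = seq_rna, count = cnt, chrom = ch,
          start = IRanges::start(m), end = IRanges::end(m),
          strand = str, mismatches = as.integer(mm),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(sequence = character(), count = integer(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$chrom, res$strand, res$start, res$sequence), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cluster genomic hits within a merge gap
#'
#' Hits on the same chromosome and strand whose intervals are separated by
#' at most `merge_gap` unaligned nucleotides fall into one cluster; clusters
#' are maximal. Opposite strands never merge.
#'
#' @param hits data.frame from [map_reads()].
#' @param merge_gap maximum gap in nt between member intervals (default 200).
#' @return list of clusters; each is a list with `chrom`, `strand`, `start`,
#'   `end` (union span) and `members` (the hit rows).
#' @export
cluster_hits <- function(hits, merge_gap = 200L) {
  if (nrow(hits) == 0L) return(list())
  clusters <- list()
  for (key in split(seq_len(nrow(hits)),
                    paste(hits$chrom, hits$strand, sep = "\r"))) {
    h <- hits[key, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    cur_end <- h$end[1]
    grp <- integer(nrow(h)); grp[1] <- 1L; g <- 1L
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] - cur_end - 1L > merge_gap) g <- g + 1L
      grp[i] <- g
      cur_end <- max(cur_end, h$end[i])
    }
    for (gg in seq_len(g)) {
      m <- h[grp == gg, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <-
        list(chrom = m$chrom[1], strand = m$strand[1],
             start = min(m$start), end = max(m$end), members = m)
    }
  }
  ord <- order(vapply(clusters, `[[`, character(1), "chrom"),
               vapply(clusters, `[[`, character(1), "strand"),
               vapply(clusters, `[[`, integer(1), "start"))
  clusters[ord]
}

## ---- repeat filter ----------------------------------------------------

dinucleotide_entropy <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < 2L) return(0)
  din <- paste0(chars[-length(chars)], chars[-1])
  p <- table(din) / length(din)
  -sum(p * log2(p))
}

## Longest tandem run for a given period: positions where s[i] == s[i+p].
max_tandem_units <- function(seq, period) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n <= period) return(1)
  eq <- chars[seq_len(n - period)] == chars[(period + 1L):n]
  best <- 0L; run <- 0L
  for (e in eq) {
    run <- if (e) run + 1L else 0L
    best <- max(best, run)
  }
  (best + period) / period
}

#' Repeat / low-complexity filter for candidate windows
#'
#' A window fails when it contains a supplied repeat-library sequence (either
#' strand), a tandem repeat of at least `tandem_units` units with period at
#' most `tandem_max_period`, or dinucleotide Shannon entropy below
#' `entropy_min` bits (low complexity).
#'
#' @param window nucleotide sequence of the candidate window.
#' @param repeat_library optional character vector of repeat sequences.
#' @param entropy_min entropy threshold in bits (max 4 for random sequence).
#' @param tandem_units,tandem_max_period tandem-repeat thresholds.
#' @return TRUE (pass) or FALSE (fail).
#' @export
repeat_filter <- function(window, repeat_library = NULL,
                          entropy_min = 3.0, tandem_units = 9L,
                          tandem_max_period = 6L) {
  window <- normalize_rna(window)
  if (!is.null(repeat_library) && length(repeat_library) > 0L) {
    reps <- normalize_rna(repeat_library)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::RNAStringSet(reps)))
    for (rp in c(reps, rc))
      if (grepl(rp, window, fixed = TRUE)) return(FALSE)
  }
  for (p in seq_len(tandem_max_period))
    if (max_tandem_units(window, p) >= tandem_units) return(FALSE)
  if (dinucleotide_entropy(window) < entropy_min) return(FALSE)
  TRUE
}

## ---- mature / star calling --------------------------------------------

#' Call the mature miRNA of a hairpin candidate from its read cluster
#'
#' The mature is the most abundant member read of length
#' `mature_len_min`..`mature_len_max` with count at least `min_count` that
#' lies wholly within one arm of the hairpin (no overlap with the terminal
#' loop). Ties break to the lexicographically smallest sequence.
#'
#' @param members data.frame of member hits with columns `sequence`, `count`,
#'   `cand_start`, `cand_end` (1-based positions within the candidate).
#' @param candidate a `HairpinCandidate`.
#' @param min_count minimum read count (default 5).
#' @param len_min,len_max mature length bounds in nt (defaults 20/22).
#' @return one-row data.frame of the mature read (with its candidate
#'   coordinates), or NULL when no read qualifies.
#' @export
call_mature <- function(members, candidate, min_count = 5L,
                        len_min = 20L, len_max = 22L) {
  if (nrow(members) == 0L) return(NULL)
  len <- nchar(members$sequence)
  in_cand <- members$cand_start >= 1L & members$cand_end <= candidate$length
  arm5 <- members$cand_start >= candidate$arm5[1] &
    members$cand_end <= candidate$arm5[2]
  arm3 <- members$cand_start >= candidate$arm3[1] &
    members$cand_end <= candidate$arm3[2]
  no_loop <- !(members$cand_start <= candidate$loop[2] &
                 members$cand_end >= candidate$loop[1])
  ok <- len >= len_min & len <= len_max & members$count >= min_count &
    in_cand & (arm5 | arm3) & no_loop
  if (!any(ok)) return(NULL)
  m <- members[ok, , drop = FALSE]
  m <- m[order(-m$count, m$sequence), , drop = FALSE]
  m[1, , drop = FALSE]
}

#' Locate the star strand of a mature miRNA on a hairpin
#'
#' Uses the candidate's base-pairing map and canonical Dicer duplex
#' geometry: each strand of the miRNA:miRNA* duplex carries a 2-nt 3'
#' overhang, so the star spans the partners of the mature positions
#' 1..(L-2), extended by two nucleotides at the star's own 3' end. Bulged
#' (unpaired) anchor positions are skipped inward along the pairing map.
#'
#' @param candidate a `HairpinCandidate`.
#' @param mature_interval c(start, end) of the mature within the candidate.
#' @param max_unpaired maximum tolerated fraction of unpaired mature
#'   positions (default 0.5); above it no star is derivable.
#' @return list with `start`, `end`, `sequence` of the star (candidate
#'   coordinates), or NULL.
#' @export
find_star <- function(candidate, mature_interval, max_unpaired = 0.5) {
  p <- candidate$pairs
  m1 <- mature_interval[1]; m2 <- mature_interval[2]
  stopifnot(m1 >= 1L, m2 <= candidate$length, m1 < m2)
  mpos <- m1:m2
  if (mean(is.na(p[mpos])) > max_unpaired) return(NULL)

  ## anchor near the mature 3' end: partner of position m2-2 (or nearest
  ## paired position inward); gives the star 5' boundary
  a1 <- m2 - 2L
  while (a1 >= m1 && is.na(p[a1])) a1 <- a1 - 1L
  ## anchor at the mature 5' end: partner of m1 (or nearest paired inward);
  ## star 3' end extends 2 nt beyond it
  a2 <- m1
  while (a2 <= m2 && is.na(p[a2])) a2 <- a2 + 1L
  if (a1 < m1 || a2 > m2) return(NULL)

  s_from <- p[a1]
  s_to <- p[a2] + 2L
  lo <- max(1L, min(s_from, s_to))
  hi <- min(candidate$length, max(s_from, s_to))
  list(start = lo, end = hi,
       sequence = substr(candidate$sequence, lo, hi))
}

## ---- genomic context ---------------------------------------------------

#' Genomic context of a precursor locus
#'
#' @param chrom,start,end precursor interval (1-based closed).
#' @param gene_models `GRanges` with `type` containing `gene` and `exon`.
#' @return one of "Intergenic", "Intron", "Exon", "Overlap". A precursor
#'   wholly inside one intron (exon) is Intron (Exon); spanning an
#'   exon/intron boundary within a gene is Overlap; overlapping no gene is
#'   Intergenic. A precursor straddling a gene edge is classified Intergenic
#'   with a message (it is partly outside any gene model).
#' @export
genomic_context <- function(chrom, start, end, gene_models) {
  feats <- gene_features(gene_models)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  within_any <- function(gr) {
    ov <- GenomicRanges::findOverlaps(q, gr, type = "within",
                                      ignore.strand = TRUE)
    length(ov) > 0L
  }
  overlaps_any <- function(gr) {
    length(GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)) > 0L
  }
  if (!overlaps_any(feats$gene)) return("Intergenic")
  if (!within_any(feats$gene)) {
    message(sprintf("precursor %s:%d-%d straddles a gene boundary; classified Intergenic",
                    chrom, start, end))
    return("Intergenic")
  }
  if (within_any(feats$intron)) return("Intron")
  if (within_any(GenomicRanges::reduce(feats$exon, ignore.strand = TRUE)))
    return("Exon")
  "Overlap"
}

## ---- family grouping ---------------------------------------------------

#' Group mature sequences into families
#'
#' Single-linkage clustering: two matures link iff they have equal length
#' and Hamming distance at most 1. Identical sequences (multi-locus
#' miRNAs) are always one family. Family ids are assigned in order of each
#' family's lexicographically smallest member, so the grouping is
#' permutation-invariant.
#'
#' @param matures character vector of mature sequences (T or U form).
#' @return integer vector of family ids parallel to `matures` (1-based,
#'   dense).
#' @export
group_families <- function(matures) {
  if (length(matures) == 0L) return(integer())
  seqs <- normalize_rna(matures)
  uniq <- sort(unique(seqs))
  n <- length(uniq)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (nchar(uniq[i]) != nchar(uniq[j])) next
      if (hamming(uniq[i], uniq[j]) <= 1L) {
        ri <- findp(i); rj <- findp(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), findp, integer(1))
  ## dense ids ordered by smallest member (uniq is sorted, so order of first
  ## appearance of each root is lexicographic)
  ids <- match(roots, unique(roots))
  ids[match(seqs, uniq)]
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## ---- candidate extraction ----------------------------------------------

## Build the hairpin candidate for one cluster: pad the cluster span, fold
## the window, excise the stem-loop unit containing the cluster reads,
## refold the excised region. Returns NULL or a list(candidate, members)
## where members carry candidate coordinates.
cluster_candidate <- function(cl, genome, cfg, pad) {
  chrom_len <- Biostrings::width(genome[names(genome) == cl$chrom])
  span <- cl$end - cl$start + 1L
  pad_eff <- min(pad, max(0L, (cfg$window_cap - span) %/% 2L))
  wstart <- max(1L, cl$start - pad_eff)
  wend <- min(chrom_len, cl$end + pad_eff)
  if (wend - wstart + 1L < cfg$min_precursor_len) return(NULL)
  wseq_dna <- as.character(Biostrings::subseq(genome[[cl$chrom]], wstart, wend))
  if (cl$strand == "-")
    wseq_dna <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(wseq_dna)))
  wseq <- normalize_rna(wseq_dna)

  ## member positions in window coordinates (5'->3' on the cluster strand)
  mem <- cl$members
  if (cl$strand == "+") {
    ws <- mem$start - wstart + 1L
    we <- mem$end - wstart + 1L
  } else {
    ws <- wend - mem$end + 1L
    we <- wend - mem$start + 1L
  }

  wf <- fold(wseq)
  ## centre the excision on the reads that could become the mature; distant
  ## low-count cluster members (degradation background absorbed by the
  ## merge gap) must not drag the excised unit away from the hairpin
  len <- nchar(mem$sequence)
  elig <- len >= cfg$mature_len_min & len <= cfg$mature_len_max &
    mem$count >= cfg$min_count
  fsel <- if (any(elig)) which(elig) else seq_len(nrow(mem))
  focus <- range(c(ws[fsel], we[fsel]))
  unit <- excise_unit(wf$structure, focus[1], focus[2])
  if (is.null(unit)) return(NULL)
  ## precursor boundaries are not exactly the outermost stem pair: keep a
  ## small unpaired margin (Dicer/Drosha products carry flanking residues,
  ## and the star 3' overhang can lie outside the stem)
  unit[1] <- max(1L, unit[1] - cfg$excise_margin)
  unit[2] <- min(nchar(wseq), unit[2] + cfg$excise_margin)
  if (unit[2] - unit[1] + 1L < cfg$min_precursor_len) {
    unit[1] <- max(1L, unit[1] - (cfg$min_precursor_len - (unit[2] - unit[1] + 1L)))
  }
  prec_seq <- substr(wseq, unit[1], unit[2])
  ## genomic placement of the excised precursor
  if (cl$strand == "+") {
    gstart <- wstart + unit[1] - 1L
    gend <- wstart + unit[2] - 1L
  } else {
    gstart <- wend - unit[2] + 1L
    gend <- wend - unit[1] + 1L
  }
  cand <- hairpin_candidate(prec_seq, chrom = cl$chrom, start = gstart,
                            strand = cl$strand)
  if (is.null(cand)) return(NULL)
  mem$cand_start <- ws - unit[1] + 1L
  mem$cand_end <- we - unit[1] + 1L
  list(candidate = cand, members = mem, genomic = c(gstart, gend))
}

#' Discover novel miRNAs in a read library
#'
#' Composition of the full discovery chain: map reads to the genome, cluster
#' hits, extract and fold padded windows, excise the candidate precursor
#' stem-loop, apply the repeat and MFEI filters, call the mature read
#' (length/abundance/arm rules), locate the star strand, annotate the
#' genomic context and group matures into families. The library should
#' already be stripped of known-miRNA and structural-RNA matches (see
#' [classify_reads()]).
#'
#' @param lib a `ReadLibrary`.
#' @param genome `DNAStringSet`.
#' @param gene_models optional `GRanges` gene models for context annotation.
#' @param config parameter list from [discovery_config()].
#' @param repeat_library optional character vector for [repeat_filter()].
#' @return data.frame with one row per novel miRNA locus: `id`, `mature`,
#'   `length`, `count`, `star`, `star_count`, `chrom`, `precursor_start`,
#'   `precursor_end`, `strand`, `precursor`, `structure`, `mfe`, `mfei`,
#'   `context`, `family`.
#' @export
discover <- function(lib, genome, gene_models = NULL,
                     config = discovery_config(), repeat_library = NULL) {
  cfg <- utils::modifyList(discovery_config(), config)
  hits <- map_reads(lib, genome, cfg$max_mismatch)
  clusters <- cluster_hits(hits, cfg$merge_gap)

  ## abundance screen: a cluster can only yield a mature if some member is
  ## length-eligible with sufficient count, so skip folding the rest
  eligible <- vapply(clusters, function(cl) {
    len <- nchar(cl$members$sequence)
    any(len >= cfg$mature_len_min & len <= cfg$mature_len_max &
          cl$members$count >= cfg$min_count)
  }, logical(1))
  clusters <- clusters[eligible]

  rows <- list()
  for (cl in clusters) {
    res <- NULL
    for (pad in c(cfg$window_pad, cfg$window_pad_retry)) {
      cc <- cluster_candidate(cl, genome, cfg, pad)
      if (is.null(cc)) next
      window_seq <- cc$candidate$sequence
      if (!repeat_filter(window_seq, repeat_library,
                         cfg$repeat_entropy_min, cfg$repeat_tandem_units,
                         cfg$repeat_tandem_max_period)) next
      if (cc$candidate$mfei <= cfg$mfei_min) next
      mat <- call_mature(cc$members, cc$candidate, cfg$min_count,
                         cfg$mature_len_min, cfg$mature_len_max)
      if (is.null(mat)) next
      res <- list(cc = cc, mat = mat)
      break
    }
    if (is.null(res)) next
    cc <- res$cc; mat <- res$mat
    st <- find_star(cc$candidate, c(mat$cand_start, mat$cand_end),
                    cfg$star_max_unpaired)
    star_seq <- if (is.null(st)) NA_character_ else st$sequence
    star_count <- if (is.na(star_seq)) NA_integer_ else {
      i <- match(star_seq, lib$reads$sequence)
      if (is.na(i)) 0L else lib$reads$count[i]
    }
    ctx <- if (is.null(gene_models)) NA_character_ else
      genomic_context(cl$chrom, cc$genomic[1], cc$genomic[2], gene_models)
    rows[[length(rows) + 1L]] <- data.frame(
      mature = mat$sequence, length = nchar(mat$sequence),
      count = mat$count, star = star_seq, star_count = star_count,
      chrom = cl$chrom, precursor_start = cc$genomic[1],
      precursor_end = cc$genomic[2], strand = cl$strand,
      precursor = cc$candidate$sequence,
      structure = cc$candidate$structure,
      mfe = cc$candidate$mfe, mfei = cc$candidate$mfei,
      context = ctx, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(id = character(), mature = character(),
                      length = integer(), count = integer(),
                      star = character(), star_count = integer(),
                      chrom = character(), precursor_start = integer(),
                      precursor_end = integer(), strand = character(),
                      precursor = character(), structure = character(),
                      mfe = numeric(), mfei = numeric(),
                      context = character(), family = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$precursor_start, out$strand), , drop = FALSE]
  out$family <- group_families(out$mature)
  out <- cbind(id = sprintf("nmiR-%02d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
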