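## Synthetic study generator: genomes with planted pre-miRNA hairpins in
## defined genomic contexts, gene annotations, non-coding RNA references,
## read libraries with mature/star/background structure, and target
## transcripts with designed site mismatch patterns. Every planted feature
## is recorded in a ground-truth table so each pipeline stage can be tested
## against known answers.

#' Define a synthetic scenario
#'
#' Defaults describe the study conditions the pipeline is designed for: a
#' 200-kb genome with 30 planted hairpins whose contexts follow the
#' intergenic/intron/overlap proportions typical of plant novel-miRNA
#' surveys (about 57/37/6 percent), mature abundances log-uniform on 5-500
#' (discovery operates right down at the 5-read rule), star reads at 5% of
#' mature sampling, a degradation background biased to 24 nt (the
#' heterochromatic siRNA class that dominates seed libraries) and a
#' per-base sequencing error rate of 0.005.
#'
#' @param seed RNG seed (integer).
#' @param genome_length genome size in nt.
#' @param n_hairpins number of planted pre-miRNA hairpins.
#' @param context_weights named numeric weights for Intergenic/Intron/Overlap
#'   placement of hairpins.
#' @param mature_length mature length in nt (20-22).
#' @param gc_target GC fraction of planted matures.
#' @param count_range mature abundance range (log-uniform).
#' @param star_ratio star:mature sampling ratio.
#' @param n_genes number of three-exon gene models.
#' @param n_background background degradation fragments per library.
#' @param background_from_refs additional fragments drawn from the ncRNA
#'   references per library.
#' @param error_rate per-base substitution error rate.
#' @param libraries character vector of library labels.
#' @param length_preset "seed" (24-nt dominant background) or "leaf"
#'   (21-nt dominant).
#' @return a `SyntheticScenario` list.
#' @export
scenario <- function(seed = 1L,
                     genome_length = 200000L,
                     n_hairpins = 30L,
                     context_weights = c(Intergenic = 31, Intron = 20, Overlap = 3),
                     mature_length = 21L,
                     gc_target = 0.5,
                     count_range = c(5L, 500L),
                     star_ratio = 0.05,
                     n_genes = 24L,
                     n_background = 250L,
                     background_from_refs = 80L,
                     error_rate = 0.005,
                     libraries = "seed",
                     length_preset = c("seed", "leaf")) {
  length_preset <- match.arg(length_preset)
  stopifnot(seed < 2^31, genome_length > 0, n_hairpins >= 0,
            error_rate >= 0, error_rate < 1, star_ratio >= 0)
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_hairpins = n_hairpins, context_weights = context_weights,
                 mature_length = mature_length, gc_target = gc_target,
                 count_range = count_range, star_ratio = star_ratio,
                 n_genes = n_genes, n_background = n_background,
                 background_from_refs = background_from_refs,
                 error_rate = error_rate, libraries = libraries,
                 length_preset = length_preset),
            class = "SyntheticScenario")
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T"),
                       prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

## mature with an exact number of G/C bases (controls stem stability)
random_mature <- function(len, gc_target) {
  n_gc <- round(len * gc_target)
  bases <- c(sample(c("A", "U"), len - n_gc, replace = TRUE),
             sample(c("G", "C"), n_gc, replace = TRUE))
  paste(sample(bases), collapse = "")
}

## Precursor construction: a continuous perfect stem holding the mature on
## the 5' arm plus a short stem extension toward an A/C loop (A and C
## cannot pair with each other, keeping the loop unstructured), the full
## reverse complement as the 3' arm, and a 2-nt 3' tail. The star strand is
## then fixed by canonical Dicer duplex geometry (2-nt 3' overhangs on both
## ends): reverse complement of mature[1..L-2] followed by the tail, so
## find_star has a known answer by construction.
## Real stems are imperfect: two star-arm positions (facing mature
## positions 7 and 13, well away from the duplex ends that anchor the star
## interval) are replaced by the mature base itself, which can pair with
## nothing (A:A, C:C, G:G, U:U are never base pairs, and the wobble trap
## G:U is avoided). This also prevents the mature read from mapping
## antisense onto the star arm within the 1-mismatch mapping tolerance.
build_precursor <- function(mature, ext_len = 5L, loop_len = 11L,
                            stem_mismatch_at = c(7L, 13L)) {
  L <- nchar(mature)
  ext <- random_mature(ext_len, 0.6)
  loop <- random_seq(loop_len, c("A", "C"))
  arm5 <- paste0(mature, ext)
  arm3 <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(arm5))), "")[[1]]
  mi <- strsplit(mature, "")[[1]]
  for (p in stem_mismatch_at) {
    ## arm3 position facing mature position p: arm3 = revcomp(mature+ext),
    ## so comp(mature[p]) sits at index ext_len + (L - p + 1)
    arm3[ext_len + L - p + 1L] <- mi[p]
  }
  arm3 <- paste(arm3, collapse = "")
  tail <- random_seq(2L, c("A", "C"))
  ## star by duplex geometry: partners of mature 1..(L-2) plus the 2-nt 3'
  ## tail; equals the 3' arm portion from the base facing mature L-2 onward
  star <- paste0(substr(arm3, ext_len + 3L, ext_len + L), tail)
  list(precursor = paste0(arm5, loop, arm3, tail), star = star,
       mature_interval = c(1L, L))
}

#' Build the synthetic genome, annotation and ground truth
#'
#' Deterministic given the scenario seed: plants three-exon gene models at
#' regular spacings, embeds each hairpin precursor at a context-consistent
#' locus (intergenic, wholly intronic, or straddling an exon/intron
#' boundary) on a random strand, and generates non-coding RNA reference
#' sets plus a synthetic known-miRNA reference.
#'
#' @param scn a `SyntheticScenario`.
#' @return list with `genome` (`DNAStringSet`), `gene_models` (`GRanges`
#'   with `gene`/`exon` rows), `truth` (data.frame: one row per hairpin
#'   with id, mature, star, precursor, chrom, start, end, strand, context,
#'   per-library assigned counts, expected_pass), `refs` (list of ncRNA /
#'   known-miRNA reference sequence vectors).
#' @export
build_genome <- function(scn) {
  stopifnot(inherits(scn, "SyntheticScenario"))
  set.seed(scn$seed)
  glen <- scn$genome_length
  chrom <- "chr1"
  gseq <- strsplit(random_seq(glen), "")[[1]]

  ## gene models: exon(300) intron(1200) exon(300) intron(1200) exon(300)
  exon_len <- 300L; intron_len <- 1200L
  gene_len <- 3L * exon_len + 2L * intron_len
  spacing <- floor(glen / (scn$n_genes + 1L))
  if (spacing <= gene_len + 2000L)
    stop("build_genome: infeasible packing, genome too small for gene models")
  gene_start <- spacing * seq_len(scn$n_genes) - gene_len %/% 2L
  exon_offsets <- c(0L, exon_len + intron_len, 2L * (exon_len + intron_len))
  genes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(gene_start, gene_start + gene_len - 1L),
    type = "gene", ID = sprintf("gene%02d", seq_len(scn$n_genes)))
  exons <- do.call(c, lapply(seq_len(scn$n_genes), function(i) {
    GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(gene_start[i] + exon_offsets,
                       gene_start[i] + exon_offsets + exon_len - 1L),
      type = "exon", ID = sprintf("gene%02d.e%d", i, 1:3))
  }))
  gene_models <- c(genes, exons)

  ## hairpin placement slots per context
  n_ctx <- round(scn$n_hairpins * scn$context_weights / sum(scn$context_weights))
  n_ctx[1] <- scn$n_hairpins - sum(n_ctx[-1])
  contexts <- rep(names(n_ctx), n_ctx)

  truth <- list()
  used <- IRanges::IRanges()       # occupied intervals (genes + hairpins)
  used <- c(used, IRanges::IRanges(gene_start, gene_start + gene_len - 1L))

  place_intergenic <- function(plen) {
    for (try in 1:200) {
      s <- sample.int(glen - plen - 100L, 1L) + 50L
      cand <- IRanges::IRanges(s - 400L, s + plen + 400L)  # keep clusters apart
      if (length(IRanges::findOverlaps(cand, used)) == 0L) return(s)
    }
    stop("build_genome: infeasible packing of intergenic hairpins")
  }
  place_intron <- function(plen) {
    for (try in 1:200) {
      gi <- sample.int(scn$n_genes, 1L)
      ii <- sample.int(2L, 1L)
      istart <- gene_start[gi] + exon_offsets[ii] + exon_len
      s <- istart + sample.int(intron_len - plen - 40L, 1L) + 20L
      ## 250-nt margin keeps separate hairpins in separate read clusters
      cand <- IRanges::IRanges(s - 250L, s + plen + 250L)
      hp_used <- used[-(seq_len(scn$n_genes))]
      if (length(IRanges::findOverlaps(cand, hp_used)) == 0L) return(s)
    }
    stop("build_genome: infeasible packing of intronic hairpins")
  }
  place_overlap <- function(plen) {
    for (try in 1:200) {
      gi <- sample.int(scn$n_genes, 1L)
      ## straddle the boundary between exon 1 and intron 1
      boundary <- gene_start[gi] + exon_len         # first intron base
      s <- boundary - sample(10:(plen - 10L), 1L)
      cand <- IRanges::IRanges(s - 250L, s + plen + 250L)
      hp_used <- used[-(seq_len(scn$n_genes))]
      if (length(IRanges::findOverlaps(cand, hp_used)) == 0L) return(s)
    }
    stop("build_genome: infeasible packing of overlap hairpins")
  }

  lo <- log(scn$count_range[1]); hi <- log(scn$count_range[2])

  for (i in seq_len(scn$n_hairpins)) {
    mature <- random_mature(scn$mature_length, scn$gc_target)
    hp <- build_precursor(mature)
    plen <- nchar(hp$precursor)
    ctx <- contexts[i]
    s <- switch(ctx,
                Intergenic = place_intergenic(plen),
                Intron = place_intron(plen),
                Overlap = place_overlap(plen))
    strand <- sample(c("+", "-"), 1L)
    prec_dna <- rna_to_dna(hp$precursor)
    if (strand == "-")
      prec_dna <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(prec_dna)))
    gseq[s:(s + plen - 1L)] <- strsplit(prec_dna, "")[[1]]
    used <- c(used, IRanges::IRanges(s, s + plen - 1L))
    truth[[i]] <- data.frame(
      id = sprintf("hp%02d", i), mature = mature, star = hp$star,
      precursor = hp$precursor, chrom = chrom, start = s,
      end = s + plen - 1L, strand = strand, context = ctx,
      expected_pass = TRUE, stringsAsFactors = FALSE)
    for (l in scn$libraries) {
      cl <- as.integer(round(exp(stats::runif(1, lo, hi))))
      truth[[i]][[paste0("count_", l)]] <- max(scn$count_range[1], cl)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(), mature = character(), star = character(),
               precursor = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               context = character(), expected_pass = logical(),
               stringsAsFactors = FALSE)

  refs <- list(
    rrna = vapply(1:2, function(i) random_seq(600), character(1)),
    trna = vapply(1:4, function(i) random_seq(75), character(1)),
    snrna = vapply(1:2, function(i) random_seq(150), character(1)),
    snorna = vapply(1:2, function(i) random_seq(100), character(1)),
    sirna = vapply(1:10, function(i) random_seq(24), character(1)),
    known_mature = vapply(1:10, function(i)
      rna_to_dna(random_mature(21L, 0.5)), character(1)),
    known_star = vapply(1:10, function(i)
      rna_to_dna(random_mature(21L, 0.5)), character(1))
  )
  refs <- lapply(refs, function(x) {
    names(x) <- sprintf("ref%02d", seq_along(x)); x
  })

  list(genome = Biostrings::DNAStringSet(stats::setNames(
         paste(gseq, collapse = ""), chrom)),
       gene_models = gene_models, truth = truth, refs = refs)
}

## apply per-base substitution errors to expanded read copies
mutate_reads <- function(copies, error_rate) {
  if (error_rate == 0 || length(copies) == 0L) return(copies)
  vapply(copies, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(ch)) < error_rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "U"), b), 1L), character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate read libraries from a built scenario
#'
#' For each configured library: every planted mature contributes its
#' assigned number of copies, the star strand is sampled at the scenario's
#' star:mature ratio, background degradation fragments are drawn from the
#' genome with the preset length bias (24-nt dominant for "seed", 21-nt for
#' "leaf") and from the ncRNA references, known-miRNA reads are added for
#' the synthetic known reference, and every copy is subjected to
#' independent per-base substitution errors before collapsing.
#'
#' @param scn a `SyntheticScenario`.
#' @param built result of [build_genome()].
#' @return named list of `ReadLibrary` objects (one per library label),
#'   plus attribute "known_counts" (data.frame of planted known-miRNA
#'   counts per library).
#' @export
simulate_reads <- function(scn, built) {
  stopifnot(inherits(scn, "SyntheticScenario"))
  set.seed(scn$seed + 1L)
  glen <- scn$genome_length
  gstr <- as.character(built$genome[[1]])

  len_weights <- function() {
    lens <- 18:30
    w <- rep(0.5 / 12, 13)
    if (scn$length_preset == "seed") w[lens == 24] <- 0.5
    else w[lens == 21] <- 0.5
    w / sum(w)
  }

  known_counts <- data.frame(name = names(built$refs$known_mature),
                             stringsAsFactors = FALSE)
  libs <- list()
  for (l in scn$libraries) {
    records <- character(0)
    for (i in seq_len(nrow(built$truth))) {
      cnt <- built$truth[[paste0("count_", l)]][i]
      records <- c(records, rep(built$truth$mature[i], cnt))
      star_n <- stats::rbinom(1L, cnt, scn$star_ratio)
      if (star_n > 0L) records <- c(records, rep(built$truth$star[i], star_n))
    }
    ## known miRNAs: planted counts, log-uniform 0..200 with dropout
    kc <- integer(length(built$refs$known_mature))
    for (k in seq_along(built$refs$known_mature)) {
      if (stats::runif(1) < 0.2) next
      kc[k] <- 1L + stats::rpois(1L, exp(stats::runif(1, 0, log(200))))
      records <- c(records,
                   rep(normalize_rna(built$refs$known_mature[[k]]), kc[k]))
    }
    known_counts[[paste0("count_", l)]] <- kc
    ## background from the genome (either strand); planted hairpin loci are
    ## excluded so that planted features and background stay non-overlapping
    hp_loci <- if (nrow(built$truth))
      IRanges::IRanges(built$truth$start - 50L, built$truth$end + 50L)
    else IRanges::IRanges()
    lens <- sample(18:30, scn$n_background, replace = TRUE,
                   prob = len_weights())
    for (j in seq_len(scn$n_background)) {
      repeat {
        s <- sample.int(glen - 31L, 1L)
        if (length(IRanges::findOverlaps(
          IRanges::IRanges(s, s + lens[j] - 1L), hp_loci)) == 0L) break
      }
      frag <- substr(gstr, s, s + lens[j] - 1L)
      if (stats::runif(1) < 0.5)
        frag <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(frag)))
      reps <- 1L + stats::rgeom(1L, 0.7)
      records <- c(records, rep(normalize_rna(frag), reps))
    }
    ## degradation fragments of the ncRNA references
    ref_pool <- unlist(built$refs[c("rrna", "trna", "snrna", "snorna")],
                       use.names = FALSE)
    for (j in seq_len(scn$background_from_refs)) {
      rs <- sample(ref_pool, 1L)
      flen <- sample(18:28, 1L)
      s <- sample.int(nchar(rs) - flen, 1L)
      reps <- 1L + stats::rgeom(1L, 0.5)
      records <- c(records, rep(normalize_rna(substr(rs, s, s + flen - 1L)),
                                reps))
    }
    ## full-abundance siRNA reference reads
    records <- c(records, rep(normalize_rna(built$refs$sirna), 3L))
    records <- mutate_reads(records, scn$error_rate)
    libs[[l]] <- collapse_reads(records, l)
  }
  attr(libs, "known_counts") <- known_counts
  libs
}

## site-pattern definitions used by make_target_transcripts; a "wobble"
## edit keeps the duplex energetically near-perfect (G:U) while counting as
## a positional mismatch
TARGET_PATTERNS <- c("perfect", "pos10", "adjacent_14_15", "three_spread",
                     "four_mm")

## Edit the perfect site so the duplex shows a mismatch at the given miRNA
## positions. The site base facing miRNA position i is site position L-i+1.
## prefer_wobble makes the edit a G:U wobble when possible (cheap in energy).
edit_site <- function(mirna, positions, prefer_wobble = TRUE) {
  L <- nchar(mirna)
  site <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(mirna))), "")[[1]]
  mi <- strsplit(mirna, "")[[1]]
  for (p in positions) {
    sp <- L - p + 1L
    b <- mi[p]
    repl <- if (prefer_wobble && b == "G") "U"
            else if (prefer_wobble && b == "U") "G"
            else setdiff(c("A", "C"), COMPLEMENT[[b]])[1]
    site[sp] <- repl
  }
  paste(site, collapse = "")
}

#' Generate target transcripts with designed site patterns
#'
#' One 500-nt transcript per (mature, pattern): a perfect site; a single
#' mismatch at miRNA position 10; adjacent mismatches at positions 14/15
#' (wobble edits, so the duplex stays energetically strong); three spread
#' mismatches at positions 5/9/15; and four mismatches at 5/8/15/18. The
#' ground truth records the expected positional outcome of each pattern
#' (the three position-based criteria) and the expected strict-filter
#' outcome.
#'
#' @param scn a `SyntheticScenario` (seeds the flanking sequence).
#' @param matures named character vector of mature sequences.
#' @param site_pos 1-based position at which the site is embedded.
#' @return list with `transcripts` (named character vector) and `truth`
#'   (data.frame: transcript, mirna, pattern, site_start, site_end,
#'   expected_positional, expected_strict).
#' @export
make_target_transcripts <- function(scn, matures, site_pos = 200L) {
  stopifnot(inherits(scn, "SyntheticScenario"), !is.null(names(matures)))
  set.seed(scn$seed + 2L)
  edits <- list(perfect = integer(0), pos10 = 10L,
                adjacent_14_15 = c(14L, 15L), three_spread = c(5L, 9L, 15L),
                four_mm = c(5L, 8L, 15L, 18L))
  expected_positional <- c(perfect = TRUE, pos10 = FALSE,
                           adjacent_14_15 = TRUE, three_spread = TRUE,
                           four_mm = FALSE)
  expected_strict <- c(perfect = TRUE, pos10 = FALSE, adjacent_14_15 = FALSE,
                       three_spread = FALSE, four_mm = FALSE)
  transcripts <- character(0)
  truth <- list()
  for (nm in names(matures)) {
    m <- normalize_rna(matures[[nm]])
    L <- nchar(m)
    for (pat in TARGET_PATTERNS) {
      site <- edit_site(m, edits[[pat]])
      tx_id <- paste0(nm, "_", pat)
      flank5 <- normalize_rna(random_seq(site_pos - 1L))
      flank3 <- normalize_rna(random_seq(500L - site_pos + 1L - L))
      transcripts[[tx_id]] <- paste0(flank5, site, flank3)
      truth[[length(truth) + 1L]] <- data.frame(
        transcript = tx_id, mirna = nm, pattern = pat,
        site_start = site_pos, site_end = site_pos + L - 1L,
        expected_positional = expected_positional[[pat]],
        expected_strict = expected_strict[[pat]],
        stringsAsFactors = FALSE)
    }
  }
  list(transcripts = transcripts, truth = do.call(rbind, truth))
}
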