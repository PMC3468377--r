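# Independent oracles and fixture builders shared across test files.
# The oracles deliberately avoid the code paths they check: plain character
# arithmetic instead of Biostrings matching, per-window loops instead of the
# vectorized scanner.

# manual reverse complement on character vectors (DNA or RNA form)
rc_chr <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTU", "TGCAA", toupper(s))
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force Hamming scan of a read over one chromosome string (DNA form),
# both strands; returns data.frame(start, end, strand, mismatches)
brute_hamming_scan <- function(read_rna, chrom_str, max_mm) {
  read_dna <- chartr("U", "T", toupper(read_rna))
  g <- strsplit(toupper(chrom_str), "")[[1]]
  n <- length(g); w <- nchar(read_dna)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") read_dna else rc_chr(read_dna)
    pch <- strsplit(pat, "")[[1]]
    mm <- integer(n - w + 1L)
    for (k in seq_len(w)) {
      mm <- mm + (g[k:(n - w + k)] != pch[k])
    }
    hit <- which(mm <= max_mm)
    if (length(hit))
      out[[strand]] <- data.frame(start = hit, end = hit + w - 1L,
                                  strand = strand, mismatches = mm[hit],
                                  stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$strand, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exhaustive per-window positional evaluation of a miRNA over transcripts;
# plain loops, one window at a time
brute_positional_scan <- function(mirna, transcripts, max_mismatch = 3L) {
  mirna <- chartr("T", "U", toupper(mirna))
  L <- nchar(mirna)
  mi <- strsplit(mirna, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rows <- list()
  for (tx in names(transcripts)) {
    t <- chartr("T", "U", toupper(transcripts[[tx]]))
    for (s in seq_len(max(0L, nchar(t) - L + 1L))) {
      site <- strsplit(substr(t, s, s + L - 1L), "")[[1]]
      mm <- logical(L)
      for (i in seq_len(L)) mm[i] <- site[L - i + 1L] != comp[[mi[i]]]
      if (sum(mm) > max_mismatch) next
      if (mm[10] || mm[11]) next
      run <- 0L; maxrun <- 0L
      for (i in 2:12) {
        run <- if (mm[i]) run + 1L else 0L
        maxrun <- max(maxrun, run)
      }
      if (maxrun > 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = tx, start = s, mismatches = sum(mm),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(transcript = character(), start = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$transcript, out$start), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# small designed hairpin used by structure-geometry tests: 24-bp perfect
# stem, unstructured A/C loop
designed_hairpin <- function(stem = "GGCAUGCCUGACGUUAGCACGAUC",
                             loop = "CAACAACAACA") {
  paste0(stem, loop, rc_chr(chartr("U", "T", stem)))
}

small_scenario <- function(seed = 11L) {
  scenario(seed = seed, genome_length = 60000L, n_hairpins = 8L,
           n_genes = 8L, n_background = 80L, background_from_refs = 30L)
}
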