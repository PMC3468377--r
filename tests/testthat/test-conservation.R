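test_that("near-match search honors the four-mismatch ceiling", {
  set.seed(51)
  g <- random_dna(20000)
  m <- srnapipe:::random_mature(21, 0.5)
  exact_at <- 5000L
  g <- paste0(substr(g, 1, exact_at - 1), chartr("U", "T", m),
              substr(g, exact_at + 21, nchar(g)))
  # a copy with five substitutions must not be reported
  ch <- strsplit(chartr("U", "T", m), "")[[1]]
  for (p in c(2, 6, 10, 14, 18))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  g <- paste0(substr(g, 1, 9999), paste(ch, collapse = ""),
              substr(g, 10021, nchar(g)))
  genome <- Biostrings::DNAStringSet(c(fchr = g))
  hits <- find_near_matches(m, genome, max_mm = 4L)
  expect_true(any(hits$start == exact_at & hits$mismatches == 0))
  expect_false(any(hits$start == 10000))
})

test_that("near-match search agrees with the brute-force Hamming oracle", {
  set.seed(52)
  g <- random_dna(20000)
  m <- srnapipe:::random_mature(21, 0.5)
  # plant 0-, 2- and 4-mismatch copies, one antisense
  variant <- function(m, k) {
    ch <- strsplit(chartr("U", "T", m), "")[[1]]
    for (p in seq_len(k) * 4) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  ins <- function(g, s, at) paste0(substr(g, 1, at - 1), s,
                                   substr(g, at + nchar(s), nchar(g)))
  g <- ins(g, variant(m, 0), 2000)
  g <- ins(g, variant(m, 2), 8000)
  g <- ins(g, rc_chr(variant(m, 4)), 14000)
  genome <- Biostrings::DNAStringSet(c(fchr = g))
  got <- find_near_matches(m, genome, max_mm = 4L)
  got <- got[order(got$strand, got$start), c("start", "end", "strand",
                                             "mismatches")]
  rownames(got) <- NULL
  want <- brute_hamming_scan(m, g, 4L)
  expect_equal(got, want)
})

test_that("flanking windows are asymmetric, strand-mirrored and clipped", {
  set.seed(53)
  g <- random_dna(5000)
  genome <- Biostrings::DNAStringSet(c(fchr = g))
  hit <- data.frame(chrom = "fchr", start = 2000L, end = 2020L,
                    strand = "+", mismatches = 0L, stringsAsFactors = FALSE)
  w <- extract_windows(hit, genome)
  expect_equal(length(w), 2L)
  expect_equal(nchar(w[[1]]$sequence), 21L + 300L)
  expect_equal(nchar(w[[2]]$sequence), 21L + 300L)
  expect_equal(w[[1]]$gstart, 1950L); expect_equal(w[[1]]$gend, 2270L)
  expect_equal(w[[2]]$gstart, 1750L); expect_equal(w[[2]]$gend, 2070L)
  # the matched mature is where the window says it is
  expect_equal(substr(w[[1]]$sequence, w[[1]]$match_start, w[[1]]$match_end),
               normalize_rna(substr(g, 2000, 2020)))

  # minus-strand: windows are reverse-complemented with mirrored offsets
  hitm <- transform(hit, strand = "-")
  wm <- extract_windows(hitm, genome)
  expect_equal(substr(wm[[1]]$sequence, wm[[1]]$match_start,
                      wm[[1]]$match_end),
               normalize_rna(rc_chr(substr(g, 2000, 2020))))

  # a hit near the chromosome start is clipped at the origin
  hit0 <- data.frame(chrom = "fchr", start = 10L, end = 30L, strand = "+",
                     mismatches = 0L, stringsAsFactors = FALSE)
  w0 <- extract_windows(hit0, genome)
  expect_equal(w0[[1]]$gstart, 1L)
})

test_that("inverted repeats are detected in palindromic constructs only", {
  set.seed(54)
  stem <- random_dna(25)
  pal <- paste0(random_dna(60), stem, "AACAACAA", rc_chr(stem),
                random_dna(60))
  irs <- find_inverted_repeats(pal)
  expect_gte(nrow(irs), 1L)
  expect_gte(irs$identity[1], 0.7)
  # the reported arms cover the planted stem
  expect_lte(irs$arm1_start[1], 65)
  expect_gte(irs$arm2_end[1], 61 + 25 + 8 + 20)

  # two planted non-overlapping palindromes give two repeats
  stem2 <- random_dna(22)
  two <- paste0(random_dna(40), stem, "AACAACAA", rc_chr(stem),
                random_dna(80), stem2, "CCACCACC", rc_chr(stem2),
                random_dna(40))
  irs2 <- find_inverted_repeats(two)
  expect_gte(nrow(irs2), 2L)

  # random high-entropy windows stay clean at the thresholds
  hits <- vapply(1:100, function(i) {
    nrow(find_inverted_repeats(random_dna(300)))
  }, integer(1))
  expect_equal(sum(hits > 0), 0L)
})

test_that("conservation calls require hairpin context around the match", {
  scn <- small_scenario()
  built <- build_genome(scn)
  set.seed(55)
  fg <- random_dna(30000)
  ins <- function(g, s, at) paste0(substr(g, 1, at - 1), s,
                                   substr(g, at + nchar(s), nchar(g)))
  # a full planted precursor: conserved
  fg <- ins(fg, chartr("U", "T", built$truth$precursor[1]), 10000)
  # a bare mature copy inside a non-folding A/T-rich desert: not conserved
  desert <- paste0(strrep("AT", 150), chartr("U", "T", built$truth$mature[2]),
                   strrep("TA", 150))
  fg <- ins(fg, desert, 20000)
  genome <- Biostrings::DNAStringSet(c(fchr = fg))
  cons <- scan_conservation(
    stats::setNames(built$truth$mature[1:2], c("hpA", "hpB")), genome)
  consA <- cons[cons$mirna == "hpA" & cons$mismatches == 0, ]
  expect_true(all(consA$conserved))
  consB <- cons[cons$mirna == "hpB", ]
  expect_false(any(consB$conserved))
})

test_that("conservation is symmetric under genome reverse complementation", {
  scn <- small_scenario()
  built <- build_genome(scn)
  set.seed(56)
  fg <- random_dna(12000)
  fg <- paste0(substr(fg, 1, 3999), chartr("U", "T", built$truth$precursor[1]),
               substr(fg, 4000 + nchar(built$truth$precursor[1]), 12000))
  fwd <- Biostrings::DNAStringSet(c(fchr = fg))
  rev <- Biostrings::DNAStringSet(c(fchr = rc_chr(fg)))
  m <- stats::setNames(built$truth$mature[1], "q")
  c1 <- scan_conservation(m, fwd)
  c2 <- scan_conservation(m, rev)
  expect_equal(nrow(c1), nrow(c2))
  expect_equal(sort(c1$mismatches), sort(c2$mismatches))
  expect_equal(sum(c1$conserved), sum(c2$conserved))
})
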