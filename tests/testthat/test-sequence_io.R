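test_that("collapse_reads merges identical sequences and enforces length bounds", {
  r21 <- "UGACUAGGCUAAUCGGAAUCC"
  lib <- collapse_reads(rep(r21, 3), "seed")
  expect_equal(lib$unique_reads, 1L)
  expect_equal(lib$total_reads, 3L)
  expect_equal(lib$reads$count, 3L)

  empty <- collapse_reads(character(0), "seed")
  expect_equal(empty$unique_reads, 0L)
  expect_equal(empty$total_reads, 0L)

  # one 17-nt and one 31-nt record with the 18-30 analysis bounds
  out <- collapse_reads(c(strrep("A", 17), strrep("C", 31)), "seed")
  expect_equal(out$unique_reads, 0L)

  # gel preset admits 16-17 nt
  gel <- collapse_reads(strrep("ACGU", 4), "seed", length_preset = "gel")
  expect_equal(gel$unique_reads, 1L)
})

test_that("collapse_reads normalizes T to U and rejects bad records with a warning", {
  lib <- collapse_reads(c("TGACTAGGCTAATCGGAATCC", "UGACUAGGCUAAUCGGAAUCC"),
                        "x")
  expect_equal(lib$unique_reads, 1L)
  expect_equal(lib$reads$sequence, "UGACUAGGCUAAUCGGAAUCC")

  expect_warning(lib2 <- collapse_reads(c("UGACUAGGCUAAUCGGAAUCC",
                                          "UGACUAGGCUAANCGGAAUCC"), "x"),
                 "non-nucleotide")
  expect_equal(lib2$total_reads, 1L)
})

test_that("collapsing is order-invariant", {
  set.seed(3)
  recs <- replicate(60, random_dna(sample(18:30, 1)))
  recs <- sample(rep(recs, sample(1:4, 60, TRUE)))
  a <- collapse_reads(recs, "x")
  b <- collapse_reads(sample(recs), "x")
  expect_identical(a, b)
})

test_that("length_distribution computes exact fractions that sum to one", {
  lib <- read_library(c(strrep("A", 24), strrep("C", 21)), c(7L, 3L), "x")
  d <- length_distribution(lib)
  expect_equal(d$total_fraction[d$length == 24], 0.7)
  expect_equal(d$unique_fraction[d$length == 24], 0.5)
  expect_equal(d$total_fraction[d$length == 21], 0.3)
  expect_equal(sum(d$total_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(d$unique_fraction), 1, tolerance = 1e-9)

  single <- read_library(strrep("G", 22), 5L, "x")
  ds <- length_distribution(single)
  expect_equal(ds$total_fraction, 1)
  expect_equal(ds$unique_fraction, 1)

  expect_error(length_distribution(collapse_reads(character(0), "x")),
               "empty")
})

test_that("histogram totals are conserved and generator length bias shows up", {
  scn <- small_scenario()
  built <- build_genome(scn)
  libs <- simulate_reads(scn, built)
  d <- length_distribution(libs$seed)
  # conservation of totals
  tot <- sum(libs$seed$reads$count)
  expect_equal(sum(d$total_fraction) * libs$seed$total_reads, tot)
  # 24-nt class carries weight 0.5 of the background; the planted 21-nt
  # matures shift mass, so only check that 24 nt dominates the background
  bg_frac <- d$unique_fraction[d$length == 24]
  expect_gt(bg_frac, d$unique_fraction[d$length == 23])
})

test_that("FASTA, FASTQ and collapsed-FASTA round-trip correctly", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "x.fasta")
  seqs <- c(x = "ACGT")
  write_fasta(seqs, f)
  back <- read_fasta(f, rna = FALSE)
  expect_identical(back, c(x = "ACGT"))

  set.seed(4)
  many <- setNames(replicate(100, random_dna(sample(18:30, 1))),
                   sprintf("s%03d", 1:100))
  write_fasta(many, f)
  expect_identical(read_fasta(f, rna = FALSE), many)

  # collapsed dialect keeps counts
  lib <- read_library(c(strrep("A", 20), "UGACUAGGCUAAUCGGAAUCC"),
                      c(4L, 9L), "seed")
  cf <- file.path(tmp, "lib.fasta")
  write_collapsed_fasta(lib, cf)
  lib2 <- read_collapsed_fasta(cf, "seed")
  expect_identical(lib, lib2)

  # FASTQ: sequences parsed, malformed quality detected with line number
  fq <- file.path(tmp, "r.fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACG", "+", strrep("I", 19)), fq)
  expect_equal(read_fastq(fq), "ACGUACGUACGUACGUACG")
  writeLines(c("@r1", "ACGT", "+", "III"), fq)
  expect_error(read_fastq(fq), "line 4")
  writeLines(c("r1", "ACGT", "+", "IIII"), fq)
  expect_error(read_fastq(fq), "malformed header")
})

test_that("GFF3 written intervals survive a round trip", {
  tmp <- withr::local_tempdir()
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 500), c(10, 900)),
                               type = c("gene", "exon"))
  f <- file.path(tmp, "a.gff3")
  rtracklayer::export(gr, f, format = "gff3")
  back <- read_gff3(f)
  expect_equal(GenomicRanges::start(back), c(1, 500))
  expect_equal(GenomicRanges::end(back), c(10, 900))
  expect_equal(as.character(back$type), c("gene", "exon"))
})
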