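perfect_site <- function(m) as.character(
  Biostrings::reverseComplement(Biostrings::RNAString(m)))

# flip the site base facing miRNA position p to a non-pairing base
mm_site <- function(m, positions, wobble = FALSE) {
  srnapipe:::edit_site(m, positions, prefer_wobble = wobble)
}

test_that("duplex evaluation scores positions from the miRNA 5' end", {
  m <- "UGGAGAAGCAGGGCACGUGCA"
  ev <- evaluate_duplex(m, perfect_site(m))
  expect_equal(ev$mismatch_total, 0L)
  expect_true(ev$basic_positional_pass)
  expect_true(all(ev$states == "match"))

  # single mismatch at position 10 violates the cleavage-site rule
  ev10 <- evaluate_duplex(m, mm_site(m, 10))
  expect_false(ev10$positions_10_11_clean)
  expect_false(ev10$basic_positional_pass)

  # mismatches at 5,6,7: a run of three inside positions 2-12
  ev567 <- evaluate_duplex(m, mm_site(m, c(5, 6, 7)))
  expect_equal(ev567$max_consecutive_mismatches_2_12, 3L)
  expect_false(ev567$basic_positional_pass)

  # G:U wobble counts as a mismatch for the positional rules
  gpos <- which(strsplit(m, "")[[1]] == "G")[1]
  evw <- evaluate_duplex(m, mm_site(m, gpos, wobble = TRUE))
  expect_equal(evw$wobble_total, 1L)
  expect_equal(evw$mismatch_total, 1L)

  expect_error(evaluate_duplex(m, substr(perfect_site(m), 1, 10)), "length")
})

test_that("MFE ratio is 1 for the perfect complement and below for impaired sites", {
  m <- "UGGAGAAGCAGGGCACGUGCA"
  expect_equal(mfe_ratio(m, perfect_site(m)), 1)
  r3 <- mfe_ratio(m, mm_site(m, c(9, 10, 11)))
  expect_lt(r3, 1)
  # adding mismatches to a site never increases the ratio
  r1 <- mfe_ratio(m, mm_site(m, 10))
  expect_lte(r3, r1)
  expect_lte(r1, 1)
})

test_that("strict filter requires clean 2-12 and no adjacent mismatches", {
  m <- "UGGAGAAGCAGGGCACGUGCA"
  expect_true(strict_filter(evaluate_duplex(m, mm_site(m, c(15, 18)))))
  expect_false(strict_filter(evaluate_duplex(m, mm_site(m, 7))))
  expect_false(strict_filter(evaluate_duplex(m, mm_site(m, c(14, 15)))))
})

test_that("predict_targets finds planted sites and honors the rules", {
  set.seed(31)
  m <- srnapipe:::random_mature(21, 0.5)
  tx <- c(good = paste0(normalize_rna(random_dna(120)), perfect_site(m),
                        normalize_rna(random_dna(120))),
          four = paste0(normalize_rna(random_dna(120)),
                        mm_site(m, c(5, 8, 15, 18)),
                        normalize_rna(random_dna(120))))
  p <- predict_targets(m, tx)
  expect_true(any(p$transcript == "good" & p$start == 121))
  expect_equal(p$ratio[p$transcript == "good" & p$start == 121], 1)
  # a 4-mismatch best site yields no prediction
  expect_false(any(p$transcript == "four"))
})

test_that("prediction does not cross transcript boundaries", {
  set.seed(32)
  m <- srnapipe:::random_mature(21, 0.5)
  site <- perfect_site(m)
  # split the site across two transcripts: no window may recover it
  tx <- c(a = paste0(normalize_rna(random_dna(50)), substr(site, 1, 10)),
          b = paste0(substr(site, 11, 21), normalize_rna(random_dna(50))))
  p <- predict_targets(m, tx)
  expect_equal(nrow(p), 0L)
  # whereas the concatenated sequence does contain it
  p2 <- predict_targets(m, c(ab = paste0(tx[["a"]], tx[["b"]])))
  expect_true(any(p2$start == 51))
})

test_that("the scanner agrees exactly with the exhaustive per-window oracle", {
  set.seed(33)
  m <- srnapipe:::random_mature(21, 0.5)
  tx <- setNames(replicate(12, normalize_rna(random_dna(400))),
                 sprintf("t%02d", 1:12))
  # plant sites of varying quality
  plant <- function(t, site, at) paste0(substr(t, 1, at - 1), site,
                                        substr(t, at + nchar(site), nchar(t)))
  tx[1] <- plant(tx[1], perfect_site(m), 100)
  tx[2] <- plant(tx[2], mm_site(m, c(14, 15), wobble = TRUE), 200)
  tx[3] <- plant(tx[3], mm_site(m, 10), 150)
  tx[4] <- plant(tx[4], mm_site(m, c(5, 9, 15), wobble = TRUE), 50)

  want <- brute_positional_scan(m, tx)
  # compare against the scanner with the energy criterion disabled
  got <- predict_targets(m, tx, min_ratio = -Inf)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$transcript, want$transcript)
  expect_equal(got$start, want$start)
  expect_equal(got$mismatches, want$mismatches)
  # and with the energy criterion on, predictions are a subset
  got_full <- predict_targets(m, tx)
  expect_true(all(paste(got_full$transcript, got_full$start) %in%
                    paste(got$transcript, got$start)))
  # strict passes are a subset of basic passes by construction
  expect_true(all(got_full$strict_pass %in% c(TRUE, FALSE)))
  expect_true(all(got_full$mismatches <= 3L))
})

test_that("designed site patterns meet their ground-truth positional outcomes", {
  scn <- scenario(seed = 41)
  set.seed(41)
  matures <- setNames(replicate(2, srnapipe:::random_mature(21, 0.5)),
                      c("mA", "mB"))
  tt <- make_target_transcripts(scn, matures)
  for (i in seq_len(nrow(tt$truth))) {
    row <- tt$truth[i, ]
    site <- substr(tt$transcripts[[row$transcript]], row$site_start,
                   row$site_end)
    ev <- evaluate_duplex(matures[[row$mirna]], site)
    expect_equal(ev$basic_positional_pass, row$expected_positional,
                 info = row$transcript)
    expect_equal(strict_filter(ev), row$expected_strict,
                 info = row$transcript)
  }
})
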