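test_that("synthetic transcriptome embeds precursors at their printed coordinates", {
  fb <- fixtures_once()
  spec <- simulationSpec(seed = 5L, nDecoyTranscripts = 0L)
  tx <- buildTranscriptome(fb, spec)
  expect_equal(nrow(tx), 14L)
  pre2062 <- fb@precursors$sequence[fb@precursors$name == "Hvi-miR2062"]
  host <- tx[tx$id == "host_Hvi-miR2062", ]
  expect_equal(as.integer(regexpr(pre2062, host$seq, fixed = TRUE)), 147L)
  expect_match(host$desc, "Gamma amino butyric acid receptor")
  # every precursor is recoverable by substring extraction at its offset
  for (i in seq_len(14)) {
    pre <- fb@precursors$sequence[i]
    hseq <- tx$seq[tx$id == paste0("host_", fb@precursors$name[i])]
    start <- fb@origins$start[match(fb@precursors$name[i],
                                    fb@origins$name)]
    expect_equal(substr(hseq, start, start + nchar(pre) - 1L), pre)
  }
  # same seed, same bytes
  expect_identical(tx, buildTranscriptome(fb, spec))
})

test_that("decoy transcripts contain no precursor", {
  fb <- fixtures_once()
  spec <- simulationSpec(seed = 9L, nDecoyTranscripts = 6L,
                         decoyLengthRange = c(200L, 400L))
  tx <- buildTranscriptome(fb, spec)
  decoys <- tx$seq[grepl("^decoy_", tx$id)]
  expect_length(decoys, 6L)
  for (d in decoys)
    expect_false(any(vapply(fb@precursors$sequence, grepl, logical(1),
                            x = d, fixed = TRUE)))
})

test_that("reference sets respect the exclusion distance and the inclusion flag", {
  fb <- fixtures_once()
  refs <- makeReferenceSet(fb, includeNovel = FALSE, nConserved = 25L,
                           seed = 4L)
  expect_equal(nrow(refs), 25L)
  expect_true(all(nchar(refs$seq) %in% 21:23))
  # all-pairs scan: no packaged mature within 2 mismatches of any entry
  for (m in fb@matures$sequence) {
    d <- vapply(refs$seq, miRquarry:::placement_mismatches, numeric(1),
                b = m)
    expect_true(all(d >= 3))
  }
  withnovel <- makeReferenceSet(fb, includeNovel = TRUE, nConserved = 5L,
                                seed = 4L)
  expect_true(all(fb@matures$sequence %in% withnovel$seq))
  none <- makeReferenceSet(fb, includeNovel = FALSE, nConserved = 0L)
  expect_equal(nrow(none), 0L)
})

test_that("contaminant sets avoid mature 22-mers and are reproducible", {
  fb <- fixtures_once()
  cont <- makeContaminantSet(fb, 5L, seed = 2L)
  expect_equal(nrow(cont), 5L)
  expect_true(all(nchar(cont$seq) >= 60 & nchar(cont$seq) <= 120))
  for (s in cont$seq)
    expect_false(any(vapply(fb@matures$sequence, grepl, logical(1), x = s,
                            fixed = TRUE)))
  expect_identical(cont, makeContaminantSet(fb, 5L, seed = 2L))
})

test_that("simulated reads realize the abundance plan exactly, with labels", {
  fb <- fixtures_once()
  plan <- data.frame(name = c("Hvi-miR29828", "Hvi-miR2062"),
                     mature_count = c(12L, 7L), star_count = c(5L, 0L))
  spec <- simulationSpec(seed = 6L, abundancePlan = plan,
                         backgroundReads = 9L, contaminantReads = 4L)
  tx <- buildTranscriptome(fb, spec)
  hps <- hairpinsFromFixtures(fb, tx)
  cont <- makeContaminantSet(fb, 3L, seed = 6L)
  reads <- simulateReads(fb, hps, spec, cont)
  expect_length(reads, 12L + 5L + 7L + 9L + 4L)
  tab <- table(reads@label)
  expect_equal(unname(tab[["Hvi-miR29828|mature"]]), 12L)
  expect_equal(unname(tab[["Hvi-miR29828|star"]]), 5L)
  expect_equal(unname(tab[["Hvi-miR2062|mature"]]), 7L)
  expect_equal(unname(tab[["background|random"]]), 9L)
  # raw reads carry the fixed read length and the adapter
  expect_true(all(nchar(reads@seq) == spec$readLength))
  # empty plan, no background or contaminants: empty FASTQ
  empty <- simulateReads(fb, hps, simulationSpec(seed = 6L))
  expect_length(empty, 0L)
  # determinism
  expect_identical(as.data.frame(reads),
                   as.data.frame(simulateReads(fb, hps, spec, cont)))
})
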