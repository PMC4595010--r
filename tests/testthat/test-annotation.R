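test_that("conservation calls follow the placement mismatch rule", {
  refs <- data.frame(id = c("r1", "r2"),
                     seq = c("ugcaacaguucuggcuuggcaa",
                             "uuuguucugaauggcacgucgg"),
                     stringsAsFactors = FALSE)
  hit <- classifyConservation("ugcaacaguucuggcuuggcaa", refs)
  expect_equal(hit$status, "conserved")
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$best_reference, "r1")
  # three substitutions: novel under the 2-mismatch allowance
  q3 <- "agcaacaguucuggcuuggcag"
  q3 <- sub("^u", "a", "ugcaacaguucuggcuuggcaa")
  substr(q3, 10, 10) <- "a"
  substr(q3, 15, 15) <- "a"
  call3 <- classifyConservation(q3, refs)
  expect_equal(call3$status, "novel")
  expect_gte(call3$mismatches, 3L)
  # empty reference set
  none <- classifyConservation(q3, refs[0, ])
  expect_equal(none$status, "novel")
  expect_true(is.na(none$best_reference))
})

test_that("placement mismatch count is symmetric for equal lengths", {
  set.seed(41)
  for (rep in 1:30) {
    a <- random_seq(22)
    b <- random_seq(22)
    expect_equal(miRquarry:::placement_mismatches(a, b),
                 miRquarry:::placement_mismatches(b, a))
  }
})

test_that("5' nucleotide tallies are order-invariant and conserve the input size", {
  expect_equal(fivePrimeSummary(character(0)),
               c(a = 0L, c = 0L, g = 0L, u = 0L))
  seqs <- c("uggc", "aggc", "uccg", "gacu", "cacu")
  t1 <- fivePrimeSummary(seqs)
  expect_equal(sum(t1), length(seqs))
  expect_equal(t1, fivePrimeSummary(rev(seqs)))
  expect_equal(unname(t1["u"]), 2L)
})

test_that("origin keyword cascade is ordered and rolls up transposable elements", {
  expect_equal(annotateOrigin("x", "Gamma amino butyric acid receptor")$category,
               "named_gene")
  tc3 <- annotateOrigin("x", "TC3 type transposable element")
  expect_equal(tc3$category, "tc3_transposable_element")
  expect_true(tc3$transposable)
  retro <- annotateOrigin("x", "Retro transposable element")
  expect_equal(retro$category, "retrotransposon")
  expect_true(retro$transposable)
  expect_equal(annotateOrigin("x", "Transposable element")$category,
               "transposable_element")
  expect_equal(annotateOrigin("x", "Uncharacterized protein")$category,
               "uncharacterized")
  expect_equal(annotateOrigin("x", "")$category, "uncharacterized")
})

test_that("quantification honours the cutoff boundary and conserves reads", {
  sc <- table5_scenario()
  # at cutoff 1 the full table is present; a planned miRNA pushed under 10
  # total reads disappears at cutoff 10 but stays at cutoff 1
  fb <- sc$fb
  small_plan <- data.frame(name = c("Hvi-miR41359", "Hvi-miR29828"),
                           mature_count = c(5L, 30L),
                           star_count = c(4L, 10L))
  spec <- simulationSpec(seed = 55L, nDecoyTranscripts = 0L,
                         abundancePlan = small_plan)
  tx <- buildTranscriptome(fb, spec)
  hps <- hairpinsFromFixtures(fb, tx)
  reads <- simulateReads(fb, hps, spec)
  proc <- processReads(reads, NULL,
                       pipelineConfig(minLen = 18L, maxLen = 30L))
  hits <- mapReads(proc$reads, tx, 0L)
  q10 <- quantifyAbundance(hits, proc$reads, hps, cutoff = 10L,
                           tolerance = 0L)
  q1 <- quantifyAbundance(hits, proc$reads, hps, cutoff = 1L,
                          tolerance = 0L)
  expect_false("Hvi-miR41359" %in% q10$records$name)
  expect_true("Hvi-miR41359" %in% q1$records$name)
  expect_equal(q1$records$total[q1$records$name == "Hvi-miR41359"], 9L)
  # raising the cutoff never increases the number of records
  ns <- vapply(c(1L, 5L, 10L, 50L, 500L), function(k)
    nrow(quantifyAbundance(sc$hits, sc$proc$reads, sc$hps, cutoff = k,
                           tolerance = 0L)$records), integer(1))
  expect_true(all(diff(ns) <= 0))
  # assigned + unassigned equals the mapped total
  sense <- sc$hits[sc$hits$strand == "sense", ]
  mapped <- sum(sc$proc$reads@count[sc$proc$reads@id %in% sense$read_id])
  q <- sc$quant
  expect_equal(sum(q$records$total) + q$unassigned, mapped)
})

test_that("random abundance plans are recovered exactly through the pipeline", {
  fb <- fixtures_once()
  set.seed(77)
  for (rep in 1:2) {
    nm <- sample(fb@abundance$name, 5L)
    plan <- data.frame(name = nm,
                       mature_count = sample(0:300, 5L, replace = TRUE),
                       star_count = sample(0:150, 5L, replace = TRUE))
    spec <- simulationSpec(seed = 900L + rep, nDecoyTranscripts = 2L,
                           abundancePlan = plan, backgroundReads = 40L)
    tx <- buildTranscriptome(fb, spec)
    hps <- hairpinsFromFixtures(fb, tx)
    reads <- simulateReads(fb, hps, spec)
    proc <- processReads(reads, NULL,
                         pipelineConfig(minLen = 18L, maxLen = 30L))
    hits <- mapReads(proc$reads, tx, 0L)
    q <- quantifyAbundance(hits, proc$reads, hps, cutoff = 0L,
                           tolerance = 0L)
    got <- q$records[match(plan$name, q$records$name), ]
    expect_equal(got$mature_reads, plan$mature_count)
    expect_equal(got$star_reads, plan$star_count)
  }
})
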