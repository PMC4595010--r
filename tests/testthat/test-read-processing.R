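TRUSEQ <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming recovers the insert and rejects adapter-only reads", {
  mature <- "ugcaacaguucuggcuuggcaa"
  raw <- paste0(mature, substr(normalizeRNA(TRUSEQ), 1, 14))
  reads <- smallRNAReads(id = c("good", "adapter_only", "no_adapter"),
                         seq = c(raw, normalizeRNA(TRUSEQ),
                                 strrep("ac", 18)))
  out <- trimAdapter(reads, TRUSEQ)
  expect_equal(out$kept@id, "good")
  expect_equal(out$kept@seq, mature)
  expect_setequal(out$rejected@id, c("adapter_only", "no_adapter"))
  # multiset conservation
  expect_equal(length(out$kept) + length(out$rejected), length(reads))
})

test_that("length filtering applies inclusive bounds", {
  reads <- smallRNAReads(id = c("a", "b", "c"),
                         seq = c(strrep("u", 22), strrep("u", 21),
                                 strrep("a", 24)))
  paper <- filterByLength(reads, 22L, 22L)
  expect_equal(paper$kept@id, "a")
  expect_setequal(paper$removed@id, c("b", "c"))
  general <- filterByLength(reads, 18L, 26L)
  expect_length(general$kept, 3L)
  expect_equal(sum(paper$kept@count) + sum(paper$removed@count),
               sum(reads@count))
})

test_that("collapsing merges identical sequences and conserves counts", {
  reads <- smallRNAReads(id = c("r3", "r1", "r2", "r4"),
                         seq = c("acgu", "acgu", "acgu", "ggcc"))
  col <- collapseReads(reads)
  expect_length(col, 2L)
  expect_equal(col@count[col@seq == "acgu"], 3L)
  expect_equal(col@id[col@seq == "acgu"], "r1") # smallest member id
  expect_equal(sum(col@count), sum(reads@count))
  expect_length(collapseReads(smallRNAReads()), 0L)
})

test_that("contaminant filtering removes embedded reads and conserves the multiset", {
  cont <- data.frame(id = "rrna1",
                     seq = paste0(strrep("ga", 20), "ugcaacaguucuggcuuggcaa",
                                  strrep("cu", 20)),
                     stringsAsFactors = FALSE)
  reads <- smallRNAReads(id = c("inside", "outside", "rc_inside"),
                         seq = c("ugcaacaguucuggcuuggcaa",
                                 "uuuuggggccccaaaauuuugg",
                                 reverseComplementRNA(
                                   "ugcaacaguucuggcuuggcaa")))
  out <- filterContaminants(reads, cont)
  expect_setequal(out$removed@id, c("inside", "rc_inside"))
  expect_equal(out$kept@id, "outside")
  expect_equal(sum(out$kept@count) + sum(out$removed@count),
               sum(reads@count))
})

test_that("mapping agrees with a naive substring-scan oracle", {
  set.seed(31)
  for (rep in 1:12) {
    tx <- data.frame(id = c("t1", "t2"),
                     seq = c(random_seq(sample(80:300, 1)),
                             random_seq(sample(80:300, 1))),
                     stringsAsFactors = FALSE)
    # a read planted in t1 (twice for some repetitions), plus a random read
    insert <- random_seq(sample(8:12, 1))
    t1 <- paste0(substr(tx$seq[1], 1, 30), insert,
                 substr(tx$seq[1], 31, 60), insert,
                 substr(tx$seq[1], 61, nchar(tx$seq[1])))
    tx$seq[1] <- t1
    reads <- smallRNAReads(id = c("planted", "rand"),
                           seq = c(insert, random_seq(15)))
    hits <- mapReads(reads, tx, 0L)
    for (i in 1:2) {
      for (t in 1:2) {
        got <- hits[hits$read_id == reads@id[i] &
                      hits$transcript == tx$id[t], ]
        want <- naive_map_oracle(reads@seq[i], tx$seq[t])
        expect_equal(nrow(got), nrow(want))
        if (nrow(want)) {
          expect_equal(got$start, want$start[order(want$start)])
          expect_true(all(got$mismatches == 0L))
        }
      }
    }
  }
})

test_that("the mature of Hvi-miR2062 maps to its host transcript at the printed offset", {
  fb <- fixtures_once()
  tx <- buildTranscriptome(fb, simulationSpec(seed = 5L,
                                              nDecoyTranscripts = 0L))
  mat <- fb@matures$sequence[fb@matures$name == "Hvi-miR2062"]
  reads <- smallRNAReads(id = "q", seq = mat)
  hits <- mapReads(reads, tx, 0L)
  sense <- hits[hits$strand == "sense", ]
  # the mature is the precursor's prefix; the precursor is embedded at 147
  expect_true(any(sense$transcript == "host_Hvi-miR2062" &
                    sense$start == 147L))
  # a read absent from every transcript yields no hits
  none <- mapReads(smallRNAReads(id = "x", seq = strrep("augc", 6)), tx, 0L)
  expect_equal(nrow(none[none$strand == "sense", ]), 0L)
})

test_that("ground-truth reads survive processing and map to their hosts", {
  sc <- table5_scenario()
  # every planned mature/star read survives trimming, length filter and
  # contaminant filter...
  lab <- sc$proc$reads@label
  planned <- !is.na(lab) & grepl("^Hvi-", lab)
  expect_equal(sum(sc$proc$reads@count[planned]),
               sum(sc$fb@abundance$total))
  # ...and every planned sequence maps to its own host transcript
  sense <- sc$hits[sc$hits$strand == "sense", ]
  for (i in which(planned)) {
    nm <- sub("\\|.*$", "", lab[i])
    expect_true(any(sense$read_id == sc$proc$reads@id[i] &
                      sense$transcript == paste0("host_", nm)))
  }
})
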