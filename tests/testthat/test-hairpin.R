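test_that("base-pair maximization matches exhaustive enumeration", {
  expect_equal(-foldMaxPair("gggaaaccc")@energy, 3)
  open <- foldMaxPair("aaaa")
  expect_equal(open@dotbracket, "....")
  expect_equal(open@energy, 0)
  set.seed(71)
  for (rep in 1:40) {
    s <- random_seq(sample(6:11, 1))
    expect_equal(-foldMaxPair(s)@energy, max_pairs_oracle(s), info = s)
  }
})

test_that("MFE folding is self-consistent and bounded by enumerated structures", {
  expect_equal(foldMFE("aaaaaaaaaa")@dotbracket, "..........")
  expect_equal(foldMFE("aaaaaaaaaa")@energy, 0)
  set.seed(72)
  for (rep in 1:18) {
    s <- random_seq(sample(10:14, 1))
    f <- foldMFE(s)
    expect_equal(f@energy, evaluateEnergy(s, f), tolerance = 1e-6, info = s)
    for (pt in enumerate_structures(s)) {
      e <- evaluateEnergy(s, db_from_pt(pt))
      expect_gte(e, f@energy - 1e-6)
    }
  }
})

test_that("the structure evaluator reproduces a hand-summed energy", {
  # gcgcaaaagcgc folded ((((....)))): three stacks read off the packaged
  # table (gc on cg -3.40, cg on gc -2.40, gc on cg -3.40), a 4-nt hairpin
  # loop (+5.60), no AU/GU helix ends: total -3.60
  expect_equal(evaluateEnergy("gcgcaaaagcgc", "((((....))))"), -3.6,
               tolerance = 1e-9)
  expect_equal(evaluateEnergy("acguacgu", "........"), 0)
  # an all-GC stem is more stable than the same shape in AU
  shape <- "((((((....))))))"
  e_gc <- evaluateEnergy("ggggggaaaacccccc", shape)
  e_au <- evaluateEnergy("aaaaaagaaguuuuuu", shape)
  expect_lt(e_gc, e_au)
  # length mismatch and unpairable pairings are rejected
  expect_error(evaluateEnergy("acgu", "((((....))))"), "length")
  expect_error(evaluateEnergy("ccccaaaacccc", "((((....))))"),
               "non-pairable")
})

test_that("terminal loop counting works on toy and printed structures", {
  expect_equal(countTerminalLoops("((((...))))"), 1L)
  expect_equal(countTerminalLoops("((..))..((..))"), 2L)
  fb <- fixtures_once()
  st <- function(nm) fb@structures$structure[fb@structures$name == nm]
  expect_equal(countTerminalLoops(st("Hvi-miR2062")), 1L)
  expect_equal(countTerminalLoops(st("Hvi-miR9237")), 2L)
})

test_that("precursor windows flank each occurrence on both arms", {
  fb <- fixtures_once()
  mat <- fb@matures$sequence[fb@matures$name == "Hvi-miR2062"]
  pre <- fb@precursors$sequence[fb@precursors$name == "Hvi-miR2062"]
  # the mature is the precursor's prefix: occurrence at [1, 22]
  win <- locatePrecursor(mat, pre, flank = 70L)
  expect_equal(nrow(win), 2L)
  expect_equal(win$mature_start + win$window_start - 1L, c(1L, 1L))
  expect_equal(win$window_end[1], nchar(pre)) # clipped to the transcript
  expect_equal(nrow(locatePrecursor("acgugcaugcaugcaugcaugc", pre)), 0L)
  twice <- paste0(strrep("g", 30), mat, strrep("c", 30), mat,
                  strrep("g", 30))
  expect_equal(nrow(locatePrecursor(mat, twice)), 4L)
})

test_that("hairpin evaluation reports violated criteria and is monotone", {
  fb <- fixtures_once()
  pre <- fb@precursors$sequence[fb@precursors$name == "Hvi-miR29035"]
  db <- fb@structures$structure[fb@structures$name == "Hvi-miR29035"]
  mat <- fb@matures$sequence[fb@matures$name == "Hvi-miR29035"]
  ms <- as.integer(regexpr(mat, pre, fixed = TRUE))
  span <- c(ms, ms + 21L)
  ev <- evaluateHairpin(pre, db, span,
                        hairpinCriteria(minMatchedPairs = 15L,
                                        maxTerminalLoops = 1L,
                                        maxEnergy = 0))
  expect_true(ev$pass)
  nopairs <- evaluateHairpin("aaaacccgggaaaggg", strrep(".", 16), c(1L, 4L))
  expect_false(nopairs$pass)
  expect_true("min_matched_pairs" %in% nopairs$reasons)
  # tightening any threshold can only shrink the pass set
  loose <- hairpinCriteria(minMatchedPairs = 10L)
  tight <- hairpinCriteria(minMatchedPairs = 30L)
  for (i in seq_len(nrow(fb@precursors))) {
    p <- fb@precursors$sequence[i]
    d <- fb@structures$structure[match(fb@precursors$name[i],
                                       fb@structures$name)]
    m <- fb@matures$sequence[match(fb@precursors$name[i],
                                   fb@matures$name)]
    s <- as.integer(regexpr(m, p, fixed = TRUE))
    if (evaluateHairpin(p, d, c(s, s + 21L), tight)$pass)
      expect_true(evaluateHairpin(p, d, c(s, s + 21L), loose)$pass)
  }
  expect_error(evaluateHairpin(pre, db, c(0L, 21L)), "outside")
})

test_that("star inference obeys the 2-nt 3' overhang rule on a perfect duplex", {
  arm <- "ggcaucgaucgauugcaucgga" # 22 nt
  hp <- perfect_hairpin(arm)
  hair <- hairpinPrecursor("toy", hp$seq, secondaryStructure(hp$db),
                           c(1L, 22L))
  st <- suppressWarnings(inferStar(hair))
  pt <- pairTableFromDotBracket(hp$db)
  # star 3' end sits 2 nt past the pairing partner of mature position 1
  expect_equal(st$star_span[2], pt[1] + 2L)
  # mature 3' end extends 2 nt past the partner of the star 5' end
  expect_equal(st$star_span[1], pt[22 - 2L])
  # with transcript context the overhang is resolved instead of clipped
  tseq <- paste0(hp$seq, "gcua")
  hair2 <- hairpinPrecursor("toy", hp$seq, secondaryStructure(hp$db),
                            c(1L, 22L), transcriptId = "t",
                            transcriptSpan = c(1L, nchar(hp$seq)))
  st2 <- inferStar(hair2, transcriptSeq = tseq)
  expect_equal(nchar(st2$star_seq), diff(st2$star_span) + 1L)
})

test_that("a 1-nt bulge on the mature arm shortens the star to 21 nt", {
  s1 <- "ggcaucgauc"            # 10 nt
  s2 <- "gcaucggcaug"           # 11 nt
  mature <- paste0(s1, "a", s2) # 22 nt, position 11 bulged
  pre <- paste0(mature, "gaaag", reverseComplementRNA(s2),
                reverseComplementRNA(s1))
  db <- paste0(strrep("(", 10), ".", strrep("(", 11), ".....",
               strrep(")", 11), strrep(")", 10))
  hp <- hairpinPrecursor("bulged", pre, secondaryStructure(db), c(1L, 22L))
  st <- suppressWarnings(inferStar(hp))
  expect_equal(diff(st$star_span) + 1L, 21L)
})

test_that("star inference fails cleanly when the mature arm is unpaired", {
  pre <- paste0("aaaaaaaa", "gggcaaagccc", "aaaa")
  db <- paste0("........", "(((.....)))", "....")
  hp <- hairpinPrecursor("flat", pre, secondaryStructure(db), c(1L, 6L))
  expect_error(inferStar(hp), "unpaired")
})

test_that("fixture stars are duplex-partner sized and never overlap the mature", {
  fb <- fixtures_once()
  tx <- buildTranscriptome(fb, simulationSpec(seed = 5L,
                                              nDecoyTranscripts = 0L))
  hps <- hairpinsFromFixtures(fb, tx)
  expect_length(hps, 14L)
  for (hp in hps) {
    ss <- hp@starSpan
    ms <- hp@matureSpan
    expect_length(ss, 2L)
    expect_true(ss[1] > ms[2] || ss[2] < ms[1])
    len <- ss[2] - ss[1] + 1L
    expect_gte(len, 20L)
    expect_lte(len, 27L)
    expect_equal(nchar(attr(hp, "star_seq")), len)
  }
})
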