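# Independent brute-force oracles and shared scenario builders.

BASES <- c("a", "c", "g", "u")

random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

enc_seq <- function(s) match(strsplit(s, "")[[1]], BASES)

pairable_bases <- function(a, b)
  paste0(a, b) %in% c("au", "ua", "gc", "cg", "gu", "ug")

db_from_pt <- function(pt) {
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(ch, collapse = "")
}

# Exhaustive enumeration of all nested structures (min hairpin loop 3)
# whose pairs are pairable for the given sequence.  Independent of the
# package's dynamic programmes.
enumerate_structures <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  res <- list()
  rec <- function(pt, i) {
    if (i > n) { res[[length(res) + 1L]] <<- pt; return(invisible()) }
    if (pt[i] != 0L) { rec(pt, i + 1L); return(invisible()) }
    rec(pt, i + 1L) # i unpaired
    for (j in seq_len(n)) {
      if (j <= i + 3L || pt[j] != 0L) next
      if (!pairable_bases(ch[i], ch[j])) next
      inner <- pt[(i + 1L):(j - 1L)]
      if (all(inner == 0L | (inner > i & inner < j))) {
        p2 <- pt; p2[i] <- j; p2[j] <- i
        rec(p2, i + 1L)
      }
    }
  }
  rec(integer(n), 1L)
  res
}

# maximum pair count over the enumerated structures
max_pairs_oracle <- function(seq) {
  max(vapply(enumerate_structures(seq), function(pt) sum(pt > 0L) %/% 2L,
             integer(1)))
}

# naive substring-scan mapping oracle (exact matches, both strands)
naive_map_oracle <- function(read, transcript) {
  hits <- data.frame(start = integer(), strand = character(),
                     stringsAsFactors = FALSE)
  L <- nchar(transcript); l <- nchar(read)
  rc <- reverseComplementRNA(read)
  for (p in seq_len(max(0L, L - l + 1L))) {
    frag <- substr(transcript, p, p + l - 1L)
    if (frag == read)
      hits <- rbind(hits, data.frame(start = p, strand = "sense",
                                     stringsAsFactors = FALSE))
    if (frag == rc)
      hits <- rbind(hits, data.frame(start = p, strand = "antisense",
                                     stringsAsFactors = FALSE))
  }
  hits
}

# duplex alignment enumeration oracle (shared ruleset, independent recursion)
duplex_score_oracle <- function(miRNA, window, scheme = scoringScheme()) {
  w <- c(match = scheme$match, gu = scheme$gu, mismatch = scheme$mismatch,
         gap_open = scheme$gapOpen, gap_extend = scheme$gapExtend,
         seed_scale = scheme$seedScale)
  miRquarry:::.duplex_enum_cpp(enc_seq(normalizeRNA(miRNA)),
                               enc_seq(reverseComplementRNA(
                                 normalizeRNA(window))),
                               w, scheme$seedScaleEnd)
}

# A perfect hairpin with given arm and loop sequences.
perfect_hairpin <- function(arm, loop = "gaaag") {
  list(seq = paste0(arm, loop, reverseComplementRNA(arm)),
       db = paste0(strrep("(", nchar(arm)), strrep(".", nchar(loop)),
                   strrep(")", nchar(arm))))
}

# Shared fixture bundle and, built once on demand, the full printed-count
# simulation scenario used by the abundance tests.
.scenario_cache <- new.env()

fixtures_once <- function() {
  if (is.null(.scenario_cache$fb)) .scenario_cache$fb <- loadFixtures()
  .scenario_cache$fb
}

table5_scenario <- function(seed = 101L) {
  key <- paste0("sc", seed)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  fb <- fixtures_once()
  spec <- simulationSpec(
    seed = seed, nDecoyTranscripts = 3L,
    abundancePlan = data.frame(name = fb@abundance$name,
                               mature_count = fb@abundance$mature_reads,
                               star_count = fb@abundance$star_reads),
    backgroundReads = 100L, contaminantReads = 60L)
  tx <- buildTranscriptome(fb, spec)
  hps <- hairpinsFromFixtures(fb, tx)
  cont <- makeContaminantSet(fb, 12L, seed = seed)
  reads <- simulateReads(fb, hps, spec, cont)
  cfg <- pipelineConfig(minLen = 18L, maxLen = 30L, armTolerance = 0L)
  proc <- processReads(reads, cont, cfg)
  hits <- mapReads(proc$reads, tx, 0L)
  quant <- quantifyAbundance(hits, proc$reads, hps, cutoff = 10L,
                             tolerance = 0L)
  sc <- list(fb = fb, spec = spec, tx = tx, hps = hps, cont = cont,
             reads = reads, proc = proc, hits = hits, quant = quant)
  .scenario_cache[[key]] <- sc
  sc
}
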