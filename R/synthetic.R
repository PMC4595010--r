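## Deterministic simulator: synthetic transcriptomes, reference mature sets,
## rRNA/tRNA-like contaminants and adapter-ligated small-RNA read pools with
## ground-truth labels, so every downstream stage is testable offline.

#' Simulation specification
#'
#' All knobs of the synthetic-data generator in one object.  With a fixed
#' seed every generated artifact is byte-identical across runs.
#'
#' @param seed integer RNG seed.
#' @param nDecoyTranscripts number of decoy transcripts.
#' @param decoyLengthRange integer(2), decoy length range in nt.
#' @param abundancePlan data.frame(name, mature_count, star_count); per-miRNA
#'   read counts to emit.
#' @param adapter 3' adapter sequence (DNA alphabet accepted; the packaged
#'   default is the TruSeq small-RNA 3' adapter).
#' @param backgroundReads number of random-sequence background reads.
#' @param contaminantReads number of reads drawn from the contaminant set.
#' @param readLength raw read length in nt before trimming (default 36).
#' @return Named list (class \code{"simulationSpec"}).
#' @export
simulationSpec <- function(seed = 1L, nDecoyTranscripts = 10L,
                           decoyLengthRange = c(300L, 800L),
                           abundancePlan = NULL,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           backgroundReads = 0L, contaminantReads = 0L,
                           readLength = 36L) {
  stopifnot(nDecoyTranscripts >= 0L, backgroundReads >= 0L,
            contaminantReads >= 0L, readLength > 0L,
            decoyLengthRange[1] <= decoyLengthRange[2])
  if (!is.null(abundancePlan))
    stopifnot(all(c("name", "mature_count", "star_count") %in%
                    colnames(abundancePlan)),
              all(abundancePlan$mature_count >= 0L),
              all(abundancePlan$star_count >= 0L))
  structure(list(seed = as.integer(seed),
                 nDecoyTranscripts = as.integer(nDecoyTranscripts),
                 decoyLengthRange = as.integer(decoyLengthRange),
                 abundancePlan = abundancePlan,
                 adapter = normalizeRNA(adapter),
                 backgroundReads = as.integer(backgroundReads),
                 contaminantReads = as.integer(contaminantReads),
                 readLength = as.integer(readLength)),
            class = "simulationSpec")
}

## Distinct deterministic sub-seed per generator stage, so that a single
## user-facing seed cannot make independent artifacts (transcript padding,
## contaminants, background reads) replay the same RNG stream.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000000L) + sum(utf8ToInt(stage)) * 1009L
}

## run expr under a locally-seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("a", "c", "g", "u"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Build a synthetic transcriptome around the packaged precursors
#'
#' One host transcript per packaged precursor: the precursor embedded
#' starting at its printed origin coordinate (1-based), padded left with
#' seeded random sequence up to that coordinate and right with random
#' sequence (at least 40 nt, so Dicer-duplex overhangs that reach past the
#' precursor stay on the transcript).  The transcript description carries
#' the printed origin text.  Decoy transcripts are random sequences
#' re-drawn until they contain none of the precursors.
#'
#' @param fixtures a [FixtureBundle-class].
#' @param spec a [simulationSpec()].
#' @return data.frame(id, seq, desc); host transcripts are named
#'   \code{host_<miRNA>}.
#' @export
buildTranscriptome <- function(fixtures, spec = simulationSpec()) {
  with_seed(stage_seed(spec$seed, "transcriptome"), {
    pre <- fixtures@precursors
    ori <- fixtures@origins[match(pre$name, fixtures@origins$name), ]
    hosts <- lapply(seq_len(nrow(pre)), function(i) {
      start <- ori$start[i]
      left <- if (start > 1L) random_rna(1, start - 1L) else ""
      right <- random_rna(1, 40L)
      data.frame(id = paste0("host_", pre$name[i]),
                 seq = paste0(left, pre$sequence[i], right),
                 desc = ori$origin[i], stringsAsFactors = FALSE)
    })
    decoys <- list()
    while (length(decoys) < spec$nDecoyTranscripts) {
      len <- sample(spec$decoyLengthRange[1]:spec$decoyLengthRange[2], 1)
      s <- random_rna(1, len)
      if (!any(vapply(pre$sequence, grepl, logical(1), x = s, fixed = TRUE)))
        decoys[[length(decoys) + 1L]] <-
          data.frame(id = paste0("decoy_", length(decoys) + 1L), seq = s,
                     desc = "uncharacterized", stringsAsFactors = FALSE)
    }
    do.call(rbind, c(hosts, decoys))
  })
}

#' Build a miRBase-like reference set of mature miRNAs
#'
#' \code{nConserved} random 21-23 nt sequences, each checked to lie at
#' least 3 mismatches (under the [classifyConservation()] placement rule)
#' from every packaged mature sequence, plus, when \code{includeNovel}, the
#' 14 packaged matures verbatim.
#'
#' @param fixtures a [FixtureBundle-class].
#' @param includeNovel include the packaged mature sequences.
#' @param nConserved number of random reference entries.
#' @param seed RNG seed.
#' @return data.frame(id, seq, desc).
#' @export
makeReferenceSet <- function(fixtures, includeNovel = FALSE,
                             nConserved = 50L, seed = 1L) {
  stopifnot(nConserved >= 0L)
  refs <- with_seed(stage_seed(seed, "reference"), {
    out <- character(0)
    while (length(out) < nConserved) {
      s <- random_rna(1, sample(21:23, 1))
      d <- min(vapply(fixtures@matures$sequence,
                      function(m) placement_mismatches(s, m), numeric(1)))
      if (d >= 3) out <- c(out, s)
    }
    out
  })
  df <- if (length(refs))
    data.frame(id = sprintf("ref-miR-%03d", seq_along(refs)), seq = refs,
               desc = "synthetic conserved reference",
               stringsAsFactors = FALSE)
  else data.frame(id = character(), seq = character(), desc = character(),
                  stringsAsFactors = FALSE)
  if (includeNovel)
    df <- rbind(df, data.frame(id = fixtures@matures$name,
                               seq = fixtures@matures$sequence,
                               desc = "packaged novel mature",
                               stringsAsFactors = FALSE))
  df
}

#' Build a synthetic rRNA/tRNA-like contaminant set
#'
#' \code{n} random 60-120 nt sequences, re-drawn until none contains any
#' packaged mature sequence as a substring.
#'
#' @param fixtures a [FixtureBundle-class].
#' @param n number of contaminant sequences.
#' @param seed RNG seed.
#' @return data.frame(id, seq, desc).
#' @export
makeContaminantSet <- function(fixtures, n = 20L, seed = 1L) {
  stopifnot(n >= 0L)
  with_seed(stage_seed(seed, "contaminants"), {
    out <- list()
    while (length(out) < n) {
      s <- random_rna(1, sample(60:120, 1))
      if (!any(vapply(fixtures@matures$sequence, grepl, logical(1), x = s,
                      fixed = TRUE)))
        out[[length(out) + 1L]] <-
          data.frame(id = sprintf("contaminant_%03d", length(out) + 1L),
                     seq = s, desc = "synthetic rRNA/tRNA",
                     stringsAsFactors = FALSE)
    }
    if (!length(out))
      return(data.frame(id = character(), seq = character(),
                        desc = character(), stringsAsFactors = FALSE))
    do.call(rbind, out)
  })
}

#' Simulate an adapter-ligated small-RNA read pool
#'
#' For each planned miRNA, emits exactly \code{mature_count} reads whose
#' insert is the mature sequence and \code{star_count} reads whose insert is
#' the star sequence inferred from its hairpin, each suffixed with the 3'
#' adapter and padded with \code{a} (the post-adapter tail) or truncated to
#' the fixed read length; plus random background reads (22-nt inserts) and
#' reads drawn as substrings of the contaminant set.  Read ids encode the
#' ground truth as \code{"<name>|<arm>|<serial>"}; output order is a seeded
#' permutation.
#'
#' @param fixtures a [FixtureBundle-class].
#' @param hairpins named list from [hairpinsFromFixtures()] (carries the
#'   inferred star sequences).
#' @param spec a [simulationSpec()]; \code{spec$abundancePlan} names must be
#'   packaged miRNA names.
#' @param contaminants data.frame from [makeContaminantSet()]; required when
#'   \code{spec$contaminantReads > 0}.
#' @return A [SmallRNAReads-class] object (one record per read, count 1).
#' @export
simulateReads <- function(fixtures, hairpins, spec = simulationSpec(),
                          contaminants = NULL) {
  plan <- spec$abundancePlan
  if (!is.null(plan)) {
    unknown <- setdiff(plan$name, fixtures@matures$name)
    if (length(unknown))
      stop("abundance plan names not in fixtures: ",
           paste(unknown, collapse = ", "))
  }
  if (spec$contaminantReads > 0L && is.null(contaminants))
    stop("contaminantReads > 0 but no contaminant set supplied")
  with_seed(stage_seed(spec$seed, "reads"), {
    ids <- character(0); inserts <- character(0); labels <- character(0)
    if (!is.null(plan)) {
      for (i in seq_len(nrow(plan))) {
        nm <- plan$name[i]
        mat <- fixtures@matures$sequence[match(nm, fixtures@matures$name)]
        if (plan$mature_count[i] > 0L) {
          k <- plan$mature_count[i]
          ids <- c(ids, sprintf("%s|mature|%d", nm, seq_len(k)))
          inserts <- c(inserts, rep(mat, k))
          labels <- c(labels, rep(paste0(nm, "|mature"), k))
        }
        if (plan$star_count[i] > 0L) {
          hp <- hairpins[[nm]]
          star <- if (!is.null(hp)) attr(hp, "star_seq") else NULL
          if (is.null(star))
            stop("star reads requested for '", nm,
                 "' but no star sequence is inferable")
          k <- plan$star_count[i]
          ids <- c(ids, sprintf("%s|star|%d", nm, seq_len(k)))
          inserts <- c(inserts, rep(star, k))
          labels <- c(labels, rep(paste0(nm, "|star"), k))
        }
      }
    }
    if (spec$backgroundReads > 0L) {
      k <- spec$backgroundReads
      ids <- c(ids, sprintf("background|random|%d", seq_len(k)))
      inserts <- c(inserts, random_rna(k, 22L))
      labels <- c(labels, rep("background|random", k))
    }
    if (spec$contaminantReads > 0L) {
      k <- spec$contaminantReads
      src <- sample(nrow(contaminants), k, replace = TRUE)
      len <- sample(20:24, k, replace = TRUE)
      start <- vapply(seq_len(k), function(i)
        sample(nchar(contaminants$seq[src[i]]) - len[i] + 1L, 1L), integer(1))
      ids <- c(ids, sprintf("contaminant|%s|%d", contaminants$id[src],
                            seq_len(k)))
      inserts <- c(inserts, substr(contaminants$seq[src], start,
                                   start + len - 1L))
      labels <- c(labels, rep("contaminant|rRNA_tRNA", k))
    }
    if (!length(ids)) return(smallRNAReads())
    raw <- paste0(inserts, spec$adapter,
                  strrep("a", spec$readLength))
    raw <- substr(raw, 1L, spec$readLength)
    ord <- sample(length(ids))
    smallRNAReads(id = ids[ord], seq = raw[ord],
                  qual = strrep("I", nchar(raw[ord])), label = labels[ord])
  })
}
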