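## Hairpin-precursor location, evaluation against the structural criteria,
## and star-strand inference from the Dicer duplex geometry.

#' Hairpin acceptance criteria
#'
#' The three structural criteria a candidate precursor must meet: a minimum
#' number of matched base pairs, a maximum number of terminal loops, and a
#' maximum folding energy.  Defaults are calibrated so that the packaged
#' precursor structures all pass under the packaged energy model (which
#' omits the stabilizing terminal-mismatch terms of mfold, so its energies
#' are milder); \code{preset = "paper"} applies the stated study thresholds
#' (18 pairs, one central loop, energy below -18 kcal/mol).
#'
#' @param minMatchedPairs minimum base-pair count (default 15).
#' @param maxTerminalLoops maximum terminal-loop count (default 2).
#' @param maxEnergy maximum (least negative) energy in kcal/mol (default -5).
#' @param preset \code{"default"} or \code{"paper"}.
#' @return Named list of the three thresholds.
#' @export
hairpinCriteria <- function(minMatchedPairs = 15L, maxTerminalLoops = 2L,
                            maxEnergy = -5, preset = c("default", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    minMatchedPairs <- 18L; maxTerminalLoops <- 1L; maxEnergy <- -18
  }
  stopifnot(minMatchedPairs >= 0L, maxTerminalLoops >= 1L)
  list(minMatchedPairs = as.integer(minMatchedPairs),
       maxTerminalLoops = as.integer(maxTerminalLoops),
       maxEnergy = as.numeric(maxEnergy))
}

#' Locate candidate precursor windows for a mature sequence
#'
#' For each exact occurrence of the mature in the transcript, two candidate
#' windows are emitted: the mature on the 5' arm (window extends
#' \code{flank} nt downstream) and on the 3' arm (window extends
#' \code{flank} nt upstream), clipped to the transcript.
#'
#' @param mature mature sequence (character or one-row data.frame with
#'   \code{seq}).
#' @param transcript transcript sequence (character or one-row data.frame
#'   with \code{id}, \code{seq}).
#' @param flank flank width in nt (default 70).
#' @return data.frame with one row per candidate window: \code{window_start},
#'   \code{window_end} (transcript coordinates), \code{residues},
#'   \code{mature_start}, \code{mature_end} (window coordinates) and
#'   \code{arm} ("5p" or "3p").
#' @export
locatePrecursor <- function(mature, transcript, flank = 70L) {
  mseq <- if (is.data.frame(mature)) mature$seq else normalizeRNA(mature)
  tseq <- if (is.data.frame(transcript)) transcript$seq
          else normalizeRNA(transcript)
  stopifnot(flank >= 0L)
  occ <- gregexpr(mseq, tseq, fixed = TRUE)[[1]]
  if (occ[1] == -1L)
    return(data.frame(window_start = integer(), window_end = integer(),
                      residues = character(), mature_start = integer(),
                      mature_end = integer(), arm = character(),
                      stringsAsFactors = FALSE))
  mlen <- nchar(mseq)
  tlen <- nchar(tseq)
  rows <- lapply(as.integer(occ), function(p) {
    e <- p + mlen - 1L
    w5 <- c(p, min(tlen, e + flank))
    w3 <- c(max(1L, p - flank), e)
    data.frame(window_start = c(w5[1], w3[1]), window_end = c(w5[2], w3[2]),
               residues = c(substr(tseq, w5[1], w5[2]),
                            substr(tseq, w3[1], w3[2])),
               mature_start = c(p - w5[1] + 1L, p - w3[1] + 1L),
               mature_end = c(e - w5[1] + 1L, e - w3[1] + 1L),
               arm = c("5p", "3p"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a candidate hairpin against the acceptance criteria
#'
#' Pass requires (a) base-pair count at or above \code{minMatchedPairs},
#' (b) terminal-loop count at or below \code{maxTerminalLoops}, and (c)
#' structure energy at or below \code{maxEnergy}.  Every violated criterion
#' is reported.
#'
#' @param residues candidate window sequence.
#' @param structure [SecondaryStructure-class] or dot-bracket string for the
#'   window.
#' @param matureSpan integer(2), mature span in window coordinates.
#' @param criteria list from [hairpinCriteria()].
#' @return list with \code{pass} (logical) and \code{reasons} (character
#'   vector of violated criteria, empty on pass), plus the measured
#'   \code{pairs}, \code{loops}, \code{energy}.
#' @export
evaluateHairpin <- function(residues, structure, matureSpan,
                            criteria = hairpinCriteria()) {
  s <- normalizeRNA(residues)
  if (is.character(structure))
    structure <- secondaryStructure(structure,
                                    evaluateEnergy(s, structure))
  if (matureSpan[1] < 1L || matureSpan[2] > nchar(s))
    stop("mature span outside candidate window")
  npairs <- sum(structure@pairTable > 0) %/% 2L
  nloops <- countTerminalLoops(structure)
  energy <- structure@energy
  reasons <- character(0)
  if (npairs < criteria$minMatchedPairs)
    reasons <- c(reasons, "min_matched_pairs")
  if (nloops > criteria$maxTerminalLoops)
    reasons <- c(reasons, "max_terminal_loops")
  if (energy > criteria$maxEnergy)
    reasons <- c(reasons, "max_energy")
  list(pass = length(reasons) == 0L, reasons = reasons, pairs = npairs,
       loops = nloops, energy = energy)
}

#' Infer the star strand from the duplex geometry
#'
#' The star span is the segment pairing with the mature arm, positioned so
#' that each strand's 3' end extends exactly 2 nt past the last base paired
#' with the other strand (the Dicer/Drosha 2-nt 3' overhang rule).  Pairing
#' is anchored on the stem holding the mature arm: the maximal helix run
#' with the largest overlap with the mature span, extended across bulges and
#' internal loops (but not branch points).  Unpaired mature positions are
#' bridged through the nearest anchored pair, so bulges shift the star span
#' and asymmetric bulges change its length.  The inferred span may extend
#' past the precursor boundary (into the host transcript, when the hairpin
#' is placed on one).
#'
#' @param hairpin a [HairpinPrecursor-class].
#' @param transcriptSeq optional host transcript sequence; when supplied and
#'   the hairpin carries a transcript span, star residues crossing the
#'   precursor boundary are taken from the transcript.
#' @return list with \code{star_span} (integer(2), precursor coordinates,
#'   possibly outside \code{[1, length]}) and \code{star_seq} (character;
#'   clipped to the precursor, with a warning, when no transcript context is
#'   available).
#' @export
inferStar <- function(hairpin, transcriptSeq = NULL) {
  pt <- hairpin@structure@pairTable
  n <- length(pt)
  m1 <- hairpin@matureSpan[1]
  m2 <- hairpin@matureSpan[2]
  runs <- helix_runs(pt)
  ov <- vapply(runs, function(r) {
    ja <- pt[r[1]]; jb <- pt[r[2]]
    max(min(r[2], m2) - max(r[1], m1) + 1L,
        min(ja, m2) - max(jb, m1) + 1L)
  }, integer(1))
  if (!length(runs) || max(ov) <= 0L)
    stop("mature arm of '", hairpin@name,
         "' is entirely unpaired; star strand uninferable")
  run <- runs[[which.max(ov)]]
  stem <- stem_pairs(pt, run)
  anchors <- integer(0) # mature-side position -> partner
  for (p in stem) {
    if (p[1] >= m1 && p[1] <= m2) anchors[as.character(p[1])] <- p[2]
    if (p[2] >= m1 && p[2] <= m2) anchors[as.character(p[2])] <- p[1]
  }
  apos <- as.integer(names(anchors))
  partner <- function(p) {
    if (p %in% apos) return(anchors[[as.character(p)]])
    q <- apos[order(abs(apos - p), apos)][1]
    anchors[[as.character(q)]] - (p - q)
  }
  sa <- partner(m1) + 2L
  sb <- partner(m2 - 2L)
  span <- as.integer(sort(c(sa, sb)))
  if (span[1] <= m2 && span[2] >= m1)
    stop("inferred star span of '", hairpin@name,
         "' overlaps the mature span")
  if (span[1] >= 1L && span[2] <= n) {
    seq <- substr(hairpin@residues, span[1], span[2])
  } else if (!is.null(transcriptSeq) && length(hairpin@transcriptSpan)) {
    off <- hairpin@transcriptSpan[1] - 1L
    lo <- span[1] + off; hi <- span[2] + off
    if (lo < 1L || hi > nchar(transcriptSeq))
      stop("star span of '", hairpin@name,
           "' extends past the host transcript")
    seq <- substr(transcriptSeq, lo, hi)
  } else {
    warning("star span of '", hairpin@name,
            "' extends past the precursor; clipping")
    seq <- substr(hairpin@residues, max(1L, span[1]), min(n, span[2]))
  }
  list(star_span = span, star_seq = seq)
}

## Pairs of the stem containing a helix run: walk inward and outward across
## bulges/internal loops; stop at branch points.  Returns a list of c(i, j).
stem_pairs <- function(pt, run) {
  pairs <- lapply(run[1]:run[2], function(i) c(i, pt[i]))
  n <- length(pt)
  # inward
  i <- run[2]; j <- pt[run[2]]
  repeat {
    if (j - i - 1L < 2L) break
    top <- toplevel_pairs(pt, i + 1L, j - 1L)
    if (length(top) != 1L) break
    a <- top[[1]][1]; b <- top[[1]][2]
    pairs[[length(pairs) + 1L]] <- c(a, b)
    while (b - 1L > a + 1L && pt[a + 1L] == b - 1L) {
      a <- a + 1L; b <- b - 1L
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
    i <- a; j <- b
  }
  # outward
  i <- run[1]; j <- pt[run[1]]
  repeat {
    a <- i - 1L; b <- j + 1L
    while (a >= 1L && pt[a] == 0L) a <- a - 1L
    while (b <= n && pt[b] == 0L) b <- b + 1L
    if (a < 1L || b > n || pt[a] != b) break
    pairs[[length(pairs) + 1L]] <- c(a, b)
    while (a - 1L >= 1L && pt[a - 1L] == b + 1L) {
      a <- a - 1L; b <- b + 1L
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
    i <- a; j <- b
  }
  pairs
}

#' Build hairpin precursors from the packaged study tables
#'
#' One [HairpinPrecursor-class] per packaged miRNA: the printed precursor
#' with its normalized printed structure, the mature span located by exact
#' match, the star arm inferred via [inferStar()], and, when a transcriptome
#' from [buildTranscriptome()] is supplied, placement on the host transcript
#' (star residues crossing the precursor boundary are then resolved from the
#' transcript).
#'
#' @param fixtures a [FixtureBundle-class] from [loadFixtures()].
#' @param transcriptome optional data.frame from [buildTranscriptome()].
#' @return Named list of [HairpinPrecursor-class] objects.
#' @export
hairpinsFromFixtures <- function(fixtures, transcriptome = NULL) {
  out <- list()
  for (i in seq_len(nrow(fixtures@matures))) {
    nm <- fixtures@matures$name[i]
    mat <- fixtures@matures$sequence[i]
    pre <- fixtures@precursors$sequence[
      match(nm, fixtures@precursors$name)]
    db <- fixtures@structures$structure[
      match(nm, fixtures@structures$name)]
    ms <- as.integer(regexpr(mat, pre, fixed = TRUE))
    struct <- secondaryStructure(db, evaluateEnergy(pre, db))
    tid <- ""
    tspan <- integer(0)
    tseq <- NULL
    if (!is.null(transcriptome)) {
      hit <- match(nm, sub("^host_", "", transcriptome$id))
      if (!is.na(hit)) {
        tid <- transcriptome$id[hit]
        tseq <- transcriptome$seq[hit]
        p <- as.integer(regexpr(pre, tseq, fixed = TRUE))
        tspan <- c(p, p + nchar(pre) - 1L)
      }
    }
    hp <- hairpinPrecursor(nm, pre, struct,
                           matureSpan = c(ms, ms + nchar(mat) - 1L),
                           transcriptId = tid, transcriptSpan = tspan)
    star <- inferStar(hp, transcriptSeq = tseq)
    hp@starSpan <- star$star_span
    validObject(hp)
    attr(hp, "star_seq") <- star$star_seq
    out[[nm]] <- hp
  }
  out
}
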