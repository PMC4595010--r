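## miRanda-style miRNA:mRNA target scan: seed-scaled duplex alignment,
## nearest-neighbour duplex energy, seed/gap screening rules, thresholds.

#' Target-scan scoring scheme and thresholds
#'
#' Per-position alignment weights (canonical target-scanner defaults:
#' match +5, G:U +1, mismatch -3, affine gaps -9/-4, with column scores
#' scaled by 4 at miRNA positions 1-8) together with the screening
#' thresholds: minimum total score 145, maximum duplex energy -10 kcal/mol,
#' no seed (positions 2-7) mismatch or gap, at most 1 G:U in the seed, and
#' at most 1 gap in the whole duplex.
#'
#' @param match,gu,mismatch,gapOpen,gapExtend column weights.
#' @param seedScale scale factor over miRNA positions 1 to
#'   \code{seedScaleEnd}.
#' @param seedScaleEnd last scaled miRNA position (default 8).
#' @param minScore minimum accepted alignment score (default 145).
#' @param maxEnergy maximum accepted duplex energy, kcal/mol (default -10).
#' @param seedSpan integer(2): the seed region, miRNA positions 2-7.
#' @param maxSeedGU maximum G:U columns inside the seed (default 1).
#' @param maxDuplexGaps maximum gap columns in the duplex (default 1).
#' @return Named list (class \code{"scoringScheme"}).
#' @export
scoringScheme <- function(match = 5, gu = 1, mismatch = -3, gapOpen = -9,
                          gapExtend = -4, seedScale = 4, seedScaleEnd = 8L,
                          minScore = 145, maxEnergy = -10,
                          seedSpan = c(2L, 7L), maxSeedGU = 1L,
                          maxDuplexGaps = 1L) {
  stopifnot(minScore > 0, seedSpan[1] >= 1L, seedSpan[1] <= seedSpan[2])
  structure(list(match = match, gu = gu, mismatch = mismatch,
                 gapOpen = gapOpen, gapExtend = gapExtend,
                 seedScale = seedScale, seedScaleEnd = as.integer(seedScaleEnd),
                 minScore = minScore, maxEnergy = maxEnergy,
                 seedSpan = as.integer(seedSpan),
                 maxSeedGU = as.integer(maxSeedGU),
                 maxDuplexGaps = as.integer(maxDuplexGaps)),
            class = "scoringScheme")
}

scheme_weights <- function(scheme) {
  c(match = scheme$match, gu = scheme$gu, mismatch = scheme$mismatch,
    gap_open = scheme$gapOpen, gap_extend = scheme$gapExtend,
    seed_scale = scheme$seedScale)
}

#' Align a miRNA against a target window
#'
#' Best alignment of the miRNA (5' to 3', fully covered) against the
#' reverse-complemented reading of the window (free target flanks), with
#' affine gaps and seed scaling per the scheme.  Column classes are
#' \code{watson_crick}, \code{gu}, \code{mismatch}, \code{gap_miRNA}
#' (target base against a gap) and \code{gap_target} (miRNA base against a
#' gap).
#'
#' @param miRNA miRNA sequence (character).
#' @param window target window sequence, 5' to 3' on the mRNA.
#' @param scheme a [scoringScheme()].
#' @return list with \code{score}, \code{columns} (data.frame of
#'   \code{class}, \code{mirna_pos}, \code{target_pos} in window
#'   coordinates), and \code{target_span} (integer(2), window coordinates
#'   of the aligned target block).
#' @export
alignDuplex <- function(miRNA, window, scheme = scoringScheme()) {
  mi <- normalizeRNA(miRNA)
  win <- normalizeRNA(window)
  stopifnot(nchar(win) >= nchar(mi))
  rc <- reverseComplementRNA(win)
  res <- .duplex_align_cpp(seq_to_int(mi), seq_to_int(rc),
                           scheme_weights(scheme), scheme$seedScaleEnd)
  cls <- c("watson_crick", "gu", "mismatch", "gap_miRNA",
           "gap_target")[res$class + 1L]
  wlen <- nchar(win)
  tpos <- ifelse(is.na(res$window_pos), NA_integer_,
                 wlen - res$window_pos + 1L)
  span <- if (is.na(res$rc_start)) c(NA_integer_, NA_integer_)
          else c(wlen - res$rc_end + 1L, wlen - res$rc_start + 1L)
  list(score = res$score,
       columns = data.frame(class = cls, mirna_pos = res$mirna_pos,
                            target_pos = tpos, stringsAsFactors = FALSE),
       target_span = as.integer(span))
}

#' Recompute an alignment's score from its columns
#'
#' Independent column-wise rescoring (used by tests and validity checks):
#' per-column weights with seed scaling, affine gap runs.
#'
#' @param alignment result of [alignDuplex()].
#' @param scheme the [scoringScheme()] used.
#' @return numeric score.
#' @export
rescoreAlignment <- function(alignment, scheme = scoringScheme()) {
  cols <- alignment$columns
  sc <- 0
  prev_gap <- ""
  for (k in seq_len(nrow(cols))) {
    cl <- cols$class[k]
    pos <- cols$mirna_pos[k]
    scale <- if (max(pos, 1L) <= scheme$seedScaleEnd) scheme$seedScale else 1
    w <- switch(cl,
                watson_crick = scheme$match,
                gu = scheme$gu,
                mismatch = scheme$mismatch,
                gap_miRNA = if (prev_gap == "gap_miRNA") scheme$gapExtend
                            else scheme$gapOpen,
                gap_target = if (prev_gap == "gap_target") scheme$gapExtend
                             else scheme$gapOpen)
    sc <- sc + w * scale
    prev_gap <- if (cl %in% c("gap_miRNA", "gap_target")) cl else ""
  }
  sc
}

#' Duplex hybridization energy of an alignment
#'
#' Nearest-neighbour sum over runs of consecutive paired columns
#' (Watson-Crick or G:U) using the shared stacking table, plus the duplex
#' initiation penalty; mismatch and gap columns break stacking runs; no
#' intramolecular terms.
#'
#' @param alignment result of [alignDuplex()].
#' @param miRNA,window the aligned sequences.
#' @param params parameter set from [energyParameters()].
#' @return Energy in kcal/mol.
#' @export
duplexEnergy <- function(alignment, miRNA, window,
                         params = energyParameters()) {
  mi <- strsplit(normalizeRNA(miRNA), "")[[1]]
  win <- strsplit(normalizeRNA(window), "")[[1]]
  cols <- alignment$columns
  E <- params$misc[["duplex_init"]]
  prev <- NULL # previous paired column as c(mirna base, target base)
  for (k in seq_len(nrow(cols))) {
    if (cols$class[k] %in% c("watson_crick", "gu")) {
      x <- mi[cols$mirna_pos[k]]
      t <- win[cols$target_pos[k]]
      if (!is.null(prev)) {
        t1 <- pair_type(prev[1], prev[2])
        t2 <- pair_type(x, t)
        E <- E + params$stack[t1, t2]
      }
      prev <- c(x, t)
    } else {
      prev <- NULL
    }
  }
  unname(E)
}

#' Apply the seed and gap screening rules to an alignment
#'
#' Pass iff the seed region (miRNA positions per \code{scheme$seedSpan})
#' contains no mismatch and no gap column and at most \code{maxSeedGU} G:U
#' columns, and the whole duplex contains at most \code{maxDuplexGaps} gap
#' columns.
#'
#' @param alignment result of [alignDuplex()].
#' @param scheme a [scoringScheme()].
#' @return list with \code{pass} and \code{reasons} (subset of
#'   \code{seed_mismatch}, \code{seed_gap}, \code{seed_gu},
#'   \code{duplex_gaps}).
#' @export
seedFilter <- function(alignment, scheme = scoringScheme()) {
  cols <- alignment$columns
  seed <- cols$mirna_pos >= scheme$seedSpan[1] &
    cols$mirna_pos <= scheme$seedSpan[2]
  gap <- cols$class %in% c("gap_miRNA", "gap_target")
  reasons <- character(0)
  if (any(seed & cols$class == "mismatch"))
    reasons <- c(reasons, "seed_mismatch")
  if (any(seed & gap)) reasons <- c(reasons, "seed_gap")
  if (sum(seed & cols$class == "gu") > scheme$maxSeedGU)
    reasons <- c(reasons, "seed_gu")
  if (sum(gap) > scheme$maxDuplexGaps)
    reasons <- c(reasons, "duplex_gaps")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Scan a transcriptome for target sites of a miRNA
#'
#' Slides a window of width miRNA length + 8 (step 1) over every
#' transcript, aligns the miRNA to each window, merges overlapping hits
#' keeping the best-scoring site (ties: smaller start, fewer gaps), then
#' applies the seed filter, score threshold and energy threshold.  Output
#' order is deterministic (transcript id, then start).
#'
#' @param miRNA miRNA sequence or one-row data.frame with \code{id},
#'   \code{seq}.
#' @param transcriptome data.frame(id, seq).
#' @param scheme a [scoringScheme()].
#' @param params energy parameters.
#' @return data.frame with one row per merged site: \code{mirna},
#'   \code{transcript}, \code{start}, \code{end}, \code{score},
#'   \code{energy}, \code{passes_seed}, \code{passes_score},
#'   \code{passes_energy}, \code{accepted}.
#' @export
predictTargets <- function(miRNA, transcriptome, scheme = scoringScheme(),
                           params = energyParameters()) {
  mid <- if (is.data.frame(miRNA)) miRNA$id else "miRNA"
  mseq <- if (is.data.frame(miRNA)) miRNA$seq else normalizeRNA(miRNA)
  width <- nchar(mseq) + 8L
  sites <- list()
  for (t in seq_len(nrow(transcriptome))) {
    tseq <- transcriptome$seq[t]
    tlen <- nchar(tseq)
    if (tlen < nchar(mseq)) next
    cand <- list()
    for (ws in seq_len(max(1L, tlen - width + 1L))) {
      we <- min(tlen, ws + width - 1L)
      win <- substr(tseq, ws, we)
      if (nchar(win) < nchar(mseq)) next
      aln <- alignDuplex(mseq, win, scheme)
      if (is.na(aln$target_span[1])) next
      ngaps <- sum(aln$columns$class %in% c("gap_miRNA", "gap_target"))
      cand[[length(cand) + 1L]] <-
        list(start = ws + aln$target_span[1] - 1L,
             end = ws + aln$target_span[2] - 1L, aln = aln,
             window = win, gaps = ngaps)
    }
    if (!length(cand)) next
    # merge overlapping candidate sites, keeping the best
    ord <- order(vapply(cand, function(x) x$start, integer(1)))
    cand <- cand[ord]
    merged <- list()
    cur <- cand[[1]]
    better <- function(a, b) {
      if (a$aln$score != b$aln$score) return(a$aln$score > b$aln$score)
      if (a$start != b$start) return(a$start < b$start)
      a$gaps < b$gaps
    }
    for (x in cand[-1]) {
      if (x$start <= cur$end) {
        if (better(x, cur)) cur <- x
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- x
      }
    }
    merged[[length(merged) + 1L]] <- cur
    for (x in merged) {
      sf <- seedFilter(x$aln, scheme)
      en <- duplexEnergy(x$aln, mseq, x$window, params)
      passes_score <- x$aln$score >= scheme$minScore
      passes_energy <- en <= scheme$maxEnergy
      sites[[length(sites) + 1L]] <- data.frame(
        mirna = mid, transcript = transcriptome$id[t], start = x$start,
        end = x$end, score = x$aln$score, energy = en,
        passes_seed = sf$pass, passes_score = passes_score,
        passes_energy = passes_energy,
        accepted = sf$pass && passes_score && passes_energy,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(sites))
    return(data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(), score = numeric(),
                      energy = numeric(), passes_seed = logical(),
                      passes_score = logical(), passes_energy = logical(),
                      accepted = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, sites)
  out <- out[order(out$transcript, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
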