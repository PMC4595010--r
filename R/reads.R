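## Read handling: adapter trimming, length filtering, collapsing,
## contaminant removal and exact/near-exact transcriptome mapping.

#' Trim the 3' adapter from reads
#'
#' For each read the earliest position is found at which the remainder of
#' the read matches a prefix of the adapter with overlap at least
#' \code{minOverlap} and mismatch rate at most \code{maxMismatchRate}
#' (the earliest such position gives the longest matching read suffix).
#' Everything from that position on is removed.  Reads with no qualifying
#' overlap are rejected as untrimmed; reads whose insert is empty after
#' trimming are rejected too.
#'
#' @param reads a [SmallRNAReads-class].
#' @param adapter 3' adapter sequence (normalized internally).
#' @param minOverlap minimum read/adapter overlap in nt (default 6).
#' @param maxMismatchRate maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return list with \code{kept} (trimmed reads) and \code{rejected}
#'   (untrimmed or empty-insert reads), both [SmallRNAReads-class].
#' @export
trimAdapter <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                        minOverlap = 6L, maxMismatchRate = 0.1) {
  adapter <- normalizeRNA(adapter)
  alen <- nchar(adapter)
  stopifnot(alen >= minOverlap)
  n <- length(reads)
  if (!n) return(list(kept = reads, rejected = reads))
  avec <- strsplit(adapter, "")[[1]]
  cut <- rep(NA_integer_, n) # first removed position, per read
  for (len in sort(unique(nchar(reads@seq)))) {
    idx <- which(nchar(reads@seq) == len)
    mat <- matrix(unlist(strsplit(reads@seq[idx], "")), ncol = len,
                  byrow = TRUE)
    for (p in seq_len(max(0L, len - minOverlap + 1L))) {
      ov <- min(alen, len - p + 1L)
      cmp <- mat[, p:(p + ov - 1L), drop = FALSE] !=
        matrix(avec[seq_len(ov)], nrow = length(idx), ncol = ov, byrow = TRUE)
      hit <- which(rowSums(cmp) / ov <= maxMismatchRate & is.na(cut[idx]))
      if (length(hit)) cut[idx[hit]] <- p
    }
  }
  ok <- !is.na(cut) & cut > 1L
  trimmed <- reads[ok]
  trimmed@seq <- substr(trimmed@seq, 1L, cut[ok] - 1L)
  trimmed@qual <- substr(trimmed@qual, 1L, cut[ok] - 1L)
  list(kept = trimmed, rejected = reads[!ok])
}

#' Filter reads by insert length
#'
#' Paper mode keeps exactly 22-nt inserts (\code{minLen = maxLen = 22});
#' the general default window is 18-26 nt.
#'
#' @param reads a [SmallRNAReads-class].
#' @param minLen,maxLen inclusive length bounds.
#' @return list with \code{kept} and \code{removed} [SmallRNAReads-class].
#' @export
filterByLength <- function(reads, minLen = 18L, maxLen = 26L) {
  stopifnot(minLen <= maxLen)
  len <- nchar(reads@seq)
  keep <- len >= minLen & len <= maxLen
  list(kept = reads[keep], removed = reads[!keep])
}

#' Collapse identical reads
#'
#' One record per distinct sequence; counts are summed, the representative
#' id is the lexicographically smallest member id, and the label is kept
#' when unanimous among members.
#'
#' @param reads a [SmallRNAReads-class].
#' @return A collapsed [SmallRNAReads-class].
#' @export
collapseReads <- function(reads) {
  if (!length(reads)) return(reads)
  grp <- split(seq_along(reads@seq), reads@seq)
  ids <- vapply(grp, function(i) min(reads@id[i]), character(1))
  cnt <- vapply(grp, function(i) sum(reads@count[i]), integer(1))
  lab <- vapply(grp, function(i) {
    u <- unique(reads@label[i])
    if (length(u) == 1L) u else NA_character_
  }, character(1))
  ord <- order(ids)
  smallRNAReads(id = ids[ord], seq = names(grp)[ord],
                qual = rep("", length(grp)), count = cnt[ord],
                label = lab[ord])
}

#' Remove reads matching the rRNA/tRNA contaminant set
#'
#' A read is removed iff it occurs as a substring of any contaminant
#' sequence, or of its reverse complement, with at most \code{maxMismatch}
#' mismatches (default 0, exact substring).
#'
#' @param reads a [SmallRNAReads-class].
#' @param contaminants data.frame(id, seq) of contaminant sequences.
#' @param maxMismatch maximum mismatches in the match.
#' @return list with \code{kept} and \code{removed} [SmallRNAReads-class].
#' @export
filterContaminants <- function(reads, contaminants, maxMismatch = 0L) {
  stopifnot(maxMismatch >= 0L)
  if (!length(reads) || !nrow(contaminants))
    return(list(kept = reads, removed = reads[integer(0)]))
  subj <- Biostrings::RNAStringSet(toupper(
    c(contaminants$seq, reverseComplementRNA(contaminants$seq))))
  uniq <- unique(reads@seq)
  bad <- vapply(uniq, function(s) {
    hits <- Biostrings::vcountPattern(toupper(s), subj,
                                      max.mismatch = maxMismatch)
    any(hits > 0L)
  }, logical(1))
  removed <- reads@seq %in% uniq[bad]
  list(kept = reads[!removed], removed = reads[removed])
}

#' Map reads to a transcriptome
#'
#' Reports every occurrence of each read within each transcript (sense) and
#' within its reverse complement (antisense) with at most \code{maxMismatch}
#' mismatches (default 0, exact).  Positions are 1-based on the sense
#' strand; for an antisense hit, \code{start} is the sense-strand position
#' of the alignment's leftmost base.
#'
#' @param reads a [SmallRNAReads-class] (typically collapsed).
#' @param transcriptome data.frame(id, seq).
#' @param maxMismatch maximum mismatches (default 0; the 2-mismatch mode
#'   exists for sensitivity studies).
#' @return data.frame(read_id, seq, transcript, start, strand, mismatches),
#'   ordered by read id, transcript, start.
#' @export
mapReads <- function(reads, transcriptome, maxMismatch = 0L) {
  stopifnot(nrow(transcriptome) > 0L)
  subj <- Biostrings::RNAStringSet(setNames(toupper(transcriptome$seq),
                                            transcriptome$id))
  empty <- data.frame(read_id = character(), seq = character(),
                      transcript = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (!length(reads)) return(empty)
  uniq <- unique(data.frame(id = reads@id, seq = reads@seq,
                            stringsAsFactors = FALSE))
  rows <- list()
  scan <- function(pattern, strand, rid, rseq) {
    m <- Biostrings::vmatchPattern(toupper(pattern), subj,
                                   max.mismatch = maxMismatch)
    for (t in seq_along(m)) {
      st <- Biostrings::startIndex(m)[[t]]
      if (is.null(st) || !length(st)) next
      ok <- st >= 1L & st + nchar(pattern) - 1L <= nchar(transcriptome$seq[t])
      st <- st[ok]
      if (!length(st)) next
      mm <- vapply(st, function(p) {
        frag <- substr(transcriptome$seq[t], p, p + nchar(pattern) - 1L)
        sum(strsplit(frag, "")[[1]] !=
              strsplit(tolower(pattern), "")[[1]])
      }, integer(1))
      rows[[length(rows) + 1L]] <<- data.frame(
        read_id = rid, seq = rseq, transcript = transcriptome$id[t],
        start = as.integer(st), strand = strand, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(uniq))) {
    scan(uniq$seq[i], "sense", uniq$id[i], uniq$seq[i])
    scan(reverseComplementRNA(uniq$seq[i]), "antisense", uniq$id[i],
         uniq$seq[i])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$read_id, out$transcript, out$start), , drop = FALSE]
}
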