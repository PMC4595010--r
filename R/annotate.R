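## Conservation/novelty classification, 5'-nucleotide bias, origin
## annotation and per-strand abundance quantification with the read-count
## cutoff.

## Minimum mismatch count over all ungapped placements of the shorter
## sequence within the longer with end offsets up to 2 nt; overhanging
## positions count as mismatches.  Hamming distance when lengths are equal
## and the unshifted placement wins.
placement_mismatches <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- Inf
  for (off in seq(-2L, lb - la + 2L)) {
    i <- seq_len(la)
    j <- i + off
    inside <- j >= 1L & j <= lb
    mism <- sum(av[i[inside]] != bv[j[inside]]) + sum(!inside)
    if (mism < best) best <- mism
  }
  best
}

#' Classify a miRNA as conserved or novel against a reference set
#'
#' For every reference the minimum mismatch count is computed over all
#' ungapped placements of the shorter sequence within the longer, allowing
#' end offsets of up to 2 nt (plain Hamming distance for equal lengths);
#' overhanging positions count as mismatches.  The query is conserved iff
#' the global minimum is at most \code{maxMismatch}.  Ties are broken by
#' reference input order.
#'
#' @param query query sequence (character) or one-row data.frame with
#'   \code{id}, \code{seq}.
#' @param references data.frame(id, seq) of reference matures.
#' @param maxMismatch mismatch allowance (default 2).
#' @return list with \code{query}, \code{status} ("conserved" or "novel"),
#'   \code{best_reference} (NA when the reference set is empty) and
#'   \code{mismatches} (NA likewise).
#' @export
classifyConservation <- function(query, references, maxMismatch = 2L) {
  stopifnot(maxMismatch >= 0L)
  qid <- if (is.data.frame(query)) query$id else NA_character_
  qseq <- if (is.data.frame(query)) query$seq else normalizeRNA(query)
  if (!nrow(references))
    return(list(query = qid, status = "novel",
                best_reference = NA_character_, mismatches = NA_integer_))
  d <- vapply(references$seq, placement_mismatches, numeric(1), a = qseq)
  k <- which.min(d) # first minimum wins
  list(query = qid,
       status = if (d[k] <= maxMismatch) "conserved" else "novel",
       best_reference = references$id[k], mismatches = as.integer(d[k]))
}

#' Tally first nucleotides of mature miRNAs
#'
#' The 5'-terminal nucleotide biases Argonaute loading (5' uridine favours
#' AGO1), so the tally summarizes the discovery set's loading propensity.
#'
#' @param matures character vector of mature sequences, or a data.frame
#'   with a \code{sequence} or \code{seq} column.
#' @return Named integer vector with counts for a, c, g, u (summing to the
#'   number of inputs).
#' @examples
#' fivePrimeSummary(c("uggc", "aggc", "uccg"))
#' @export
fivePrimeSummary <- function(matures) {
  if (is.data.frame(matures))
    matures <- if (!is.null(matures$sequence)) matures$sequence
               else matures$seq
  first <- substr(normalizeRNA(matures), 1L, 1L)
  tab <- table(factor(first, levels = c("a", "c", "g", "u")))
  setNames(as.integer(tab), names(tab))
}

#' Annotate the origin of a precursor from its host-transcript description
#'
#' Case-insensitive keyword cascade, in fixed order: \code{tc3} (TC3-type
#' transposable element), \code{retro} (retrotransposon),
#' \code{transposable} (other transposable element), then
#' \code{uncharacterized} (or an empty description), else a named gene.
#' TC3 and retro elements also count as transposable in rollups.
#'
#' @param name miRNA name.
#' @param description host-transcript description text.
#' @return list with \code{name}, \code{category} (one of
#'   \code{tc3_transposable_element}, \code{retrotransposon},
#'   \code{transposable_element}, \code{uncharacterized},
#'   \code{named_gene}), \code{transposable} (rollup flag) and
#'   \code{evidence} (the matched description).
#' @export
annotateOrigin <- function(name, description) {
  d <- tolower(description)
  category <-
    if (grepl("tc3", d)) "tc3_transposable_element"
    else if (grepl("retro", d)) "retrotransposon"
    else if (grepl("transposable", d)) "transposable_element"
    else if (!nzchar(trimws(d)) || grepl("uncharacterized", d))
      "uncharacterized"
    else "named_gene"
  list(name = name, category = category,
       transposable = category %in% c("tc3_transposable_element",
                                      "retrotransposon",
                                      "transposable_element"),
       evidence = description)
}

#' Quantify per-strand miRNA abundance from mapped reads
#'
#' A collapsed read's count accrues to a miRNA's mature (resp. star) tally
#' iff its sense-strand mapping interval on the host transcript lies within
#' the mature (resp. star) arm interval extended by \code{tolerance} nt at
#' each end.  Each read is assigned at most once: hairpins are visited in
#' order and the mature arm takes precedence over the star arm.  Records
#' with total below \code{cutoff} are dropped.
#'
#' @param hits data.frame from [mapReads()].
#' @param reads the [SmallRNAReads-class] that was mapped (provides counts).
#' @param hairpins named list of [HairpinPrecursor-class] with transcript
#'   placements and star spans (e.g. from [hairpinsFromFixtures()]).
#' @param cutoff minimum total read count to report (default 10).
#' @param tolerance isomiR end-shift tolerance in nt (default 0, the
#'   exact-arm paper mode; the reusable default elsewhere is 2).
#' @return list with \code{records} -- data.frame(name, mature_reads,
#'   star_reads, total) for hairpins passing the cutoff, ordered as the
#'   input hairpins -- and \code{unassigned}, the summed count of mapped
#'   reads matching no arm.
#' @export
quantifyAbundance <- function(hits, reads, hairpins, cutoff = 10L,
                              tolerance = 0L) {
  stopifnot(cutoff >= 0L, tolerance >= 0L)
  counts <- setNames(reads@count, reads@id)
  sense <- hits[hits$strand == "sense", , drop = FALSE]
  sense <- sense[!duplicated(paste(sense$read_id, sense$transcript,
                                   sense$start)), , drop = FALSE]
  mature_tally <- setNames(integer(length(hairpins)), names(hairpins))
  star_tally <- mature_tally
  assigned <- character(0)
  for (nm in names(hairpins)) {
    hp <- hairpins[[nm]]
    if (!length(hp@transcriptSpan)) next
    off <- hp@transcriptSpan[1] - 1L
    arms <- list(mature = hp@matureSpan + off,
                 star = if (length(hp@starSpan)) hp@starSpan + off)
    for (arm in c("mature", "star")) {
      iv <- arms[[arm]]
      if (is.null(iv)) next
      h <- sense[sense$transcript == hp@transcriptId &
                   !(sense$read_id %in% assigned), , drop = FALSE]
      if (!nrow(h)) next
      rlen <- nchar(h$seq)
      inside <- h$start >= iv[1] - tolerance &
        h$start + rlen - 1L <= iv[2] + tolerance
      h <- h[inside, , drop = FALSE]
      if (!nrow(h)) next
      ids <- unique(h$read_id)
      tot <- sum(counts[ids])
      if (arm == "mature") mature_tally[nm] <- mature_tally[nm] + tot
      else star_tally[nm] <- star_tally[nm] + tot
      assigned <- c(assigned, ids)
    }
  }
  mapped_ids <- unique(sense$read_id)
  unassigned <- sum(counts[setdiff(mapped_ids, assigned)])
  rec <- data.frame(name = names(hairpins),
                    mature_reads = as.integer(mature_tally),
                    star_reads = as.integer(star_tally),
                    stringsAsFactors = FALSE, row.names = NULL)
  rec$total <- rec$mature_reads + rec$star_reads
  rec <- rec[rec$total >= cutoff, , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, unassigned = as.integer(unassigned))
}
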