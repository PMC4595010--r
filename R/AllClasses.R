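#' RNA secondary structure in dot-bracket notation
#'
#' Holds a nested (pseudoknot-free) secondary structure: the dot-bracket
#' string, the 1-based pair table (0 = unpaired) and a free energy in
#' kcal/mol (0 for the open chain; \code{-1 * pair count} in surrogate units
#' when produced by [foldMaxPair()]).
#'
#' @slot dotbracket character(1), over \code{(}, \code{)}, \code{.}.
#' @slot pairTable integer vector, position i holds the partner of i or 0.
#' @slot energy numeric(1), kcal/mol.
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
  representation(dotbracket = "character", pairTable = "integer",
                 energy = "numeric"))

setValidity("SecondaryStructure", function(object) {
  db <- object@dotbracket
  if (length(db) != 1L) return("dotbracket must be a single string")
  ch <- strsplit(db, "")[[1]]
  if (length(ch) && !all(ch %in% c("(", ")", ".")))
    return("dotbracket may contain only '(', ')' and '.'")
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0))
    return("unbalanced dot-bracket string")
  if (length(object@pairTable) != nchar(db))
    return("pair table length disagrees with dotbracket")
  pt <- object@pairTable
  paired <- which(pt > 0)
  if (any(pt[paired] < 1 | pt[paired] > length(pt)))
    return("pair table index out of range")
  if (any(pt[pt[paired]] != paired))
    return("pair table is not symmetric")
  if (any(abs(pt[paired] - paired) <= 3L))
    return("hairpin loop shorter than 3 nt")
  TRUE
})

#' Construct a SecondaryStructure from a dot-bracket string
#'
#' @param dotbracket dot-bracket string (already normalized; see
#'   [normalizeStructure()]).
#' @param energy free energy in kcal/mol; default 0.
#' @return A [SecondaryStructure-class] object.
#' @examples
#' secondaryStructure("((((...))))", -4.2)
#' @export
secondaryStructure <- function(dotbracket, energy = 0) {
  new("SecondaryStructure", dotbracket = dotbracket,
      pairTable = pairTableFromDotBracket(dotbracket),
      energy = as.numeric(energy))
}

setMethod("show", "SecondaryStructure", function(object) {
  cat("SecondaryStructure: ", nchar(object@dotbracket), " nt, ",
      sum(object@pairTable > 0) %/% 2L, " pairs, energy ",
      sprintf("%.2f", object@energy), " kcal/mol\n", sep = "")
  cat(" ", object@dotbracket, "\n", sep = "")
})

#' Hairpin precursor of a microRNA
#'
#' A precursor window together with its secondary structure, the mature-arm
#' span and (once inferred) the star-arm span, plus the coordinates of the
#' window on its host transcript.  Spans are 1-based closed intervals in
#' precursor coordinates; the star span may extend past \code{[1, length]}
#' when the Dicer-duplex overhang reaches into the host transcript beyond
#' the excised window.
#'
#' @slot name miRNA name.
#' @slot residues precursor sequence, lowercase RNA.
#' @slot structure a [SecondaryStructure-class].
#' @slot matureSpan integer(2).
#' @slot starSpan integer(2) or integer(0) when not inferred.
#' @slot transcriptId host transcript id ("" when unplaced).
#' @slot transcriptSpan integer(2) or integer(0): precursor location on the
#'   host transcript.
#' @exportClass HairpinPrecursor
setClass("HairpinPrecursor",
  representation(name = "character", residues = "character",
                 structure = "SecondaryStructure", matureSpan = "integer",
                 starSpan = "integer", transcriptId = "character",
                 transcriptSpan = "integer"))

setValidity("HairpinPrecursor", function(object) {
  n <- nchar(object@residues)
  if (nchar(object@structure@dotbracket) != n)
    return("structure length disagrees with residues")
  ms <- object@matureSpan
  if (length(ms) != 2L || ms[1] < 1L || ms[2] > n || ms[1] > ms[2])
    return("matureSpan outside precursor")
  ss <- object@starSpan
  if (length(ss) && ss[1] <= ms[2] && ss[2] >= ms[1])
    return("starSpan overlaps matureSpan")
  TRUE
})

#' Construct a HairpinPrecursor
#'
#' @param name miRNA name.
#' @param residues precursor sequence (normalized to lowercase RNA).
#' @param structure a [SecondaryStructure-class] for the precursor.
#' @param matureSpan integer(2), 1-based closed span of the mature arm.
#' @param starSpan optional integer(2) star-arm span.
#' @param transcriptId,transcriptSpan optional host-transcript placement.
#' @return A [HairpinPrecursor-class] object.
#' @export
hairpinPrecursor <- function(name, residues, structure, matureSpan,
                             starSpan = integer(0), transcriptId = "",
                             transcriptSpan = integer(0)) {
  new("HairpinPrecursor", name = name, residues = normalizeRNA(residues),
      structure = structure, matureSpan = as.integer(matureSpan),
      starSpan = as.integer(starSpan), transcriptId = transcriptId,
      transcriptSpan = as.integer(transcriptSpan))
}

setMethod("show", "HairpinPrecursor", function(object) {
  cat("HairpinPrecursor ", object@name, ": ", nchar(object@residues),
      " nt, mature [", object@matureSpan[1], ",", object@matureSpan[2], "]",
      sep = "")
  if (length(object@starSpan))
    cat(", star [", object@starSpan[1], ",", object@starSpan[2], "]", sep = "")
  if (nzchar(object@transcriptId))
    cat(", on ", object@transcriptId, sep = "")
  cat("\n ", object@structure@dotbracket, "\n", sep = "")
})

#' Collection of (possibly collapsed) small-RNA reads
#'
#' Parallel-slot container: one element per read record.  After
#' [collapseReads()] a record represents all identical reads and carries
#' their summed count.
#'
#' @slot id read identifiers.
#' @slot seq read sequences, lowercase RNA.
#' @slot qual quality strings ("" when absent).
#' @slot count integer copy counts (>= 1).
#' @slot label optional ground-truth labels (NA when unknown).
#' @exportClass SmallRNAReads
setClass("SmallRNAReads",
  representation(id = "character", seq = "character", qual = "character",
                 count = "integer", label = "character"))

setValidity("SmallRNAReads", function(object) {
  n <- length(object@id)
  if (length(object@seq) != n || length(object@qual) != n ||
      length(object@count) != n || length(object@label) != n)
    return("slots must have equal length")
  if (n && any(object@count < 1L)) return("counts must be >= 1")
  if (n && any(!nzchar(object@seq))) return("empty read sequence")
  if (n && any(grepl("[^acgu]", object@seq)))
    return("read sequences must be over {a,c,g,u}")
  TRUE
})

#' Construct a SmallRNAReads object
#'
#' @param id,seq,qual,count,label parallel vectors; \code{seq} is normalized
#'   (T/t to u, lowercased).
#' @return A [SmallRNAReads-class] object.
#' @export
smallRNAReads <- function(id = character(), seq = character(),
                          qual = rep("", length(id)),
                          count = rep(1L, length(id)),
                          label = rep(NA_character_, length(id))) {
  new("SmallRNAReads", id = as.character(id), seq = normalizeRNA(seq),
      qual = as.character(qual), count = as.integer(count),
      label = as.character(label))
}

setMethod("length", "SmallRNAReads", function(x) length(x@id))

setMethod("[", "SmallRNAReads", function(x, i, j, ..., drop = TRUE) {
  new("SmallRNAReads", id = x@id[i], seq = x@seq[i], qual = x@qual[i],
      count = x@count[i], label = x@label[i])
})

setMethod("show", "SmallRNAReads", function(object) {
  cat("SmallRNAReads: ", length(object), " records, ",
      sum(object@count), " reads\n", sep = "")
  if (length(object)) {
    k <- min(3L, length(object))
    for (i in seq_len(k))
      cat("  ", object@id[i], " ", object@seq[i], " x", object@count[i],
          "\n", sep = "")
    if (length(object) > k) cat("  ...\n")
  }
})

#' @exportS3Method base::as.data.frame
as.data.frame.SmallRNAReads <- function(x, ...) {
  data.frame(id = x@id, seq = x@seq, qual = x@qual, count = x@count,
             label = x@label, stringsAsFactors = FALSE)
}

#' Bundle of the packaged study tables
#'
#' The five per-miRNA tables shipped with the package, cross-keyed by the
#' same 14 miRNA names: mature sequences, precursor sequences, origin
#' descriptions with as-printed coordinates, normalized dot-bracket
#' structures, and per-strand read counts.
#'
#' @slot matures data.frame(name, sequence).
#' @slot precursors data.frame(name, sequence).
#' @slot origins data.frame(name, origin, start, end).  Coordinates are
#'   stored verbatim as printed; their convention is not fully specified at
#'   source, so they are used as embedding positions, not as ground truth.
#' @slot structures data.frame(name, structure), normalized dot-bracket.
#' @slot abundance data.frame(name, total, mature_reads, star_reads).
#' @exportClass FixtureBundle
setClass("FixtureBundle",
  representation(matures = "data.frame", precursors = "data.frame",
                 origins = "data.frame", structures = "data.frame",
                 abundance = "data.frame"))

setValidity("FixtureBundle", function(object) {
  key <- object@matures$name
  if (anyDuplicated(key)) return("duplicate miRNA names")
  for (tb in c("precursors", "origins", "structures", "abundance")) {
    nm <- slot(object, tb)$name
    if (!identical(sort(nm), sort(key)))
      return(sprintf("table '%s' is not keyed by the same miRNA names", tb))
  }
  ab <- object@abundance
  if (!all(ab$total == ab$mature_reads + ab$star_reads))
    return("abundance totals must equal mature_reads + star_reads")
  for (s in object@structures$structure) {
    ch <- strsplit(s, "")[[1]]
    depth <- cumsum((ch == "(") - (ch == ")"))
    if (any(depth < 0) || depth[length(depth)] != 0)
      return("unbalanced structure string")
  }
  ok <- mapply(function(m, p) grepl(m, p, fixed = TRUE),
               object@matures$sequence,
               object@precursors$sequence[match(object@matures$name,
                                                object@precursors$name)])
  if (!all(ok)) return("a mature sequence is not contained in its precursor")
  TRUE
})

setMethod("show", "FixtureBundle", function(object) {
  cat("FixtureBundle: ", nrow(object@matures), " miRNAs (",
      paste(utils::head(object@matures$name, 3), collapse = ", "),
      ", ...)\n", sep = "")
})
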