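## Readers and writers for the standard formats the pipeline touches
## (FASTA/FASTQ via Biostrings, TSV reports) and the packaged study tables.

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Sequences are normalized to lowercase RNA (T/t to u).  An empty file
#' yields a zero-row result rather than an error.
#'
#' @param path FASTA file (wrapped or unwrapped, optionally gzipped).
#' @return data.frame with columns \code{id}, \code{seq}, \code{desc}
#'   (text after the first whitespace in the header, "" when absent), in
#'   file order.
#' @export
readRNAFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(data.frame(id = character(), seq = character(),
                      desc = character(), stringsAsFactors = FALSE))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- normalizeRNA(as.character(set))
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1]
    stop("empty sequence for record '", id[bad], "' in '", path, "'")
  }
  if (any(grepl("[^acgu]", seqs))) {
    bad <- which(grepl("[^acgu]", seqs))[1]
    stop("non-nucleotide characters in record '", id[bad], "'")
  }
  data.frame(id = id, seq = unname(seqs), desc = desc,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x data.frame with columns \code{id}, \code{seq} and optionally
#'   \code{desc}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeRNAFasta <- function(x, path) {
  hdr <- x$id
  if (!is.null(x$desc)) hdr <- ifelse(nzchar(x$desc),
                                      paste(x$id, x$desc), x$id)
  set <- Biostrings::BStringSet(setNames(x$seq, hdr))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read small-RNA reads from FASTQ
#'
#' Four-line FASTQ records (Sanger qualities, optionally gzipped).
#' Sequences are normalized to lowercase RNA and counts initialized to 1.
#' Ground-truth labels are recovered from read ids of the form
#' \code{"name|arm|serial"} written by [simulateReads()].
#'
#' @param path FASTQ file.
#' @return A [SmallRNAReads-class] object.
#' @export
readSmallRNAFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("FASTQ parse error in '", path, "': ",
                             conditionMessage(e)))
  qual <- tryCatch(
    unname(as.character(S4Vectors::mcols(set)$qualities)),
    error = function(e) stop("FASTQ parse error in '", path,
                             "': malformed quality string"))
  if (length(set) && any(nchar(qual) != Biostrings::width(set)))
    stop("FASTQ parse error in '", path,
         "': sequence and quality lengths differ")
  id <- sub("\\s.*$", "", names(set))
  lab <- ifelse(grepl("|", id, fixed = TRUE),
                vapply(strsplit(id, "|", fixed = TRUE),
                       function(p) paste(p[1], p[2], sep = "|"), character(1)),
                NA_character_)
  smallRNAReads(id = id, seq = unname(as.character(set)), qual = qual,
                label = lab)
}

#' Write small-RNA reads to FASTQ
#'
#' Sequences are emitted in the DNA alphabet (u to T, uppercased), as a
#' sequencer would produce them; [readSmallRNAFastq()] restores lowercase
#' RNA, so read-write-read is the identity on (id, residues).
#'
#' @param reads a [SmallRNAReads-class] object.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeSmallRNAFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    dna <- toupper(chartr("u", "t", reads@seq))
    qual <- ifelse(nzchar(reads@qual), reads@qual,
                   strrep("I", nchar(reads@seq)))
    writeLines(paste0("@", reads@id, "\n", dna, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Normalize a printed dot-bracket string
#'
#' Typographic ellipsis glyphs (as printed in the study tables) are expanded
#' to three \code{.} characters; the result must balance.
#'
#' @param raw structure string over \code{(}, \code{)}, \code{.} and the
#'   ellipsis glyph.
#' @return Normalized dot-bracket string.
#' @examples
#' normalizeStructure("((\u2026))")
#' @export
normalizeStructure <- function(raw) {
  s <- gsub("\u2026", "...", raw)
  if (grepl("[^().]", s))
    stop("unexpected characters in structure string: ",
         gsub("[().]", "", s))
  pairTableFromDotBracket(s) # errors on unbalanced input, naming the position
  s
}

#' Load the packaged study tables
#'
#' Reads the five per-miRNA tables shipped under \code{inst/extdata}
#' (mature sequences, precursors, origin loci with as-printed coordinates,
#' dot-bracket structures, per-strand read counts), strips thousands
#' separators from counts, normalizes structures via [normalizeStructure()]
#' and cross-checks the keys.
#'
#' @return A [FixtureBundle-class] object with 14 miRNAs.
#' @examples
#' fb <- loadFixtures()
#' nrow(fb@matures)
#' @export
loadFixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "miRquarry",
                                 mustWork = TRUE)
  rd <- function(f) read.delim(ext(f), stringsAsFactors = FALSE,
                               encoding = "UTF-8")
  matures <- rd("table1_mature.tsv")
  precursors <- rd("table2_precursor.tsv")
  origins <- rd("table3_origin.tsv")
  structures <- rd("table4_structure.tsv")
  abundance <- rd("table5_abundance.tsv")
  for (cn in c("total", "mature_reads", "star_reads"))
    abundance[[cn]] <- as.integer(gsub(",", "", abundance[[cn]]))
  matures$sequence <- normalizeRNA(matures$sequence)
  precursors$sequence <- normalizeRNA(precursors$sequence)
  structures$structure <- vapply(structures$structure, normalizeStructure,
                                 character(1), USE.NAMES = FALSE)
  bundle <- new("FixtureBundle", matures = matures, precursors = precursors,
                origins = origins, structures = structures,
                abundance = abundance)
  validObject(bundle)
  bundle
}

#' Write records as a TSV report
#'
#' Tab-separated, header row, no quoting or thousands separators, so that
#' integer and string fields round-trip losslessly through [readTsv()].
#'
#' @param records data.frame of homogeneous records.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeTsv <- function(records, path) {
  tryCatch(
    write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read a TSV report written by [writeTsv()]
#' @param path input file.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
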