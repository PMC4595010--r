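## End-to-end orchestration: one config object holding every threshold,
## stage functions wired together with per-stage bookkeeping, and file
## artifacts for each stage.

#' Pipeline configuration
#'
#' Every threshold of the analysis in one place.  The \code{"paper"} preset
#' applies the study-stated values: 22-nt length filter, 0-mismatch
#' contaminant and transcriptome matching, 2-mismatch conservation
#' allowance, hairpin criteria of 18 matched pairs / one central loop /
#' energy at most -18 kcal/mol, abundance cutoff 10, exact (0-tolerance)
#' arm assignment, and the target thresholds score >= 145 and energy <=
#' -10 kcal/mol.  The \code{"default"} preset keeps the stated cutoffs but
#' widens the reusable knobs: 18-26 nt length window, hairpin criteria
#' calibrated to the packaged energy model (15 pairs, 2 loops, -5
#' kcal/mol), 2-nt arm tolerance.
#'
#' @param preset \code{"default"} or \code{"paper"}.
#' @param ... named overrides of individual fields.
#' @return Named list (class \code{"pipelineConfig"}).
#' @export
pipelineConfig <- function(preset = c("default", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    minOverlap = 6L,
    maxMismatchRate = 0.1,
    minLen = 18L, maxLen = 26L,
    contaminantMaxMismatch = 0L,
    mappingMaxMismatch = 0L,
    conservationMaxMismatch = 2L,
    flank = 70L,
    hairpin = hairpinCriteria(),
    abundanceCutoff = 10L,
    armTolerance = 2L,
    scoring = scoringScheme(),
    seed = 1L)
  if (preset == "paper") {
    cfg$minLen <- 22L; cfg$maxLen <- 22L
    cfg$hairpin <- hairpinCriteria(preset = "paper")
    cfg$armTolerance <- 0L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Range checks for every field; for the \code{"paper"} preset the
#' study-stated values (length 22, conservation mismatches 2, cutoff 10,
#' min score 145, max duplex energy -10) are asserted exactly.
#'
#' @param config a [pipelineConfig()].
#' @return \code{TRUE} when valid, else a character vector of violations,
#'   each naming the offending field.
#' @export
validateConfig <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(nchar(config$adapter) >= config$minOverlap,
      "adapter: shorter than minOverlap")
  chk(config$minOverlap >= 1L, "minOverlap: must be >= 1")
  chk(config$maxMismatchRate >= 0 && config$maxMismatchRate < 1,
      "maxMismatchRate: must be in [0, 1)")
  chk(config$minLen <= config$maxLen, "minLen: exceeds maxLen")
  chk(config$contaminantMaxMismatch >= 0L,
      "contaminantMaxMismatch: negative")
  chk(config$mappingMaxMismatch >= 0L, "mappingMaxMismatch: negative")
  chk(config$conservationMaxMismatch >= 0L,
      "conservationMaxMismatch: negative")
  chk(config$flank >= 0L, "flank: negative")
  chk(config$abundanceCutoff >= 0L, "cutoff: negative")
  chk(config$armTolerance >= 0L, "armTolerance: negative")
  chk(config$scoring$minScore > 0, "minScore: must be positive")
  if (config$preset == "paper") {
    chk(config$minLen == 22L && config$maxLen == 22L,
        "paper preset: length filter must be exactly 22")
    chk(config$conservationMaxMismatch == 2L,
        "paper preset: conservation mismatches must be 2")
    chk(config$abundanceCutoff == 10L, "paper preset: cutoff must be 10")
    chk(config$scoring$minScore == 145, "paper preset: minScore must be 145")
    chk(config$scoring$maxEnergy == -10,
        "paper preset: target maxEnergy must be -10")
    chk(config$hairpin$minMatchedPairs == 18L,
        "paper preset: minMatchedPairs must be 18")
  }
  if (length(errs)) errs else TRUE
}

#' Process raw reads: trim, length-filter, collapse, de-contaminate
#'
#' @param reads raw [SmallRNAReads-class].
#' @param contaminants data.frame(id, seq) or NULL.
#' @param config a [pipelineConfig()].
#' @return list with \code{reads} (collapsed, cleaned) and \code{log}
#'   (data.frame of per-stage in/kept/removed read counts).
#' @export
processReads <- function(reads, contaminants = NULL,
                         config = pipelineConfig()) {
  log <- list()
  note <- function(stage, n_in, kept, removed)
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, reads_in = n_in, reads_kept = kept,
      reads_removed = removed, stringsAsFactors = FALSE)
  n0 <- sum(reads@count)
  tr <- trimAdapter(reads, config$adapter, config$minOverlap,
                    config$maxMismatchRate)
  note("trim_adapter", n0, sum(tr$kept@count), sum(tr$rejected@count))
  lf <- filterByLength(tr$kept, config$minLen, config$maxLen)
  note("length_filter", sum(tr$kept@count), sum(lf$kept@count),
       sum(lf$removed@count))
  col <- collapseReads(lf$kept)
  note("collapse", sum(lf$kept@count), sum(col@count), 0L)
  if (!is.null(contaminants) && nrow(contaminants)) {
    fc <- filterContaminants(col, contaminants,
                             config$contaminantMaxMismatch)
    note("contaminant_filter", sum(col@count), sum(fc$kept@count),
         sum(fc$removed@count))
    col <- fc$kept
  }
  list(reads = col, log = do.call(rbind, log))
}

#' Discover hairpin candidates from mapped reads
#'
#' Every mapped read is a candidate mature: for each sense hit, the two
#' flanking windows from [locatePrecursor()] are folded with [foldMFE()]
#' and evaluated against the hairpin criteria; for windows that pass, the
#' star arm is inferred.  Both arms of a duplex surface as separate
#' candidates (each is the other's star); designating which is the mature
#' is left to the caller, since the usual highest-count convention
#' misorders duplexes whose star accumulates more reads.
#'
#' @param hits data.frame from [mapReads()].
#' @param reads the mapped [SmallRNAReads-class].
#' @param transcriptome data.frame(id, seq, desc).
#' @param config a [pipelineConfig()].
#' @return data.frame with one row per passing candidate window:
#'   \code{read_id}, \code{seq}, \code{count}, \code{transcript},
#'   \code{window_start}, \code{window_end}, \code{pairs}, \code{loops},
#'   \code{energy}, \code{star_start}, \code{star_end} (transcript
#'   coordinates, NA when uninferable).
#' @export
discoverHairpins <- function(hits, reads, transcriptome,
                             config = pipelineConfig()) {
  sense <- hits[hits$strand == "sense", , drop = FALSE]
  counts <- setNames(reads@count, reads@id)
  out <- list()
  for (i in seq_len(nrow(sense))) {
    tr <- transcriptome[transcriptome$id == sense$transcript[i], ]
    cand <- locatePrecursor(sense$seq[i], tr$seq, config$flank)
    cand <- cand[cand$mature_start + cand$window_start - 1L ==
                   sense$start[i], , drop = FALSE]
    best <- NULL
    for (k in seq_len(nrow(cand))) {
      fold <- foldMFE(cand$residues[k])
      ev <- evaluateHairpin(cand$residues[k], fold,
                            c(cand$mature_start[k], cand$mature_end[k]),
                            config$hairpin)
      if (!ev$pass) next
      hp <- tryCatch(
        hairpinPrecursor(sense$read_id[i], cand$residues[k], fold,
                         c(cand$mature_start[k], cand$mature_end[k]),
                         transcriptId = tr$id,
                         transcriptSpan = c(cand$window_start[k],
                                            cand$window_end[k])),
        error = function(e) NULL)
      if (is.null(hp)) next
      star <- tryCatch(inferStar(hp, transcriptSeq = tr$seq),
                       error = function(e) NULL)
      row <- data.frame(
        read_id = sense$read_id[i], seq = sense$seq[i],
        count = unname(counts[sense$read_id[i]]), transcript = tr$id,
        window_start = cand$window_start[k],
        window_end = cand$window_end[k], pairs = ev$pairs,
        loops = ev$loops, energy = ev$energy,
        star_start = if (is.null(star)) NA_integer_
                     else star$star_span[1] + cand$window_start[k] - 1L,
        star_end = if (is.null(star)) NA_integer_
                   else star$star_span[2] + cand$window_start[k] - 1L,
        stringsAsFactors = FALSE)
      if (is.null(best) || row$energy < best$energy) best <- row
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  if (!length(out))
    return(data.frame(read_id = character(), seq = character(),
                      count = integer(), transcript = character(),
                      window_start = integer(), window_end = integer(),
                      pairs = integer(), loops = integer(),
                      energy = numeric(), star_start = integer(),
                      star_end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$transcript, res$window_start, res$read_id), , drop = FALSE]
}

#' Run the full pipeline on files
#'
#' Stage order: read processing (adapter, length, redundancy, contaminants)
#' -> transcriptome mapping -> conservation classification -> hairpin
#' discovery -> quantification.  Every stage writes its artifact next to
#' \code{outDir} and the run report records per-stage read bookkeeping.
#' Identical inputs and config give identical outputs.
#'
#' @param fastq path to the small-RNA FASTQ.
#' @param transcriptomeFasta path to the transcriptome FASTA.
#' @param referenceFasta optional path to a reference mature-miRNA FASTA
#'   (miRBase-like) for conservation classification.
#' @param contaminantFasta optional path to the rRNA/tRNA FASTA.
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @return list with \code{report} (per-stage counts), \code{reads},
#'   \code{hits}, \code{hairpins} (discovery table), \code{conservation},
#'   \code{abundance} paths and in-memory objects.
#' @export
runPipeline <- function(fastq, transcriptomeFasta, referenceFasta = NULL,
                        contaminantFasta = NULL, outDir = tempfile("run"),
                        config = pipelineConfig()) {
  v <- validateConfig(config)
  if (!isTRUE(v)) stop("invalid config:\n  ", paste(v, collapse = "\n  "))
  for (p in c(fastq, transcriptomeFasta, referenceFasta, contaminantFasta))
    if (!is.null(p) && !file.exists(p)) stop("missing input: ", p)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  raw <- stage("read_input", readSmallRNAFastq(fastq))
  transcriptome <- stage("read_input", readRNAFasta(transcriptomeFasta))
  contaminants <- if (!is.null(contaminantFasta))
    stage("read_input", readRNAFasta(contaminantFasta))
  proc <- stage("process", processReads(raw, contaminants, config))
  writeTsv(as.data.frame(proc$reads), file.path(outDir, "reads_clean.tsv"))
  hits <- stage("map", mapReads(proc$reads, transcriptome,
                                config$mappingMaxMismatch))
  writeTsv(hits, file.path(outDir, "mapping_hits.tsv"))
  mapped_ids <- unique(hits$read_id[hits$strand == "sense"])
  mapped <- proc$reads[proc$reads@id %in% mapped_ids]
  cons <- NULL
  if (!is.null(referenceFasta)) {
    refs <- stage("read_input", readRNAFasta(referenceFasta))
    cons <- stage("annotate", do.call(rbind, lapply(seq_len(length(mapped)),
      function(i) {
        cc <- classifyConservation(
          data.frame(id = mapped@id[i], seq = mapped@seq[i],
                     stringsAsFactors = FALSE),
          refs, config$conservationMaxMismatch)
        data.frame(read_id = cc$query, status = cc$status,
                   best_reference = cc$best_reference,
                   mismatches = cc$mismatches, stringsAsFactors = FALSE)
      })))
    if (!is.null(cons))
      writeTsv(cons, file.path(outDir, "conservation.tsv"))
  }
  disc <- stage("discover", discoverHairpins(hits, proc$reads,
                                             transcriptome, config))
  writeTsv(disc, file.path(outDir, "hairpins.tsv"))
  hairpins <- discovery_to_hairpins(disc, transcriptome)
  quant <- stage("quantify",
                 quantifyAbundance(hits, proc$reads, hairpins,
                                   config$abundanceCutoff,
                                   config$armTolerance))
  writeTsv(quant$records, file.path(outDir, "abundance.tsv"))
  report <- proc$log
  report <- rbind(report, data.frame(
    stage = "map", reads_in = sum(proc$reads@count),
    reads_kept = sum(proc$reads@count[proc$reads@id %in% mapped_ids]),
    reads_removed = sum(proc$reads@count) -
      sum(proc$reads@count[proc$reads@id %in% mapped_ids]),
    stringsAsFactors = FALSE))
  writeTsv(report, file.path(outDir, "run_report.tsv"))
  list(report = report, reads = proc$reads, hits = hits,
       conservation = cons, discovery = disc, abundance = quant$records,
       unassigned = quant$unassigned, outDir = outDir, config = config)
}

## Convert the discovery table into HairpinPrecursor objects for
## quantification: overlapping windows on one transcript are grouped and
## the highest-count candidate represents the duplex (ties: smaller
## window start, then read id).
discovery_to_hairpins <- function(disc, transcriptome) {
  if (!nrow(disc)) return(list())
  disc <- disc[order(disc$transcript, disc$window_start), , drop = FALSE]
  groups <- list()
  cur <- disc[1, ]
  cur_members <- list(disc[1, ])
  flush <- function() {
    members <- do.call(rbind, cur_members)
    best <- members[order(-members$count, members$window_start,
                          members$read_id), ][1, ]
    groups[[length(groups) + 1L]] <<- best
  }
  for (i in seq_len(nrow(disc))[-1]) {
    row <- disc[i, ]
    if (row$transcript == cur$transcript &&
        row$window_start <= cur$window_end) {
      cur_members[[length(cur_members) + 1L]] <- row
      cur$window_end <- max(cur$window_end, row$window_end)
    } else {
      flush()
      cur <- row
      cur_members <- list(row)
    }
  }
  flush()
  out <- list()
  for (g in groups) {
    tseq <- transcriptome$seq[transcriptome$id == g$transcript]
    win <- substr(tseq, g$window_start, g$window_end)
    ms <- as.integer(regexpr(g$seq, win, fixed = TRUE))
    if (ms < 1L) next
    fold <- foldMFE(win)
    hp <- tryCatch(
      hairpinPrecursor(g$read_id, win, fold,
                       c(ms, ms + nchar(g$seq) - 1L),
                       transcriptId = g$transcript,
                       transcriptSpan = c(g$window_start, g$window_end)),
      error = function(e) NULL)
    if (is.null(hp)) next
    if (!is.na(g$star_start)) {
      ss <- c(g$star_start, g$star_end) - g$window_start + 1L
      if (ss[1] > hp@matureSpan[2] || ss[2] < hp@matureSpan[1])
        hp@starSpan <- as.integer(ss)
    }
    out[[g$read_id]] <- hp
  }
  out
}
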