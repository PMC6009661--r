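#' Run the calling pipeline over a set of duplex molecules
#'
#' For each molecule: build per-strand consensus reads when raw subreads are
#' supplied, apply the consensus pass-count filter, align both strands to the
#' reference (first strand reverse-complemented into reference frame), apply
#' the read filter cascade, and — when both strands survive — call
#' duplex-confirmed errors. Molecules with one strand missing or rejected are
#' skipped and logged. The per-filter rejection counts and the analyzable
#' duplex-covered base count (the rate denominator: reference positions in
#' the analyzable region covered by both strands of accepted molecules;
#' deletions consume denominator bases, insertions do not) are returned with
#' the events.
#'
#' @param molecules molecule list from \code{\link{simulateDataset}} (either
#'   finished \code{StrandRead}s or raw subread vectors), or any list with
#'   elements shaped the same way.
#' @param amplicon reference \code{\linkS4class{Amplicon}}.
#' @param minPasses consensus pass-count filter (default 15).
#' @param qualThreshold per-strand event quality threshold (default 93).
#' @param minMapq,maxLenDev,expectedLen read filter thresholds, see
#'   \code{\link{applyReadFilters}}.
#' @param band alignment band half-width.
#' @param window context half-width stored on events.
#' @return list with \code{events} (combined first+second strand events,
#'   one data.frame), \code{discordant}, \code{audit} (named counters) and
#'   \code{nBases} (denominator).
#' @export
callPipeline <- function(molecules, amplicon, minPasses = 15L,
                         qualThreshold = 93L, minMapq = 60L,
                         maxLenDev = 50L, expectedLen = NULL, band = 50L,
                         window = 3L) {
  mask <- analyzableMask(amplicon)
  L <- ampLength(amplicon)
  audit <- c(molecules_in = length(molecules), molecules_called = 0L,
             min_passes = 0L, unalignable = 0L, mapq = 0L, span5 = 0L,
             span3 = 0L, chimera = 0L, length = 0L, unpaired = 0L)
  events <- list()
  disc <- list()
  nBases <- 0

  for (m in molecules) {
    reads <- list()
    for (strand in c("first", "second")) {
      if (!is.null(m[[strand]])) {
        reads[[strand]] <- m[[strand]]
      } else if (!is.null(m[[paste0(strand, "Subreads")]])) {
        reads[[strand]] <- buildConsensus(m[[paste0(strand, "Subreads")]],
                                          m$id, strand, band = band)
      }
    }
    if (length(reads) != 2L) {
      audit["unpaired"] <- audit["unpaired"] + 1L
      next
    }
    ok <- TRUE
    for (strand in c("first", "second")) {
      fc <- filterConsensus(reads[[strand]], minPasses)
      if (!fc$accept) {
        audit[fc$reason] <- audit[fc$reason] + 1L
        ok <- FALSE
      }
    }
    if (!ok) next
    aligned <- list()
    for (strand in c("first", "second")) {
      a <- alignToReference(reads[[strand]], amplicon, band = band)
      if (!is(a, "AlignedStrand")) {
        audit["unalignable"] <- audit["unalignable"] + 1L
        ok <- FALSE
        break
      }
      rf <- applyReadFilters(a, amplicon, expectedLen, minMapq, maxLenDev)
      if (!rf$accept) {
        audit[rf$reason] <- audit[rf$reason] + 1L
        ok <- FALSE
        break
      }
      aligned[[strand]] <- a
    }
    if (!ok) next
    res <- callDuplexErrors(aligned$first, aligned$second, amplicon,
                            qualThreshold, window)
    events[[length(events) + 1L]] <- rbind(res$first, res$second)
    if (nrow(res$discordant)) {
      d <- res$discordant
      d$molecule_id <- m$id
      disc[[length(disc) + 1L]] <- d
    }
    audit["molecules_called"] <- audit["molecules_called"] + 1L
    p1 <- projectToReference(aligned$first, L)
    p2 <- projectToReference(aligned$second, L)
    nBases <- nBases + sum(mask & !is.na(p1$bases) & !is.na(p2$bases))
  }
  ev <- if (length(events)) do.call(rbind, events) else .emptyEvents()
  rownames(ev) <- NULL
  dc <- if (length(disc)) do.call(rbind, disc) else
    data.frame(ref_pos = integer(), kind = character(),
               molecule_id = character(), stringsAsFactors = FALSE)
  list(events = ev, discordant = dc, audit = audit, nBases = nBases)
}

#' Run configuration
#'
#' Bundles paths, thresholds and labels for the command-style entry points.
#' Thresholds default to the standard filter cascade: 15 passes, event
#' quality 93, MAPQ 60, length deviation 50, alpha 0.05.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of configuration values.
#' @export
runConfig <- function(...) {
  cfg <- list(
    reference = NULL, reads = NULL, subreads = NULL, alignments = NULL,
    outputDir = ".",
    minPasses = 15L, qualThreshold = 93L, minMapq = 60L, maxLenDev = 50L,
    alpha = 0.05, window = 3L, band = 50L, seed = 1L,
    enzyme = "RT", template = "template", modification = "none",
    nMolecules = 100L, nPasses = 0L, rawError = 0, chimeraRate = 0,
    subRate = 1e-4, delRate = 2e-5, insRate = 1e-5,
    refLength = 500L, maxHomopolymer = 3L, requireAll4mers = FALSE)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

.writeManifest <- function(cfg, outputs, path) {
  jsonlite::write_json(
    list(tool = "DuplexFidelity",
         version = as.character(packageVersion("DuplexFidelity")),
         seed = cfg$seed,
         config = cfg[!vapply(cfg, is.null, TRUE)],
         outputs = outputs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulation entry point
#'
#' Generates (or loads) a reference, simulates a truth-annotated duplex data
#' set and writes: the reference FASTA (+ JSON sidecar), consensus FASTQ or
#' subread FASTQ, the truth TSV and a manifest recording the seed and
#' parameters. Rerunning with the same seed reproduces the outputs
#' byte-identically.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return list with the simulated data set and the written file paths.
#' @export
runSimulate <- function(cfg = runConfig()) {
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  amp <- if (!is.null(cfg$reference)) readAmplicon(cfg$reference)
         else generateReference(cfg$refLength, cfg$maxHomopolymer,
                                cfg$requireAll4mers, seed = cfg$seed,
                                modification = cfg$modification)
  ds <- simulateDataset(
    amp, cfg$nMolecules,
    rnap = errorModel(subRates = cfg$subRate, delRate = cfg$delRate,
                      insRate = cfg$insRate),
    rt1 = errorModel(subRates = cfg$subRate, delRate = cfg$delRate,
                     insRate = cfg$insRate),
    rt2 = errorModel(subRates = cfg$subRate, delRate = cfg$delRate,
                     insRate = cfg$insRate),
    seed = cfg$seed, nPasses = cfg$nPasses, rawError = cfg$rawError,
    chimeraRate = cfg$chimeraRate)
  paths <- list(reference = file.path(cfg$outputDir, "reference.fasta"),
                truth = file.path(cfg$outputDir, "truth.tsv"),
                manifest = file.path(cfg$outputDir, "manifest.json"))
  writeAmplicon(amp, paths$reference)
  writeTsv(ds$truth, paths$truth)
  if (cfg$nPasses > 0L) {
    paths$subreads <- file.path(cfg$outputDir, "subreads.fastq")
    writeSubreadFastq(ds$molecules, paths$subreads)
  } else {
    paths$reads <- file.path(cfg$outputDir, "reads.fastq")
    writeStrandFastq(unlist(lapply(ds$molecules,
                                   function(m) list(m$first, m$second))),
                     paths$reads)
  }
  .writeManifest(cfg, paths, paths$manifest)
  list(dataset = ds, paths = paths)
}

#' Error-calling entry point
#'
#' Loads the reference and reads (consensus FASTQ, subread FASTQ, or external
#' SAM/BAM alignments), runs consensus/alignment/filtering/error attribution
#' and writes the events TSV, the audit log (per-filter rejection counts and
#' the denominator) and a manifest.
#'
#' @param cfg a \code{\link{runConfig}} with \code{reference} and one of
#'   \code{reads}, \code{subreads} or \code{alignments} set.
#' @return list with events, audit counters, denominator and file paths.
#' @export
runCall <- function(cfg) {
  stopifnot(!is.null(cfg$reference))
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  amp <- readAmplicon(cfg$reference)
  if (!is.null(cfg$alignments)) {
    aligned <- readAlignedSam(cfg$alignments, amp)
    byMol <- split(aligned,
                   vapply(aligned, function(a) a@read@moleculeId, ""))
    molecules <- lapply(byMol, function(g) {
      out <- list(id = g[[1L]]@read@moleculeId)
      for (a in g) out[[a@read@strand]] <- a@read
      out
    })
  } else if (!is.null(cfg$subreads)) {
    molecules <- readSubreadFastq(cfg$subreads)
  } else {
    reads <- readStrandFastq(cfg$reads)
    byMol <- split(reads, vapply(reads, function(r) r@moleculeId, ""))
    molecules <- lapply(byMol, function(g) {
      out <- list(id = g[[1L]]@moleculeId)
      for (r in g) out[[r@strand]] <- r
      out
    })
  }
  res <- callPipeline(molecules, amp, minPasses = cfg$minPasses,
                      qualThreshold = cfg$qualThreshold,
                      minMapq = cfg$minMapq, maxLenDev = cfg$maxLenDev,
                      band = cfg$band, window = cfg$window)
  ev <- res$events
  if (nrow(ev)) {
    ev$template <- amp@id
    ev$enzyme <- cfg$enzyme
    ev$modification <- amp@modification
  }
  paths <- list(events = file.path(cfg$outputDir, "events.tsv"),
                audit = file.path(cfg$outputDir, "audit.json"),
                manifest = file.path(cfg$outputDir, "call_manifest.json"))
  writeTsv(ev, paths$events)
  jsonlite::write_json(list(filters = as.list(res$audit),
                            n_bases = res$nBases),
                       paths$audit, auto_unbox = TRUE, digits = NA)
  .writeManifest(cfg, paths, paths$manifest)
  list(events = ev, discordant = res$discordant, audit = res$audit,
       nBases = res$nBases, paths = paths)
}

#' Summary entry point
#'
#' Aggregates one or more event tables into the report tables: per-strand
#' total error rates and type percentages, indel size distributions,
#' hotspots, and — when a modified and an unmodified condition are given —
#' the per-subtype fold-change matrix with Bonferroni-adjusted t-test
#' verdicts across templates.
#'
#' @param events event data.frame (with \code{template} column).
#' @param nBases named numeric: analyzable sequenced bases per template.
#' @param amplicon reference \code{\linkS4class{Amplicon}} (for hotspots and
#'   context; optional).
#' @param eventsUnmod,nBasesUnmod optional unmodified-condition events and
#'   denominators for fold changes.
#' @param alpha significance level before Bonferroni adjustment.
#' @param outputDir if non-NULL, write the tables as TSV/JSON.
#' @return list of summary tables.
#' @export
runSummarize <- function(events, nBases, amplicon = NULL,
                         eventsUnmod = NULL, nBasesUnmod = NULL,
                         alpha = 0.05, outputDir = NULL) {
  totals <- data.frame(template = names(nBases),
                       n_bases = as.numeric(nBases),
                       stringsAsFactors = FALSE)
  out <- list()
  out$rates <- computeRates(events, totals, by = c("strand", "type"))
  out$rateSummary <- rateSummary(
    aggregate(list(n_events = out$rates$n_events),
              out$rates[c("template", "strand")], FUN = sum) |>
      merge(totals, by = "template") |>
      transform(rate = n_events / n_bases),
    by = "strand", templates = totals$template)
  out$typePercent <- errorTypePercentages(events)
  out$indelSizes <- indelSizeDistribution(events)
  if (!is.null(amplicon)) {
    out$hotspots <- rankHotspots(events[events$strand == "first", ,
                                        drop = FALSE], amplicon)
  }
  if (!is.null(eventsUnmod)) {
    sub <- function(ev, tot) {
      e <- ev[ev$strand == "first" & ev$type == "substitution", ,
              drop = FALSE]
      e$subtype <- e$rnap_pair
      r <- computeRates(e, tot, by = "subtype")
      aggregate(list(rate = r$rate), r["subtype"], FUN = mean)
    }
    totalsU <- data.frame(template = names(nBasesUnmod),
                          n_bases = as.numeric(nBasesUnmod),
                          stringsAsFactors = FALSE)
    out$foldChange <- foldChangeTable(sub(events, totals),
                                      sub(eventsUnmod, totalsU))
  }
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(out$rates, file.path(outputDir, "rates.tsv"))
    writeTsv(out$typePercent, file.path(outputDir, "type_percent.tsv"))
    writeTsv(out$indelSizes, file.path(outputDir, "indel_sizes.tsv"))
    if (!is.null(out$foldChange))
      writeTsv(out$foldChange, file.path(outputDir, "fold_change.tsv"))
  }
  out
}
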