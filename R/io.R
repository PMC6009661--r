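#' Read and write amplicon references
#'
#' The reference sequence travels as FASTA; the primer intervals (0-based,
#' half-open) and the modification label travel in a JSON sidecar
#' (\code{<fasta>.json}). A missing sidecar defaults to 20-base primers at
#' each end and no modification.
#'
#' @param amplicon an \code{\linkS4class{Amplicon}}.
#' @param path FASTA file path.
#' @return \code{readAmplicon} returns an \code{Amplicon};
#'   \code{writeAmplicon} returns \code{path} invisibly.
#' @export
writeAmplicon <- function(amplicon, path) {
  x <- Biostrings::DNAStringSet(setNames(amplicon@sequence, amplicon@id))
  Biostrings::writeXStringSet(x, path)
  jsonlite::write_json(
    list(id = amplicon@id,
         primer5 = amplicon@primer5, primer3 = amplicon@primer3,
         modification = amplicon@modification),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeAmplicon
#' @export
readAmplicon <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seq <- as.character(x[[1L]])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    Amplicon(meta$id, seq, primer5 = meta$primer5, primer3 = meta$primer3,
             modification = meta$modification)
  } else {
    Amplicon(names(x)[1L], seq)
  }
}

.PHRED_OFFSET <- 33L

#' Read and write strand-tagged consensus FASTQ
#'
#' Consensus reads are written one record per strand with the molecule id,
#' strand and pass count encoded in the read name
#' (\code{<molecule>/<strand> np=<passes>}); qualities are Phred+33.
#'
#' @param reads list of \code{\linkS4class{StrandRead}}s.
#' @param path FASTQ file path.
#' @return \code{readStrandFastq} returns a list of \code{StrandRead}s;
#'   \code{writeStrandFastq} returns \code{path} invisibly.
#' @export
writeStrandFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    writeLines(c(sprintf("@%s/%s np=%d", r@moleculeId, r@strand, r@nPasses),
                 r@sequence,
                 "+",
                 intToUtf8(r@qualities + .PHRED_OFFSET)), con)
  }
  invisible(path)
}

#' @rdname writeStrandFastq
#' @export
readStrandFastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4L == 0L)
  n <- length(lines) %/% 4L
  lapply(seq_len(n), function(i) {
    hdr <- sub("^@", "", lines[4L * i - 3L])
    m <- regmatches(hdr, regexec("^(\\S+)/(first|second) np=(\\d+)", hdr))[[1L]]
    if (length(m) != 4L) stop("unparseable read name: ", hdr)
    StrandRead(m[2L], m[3L], lines[4L * i - 2L],
               utf8ToInt(lines[4L * i]) - .PHRED_OFFSET,
               as.integer(m[4L]))
  })
}

#' Write grouped subreads as FASTQ
#'
#' Raw subreads carry no meaningful per-base qualities; they are written with
#' a constant placeholder quality and names \code{<molecule>/<strand>/<pass>}.
#'
#' @param molecules molecule list from \code{\link{simulateDataset}} run with
#'   \code{nPasses > 0}.
#' @param path FASTQ file path.
#' @return path, invisibly (\code{readSubreadFastq}: a molecule list).
#' @export
writeSubreadFastq <- function(molecules, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in molecules) {
    for (strand in c("first", "second")) {
      subs <- m[[paste0(strand, "Subreads")]]
      for (p in seq_along(subs)) {
        writeLines(c(sprintf("@%s/%s/%d", m$id, strand, p),
                     subs[p], "+",
                     strrep("!", nchar(subs[p]))), con)
      }
    }
  }
  invisible(path)
}

#' @rdname writeSubreadFastq
#' @export
readSubreadFastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4L == 0L)
  idx <- seq_len(length(lines) %/% 4L)
  hdr <- sub("^@", "", lines[4L * idx - 3L])
  seq <- lines[4L * idx - 2L]
  m <- regmatches(hdr, regexec("^(\\S+)/(first|second)/(\\d+)$", hdr))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("unparseable subread name: ", hdr[which(bad)[1L]])
  mol <- vapply(m, `[[`, "", 2L)
  strand <- vapply(m, `[[`, "", 3L)
  out <- lapply(split(seq_along(hdr), mol), function(ix) {
    list(id = mol[ix[1L]],
         firstSubreads = seq[ix[strand[ix] == "first"]],
         secondSubreads = seq[ix[strand[ix] == "second"]])
  })
  out[order(names(out))]
}

#' Tab-separated event, truth and audit tables
#'
#' Plain TSV writers/readers for the pipeline's tables (events, simulation
#' truth, per-filter audit counts). Coordinates are 0-based half-open.
#'
#' @param x data.frame.
#' @param path file path.
#' @return the path (writers, invisibly) or a data.frame (readers).
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write aligned strands as SAM
#'
#' Emits a minimal SAM file (one \code{@SQ} header line, CIGAR with
#' \code{=}/\code{X}/\code{I}/\code{D} ops, flag 0x10 for
#' reverse-complemented first-strand reads, pass count in the \code{np:i}
#' tag). Sequences are written in reference orientation, as aligners do.
#'
#' @param alignedList list of \code{\linkS4class{AlignedStrand}}s.
#' @param amplicon reference \code{\linkS4class{Amplicon}}.
#' @param path SAM file path.
#' @return path, invisibly.
#' @export
writeAlignedSam <- function(alignedList, amplicon, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", amplicon@id,
                       ampLength(amplicon))), con)
  for (a in alignedList) {
    seq <- a@read@sequence
    quals <- a@read@qualities
    flag <- 0L
    if (a@orientation == "reverse-complemented") {
      seq <- revComp(seq)
      quals <- rev(quals)
      flag <- bitwOr(flag, 16L)
    }
    writeLines(paste(
      sprintf("%s/%s", a@read@moleculeId, a@read@strand),
      flag, amplicon@id, a@refStart + 1L, a@mapq, cigarString(a), "*", 0, 0,
      seq, intToUtf8(quals + .PHRED_OFFSET),
      sprintf("np:i:%d", a@read@nPasses),
      sep = "\t"), con)
  }
  invisible(path)
}

#' Import externally produced alignments
#'
#' Reads a SAM/BAM file (via Rsamtools) of strand consensus reads mapped to
#' the reference and converts the records into
#' \code{\linkS4class{AlignedStrand}}s: CIGAR \code{M}/\code{=}/\code{X}/
#' \code{I}/\code{D} are accepted (\code{M} is resolved against the
#' reference), MAPQ is kept from the aligner, flag 0x10 marks
#' reverse-complemented (first-strand) reads and supplementary alignments
#' (flag 0x800) are counted per read name. Indels are left-aligned on import.
#'
#' @param path SAM or BAM file.
#' @param amplicon reference \code{\linkS4class{Amplicon}}.
#' @return list of \code{AlignedStrand}s (primary alignments only, with
#'   \code{supplementaryCount} filled in).
#' @export
readAlignedSam <- function(path, amplicon) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to import SAM/BAM alignments")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "np")
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  np <- x$tag$np
  supp <- bitwAnd(x$flag, 2048L) > 0L
  suppCount <- table(x$qname[supp])
  out <- list()
  for (i in which(!supp & !is.na(x$pos))) {
    qn <- x$qname[i]
    m <- regmatches(qn, regexec("^(\\S+?)/(first|second)$", qn))[[1L]]
    molId <- if (length(m) == 3L) m[2L] else qn
    strand <- if (length(m) == 3L) m[3L] else "second"
    rev <- bitwAnd(x$flag[i], 16L) > 0L
    seqRefFrame <- as.character(x$seq[[i]])
    qualRefFrame <- as.integer(charToRaw(as.character(x$qual[[i]]))) -
      .PHRED_OFFSET
    nativeSeq <- if (rev) revComp(seqRefFrame) else seqRefFrame
    nativeQual <- if (rev) rev(qualRefFrame) else qualRefFrame
    read <- StrandRead(molId, strand, nativeSeq, nativeQual,
                       if (!is.null(np) && !is.na(np[i])) np[i] else 1L)
    refStart <- x$pos[i] - 1L
    ops <- .opsFromCigar(x$cigar[i], amplicon@sequence, seqRefFrame, refStart)
    ops <- leftAlignOps(ops, amplicon@sequence, seqRefFrame, refStart)
    out[[length(out) + 1L]] <-
      new("AlignedStrand", read = read, ops = ops,
          refStart = as.integer(refStart),
          refEnd = as.integer(refStart + sum(ops != OP_INS)),
          mapq = as.integer(x$mapq[i]),
          orientation = if (rev) "reverse-complemented" else "as-is",
          supplementaryCount =
            as.integer(if (qn %in% names(suppCount)) suppCount[[qn]] else 0L),
          score = NA_real_)
  }
  out
}

.opsFromCigar <- function(cigar, ref, seqRefFrame, refStart) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  out <- integer(0)
  refCh <- strsplit(ref, "", fixed = TRUE)[[1L]]
  readCh <- strsplit(seqRefFrame, "", fixed = TRUE)[[1L]]
  i <- refStart  # 0-based
  j <- 0L
  for (k in seq_along(ops)) {
    l <- lens[k]
    code <- switch(ops[k],
                   "=" = OP_MATCH, "X" = OP_MISMATCH, "I" = OP_INS,
                   "D" = OP_DEL, "M" = NA_integer_,
                   "S" = OP_INS,  # soft clip: read-consuming, unaligned
                   "H" = NULL, "P" = NULL, "N" = OP_DEL)
    if (is.null(code)) next
    if (is.na(code)) {  # M: resolve per base against the reference
      seg <- ifelse(refCh[(i + 1L):(i + l)] == readCh[(j + 1L):(j + l)],
                    OP_MATCH, OP_MISMATCH)
      out <- c(out, seg)
      i <- i + l; j <- j + l
    } else {
      out <- c(out, rep(code, l))
      if (code != OP_INS) i <- i + l
      if (code != OP_DEL) j <- j + l
    }
  }
  out
}
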