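#' Default alignment scoring scheme
#'
#' Match +2, mismatch -4, gap open -6, gap extension -1 (a length-k gap costs
#' \code{open + k * ext}); concordant with widely used read mappers. The
#' downstream duplex-confirmation and quality filters make the pipeline
#' insensitive to moderate changes in these scores.
#'
#' @return list with \code{match}, \code{mismatch}, \code{gapOpen},
#'   \code{gapExt}.
#' @export
defaultAlignScores <- function() {
  list(match = 2L, mismatch = -4L, gapOpen = 6L, gapExt = 1L)
}

#' Align a strand consensus read to the reference
#'
#' Semi-global affine-gap alignment with free end gaps (a read may start or
#' end inside the reference, and read overhang beyond the reference is
#' unpenalised). First-strand reads are reverse-complemented into reference
#' frame before alignment and flagged. Indels are left-aligned against the
#' reference after alignment so that first- and second-strand events at the
#' same locus coincide positionally. Mapping quality is set to a sentinel
#' maximum (60) for internal alignments; alignments supplied externally keep
#' the aligner's MAPQ.
#'
#' @param read a \code{\linkS4class{StrandRead}}.
#' @param amplicon an \code{\linkS4class{Amplicon}}.
#' @param scores scoring scheme, see \code{\link{defaultAlignScores}}.
#' @param band band half-width around the main diagonal (use a negative value
#'   for an unbanded alignment).
#' @param minScore score floor below which the read is reported unalignable;
#'   default one quarter of the perfect-match score of the read.
#' @return an \code{\linkS4class{AlignedStrand}}, or an
#'   \code{"alignmentReject"} object (a list with the \code{reason}
#'   \code{"unalignable"}) when the best score is below the floor.
#' @export
alignToReference <- function(read, amplicon, scores = defaultAlignScores(),
                             band = 50L, minScore = NULL) {
  seq <- read@sequence
  quals <- read@qualities
  orient <- "as-is"
  if (read@strand == "first") {
    seq <- revComp(seq)
    quals <- rev(quals)
    orient <- "reverse-complemented"
  }
  if (is.null(minScore))
    minScore <- scores$match * nchar(seq) / 4
  r <- .align_overlap_cpp(amplicon@sequence, seq, scores$match,
                          scores$mismatch, scores$gapOpen, scores$gapExt,
                          as.integer(band))
  if (!isTRUE(r$ok) || r$score < minScore) {
    out <- structure(list(reason = "unalignable"), class = "alignmentReject")
    return(out)
  }
  ops <- leftAlignOps(as.integer(r$ops), amplicon@sequence, seq,
                      r$ref_start)
  new("AlignedStrand", read = read, ops = ops,
      refStart = as.integer(r$ref_start), refEnd = as.integer(r$ref_end),
      mapq = 60L, orientation = orient, supplementaryCount = 0L,
      score = as.numeric(r$score))
}

#' Left-align indels in an alignment op list
#'
#' Shifts every insertion/deletion run to its leftmost equivalent placement
#' against the reference: a run moves one column left whenever the preceding
#' column is a match and the trailing base of the indel equals the preceding
#' reference base. Mandatory before event extraction, so that the same indel
#' called on both strands lands on the same reference coordinate.
#'
#' @param ops integer op codes (0 match, 1 mismatch, 2 insertion,
#'   3 deletion), one per alignment column, reference order.
#' @param ref,read the aligned sequences (read already in reference frame).
#' @param refStart 0-based reference start of the alignment.
#' @return the op vector with indel runs left-aligned.
#' @export
leftAlignOps <- function(ops, ref, read, refStart = 0L) {
  refCh <- strsplit(ref, "", fixed = TRUE)[[1L]]
  readCh <- strsplit(read, "", fixed = TRUE)[[1L]]
  n <- length(ops)
  if (n == 0L) return(ops)
  repeat {
    # per-op coordinates (1-based index of the base the op consumes)
    refIdx <- refStart + cumsum(ops != OP_INS)
    readIdx <- cumsum(ops != OP_DEL)
    r <- rle(ops)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    moved <- FALSE
    for (k in seq_along(r$values)) {
      v <- r$values[k]
      if (v != OP_INS && v != OP_DEL) next
      s <- starts[k]; e <- ends[k]
      while (s > 1L && ops[s - 1L] == OP_MATCH) {
        if (v == OP_DEL) {
          a <- refIdx[s]          # first deleted ref base (1-based)
          b <- refIdx[e]          # last deleted ref base
          if (refCh[a - 1L] != refCh[b]) break
        } else {
          jb <- readIdx[e]        # last inserted read base
          pa <- refIdx[s - 1L]    # ref base of the preceding match
          if (readCh[jb] != refCh[pa]) break
        }
        ops[s - 1L] <- v
        ops[e] <- OP_MATCH
        s <- s - 1L; e <- e - 1L
        refIdx <- refStart + cumsum(ops != OP_INS)
        readIdx <- cumsum(ops != OP_DEL)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  # re-derive match/mismatch codes for aligned columns (shifts can change them)
  refIdx <- refStart + cumsum(ops != OP_INS)
  readIdx <- cumsum(ops != OP_DEL)
  aligned <- ops == OP_MATCH | ops == OP_MISMATCH
  ops[aligned] <- ifelse(refCh[refIdx[aligned]] == readCh[readIdx[aligned]],
                         OP_MATCH, OP_MISMATCH)
  as.integer(ops)
}

#' Read-level filter cascade
#'
#' Applies the read-acceptance rules in fixed order and reports the first
#' failing rule: mapping quality below 60; alignment not starting within the
#' 5'-primer region; not ending within the 3'-primer region; supplementary
#' (split/chimeric) alignments present; read length deviating from the
#' expected length by more than 50 bases. All boundaries are inclusive on the
#' accepting side (MAPQ 60 passes, deviation 50 passes). The accept/reject
#' outcome does not depend on rule order, only the recorded reason does.
#'
#' @param aligned an \code{\linkS4class{AlignedStrand}}.
#' @param amplicon an \code{\linkS4class{Amplicon}}.
#' @param expectedLen expected read length (default: amplicon length).
#' @param minMapq minimum mapping quality (default 60).
#' @param maxLenDev maximum absolute length deviation (default 50).
#' @return list with \code{accept} and \code{reason} (one of \code{"mapq"},
#'   \code{"span5"}, \code{"span3"}, \code{"chimera"}, \code{"length"} or
#'   \code{NA}).
#' @export
applyReadFilters <- function(aligned, amplicon, expectedLen = NULL,
                             minMapq = 60L, maxLenDev = 50L) {
  if (is.null(expectedLen)) expectedLen <- ampLength(amplicon)
  reject <- function(reason) list(accept = FALSE, reason = reason)
  if (aligned@mapq < minMapq) return(reject("mapq"))
  p5 <- amplicon@primer5; p3 <- amplicon@primer3
  if (!(aligned@refStart >= p5[1L] && aligned@refStart < p5[2L]))
    return(reject("span5"))
  if (!(aligned@refEnd > p3[1L] && aligned@refEnd <= p3[2L]))
    return(reject("span3"))
  if (aligned@supplementaryCount > 0L) return(reject("chimera"))
  if (abs(nchar(aligned@read@sequence) - expectedLen) > maxLenDev)
    return(reject("length"))
  list(accept = TRUE, reason = NA_character_)
}

#' Project an aligned strand into reference coordinates
#'
#' Expands the op list into per-reference-position observed bases and
#' qualities plus a table of insertions (anchored at the 0-based position of
#' the following reference base). Deleted positions carry \code{"-"};
#' positions outside the aligned span are \code{NA}.
#'
#' @param aligned an \code{\linkS4class{AlignedStrand}}.
#' @param refLen reference length.
#' @return list with \code{bases} (character), \code{quals} (integer) and
#'   \code{ins} (data.frame pos/seq/qual, insertion quality = min inserted
#'   base quality).
#' @export
projectToReference <- function(aligned, refLen) {
  seq <- aligned@read@sequence
  quals <- aligned@read@qualities
  if (aligned@orientation == "reverse-complemented") {
    seq <- revComp(seq)
    quals <- rev(quals)
  }
  readCh <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ops <- aligned@ops
  bases <- rep(NA_character_, refLen)
  qv <- rep(NA_integer_, refLen)

  refCons <- ops != OP_INS
  readCons <- ops != OP_DEL
  refIdx <- aligned@refStart + cumsum(refCons)        # 1-based ref position
  readIdx <- cumsum(readCons)
  alignedCols <- ops == OP_MATCH | ops == OP_MISMATCH
  bases[refIdx[alignedCols]] <- readCh[readIdx[alignedCols]]
  qv[refIdx[alignedCols]] <- quals[readIdx[alignedCols]]
  delCols <- ops == OP_DEL
  bases[refIdx[delCols]] <- "-"

  insCols <- which(ops == OP_INS)
  ins <- data.frame(pos = integer(), seq = character(), qual = integer(),
                    stringsAsFactors = FALSE)
  if (length(insCols)) {
    anchor <- aligned@refStart + cumsum(refCons)[insCols]  # following ref base
    grp <- cumsum(c(TRUE, diff(insCols) != 1L))
    pieces <- split(insCols, grp)
    ins <- do.call(rbind, lapply(pieces, function(ix) {
      data.frame(pos = anchor[match(ix[1L], insCols)],
                 seq = paste(readCh[readIdx[ix]], collapse = ""),
                 qual = min(quals[readIdx[ix]]),
                 stringsAsFactors = FALSE)
    }))
    rownames(ins) <- NULL
  }
  list(bases = bases, quals = qv, ins = ins,
       refStart = aligned@refStart, refEnd = aligned@refEnd)
}
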