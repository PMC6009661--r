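#' Reference amplicon with primer annotations
#'
#' An \code{Amplicon} holds a reference sequence in the RNA-sense strand
#' (DNA alphabet), the 5' and 3' primer intervals (0-based, half-open) and a
#' modification label naming which canonical base is fully substituted in the
#' RNA (\code{"none"}, \code{"m6A"}, \code{"pseudouridine"}, \code{"m5C"},
#' \code{"m5U"} or \code{"hm5U"}). The analyzable region is the sequence minus
#' both primer intervals; error calling and rate denominators are restricted
#' to it.
#'
#' @slot id character label.
#' @slot sequence character, DNA alphabet, RNA-sense strand.
#' @slot primer5,primer3 integer(2), 0-based half-open intervals.
#' @slot modification character scalar.
#' @export
setClass("Amplicon",
  representation(id = "character", sequence = "character",
                 primer5 = "integer", primer3 = "integer",
                 modification = "character"))

MODIFICATION_LABELS <- c("none", "m6A", "pseudouridine", "m5C", "m5U", "hm5U")

setValidity("Amplicon", function(object) {
  msg <- character()
  s <- object@sequence
  if (length(s) != 1L || nchar(s) < 100L)
    msg <- c(msg, "sequence must be a single string of length >= 100")
  if (length(s) == 1L && grepl("[^ACGT]", s))
    msg <- c(msg, "sequence alphabet must be A/C/G/T")
  L <- nchar(s)
  for (nm in c("primer5", "primer3")) {
    p <- slot(object, nm)
    if (length(p) != 2L || any(is.na(p)) || p[1L] < 0L || p[2L] > L ||
        p[1L] > p[2L])
      msg <- c(msg, sprintf("%s must be a 0-based half-open interval in [0, len)", nm))
  }
  p5 <- object@primer5; p3 <- object@primer3
  if (length(p5) == 2L && length(p3) == 2L &&
      max(p5[1L], p3[1L]) < min(p5[2L], p3[2L]))
    msg <- c(msg, "primer intervals must not overlap")
  if (L - diff(object@primer5) - diff(object@primer3) <= 0L)
    msg <- c(msg, "analyzable region must be non-empty")
  if (!object@modification %in% MODIFICATION_LABELS)
    msg <- c(msg, sprintf("modification must be one of %s",
                          paste(MODIFICATION_LABELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an Amplicon
#'
#' @param id character label.
#' @param sequence DNA string (A/C/G/T), RNA-sense strand, length >= 100.
#' @param primer5,primer3 integer(2), 0-based half-open primer intervals;
#'   defaults place 20-base primers at each end.
#' @param modification modification label (see \code{\linkS4class{Amplicon}}).
#' @return an \code{Amplicon} object.
#' @examples
#' amp <- Amplicon("amp1", paste(rep("ACGT", 50), collapse = ""))
#' analyzableLength(amp)
#' @export
Amplicon <- function(id, sequence,
                     primer5 = c(0L, 20L),
                     primer3 = c(nchar(sequence) - 20L, nchar(sequence)),
                     modification = "none") {
  new("Amplicon", id = as.character(id), sequence = toupper(sequence),
      primer5 = as.integer(primer5), primer3 = as.integer(primer3),
      modification = modification)
}

#' Per-molecule strand consensus read
#'
#' A \code{StrandRead} is the consensus sequence of one strand of one
#' sequenced molecule, with per-base Phred qualities (0-93) and the number of
#' polymerase passes that produced it. First-strand (cDNA) reads are stored in
#' their native orientation, i.e. the reverse complement of the reference
#' frame; second-strand reads are reference-sense.
#'
#' @slot moleculeId character.
#' @slot strand \code{"first"} or \code{"second"}.
#' @slot sequence character, DNA alphabet, native orientation.
#' @slot qualities integer per-base Phred scores in [0, 93].
#' @slot nPasses positive integer.
#' @export
setClass("StrandRead",
  representation(moleculeId = "character", strand = "character",
                 sequence = "character", qualities = "integer",
                 nPasses = "integer"))

setValidity("StrandRead", function(object) {
  msg <- character()
  if (!object@strand %in% c("first", "second"))
    msg <- c(msg, "strand must be 'first' or 'second'")
  if (length(object@qualities) != nchar(object@sequence))
    msg <- c(msg, "length(qualities) must equal sequence length")
  if (any(object@qualities < 0L | object@qualities > 93L))
    msg <- c(msg, "qualities must lie in [0, 93]")
  if (object@nPasses < 1L)
    msg <- c(msg, "nPasses must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a StrandRead
#'
#' @param moleculeId molecule label.
#' @param strand \code{"first"} or \code{"second"}.
#' @param sequence DNA string in native orientation.
#' @param qualities integer Phred scores (0-93); a scalar is recycled.
#' @param nPasses number of passes behind the consensus.
#' @return a \code{StrandRead}.
#' @export
StrandRead <- function(moleculeId, strand, sequence, qualities = 93L,
                       nPasses = 1L) {
  if (length(qualities) == 1L)
    qualities <- rep(as.integer(qualities), nchar(sequence))
  new("StrandRead", moleculeId = as.character(moleculeId), strand = strand,
      sequence = toupper(sequence), qualities = as.integer(qualities),
      nPasses = as.integer(nPasses))
}

#' A strand read projected onto the reference
#'
#' An \code{AlignedStrand} couples a \code{StrandRead} with its alignment to
#' the reference: a per-column op list in reference order (codes: 0 match,
#' 1 mismatch, 2 insertion, 3 deletion), the aligned reference span (0-based,
#' half-open), a mapping quality, the orientation applied before alignment and
#' the number of supplementary alignments (non-zero marks a split/chimeric
#' mapping when alignments come from an external aligner).
#'
#' @slot read the \code{StrandRead}.
#' @slot ops integer op codes, one per alignment column.
#' @slot refStart,refEnd integer, 0-based half-open reference span.
#' @slot mapq integer mapping quality.
#' @slot orientation \code{"as-is"} or \code{"reverse-complemented"}.
#' @slot supplementaryCount integer.
#' @slot score numeric alignment score.
#' @export
setClass("AlignedStrand",
  representation(read = "StrandRead", ops = "integer",
                 refStart = "integer", refEnd = "integer",
                 mapq = "integer", orientation = "character",
                 supplementaryCount = "integer", score = "numeric"))

OP_MATCH <- 0L; OP_MISMATCH <- 1L; OP_INS <- 2L; OP_DEL <- 3L

setValidity("AlignedStrand", function(object) {
  msg <- character()
  ops <- object@ops
  if (any(!ops %in% 0:3)) msg <- c(msg, "ops codes must be in 0..3")
  refCons <- sum(ops != OP_INS)
  readCons <- sum(ops != OP_DEL)
  if (refCons != object@refEnd - object@refStart)
    msg <- c(msg, "reference-consuming op length must equal refEnd - refStart")
  if (readCons != nchar(object@read@sequence))
    msg <- c(msg, "read-consuming op length must equal read length")
  if (!object@orientation %in% c("as-is", "reverse-complemented"))
    msg <- c(msg, "orientation must be 'as-is' or 'reverse-complemented'")
  if (length(msg)) msg else TRUE
})

#' Stage-specific replication error model
#'
#' An \code{ErrorModel} parameterises error injection for one synthesis stage
#' (RNA synthesis, first-strand cDNA synthesis or second-strand synthesis).
#' The substitution matrix is indexed (expected product base, observed product
#' base) in the frame of the strand being synthesized; the diagonal is unused.
#' \code{prevWeights} multiplies substitution probabilities by the identity of
#' the preceding template base (reference frame), which lets simulations
#' emulate sequence-context-biased misincorporation.
#'
#' @slot subRates 4x4 numeric matrix, rows/cols A,C,G,T; diagonal unused.
#' @slot delRate,insRate per-base indel start probabilities.
#' @slot slippageRate per-repeat-locus probability of whole-unit gain/loss.
#' @slot indelSizeDist probability vector over indel lengths 1..K.
#' @slot prevWeights named numeric(4) multipliers by preceding base.
#' @export
setClass("ErrorModel",
  representation(subRates = "matrix", delRate = "numeric",
                 insRate = "numeric", slippageRate = "numeric",
                 indelSizeDist = "numeric", prevWeights = "numeric"))

setValidity("ErrorModel", function(object) {
  msg <- character()
  m <- object@subRates
  if (!all(dim(m) == c(4L, 4L))) msg <- c(msg, "subRates must be 4x4")
  if (any(m < 0 | m > 1)) msg <- c(msg, "subRates must lie in [0, 1]")
  for (nm in c("delRate", "insRate", "slippageRate")) {
    v <- slot(object, nm)
    if (length(v) != 1L || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a probability", nm))
  }
  wmax <- max(object@prevWeights)
  diag2 <- m; diag(diag2) <- 0
  tot <- max(rowSums(diag2)) * wmax + object@delRate + object@insRate
  if (is.finite(tot) && tot >= 0.5)
    msg <- c(msg, "per-base total event probability must stay below 0.5")
  if (abs(sum(object@indelSizeDist) - 1) > 1e-8)
    msg <- c(msg, "indelSizeDist must sum to 1")
  if (length(object@prevWeights) != 4L ||
      !identical(names(object@prevWeights), DNA_BASES) ||
      any(object@prevWeights < 0))
    msg <- c(msg, "prevWeights must be non-negative and named A,C,G,T")
  if (length(msg)) msg else TRUE
})

#' Construct an ErrorModel
#'
#' @param subRates 4x4 substitution probability matrix (expected product base
#'   in rows, observed in columns; diagonal ignored), or a single number taken
#'   as the total per-base substitution rate spread uniformly over the three
#'   alternatives.
#' @param delRate,insRate per-base deletion / insertion start probabilities.
#' @param slippageRate per-repeat-locus probability of gaining or losing one
#'   whole repeat unit.
#' @param indelSizeDist probability vector over indel lengths 1..K
#'   (default: all indels are single-base).
#' @param prevWeights named multipliers on substitution rates by the preceding
#'   reference-frame base (default: no context bias).
#' @return an \code{ErrorModel}.
#' @examples
#' errorModel(subRates = 5e-4, delRate = 1e-4)
#' @export
errorModel <- function(subRates = 0, delRate = 0, insRate = 0,
                       slippageRate = 0, indelSizeDist = 1,
                       prevWeights = c(A = 1, C = 1, G = 1, T = 1)) {
  if (is.numeric(subRates) && length(subRates) == 1L)
    subRates <- uniformSubRates(subRates)
  dimnames(subRates) <- list(DNA_BASES, DNA_BASES)
  new("ErrorModel", subRates = subRates, delRate = delRate,
      insRate = insRate, slippageRate = slippageRate,
      indelSizeDist = indelSizeDist / sum(indelSizeDist),
      prevWeights = prevWeights[DNA_BASES])
}

#' Uniform substitution-rate matrix
#'
#' @param totalRate total per-base substitution probability, spread evenly
#'   over the three alternative bases.
#' @return a 4x4 matrix with \code{totalRate/3} off the diagonal.
#' @export
uniformSubRates <- function(totalRate) {
  m <- matrix(totalRate / 3, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(m) <- 0
  m
}

setMethod("show", "Amplicon", function(object) {
  cat(sprintf("Amplicon '%s': %d bp (%s), analyzable %d bp, primers [%d,%d) and [%d,%d)\n",
              object@id, nchar(object@sequence), object@modification,
              analyzableLength(object),
              object@primer5[1L], object@primer5[2L],
              object@primer3[1L], object@primer3[2L]))
})

setMethod("show", "StrandRead", function(object) {
  cat(sprintf("StrandRead %s/%s: %d bp, %d passes, min qual %d\n",
              object@moleculeId, object@strand, nchar(object@sequence),
              object@nPasses, min(object@qualities)))
})

setMethod("show", "AlignedStrand", function(object) {
  cat(sprintf("AlignedStrand %s/%s: ref [%d,%d), MAPQ %d, %s, CIGAR %s\n",
              object@read@moleculeId, object@read@strand,
              object@refStart, object@refEnd, object@mapq,
              object@orientation, cigarString(object)))
})
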