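#' @name accessors
#' @title Accessors for DuplexFidelity classes
#' @description Slot accessors for \code{\linkS4class{Amplicon}},
#'   \code{\linkS4class{StrandRead}} and \code{\linkS4class{AlignedStrand}}.
#' @param x an object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("ampId", function(x) standardGeneric("ampId"))
#' @rdname accessors
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))
#' @rdname accessors
#' @export
setGeneric("primer5", function(x) standardGeneric("primer5"))
#' @rdname accessors
#' @export
setGeneric("primer3", function(x) standardGeneric("primer3"))
#' @rdname accessors
#' @export
setGeneric("modification", function(x) standardGeneric("modification"))
#' @rdname accessors
#' @export
setGeneric("moleculeId", function(x) standardGeneric("moleculeId"))
#' @rdname accessors
#' @export
setGeneric("strandLabel", function(x) standardGeneric("strandLabel"))
#' @rdname accessors
#' @export
setGeneric("readSequence", function(x) standardGeneric("readSequence"))
#' @rdname accessors
#' @export
setGeneric("readQualities", function(x) standardGeneric("readQualities"))
#' @rdname accessors
#' @export
setGeneric("nPasses", function(x) standardGeneric("nPasses"))
#' @rdname accessors
#' @export
setGeneric("alignmentOps", function(x) standardGeneric("alignmentOps"))
#' @rdname accessors
#' @export
setGeneric("refStart", function(x) standardGeneric("refStart"))
#' @rdname accessors
#' @export
setGeneric("refEnd", function(x) standardGeneric("refEnd"))
#' @rdname accessors
#' @export
setGeneric("mapq", function(x) standardGeneric("mapq"))
#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname accessors
#' @export
setGeneric("cigarString", function(x) standardGeneric("cigarString"))

#' @rdname accessors
setMethod("ampId", "Amplicon", function(x) x@id)
#' @rdname accessors
setMethod("refSequence", "Amplicon", function(x) x@sequence)
#' @rdname accessors
setMethod("primer5", "Amplicon", function(x) x@primer5)
#' @rdname accessors
setMethod("primer3", "Amplicon", function(x) x@primer3)
#' @rdname accessors
setMethod("modification", "Amplicon", function(x) x@modification)
#' @rdname accessors
setMethod("moleculeId", "StrandRead", function(x) x@moleculeId)
#' @rdname accessors
setMethod("strandLabel", "StrandRead", function(x) x@strand)
#' @rdname accessors
setMethod("readSequence", "StrandRead", function(x) x@sequence)
#' @rdname accessors
setMethod("readQualities", "StrandRead", function(x) x@qualities)
#' @rdname accessors
setMethod("nPasses", "StrandRead", function(x) x@nPasses)
#' @rdname accessors
setMethod("alignmentOps", "AlignedStrand", function(x) x@ops)
#' @rdname accessors
setMethod("refStart", "AlignedStrand", function(x) x@refStart)
#' @rdname accessors
setMethod("refEnd", "AlignedStrand", function(x) x@refEnd)
#' @rdname accessors
setMethod("mapq", "AlignedStrand", function(x) x@mapq)
#' @rdname accessors
setMethod("orientation", "AlignedStrand", function(x) x@orientation)

#' @rdname accessors
setMethod("cigarString", "AlignedStrand", function(x) {
  if (length(x@ops) == 0L) return("*")
  r <- rle(x@ops)
  paste0(r$lengths, c("=", "X", "I", "D")[r$values + 1L], collapse = "")
})

#' Amplicon geometry helpers
#'
#' \code{ampLength} is the reference length; \code{analyzableMask} marks the
#' analyzable positions (outside both primer intervals) as a logical vector
#' indexed by 0-based position + 1; \code{analyzableLength} counts them.
#'
#' @param x an \code{Amplicon}.
#' @return see description.
#' @export
ampLength <- function(x) nchar(x@sequence)

#' @rdname ampLength
#' @export
analyzableMask <- function(x) {
  L <- ampLength(x)
  m <- rep(TRUE, L)
  if (diff(x@primer5) > 0L) m[(x@primer5[1L] + 1L):x@primer5[2L]] <- FALSE
  if (diff(x@primer3) > 0L) m[(x@primer3[1L] + 1L):x@primer3[2L]] <- FALSE
  m
}

#' @rdname ampLength
#' @export
analyzableLength <- function(x) sum(analyzableMask(x))
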