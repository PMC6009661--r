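#' Build a per-strand consensus read from subreads
#'
#' Column-wise majority-vote consensus: every subread is aligned pairwise to a
#' draft (the lexicographically smallest among the longest subreads, which
#' makes the result invariant to subread order), bases are tallied per draft
#' column, and the winning symbol is emitted. Column ties are broken by a
#' fixed priority (a base beats a gap, then A < C < G < T). Insertions
#' relative to the draft are kept when more than half of the covering
#' subreads carry the same inserted string. Per-base quality is the
#' Phred-scaled column agreement,
#' \code{min(93, round(-10 log10(max(1 - f, 10^-9.3))))} with \code{f} the
#' fraction of covering subreads that agree, so quality saturates at 93
#' exactly on unanimous columns.
#'
#' @param subreads character vector of subread sequences (>= 1).
#' @param moleculeId,strand metadata for the resulting read.
#' @param band alignment band half-width for subread-to-draft alignment.
#' @return a \code{\linkS4class{StrandRead}} with \code{nPasses} equal to the
#'   number of subreads.
#' @examples
#' r <- buildConsensus(rep("ACGTACGTAC", 15), "m1", "first")
#' readQualities(r)[1]  # 93: unanimous
#' @export
buildConsensus <- function(subreads, moleculeId = "mol", strand = "second",
                           band = 50L) {
  if (length(subreads) < 1L) stop("empty subread list")
  sc <- defaultAlignScores()
  res <- .build_consensus_cpp(as.character(subreads), sc$match, sc$mismatch,
                              sc$gapOpen, sc$gapExt, as.integer(band))
  StrandRead(moleculeId, strand, res$seq, as.integer(res$qual),
             length(subreads))
}

#' Consensus-level read filter
#'
#' Accepts a consensus read only if it was built from at least
#' \code{minPasses} passes (default 15, boundary inclusive: a 15-pass read is
#' accepted, a 14-pass read rejected).
#'
#' @param read a \code{\linkS4class{StrandRead}}.
#' @param minPasses minimum pass count.
#' @return list with \code{accept} (logical) and \code{reason}
#'   (\code{NA} when accepted, \code{"min_passes"} otherwise).
#' @export
filterConsensus <- function(read, minPasses = 15L) {
  if (read@nPasses < minPasses)
    list(accept = FALSE, reason = "min_passes")
  else
    list(accept = TRUE, reason = NA_character_)
}
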