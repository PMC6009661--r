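#' Classify a first-strand substitution into its equivalent RNAP/RT pair
#'
#' A first-strand (cDNA) mismatch can arise from two indistinguishable
#' misincorporation scenarios: an RNA polymerase error while synthesizing the
#' RNA, or a reverse transcriptase error while copying it. Given the expected
#' RNA-sense reference base and the base observed in the cDNA, this returns
#' both equivalent labels: the RNA polymerase pair
#' (reference RNA base -> equivalent RNA product base) and the reverse
#' transcriptase pair (cDNA template base -> incorporated cDNA base). RNA-side
#' bases are rendered with U; for example reference A with observed cDNA C
#' gives \code{rA->rG / dT->dC}.
#'
#' @param refBase reference base (RNA-sense, DNA alphabet A/C/G/T).
#' @param cdnaBase base observed in the cDNA (first strand, its own frame).
#' @return named character vector with elements \code{rnap} and \code{rt}.
#' @examples
#' classifySubstitution("A", "C")  # rA->rG / dT->dC
#' @export
classifySubstitution <- function(refBase, cdnaBase) {
  stopifnot(refBase %in% DNA_BASES, cdnaBase %in% DNA_BASES)
  if (cdnaBase == DNA_COMPLEMENT[[refBase]])
    stop("cdnaBase is the complement of refBase: a match, not an error")
  rnap <- sprintf("r%s->r%s", .toRna(refBase),
                  .toRna(DNA_COMPLEMENT[[cdnaBase]]))
  rt <- sprintf("d%s->d%s", DNA_COMPLEMENT[[refBase]], cdnaBase)
  c(rnap = rnap, rt = rt)
}

.emptyEvents <- function() {
  data.frame(molecule_id = character(), strand = character(),
             type = character(), ref_pos = integer(), expected = character(),
             observed = character(), length = integer(),
             rnap_pair = character(), rt_pair = character(),
             event_qual = integer(), context = character(),
             stringsAsFactors = FALSE)
}

.eventRow <- function(moleculeId, strand, type, pos, expected, observed,
                      len, rnap, rt, qual, context) {
  data.frame(molecule_id = moleculeId, strand = strand, type = type,
             ref_pos = pos, expected = expected, observed = observed,
             length = len, rnap_pair = rnap, rt_pair = rt,
             event_qual = qual, context = context, stringsAsFactors = FALSE)
}

.refContext <- function(refCh, pos, window) {
  lo <- max(1L, pos + 1L - window)
  hi <- min(length(refCh), pos + 1L + window)
  paste(c(refCh[lo:(pos)], "[", refCh[pos + 1L], "]",
          if (pos + 2L <= hi) refCh[(pos + 2L):hi]), collapse = "")
}

# gap runs ('-') in a projected base vector: data.frame(start0, len, endQual)
.gapRuns <- function(bases, quals) {
  isGap <- !is.na(bases) & bases == "-"
  if (!any(isGap))
    return(data.frame(start = integer(), len = integer(),
                      qual = integer(), stringsAsFactors = FALSE))
  r <- rle(isGap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  qualAt <- function(i) {
    if (i < 1L || i > length(quals) || is.na(quals[i])) NA_integer_
    else quals[i]
  }
  data.frame(
    start = starts[keep] - 1L,
    len = r$lengths[keep],
    qual = vapply(keep, function(k) {
      q <- c(qualAt(starts[k] - 1L), qualAt(ends[k] + 1L))
      if (all(is.na(q))) 0L else as.integer(min(q, na.rm = TRUE))
    }, 0L),
    stringsAsFactors = FALSE)
}

#' Call duplex-confirmed errors for one molecule
#'
#' Partitions every discrepancy between the two strand alignments of one
#' molecule into exactly one of three classes. First-strand events: the first
#' strand differs from the reference and the second strand carries the
#' identical non-reference base or indel at the same (left-aligned) position
#' — the duplex confirmation rule. Second-strand events: the second strand
#' differs from the first strand while the first strand matches the
#' reference. Discordant loci — where both strands differ from the reference
#' in different ways, or a first-strand discrepancy is unconfirmed — are
#' dropped from both classes and logged. An indel present in both strands at
#' the same locus but with different lengths yields a first-strand event of
#' the shared length plus a second-strand event for the difference.
#'
#' Substitution events additionally require the base quality to reach
#' \code{qualThreshold} on both strands; indel event quality is the minimum
#' quality of the read bases flanking a deletion, or of the inserted bases.
#' Positions inside the primer intervals are skipped. Substitution events
#' carry the equivalent RNAP/RT pair labels from
#' \code{\link{classifySubstitution}} (first strand) or the
#' (template base -> incorporated base) label in second-strand frame.
#'
#' @param first,second \code{\linkS4class{AlignedStrand}}s of one molecule
#'   (both filter-passing, indels left-aligned).
#' @param amplicon the reference \code{\linkS4class{Amplicon}}.
#' @param qualThreshold minimum per-strand event quality (default 93, the
#'   saturated consensus quality; lower it when consensus qualities do not
#'   saturate).
#' @param window flank half-width recorded in the event context column.
#' @return list with \code{first}, \code{second} (event data.frames) and
#'   \code{discordant} (logged loci: ref_pos, kind).
#' @export
callDuplexErrors <- function(first, second, amplicon, qualThreshold = 93L,
                             window = 3L) {
  L <- ampLength(amplicon)
  refCh <- strsplit(amplicon@sequence, "", fixed = TRUE)[[1L]]
  mask <- analyzableMask(amplicon)
  p1 <- projectToReference(first, L)
  p2 <- projectToReference(second, L)
  molId <- first@read@moleculeId

  firstEv <- list()
  secondEv <- list()
  disc <- list()
  note <- function(pos, kind)
    disc[[length(disc) + 1L]] <<- data.frame(ref_pos = pos, kind = kind,
                                             stringsAsFactors = FALSE)

  ## substitutions ----------------------------------------------------------
  covered <- !is.na(p1$bases) & !is.na(p2$bases) &
    p1$bases != "-" & p2$bases != "-"
  idx <- which(covered & mask &
                 (p1$bases != refCh | p2$bases != refCh))
  for (i in idx) {
    f <- p1$bases[i]; s <- p2$bases[i]; r <- refCh[i]
    pos <- i - 1L
    if (f != r && s == f) {
      if (p1$quals[i] >= qualThreshold && p2$quals[i] >= qualThreshold) {
        pair <- classifySubstitution(r, DNA_COMPLEMENT[[f]])
        firstEv[[length(firstEv) + 1L]] <-
          .eventRow(molId, "first", "substitution", pos, r, f, 1L,
                    pair[["rnap"]], pair[["rt"]],
                    min(p1$quals[i], p2$quals[i]),
                    .refContext(refCh, pos, window))
      } else note(pos, "qual_filtered")
    } else if (f == r && s != f) {
      if (p1$quals[i] >= qualThreshold && p2$quals[i] >= qualThreshold) {
        secondEv[[length(secondEv) + 1L]] <-
          .eventRow(molId, "second", "substitution", pos, f, s, 1L,
                    NA_character_, sprintf("d%s->d%s", f, s),
                    min(p1$quals[i], p2$quals[i]),
                    .refContext(refCh, pos, window))
      } else note(pos, "qual_filtered")
    } else {
      note(pos, "discordant_substitution")
    }
  }

  ## deletions --------------------------------------------------------------
  # event coordinates are normalized against the reference alone (leftmost
  # equivalent placement), the same rule the alignment uses; this keeps the
  # two strands and any truth annotation positionally comparable even when
  # an adjacent substitution blocks the alignment-level shift
  normDel <- function(d) {
    if (nrow(d))
      d$start <- vapply(seq_len(nrow(d)), function(k)
        .leftAlignDeletion(refCh, d$start[k], d$len[k]), 0L)
    d
  }
  normIns <- function(tb) {
    if (nrow(tb)) {
      for (k in seq_len(nrow(tb))) {
        la <- .leftAlignInsertion(refCh, tb$pos[k],
                                  strsplit(tb$seq[k], "", fixed = TRUE)[[1L]])
        tb$pos[k] <- la$pos
        tb$seq[k] <- paste(la$seq, collapse = "")
      }
    }
    tb
  }
  d1 <- normDel(.gapRuns(p1$bases, p1$quals))
  d2 <- normDel(.gapRuns(p2$bases, p2$quals))
  delRef <- function(pos, len) paste(refCh[(pos + 1L):(pos + len)],
                                     collapse = "")
  for (k in seq_len(nrow(d1))) {
    a <- d1$start[k]; l1 <- d1$len[k]
    j <- which(d2$start == a)
    if (!mask[a + 1L]) next
    if (length(j) == 1L) {
      l2 <- d2$len[j]
      shared <- min(l1, l2)
      q <- min(d1$qual[k], d2$qual[j])
      if (q >= qualThreshold) {
        firstEv[[length(firstEv) + 1L]] <-
          .eventRow(molId, "first", "deletion", a, delRef(a, shared), "-",
                    shared, NA_character_, NA_character_, q,
                    .refContext(refCh, a, window))
      } else note(a, "qual_filtered")
      if (l2 > l1) {
        if (d2$qual[j] >= qualThreshold) {
          secondEv[[length(secondEv) + 1L]] <-
            .eventRow(molId, "second", "deletion", a + shared,
                      delRef(a + shared, l2 - l1), "-", l2 - l1,
                      NA_character_, NA_character_, d2$qual[j],
                      .refContext(refCh, a + shared, window))
        } else note(a + shared, "qual_filtered")
      } else if (l1 > l2) note(a + shared, "discordant_deletion")
    } else {
      note(a, "discordant_deletion")
    }
  }
  for (j in seq_len(nrow(d2))) {
    a <- d2$start[j]
    if (length(which(d1$start == a)) > 0L) next
    if (!mask[a + 1L]) next
    span <- (a + 1L):min(L, a + d2$len[j])
    if (!all(!is.na(p1$bases[span]) & p1$bases[span] == refCh[span])) {
      note(a, "discordant_deletion")
      next
    }
    if (d2$qual[j] >= qualThreshold) {
      secondEv[[length(secondEv) + 1L]] <-
        .eventRow(molId, "second", "deletion", a, delRef(a, d2$len[j]), "-",
                  d2$len[j], NA_character_, NA_character_, d2$qual[j],
                  .refContext(refCh, a, window))
    } else note(a, "qual_filtered")
  }

  ## insertions -------------------------------------------------------------
  i1 <- p1$ins; i2 <- p2$ins
  interior <- function(tb, proj)
    tb[tb$pos > proj$refStart & tb$pos < proj$refEnd, , drop = FALSE]
  i1 <- normIns(interior(i1, p1)); i2 <- normIns(interior(i2, p2))
  allPos <- sort(unique(c(i1$pos, i2$pos)))
  for (a in allPos) {
    if (a < 1L || a >= L || !mask[a + 1L]) next
    s1 <- i1$seq[match(a, i1$pos)]
    s2 <- i2$seq[match(a, i2$pos)]
    q1 <- i1$qual[match(a, i1$pos)]
    q2 <- i2$qual[match(a, i2$pos)]
    ctx <- .refContext(refCh, a, window)
    if (!is.na(s1) && !is.na(s2)) {
      l1 <- nchar(s1); l2 <- nchar(s2)
      shared <- min(l1, l2)
      q <- min(q1, q2)
      if (q >= qualThreshold) {
        firstEv[[length(firstEv) + 1L]] <-
          .eventRow(molId, "first", "insertion", a, "-",
                    substr(s1, 1L, shared), shared,
                    NA_character_, NA_character_, q, ctx)
      } else note(a, "qual_filtered")
      if (l2 > l1) {
        if (q2 >= qualThreshold) {
          secondEv[[length(secondEv) + 1L]] <-
            .eventRow(molId, "second", "insertion", a, "-",
                      substr(s2, l1 + 1L, l2), l2 - l1,
                      NA_character_, NA_character_, q2, ctx)
        } else note(a, "qual_filtered")
      } else if (l1 > l2) note(a, "discordant_insertion")
    } else if (!is.na(s1)) {
      note(a, "discordant_insertion")
    } else {
      if (q2 >= qualThreshold) {
        secondEv[[length(secondEv) + 1L]] <-
          .eventRow(molId, "second", "insertion", a, "-", s2, nchar(s2),
                    NA_character_, NA_character_, q2, ctx)
      } else note(a, "qual_filtered")
    }
  }

  bindOr <- function(lst, empty) {
    if (length(lst)) {
      out <- do.call(rbind, lst)
      rownames(out) <- NULL
      out
    } else empty
  }
  list(first = bindOr(firstEv, .emptyEvents()),
       second = bindOr(secondEv, .emptyEvents()),
       discordant = bindOr(disc, data.frame(ref_pos = integer(),
                                            kind = character(),
                                            stringsAsFactors = FALSE)))
}

#' @rdname callDuplexErrors
#' @section First- and second-strand views:
#' \code{callFirstStrandErrors} and \code{callSecondStrandErrors} return the
#' corresponding event class from the shared partition, guaranteeing that
#' every discrepant locus is assigned to exactly one class.
#' @export
callFirstStrandErrors <- function(first, second, amplicon,
                                  qualThreshold = 93L, window = 3L) {
  callDuplexErrors(first, second, amplicon, qualThreshold, window)$first
}

#' @rdname callDuplexErrors
#' @export
callSecondStrandErrors <- function(first, second, amplicon,
                                   qualThreshold = 93L, window = 3L) {
  callDuplexErrors(first, second, amplicon, qualThreshold, window)$second
}

#' Collapse per-base gap records into indel events
#'
#' Deletions and insertions spanning multiple consecutive bases are counted
#' as a single event: maximal runs of consecutive deleted reference positions
#' merge into one deletion of the run length, and inserted bases sharing an
#' anchor position merge into one insertion.
#'
#' @param rawGaps data.frame with columns \code{ref_pos} (0-based; for
#'   insertions the anchor is the position of the following reference base),
#'   \code{type} (\code{"deletion"}/\code{"insertion"}) and \code{base}.
#' @return data.frame of collapsed events: \code{type}, \code{ref_pos},
#'   \code{length}, \code{observed}.
#' @examples
#' g <- data.frame(ref_pos = c(10, 11, 12, 20), type = "deletion",
#'                 base = c("A", "C", "G", "T"))
#' collapseIndels(g)  # one 3-base event and one 1-base event
#' @export
collapseIndels <- function(rawGaps) {
  if (!nrow(rawGaps))
    return(data.frame(type = character(), ref_pos = integer(),
                      length = integer(), observed = character(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (tp in c("deletion", "insertion")) {
    g <- rawGaps[rawGaps$type == tp, , drop = FALSE]
    if (!nrow(g)) next
    g <- g[order(g$ref_pos), , drop = FALSE]
    grp <- if (tp == "deletion")
      cumsum(c(TRUE, diff(g$ref_pos) != 1L))
    else
      cumsum(c(TRUE, diff(g$ref_pos) != 0L))
    for (piece in split(seq_len(nrow(g)), grp)) {
      out[[length(out) + 1L]] <-
        data.frame(type = tp, ref_pos = g$ref_pos[piece[1L]],
                   length = length(piece),
                   observed = paste(g$base[piece], collapse = ""),
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
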