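#' Simulate one duplex molecule with stage-attributed errors
#'
#' Emulates the three synthesis stages of the assay: RNA synthesis from the
#' reference (RNAP stage), first-strand cDNA synthesis from the RNA (RT1
#' stage) and second-strand synthesis from the cDNA (RT2 stage). RNAP-stage
#' errors mutate the template before reverse transcription, so they appear in
#' both strands; RT1 errors arise in the cDNA and are copied faithfully into
#' the second strand; RT2 errors appear only in the second strand. Every
#' injected event is recorded in a truth table with its stage, left-aligned
#' 0-based reference position, expected and observed reference-frame bases.
#'
#' @param amplicon an \code{\linkS4class{Amplicon}}.
#' @param rnap,rt1,rt2 \code{\linkS4class{ErrorModel}} objects for the three
#'   stages. \code{rt1} is specified in the cDNA frame and complement-
#'   transformed internally into reference frame.
#' @param seed integer seed; the molecule is reproducible from it.
#' @return list with \code{first} (cDNA sequence, reverse-complement frame),
#'   \code{second} (second-strand sequence, reference-sense) and \code{truth}
#'   (data.frame: stage, type, ref_pos, expected, observed, length).
#' @examples
#' amp <- generateReference(500, seed = 1)
#' m <- simulateMolecule(amp, errorModel(), errorModel(), errorModel(), 42)
#' identical(m$second, refSequence(amp))
#' identical(m$first, revComp(refSequence(amp)))
#' @export
simulateMolecule <- function(amplicon, rnap, rt1, rt2, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  refChars <- strsplit(amplicon@sequence, "", fixed = TRUE)[[1L]]
  st0 <- list(bases = refChars, refPos = seq_along(refChars) - 1L)
  s1 <- .mutateState(st0, rnap, antisense = FALSE, stage = "RNAP",
                     refChars = refChars)
  s2 <- .mutateState(s1, rt1, antisense = TRUE, stage = "RT1",
                     refChars = refChars)
  s3 <- .mutateState(s2, rt2, antisense = FALSE, stage = "RT2",
                     refChars = refChars)
  truth <- rbind(s1$truth, s2$truth, s3$truth)
  truth <- truth[order(truth$ref_pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(first = chartr("ACGT", "TGCA",
                      paste(rev(s2$bases), collapse = "")),
       second = paste(s3$bases, collapse = ""),
       truth = truth)
}

.emptyTruth <- function() {
  data.frame(stage = character(), type = character(), ref_pos = integer(),
             expected = character(), observed = character(),
             length = integer(), slippage = logical(),
             stringsAsFactors = FALSE)
}

# One error-injection pass over the current molecule state. `state` carries
# the current reference-frame base vector plus, per base, the reference
# coordinate it derives from (NA for bases inserted at an earlier stage;
# no further events are injected on those, a second-order effect at the rates
# this models). Returns the mutated state and the truth rows.
.mutateState <- function(state, model, antisense, stage, refChars) {
  bases <- state$bases
  refPos <- state$refPos
  n <- length(bases)
  truth <- .emptyTruth()
  if (n == 0L) return(list(bases = bases, refPos = refPos, truth = truth))

  m <- model@subRates
  diag(m) <- 0
  if (antisense) {
    # product strand is the complement frame: transform into reference frame
    m <- m[4:1, 4:1]
    dimnames(m) <- list(DNA_BASES, DNA_BASES)
  }
  baseIdx <- match(bases, DNA_BASES)
  eligible <- !is.na(refPos) & !is.na(baseIdx)
  pSub <- rowSums(m)[baseIdx]
  prev <- c(NA_character_, bases[-n])
  w <- ifelse(is.na(prev), 1, model@prevWeights[prev])
  pSub <- ifelse(eligible, pSub * w, 0)

  events <- list()
  subHit <- which(runif(n) < pSub)
  for (i in subHit) {
    p <- m[baseIdx[i], ]
    obs <- sample(DNA_BASES, 1L, prob = p / sum(p))
    events[[length(events) + 1L]] <- list(kind = "sub", i = i, len = 1L,
                                          obs = obs)
  }
  if (model@delRate > 0) {
    for (i in which(runif(n) < ifelse(eligible, model@delRate, 0))) {
      len <- sample.int(length(model@indelSizeDist), 1L,
                        prob = model@indelSizeDist)
      events[[length(events) + 1L]] <- list(kind = "del", i = i,
                                            len = len, obs = NULL)
    }
  }
  if (model@insRate > 0) {
    for (i in which(runif(n) < ifelse(eligible, model@insRate, 0))) {
      len <- sample.int(length(model@indelSizeDist), 1L,
                        prob = model@indelSizeDist)
      events[[length(events) + 1L]] <-
        list(kind = "ins", i = i, len = len,
             obs = sample(DNA_BASES, len, replace = TRUE))
    }
  }
  if (model@slippageRate > 0) {
    # slippage needs a run long enough for strand misalignment: at least
    # four tandem copies of the unit
    reps <- findTandemRepeats(bases, minCopies = 4L)
    if (nrow(reps)) {
      hit <- which(runif(nrow(reps)) < model@slippageRate)
      for (r in hit) {
        u <- reps$unitLength[r]
        i <- reps$start[r] + 1L  # 1-based index of run start
        unit <- bases[i:(i + u - 1L)]
        if (runif(1L) < 0.5) {
          events[[length(events) + 1L]] <-
            list(kind = "ins", i = i - 1L, len = u, obs = unit,
                 slip = TRUE)
        } else {
          events[[length(events) + 1L]] <-
            list(kind = "del", i = i, len = u, obs = NULL, slip = TRUE)
        }
      }
    }
  }
  if (!length(events))
    return(list(bases = bases, refPos = refPos, truth = truth))

  # resolve collisions deterministically: substitutions, then deletions, then
  # insertions; anything overlapping an already-claimed base is dropped
  ord <- order(match(vapply(events, `[[`, "", "kind"),
                     c("sub", "del", "ins")),
               vapply(events, `[[`, 0L, "i"))
  events <- events[ord]
  claimed <- logical(n)
  kept <- list()
  for (ev in events) {
    if (ev$kind == "sub") {
      if (!claimed[ev$i]) { claimed[ev$i] <- TRUE; kept <- c(kept, list(ev)) }
    } else if (ev$kind == "del") {
      span <- ev$i:min(n, ev$i + ev$len - 1L)
      ev$len <- length(span)
      if (!any(claimed[span]) && !any(is.na(refPos[span])) &&
          refPos[span[length(span)]] == refPos[span[1L]] + ev$len - 1L) {
        claimed[span] <- TRUE
        kept <- c(kept, list(ev))
      }
    } else {
      ip <- min(ev$i, n)
      if (ip >= 1L && !claimed[ip] && !is.na(refPos[ip]))
        kept <- c(kept, list(ev))
    }
  }
  if (!length(kept))
    return(list(bases = bases, refPos = refPos, truth = truth))

  # truth records (left-aligned against the reference) and state edits
  subs <- Filter(function(e) e$kind == "sub", kept)
  dels <- Filter(function(e) e$kind == "del", kept)
  inss <- Filter(function(e) e$kind == "ins", kept)

  rows <- list()
  for (ev in subs) {
    rp <- refPos[ev$i]
    rows[[length(rows) + 1L]] <-
      data.frame(stage = stage, type = "substitution", ref_pos = rp,
                 expected = refChars[rp + 1L], observed = ev$obs,
                 length = 1L, slippage = FALSE, stringsAsFactors = FALSE)
    bases[ev$i] <- ev$obs
  }
  for (ev in dels) {
    rp <- .leftAlignDeletion(refChars, refPos[ev$i], ev$len)
    rows[[length(rows) + 1L]] <-
      data.frame(stage = stage, type = "deletion", ref_pos = rp,
                 expected = paste(refChars[(rp + 1L):(rp + ev$len)],
                                  collapse = ""),
                 observed = "-", length = ev$len,
                 slippage = isTRUE(ev$slip), stringsAsFactors = FALSE)
  }
  for (ev in inss) {
    anchor <- if (ev$i == 0L) refPos[1L] else refPos[ev$i] + 1L
    la <- .leftAlignInsertion(refChars, anchor, ev$obs)
    rows[[length(rows) + 1L]] <-
      data.frame(stage = stage, type = "insertion", ref_pos = la$pos,
                 expected = "-", observed = paste(la$seq, collapse = ""),
                 length = ev$len, slippage = isTRUE(ev$slip),
                 stringsAsFactors = FALSE)
  }
  if (length(rows)) truth <- do.call(rbind, rows)

  # splice deletions and insertions (right to left so indices stay valid)
  edits <- c(lapply(dels, function(e) list(i = e$i, del = e$len, ins = NULL)),
             lapply(inss, function(e) list(i = e$i, del = 0L, ins = e$obs)))
  if (length(edits)) {
    ord <- order(vapply(edits, `[[`, 0L, "i"), decreasing = TRUE)
    for (ed in edits[ord]) {
      if (ed$del > 0L) {
        span <- ed$i:(ed$i + ed$del - 1L)
        bases <- bases[-span]
        refPos <- refPos[-span]
      } else {
        at <- ed$i  # insert after this index (0 = before the first base)
        bases <- append(bases, ed$ins, after = at)
        refPos <- append(refPos, rep(NA_integer_, length(ed$ins)), after = at)
      }
    }
  }
  list(bases = bases, refPos = refPos, truth = truth)
}

# left-align a deletion of `len` reference bases starting at 0-based `pos`
.leftAlignDeletion <- function(refChars, pos, len) {
  p <- pos + 1L  # 1-based start
  while (p > 1L && refChars[p - 1L] == refChars[p + len - 1L]) p <- p - 1L
  p - 1L
}

# left-align an insertion (char vector `s`) anchored before 0-based `pos`
.leftAlignInsertion <- function(refChars, pos, s) {
  p <- pos + 1L  # 1-based index of the following reference base
  k <- length(s)
  while (p > 1L && s[k] == refChars[p - 1L]) {
    s <- c(s[k], s[-k])
    p <- p - 1L
  }
  list(pos = p - 1L, seq = s)
}

#' Find tandem repeat loci
#'
#' Scans a base vector (or string) for maximal tandem repeats with unit
#' length 1-6 and at least \code{minCopies} copies; these are the loci where
#' replication slippage can gain or lose whole units.
#'
#' @param x character vector of bases or a single string.
#' @param minUnit,maxUnit unit-length range.
#' @param minCopies minimum number of tandem copies.
#' @return data.frame with \code{start} (0-based), \code{unitLength},
#'   \code{copies} and \code{unit}.
#' @export
findTandemRepeats <- function(x, minUnit = 1L, maxUnit = 6L, minCopies = 3L) {
  ch <- if (length(x) == 1L && nchar(x[1L]) > 1L)
    strsplit(x, "", fixed = TRUE)[[1L]] else x
  n <- length(ch)
  out <- list()
  for (u in minUnit:maxUnit) {
    if (n < u * minCopies) break
    eq <- ch[seq_len(n - u)] == ch[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= u * (minCopies - 1L))) {
      span <- r$lengths[k] + u
      copies <- span %/% u
      if (copies < minCopies) next
      st <- starts[k]
      unit <- paste(ch[st:(st + u - 1L)], collapse = "")
      if (.minimalPeriod(unit) != u) next  # canonical unit length only
      out[[length(out) + 1L]] <-
        data.frame(start = st - 1L, unitLength = u, copies = copies,
                   unit = unit, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), unitLength = integer(),
                      copies = integer(), unit = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.minimalPeriod <- function(unit) {
  u <- nchar(unit)
  for (p in seq_len(u - 1L)) {
    if (u %% p == 0L &&
        unit == strrep(substr(unit, 1L, p), u %/% p)) return(p)
  }
  u
}

#' Simulate raw sequencing passes of a strand
#'
#' Produces \code{nPasses} independently noised copies of a strand sequence,
#' emulating raw circular-sequencing passes. Each base suffers a substitution
#' with probability \code{0.6 * rawError}, a single-base deletion with
#' probability \code{0.2 * rawError} and a single-base insertion with
#' probability \code{0.2 * rawError}.
#'
#' @param strandSeq DNA string.
#' @param nPasses number of subreads (>= 1).
#' @param rawError total per-base raw error probability, in [0, 0.3].
#' @param seed integer seed.
#' @return character vector of \code{nPasses} subread sequences.
#' @export
simulateSubreads <- function(strandSeq, nPasses, rawError, seed) {
  stopifnot(nPasses >= 1L, rawError >= 0, rawError <= 0.3)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ch <- strsplit(strandSeq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  vapply(seq_len(nPasses), function(p) {
    out <- ch
    hit <- runif(n) < 0.6 * rawError
    if (any(hit)) {
      k <- sum(hit)
      alt <- sample(DNA_BASES, 3L * k, replace = TRUE)
      alt <- matrix(alt, nrow = k)
      pick <- vapply(seq_len(k), function(j) {
        a <- alt[j, ][alt[j, ] != out[hit][j]]
        if (length(a)) a[1L] else setdiff(DNA_BASES, out[hit][j])[1L]
      }, "")
      out[hit] <- pick
    }
    del <- runif(n) < 0.2 * rawError
    ins <- runif(n) < 0.2 * rawError
    if (any(ins)) {
      pieces <- ifelse(ins, paste0(out, sample(DNA_BASES, n, replace = TRUE)),
                       out)
    } else pieces <- out
    paste(pieces[!del], collapse = "")
  }, "")
}

#' Join two molecules into a chimeric strand
#'
#' Concatenates the prefix of one strand sequence with the suffix of another,
#' emulating template switching during transcription or cDNA synthesis.
#' Chimeric products are what the read-level length/split filters must remove.
#'
#' @param molA,molB strand sequences (character).
#' @param breakpoint prefix length taken from \code{molA}; the suffix of
#'   \code{molB} starts at the same coordinate (a second coordinate for
#'   \code{molB} can be given to change the product length).
#' @param breakpointB optional 0-based suffix start in \code{molB}
#'   (default \code{breakpoint}).
#' @return the chimeric sequence.
#' @examples
#' makeChimera("AAAA", "CCCC", 2)  # "AACC"
#' @export
makeChimera <- function(molA, molB, breakpoint, breakpointB = breakpoint) {
  stopifnot(breakpoint >= 0L, breakpoint <= nchar(molA),
            breakpointB >= 0L, breakpointB <= nchar(molB))
  paste0(substr(molA, 1L, breakpoint),
         substr(molB, breakpointB + 1L, nchar(molB)))
}

#' Simulate a truth-annotated duplex data set
#'
#' Drives \code{\link{simulateMolecule}} over many molecules with a stated
#' per-molecule seed scheme (molecule \eqn{i} uses
#' \code{(seed * 1000003 + i) mod (2^31 - 1)}), optionally replaces a fraction
#' of molecules by chimeras (both strands switch template at independent
#' breakpoints, changing the product length), and optionally emits noisy raw
#' subreads instead of finished consensus reads.
#'
#' @param amplicon an \code{\linkS4class{Amplicon}}.
#' @param nMolecules number of duplex molecules.
#' @param rnap,rt1,rt2 stage \code{\linkS4class{ErrorModel}}s.
#' @param seed global integer seed.
#' @param nPasses if > 0, emit \code{nPasses} raw subreads per strand at
#'   \code{rawError}; if 0, emit finished consensus \code{StrandRead}s with
#'   all qualities 93 and \code{finishedPasses} passes.
#' @param rawError per-base raw subread error probability.
#' @param chimeraRate fraction of molecules replaced by chimeras (default 0;
#'   the 1\% sometimes used in examples is a placeholder, not a measured
#'   value).
#' @param finishedPasses pass count recorded on finished consensus reads.
#' @return list with \code{molecules} (per molecule: \code{id}, \code{first}/
#'   \code{second} \code{StrandRead}s or \code{firstSubreads}/
#'   \code{secondSubreads}), \code{truth} (truth events with molecule column),
#'   and \code{info} (per-molecule metadata incl. chimera flag).
#' @export
simulateDataset <- function(amplicon, nMolecules, rnap = errorModel(),
                            rt1 = errorModel(), rt2 = errorModel(),
                            seed = 1L, nPasses = 0L, rawError = 0,
                            chimeraRate = 0, finishedPasses = 30L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  isChim <- runif(nMolecules) < chimeraRate
  bigPrime <- 1000003
  molSeed <- function(i) as.integer((as.numeric(seed) * bigPrime + i) %%
                                      2147483647)
  ids <- sprintf("mol%06d", seq_len(nMolecules))
  L <- ampLength(amplicon)
  a5 <- amplicon@primer5[2L]; a3 <- amplicon@primer3[1L]
  bp1 <- sample(seq.int(a5 + 5L, a3 - 5L), nMolecules, replace = TRUE)
  bp2 <- sample(seq.int(a5 + 5L, a3 - 5L), nMolecules, replace = TRUE)

  molecules <- vector("list", nMolecules)
  truths <- vector("list", nMolecules)
  for (i in seq_len(nMolecules)) {
    m <- simulateMolecule(amplicon, rnap, rt1, rt2, molSeed(i))
    if (isChim[i]) {
      partner <- simulateMolecule(amplicon, rnap, rt1, rt2,
                                  molSeed(i + nMolecules))
      second <- makeChimera(m$second, partner$second, bp1[i], bp2[i])
      m$second <- second
      m$first <- chartr("ACGT", "TGCA",
                        paste(rev(strsplit(second, "", fixed = TRUE)[[1L]]),
                              collapse = ""))
      m$truth <- m$truth[0L, , drop = FALSE]  # chimera truth is the flag
    }
    tr <- m$truth
    if (nrow(tr)) tr <- cbind(molecule = ids[i], tr)
    truths[[i]] <- tr
    if (nPasses > 0L) {
      molecules[[i]] <- list(
        id = ids[i],
        firstSubreads = simulateSubreads(m$first, nPasses, rawError,
                                         molSeed(i + 2L * nMolecules)),
        secondSubreads = simulateSubreads(m$second, nPasses, rawError,
                                          molSeed(i + 3L * nMolecules)))
    } else {
      molecules[[i]] <- list(
        id = ids[i],
        first = StrandRead(ids[i], "first", m$first, 93L, finishedPasses),
        second = StrandRead(ids[i], "second", m$second, 93L, finishedPasses))
    }
  }
  truth <- do.call(rbind, truths[!vapply(truths, is.null, TRUE)])
  if (is.null(truth) || !nrow(truth)) {
    truth <- cbind(molecule = character(), .emptyTruth())
  }
  rownames(truth) <- NULL
  info <- data.frame(id = ids, chimeric = isChim,
                     lengthDeviation = ifelse(isChim, bp1 - bp2, 0L),
                     stringsAsFactors = FALSE)
  list(molecules = molecules, truth = truth, info = info,
       amplicon = amplicon)
}
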