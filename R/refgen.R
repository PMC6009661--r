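#' Generate a synthetic reference amplicon
#'
#' Builds an artificial amplicon with the statistical properties of the
#' all-4-mer templates used in fidelity assays: an equimolar, homopolymer-poor
#' analyzable region that (optionally) contains every overlapping 4-mer at
#' least once, flanked by two primer regions that are excluded from error-rate
#' calculations.
#'
#' The all-4-mer construction is a seeded de Bruijn-style order-4 walk: the
#' sequence is extended one base at a time, preferring bases that complete an
#' unseen 4-mer while never exceeding the homopolymer cap; if the walk fails
#' to cover all 4-mers within the analyzable length it restarts with a fresh
#' derived seed (bounded retries). The result is re-verified by an exhaustive
#' 4-mer scan, not trusted from the construction.
#'
#' @param length total amplicon length (including primers).
#' @param maxHomopolymer longest allowed homopolymer run.
#' @param requireAll4mers if \code{TRUE}, the analyzable region must contain
#'   all 256 overlapping 4-mers. Requires \code{length - 2*primerLen >= 259}
#'   and \code{maxHomopolymer >= 4} unless \code{relaxFourMers} is set.
#' @param seed integer seed; the same seed reproduces the same amplicon.
#' @param primerLen primer length at each end (default 20, i.e. 40 excluded
#'   bases in total).
#' @param relaxFourMers with \code{maxHomopolymer < 4}, require only the
#'   4-mers that themselves respect the homopolymer cap (the homopolymeric
#'   4-mers such as AAAA are impossible by construction).
#' @param id,modification passed to \code{\link{Amplicon}}.
#' @return an \code{\linkS4class{Amplicon}}.
#' @examples
#' amp <- generateReference(600, maxHomopolymer = 4, requireAll4mers = TRUE,
#'                          seed = 1)
#' all(countKmers(analyzableSequence(amp), 4) > 0)
#' @export
generateReference <- function(length, maxHomopolymer = 3L,
                              requireAll4mers = FALSE, seed = 1L,
                              primerLen = 20L, relaxFourMers = FALSE,
                              id = sprintf("synthetic-%d", seed),
                              modification = "none") {
  length <- as.integer(length); primerLen <- as.integer(primerLen)
  analyzable <- length - 2L * primerLen
  if (requireAll4mers && maxHomopolymer < 4L && !relaxFourMers)
    stop("all 256 4-mers are infeasible with maxHomopolymer < 4 ",
         "(homopolymeric 4-mers such as AAAA require a run of 4); ",
         "set relaxFourMers = TRUE to require only cap-respecting 4-mers")
  if (requireAll4mers && analyzable < 259L)
    stop("require_all_4mers needs an analyzable region of at least 259 bases")
  if (analyzable <= 0L) stop("length too short for the primer regions")

  target <- NULL
  if (requireAll4mers) {
    target <- allKmers(4L)
    if (relaxFourMers)
      target <- target[vapply(target, function(k) maxRun(k) <= maxHomopolymer,
                              logical(1L))]
  }

  for (attempt in seq_len(50L)) {
    set.seed((seed + 7919L * (attempt - 1L)) %% .Machine$integer.max)
    core <- .growSequence(analyzable, maxHomopolymer, target)
    if (is.null(core)) next
    left <- .growSequence(primerLen, maxHomopolymer, NULL,
                          after = head(core, maxHomopolymer), before = TRUE)
    right <- .growSequence(primerLen, maxHomopolymer, NULL,
                           after = core[(analyzable - maxHomopolymer + 1L):analyzable])
    seqchr <- paste(c(left, core, right), collapse = "")
    # independent verification of the stated invariants
    if (maxRun(seqchr) > maxHomopolymer) next
    if (requireAll4mers) {
      census <- countKmers(paste(core, collapse = ""), 4L)
      if (!all(census[target] > 0L)) next
    }
    amp <- Amplicon(id, seqchr,
                    primer5 = c(0L, primerLen),
                    primer3 = c(length - primerLen, length),
                    modification = modification)
    return(amp)
  }
  stop("failed to generate a sequence meeting the constraints after 50 attempts")
}

# Grow a base vector of length n under a homopolymer cap. `target` is an
# optional character vector of k-mers to cover (k taken from its elements);
# `after` seeds run bookkeeping at the junction with existing sequence;
# `before = TRUE` grows leftwards in front of `after`.
.growSequence <- function(n, maxRun, target = NULL, after = character(),
                          before = FALSE) {
  if (n <= 0L) return(character())
  out <- character(n)
  k <- if (!is.null(target)) nchar(target[[1L]]) else 0L
  seen <- if (!is.null(target)) new.env(hash = TRUE, size = 512L) else NULL
  nLeft <- length(target)
  ctx <- if (before) rev(after) else after
  for (i in seq_len(n)) {
    runLen <- 0L
    if (i > 1L || length(ctx)) {
      prevs <- if (i > 1L) out[max(1L, i - maxRun):(i - 1L)] else character()
      tail <- c(ctx, prevs)
      tail <- tail[max(1L, length(tail) - maxRun + 1L):length(tail)]
      last <- tail[length(tail)]
      runLen <- 0L
      for (b in rev(tail)) { if (b == last) runLen <- runLen + 1L else break }
    } else last <- ""
    cand <- DNA_BASES
    if (runLen >= maxRun) cand <- setdiff(cand, last)
    pick <- NULL
    if (!is.null(target) && nLeft > 0L && i > 1L) {
      hist <- c(ctx, out[seq_len(i - 1L)])
      if (length(hist) >= k - 1L) {
        pre <- paste(hist[(length(hist) - k + 2L):length(hist)], collapse = "")
        fresh <- cand[vapply(cand, function(b) {
          km <- paste0(pre, b)
          km %in% target && !exists(km, envir = seen, inherits = FALSE)
        }, logical(1L))]
        if (length(fresh)) pick <- sample(fresh, 1L)
      }
    }
    if (is.null(pick)) pick <- sample(cand, 1L)
    out[i] <- pick
    if (!is.null(target) && i >= k) {
      hist <- c(ctx, out[seq_len(i)])
      km <- paste(hist[(length(hist) - k + 1L):length(hist)], collapse = "")
      if (km %in% target && !exists(km, envir = seen, inherits = FALSE)) {
        assign(km, TRUE, envir = seen)
        nLeft <- nLeft - 1L
      }
    }
  }
  if (!is.null(target) && nLeft > 0L) return(NULL)
  if (before) rev(out) else out
}

#' Exhaustive k-mer census
#'
#' Counts every overlapping k-mer of a sequence by direct scan. Used to
#' verify (rather than trust) the all-4-mer property of generated references.
#'
#' @param x DNA string.
#' @param k k-mer size.
#' @return named integer vector over all 4^k k-mers.
#' @export
countKmers <- function(x, k) {
  kmers <- allKmers(k)
  counts <- setNames(integer(length(kmers)), kmers)
  n <- nchar(x)
  if (n >= k) {
    obs <- substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    t <- table(obs)
    counts[names(t)] <- as.integer(t)
  }
  counts
}

#' @rdname countKmers
#' @export
allKmers <- function(k) {
  g <- do.call(expand.grid, rev(replicate(k, DNA_BASES, simplify = FALSE)))
  sort(apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = ""))
}

#' Longest homopolymer run of a sequence
#'
#' @param x DNA string.
#' @return length of the longest single-base run.
#' @export
maxRun <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (!length(ch)) return(0L)
  max(rle(ch)$lengths)
}

#' Analyzable-region sequence of an amplicon
#'
#' @param x an \code{Amplicon}.
#' @return the sequence between the primer intervals, as a character string.
#' @export
analyzableSequence <- function(x) {
  substr(x@sequence, x@primer5[2L] + 1L, x@primer3[1L])
}

#' Insert a tandem repeat into an amplicon
#'
#' Inserts \code{copies} tandem copies of \code{unit} at \code{position}
#' (0-based, inside the analyzable region). Used to provoke
#' replication slippage in simulations, e.g. a run of GCT repeats.
#'
#' @param amplicon an \code{Amplicon}.
#' @param unit repeat unit, 1-6 bases.
#' @param copies number of copies to insert; 0 returns the amplicon unchanged.
#' @param position 0-based insertion point, strictly inside the analyzable
#'   region.
#' @return a new \code{Amplicon} with the repeat inserted (the 3' primer
#'   interval shifts accordingly).
#' @examples
#' amp <- generateReference(500, seed = 2)
#' rep <- insertRepeat(amp, "GCT", 4, 200)
#' substr(refSequence(rep), 201, 212)
#' @export
insertRepeat <- function(amplicon, unit, copies, position) {
  stopifnot(nchar(unit) >= 1L, nchar(unit) <= 6L,
            !grepl("[^ACGT]", unit), copies >= 0L)
  if (copies == 0L) return(amplicon)
  if (position < amplicon@primer5[2L] || position > amplicon@primer3[1L])
    stop("insertion position must lie inside the analyzable region")
  s <- amplicon@sequence
  ins <- strrep(unit, copies)
  newseq <- paste0(substr(s, 1L, position), ins,
                   substr(s, position + 1L, nchar(s)))
  Amplicon(amplicon@id, newseq,
           primer5 = amplicon@primer5,
           primer3 = amplicon@primer3 + nchar(ins),
           modification = amplicon@modification)
}
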