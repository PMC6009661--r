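test_that("substitution classification matches the complement-table oracle", {
  # worked example: expected RNA base A, observed cDNA base C
  ex <- classifySubstitution("A", "C")
  expect_equal(unname(ex["rnap"]), "rA->rG")
  expect_equal(unname(ex["rt"]), "dT->dC")
  oracle <- oracleClassifyAll()
  expect_equal(length(oracle), 12L)
  for (key in names(oracle)) {
    parts <- strsplit(key, ">")[[1]]
    got <- classifySubstitution(parts[1], parts[2])
    expect_equal(unname(got["rnap"]), unname(oracle[[key]]["rnap"]),
                 info = key)
    expect_equal(unname(got["rt"]), unname(oracle[[key]]["rt"]), info = key)
  }
  # a correct incorporation is not an error
  expect_error(classifySubstitution("G", "C"), "match")
})

test_that("complement identity holds for every mismatch pair", {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  toDna <- c(A = "A", C = "C", G = "G", U = "T")
  for (ref in c("A", "C", "G", "T")) {
    for (cdna in setdiff(c("A", "C", "G", "T"), comp[[ref]])) {
      pair <- classifySubstitution(ref, cdna)
      rnapProd <- unname(sub(".*->r", "", pair["rnap"]))
      rtProd <- unname(sub(".*->d", "", pair["rt"]))
      rtTempl <- unname(sub("^d", "", sub("->.*", "", pair["rt"])))
      rnapTempl <- unname(sub("^r", "", sub("->.*", "", pair["rnap"])))
      expect_equal(unname(comp[toDna[rnapProd]]), rtProd)
      expect_equal(unname(comp[toDna[rnapTempl]]), rtTempl)
    }
  }
})

callOn <- function(amp, firstRefFrame, secondSeq, qual = 93L, thr = 93L) {
  pair <- refFramePair("m", firstRefFrame, secondSeq, qual)
  a1 <- alignToReference(pair$first, amp)
  a2 <- alignToReference(pair$second, amp)
  callDuplexErrors(a1, a2, amp, qualThreshold = thr)
}

test_that("duplex confirmation partitions substitution cases correctly", {
  amp <- testAmplicon(11)
  ref <- refSequence(amp)
  aPos <- regexpr("A", substr(ref, 101, 400))[1] + 99L  # 0-based ref A
  expect_equal(substr(ref, aPos + 1, aPos + 1), "A")
  # both strands G at a reference A: one confirmed first-strand event
  both <- callOn(amp, withSub(ref, aPos, "G"), withSub(ref, aPos, "G"))
  expect_equal(nrow(both$first), 1L)
  expect_equal(both$first$ref_pos, aPos)
  expect_equal(both$first$rnap_pair, "rA->rG")
  expect_equal(both$first$rt_pair, "dT->dC")
  expect_equal(nrow(both$second), 0L)
  expect_equal(nrow(both$discordant), 0L)
  # unconfirmed first-strand discrepancy: no event, logged discordant
  un <- callOn(amp, withSub(ref, aPos, "G"), ref)
  expect_equal(nrow(un$first), 0L)
  expect_equal(nrow(un$second), 0L)
  expect_equal(nrow(un$discordant), 1L)
  # second differs, first matches reference: second-strand event dA->dT
  sec <- callOn(amp, ref, withSub(ref, aPos, "T"))
  expect_equal(nrow(sec$first), 0L)
  expect_equal(nrow(sec$second), 1L)
  expect_equal(sec$second$rt_pair, "dA->dT")
  expect_true(is.na(sec$second$rnap_pair))
  # both differ discordantly: dropped from both classes
  dis <- callOn(amp, withSub(ref, aPos, "G"), withSub(ref, aPos, "C"))
  expect_equal(nrow(dis$first) + nrow(dis$second), 0L)
  expect_equal(nrow(dis$discordant), 1L)
})

test_that("event quality gates substitutions on both strands", {
  amp <- testAmplicon(12)
  ref <- refSequence(amp)
  aPos <- regexpr("A", substr(ref, 101, 400))[1] + 99L
  mut <- withSub(ref, aPos, "G")
  qual <- rep(93L, nchar(ref))
  qual[aPos + 1L] <- 92L
  pair <- list(first = StrandRead("m", "first", revComp(mut), rev(qual), 30L),
               second = StrandRead("m", "second", mut, 93L, 30L))
  res <- callDuplexErrors(alignToReference(pair$first, amp),
                          alignToReference(pair$second, amp), amp)
  expect_equal(nrow(res$first), 0L)
  expect_true("qual_filtered" %in% res$discordant$kind)
  # same molecule passes at a lowered threshold
  res2 <- callDuplexErrors(alignToReference(pair$first, amp),
                           alignToReference(pair$second, amp), amp,
                           qualThreshold = 90L)
  expect_equal(nrow(res2$first), 1L)
})

test_that("primer-region discrepancies are never called", {
  amp <- testAmplicon(13)
  ref <- refSequence(amp)
  inPrimer <- withSub(ref, 5L, setdiff(c("A", "C", "G", "T"),
                                       substr(ref, 6, 6))[1])
  res <- callOn(amp, inPrimer, inPrimer)
  expect_equal(nrow(res$first), 0L)
  expect_equal(nrow(res$second), 0L)
})

test_that("multi-base indels collapse to single events with duplex rules", {
  amp <- testAmplicon(14)
  ref <- refSequence(amp)
  ch <- strsplit(ref, "")[[1]]
  # a deletion start where neither a 2- nor a 3-base run can left-shift, so
  # both strands' deletions land on the same reference coordinate
  cand <- which(ch[100:397] != ch[99:396] & ch[101:398] != ch[99:396] &
                  ch[102:399] != ch[99:396]) + 99L  # 1-based start
  p0 <- cand[1] - 1L                                # 0-based
  del3 <- withDel(ref, p0, 3L)
  r1 <- callOn(amp, del3, del3)
  expect_equal(nrow(r1$first), 1L)
  expect_equal(r1$first$type, "deletion")
  expect_equal(r1$first$length, 3L)
  expect_equal(nrow(r1$second), 0L)
  # deletion in the second strand only: one second-strand event
  r2 <- callOn(amp, ref, del3)
  expect_equal(nrow(r2$first), 0L)
  expect_equal(nrow(r2$second), 1L)
  expect_equal(r2$second$length, 3L)
  # shared-length split: first deletes 2, second deletes 3 at the same locus
  r3 <- callOn(amp, withDel(ref, p0, 2L), del3)
  expect_equal(nrow(r3$first), 1L)
  expect_equal(r3$first$length, 2L)
  expect_equal(nrow(r3$second), 1L)
  expect_equal(r3$second$length, 1L)
})

test_that("tandem-unit insertions are called as one left-aligned event", {
  amp <- insertRepeat(testAmplicon(15), "GCT", 4, 250)
  ref <- refSequence(amp)
  ins <- withIns(ref, 262L, "GCT")  # one extra unit after the run
  res <- callOn(amp, ins, ins)
  expect_equal(nrow(res$first), 1L)
  expect_equal(res$first$type, "insertion")
  expect_equal(res$first$length, 3L)
  # left-aligned to the start of the repeat run
  expect_lte(res$first$ref_pos, 253L)
})

test_that("collapseIndels merges consecutive gap records", {
  g <- data.frame(ref_pos = c(10L, 11L, 12L, 20L, 22L),
                  type = "deletion",
                  base = c("A", "C", "G", "T", "T"),
                  stringsAsFactors = FALSE)
  ev <- collapseIndels(g)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$length, c(3L, 1L, 1L))
  expect_equal(ev$ref_pos, c(10L, 20L, 22L))
  gi <- data.frame(ref_pos = c(30L, 30L, 30L), type = "insertion",
                   base = c("G", "C", "T"), stringsAsFactors = FALSE)
  evi <- collapseIndels(gi)
  expect_equal(nrow(evi), 1L)
  expect_equal(evi$observed, "GCT")
  expect_equal(nrow(collapseIndels(g[0, ])), 0L)
})

test_that("every discrepant locus lands in exactly one class", {
  amp <- testAmplicon(16)
  ref <- refSequence(amp)
  set.seed(99)
  # a molecule with a mix of confirmed, unconfirmed and discordant loci
  f <- ref; s <- ref
  pos <- sample(seq(30L, 450L, by = 15L))
  alt <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  nConfirmed <- 0L; nUncOrDis <- 0L
  for (k in seq_len(12L)) {
    p <- pos[k]
    b <- substr(ref, p + 1, p + 1)
    kind <- k %% 3L
    if (kind == 0L) {                       # confirmed
      f <- withSub(f, p, alt(b)); s <- withSub(s, p, alt(b))
      nConfirmed <- nConfirmed + 1L
    } else if (kind == 1L) {                # unconfirmed first-strand
      f <- withSub(f, p, alt(b))
      nUncOrDis <- nUncOrDis + 1L
    } else {                                # second-strand only
      s <- withSub(s, p, alt(b))
    }
  }
  res <- callOn(amp, f, s)
  total <- nrow(res$first) + nrow(res$second) + nrow(res$discordant)
  expect_equal(total, 12L)
  expect_equal(nrow(res$first), nConfirmed)
  expect_equal(nrow(res$discordant), nUncOrDis)
})
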