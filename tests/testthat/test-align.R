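test_that("a perfect read aligns end to end as all-match", {
  amp <- testAmplicon(1)
  read <- StrandRead("m", "second", refSequence(amp))
  a <- alignToReference(read, amp)
  expect_equal(refStart(a), 0L)
  expect_equal(refEnd(a), ampLength(amp))
  expect_true(all(alignmentOps(a) == 0L))
  expect_equal(cigarString(a), sprintf("%d=", ampLength(amp)))
  expect_equal(mapq(a), 60L)
})

test_that("a deletion inside a homopolymer run is left-aligned", {
  # reference with an internal GG run; deleting either G must be reported at
  # the leftmost position of the run
  ref <- paste0(strrep("ACT", 40), "AGGTC", strrep("TCA", 40))
  amp <- Amplicon("r", ref, primer5 = c(0L, 20L),
                  primer3 = c(nchar(ref) - 20L, nchar(ref)))
  runStart <- 121L  # 0-based position of the first G
  read <- StrandRead("m", "second", withDel(ref, runStart + 1L, 1L))
  a <- alignToReference(read, amp)
  ops <- alignmentOps(a)
  expect_equal(sum(ops == 3L), 1L)
  delCol <- which(ops == 3L)
  refPosOfDel <- refStart(a) + sum(ops[seq_len(delCol)] != 2L) - 1L
  expect_equal(refPosOfDel, runStart)
  # score equals the exhaustive optimum on a trimmed instance
  sc <- defaultAlignScores()
  sub <- substr(ref, 111, 135)
  subRead <- withDel(substr(ref, 111, 135), 11L, 1L)
  r <- DuplexFidelity:::.align_overlap_cpp(sub, subRead, sc$match,
                                           sc$mismatch, sc$gapOpen,
                                           sc$gapExt, -1L)
  expect_equal(r$score, oracleOverlapScore(sub, subRead))
})

test_that("first-strand reads reverse-complement to the same op list", {
  amp <- testAmplicon(2)
  seqRef <- withSub(refSequence(amp), 100L, "A")
  seqRef <- withDel(seqRef, 200L, 2L)
  first <- StrandRead("m", "first", revComp(seqRef))
  second <- StrandRead("m", "second", seqRef)
  a1 <- alignToReference(first, amp)
  a2 <- alignToReference(second, amp)
  expect_equal(orientation(a1), "reverse-complemented")
  expect_identical(alignmentOps(a1), alignmentOps(a2))
  expect_equal(refStart(a1), refStart(a2))
})

test_that("banded and unbanded alignments agree with the DP oracle", {
  set.seed(5)
  sc <- defaultAlignScores()
  for (k in 1:40) {
    m <- sample(10:30, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    read <- ref
    if (k %% 2 == 0) read <- withDel(read, sample(m - 3, 1), sample(2, 1))
    if (k %% 3 == 0) read <- withIns(read, sample(nchar(read) - 1, 1), "GA")
    if (k %% 5 == 0) read <- withSub(read, sample(nchar(read), 1) - 1, "C")
    r <- DuplexFidelity:::.align_overlap_cpp(ref, read, sc$match,
                                             sc$mismatch, sc$gapOpen,
                                             sc$gapExt, -1L)
    expect_equal(r$score, oracleOverlapScore(ref, read))
    rb <- DuplexFidelity:::.align_overlap_cpp(ref, read, sc$match,
                                              sc$mismatch, sc$gapOpen,
                                              sc$gapExt, 10L)
    expect_equal(rb$score, r$score)
  }
})

test_that("read filters enforce the documented inclusive boundaries", {
  amp <- testAmplicon(3)
  L <- ampLength(amp)
  full <- StrandRead("m", "second", refSequence(amp))
  ok <- mkAligned(full, rep(0L, L), 0L)
  expect_true(applyReadFilters(ok, amp)$accept)
  expect_equal(applyReadFilters(mkAligned(full, rep(0L, L), 0L, mapq = 59L),
                                amp)$reason, "mapq")
  expect_true(applyReadFilters(mkAligned(full, rep(0L, L), 0L, mapq = 60L),
                               amp)$accept)
  # non-spanning: starts after the 5' primer region
  short <- StrandRead("m", "second", substr(refSequence(amp), 26, L))
  expect_equal(applyReadFilters(mkAligned(short, rep(0L, L - 25L), 25L),
                                amp)$reason, "span5")
  # ends before the 3' primer region
  short3 <- StrandRead("m", "second", substr(refSequence(amp), 1, L - 25))
  expect_equal(applyReadFilters(mkAligned(short3, rep(0L, L - 25L), 0L),
                                amp)$reason, "span3")
  # chimera flag from supplementary alignments
  expect_equal(applyReadFilters(mkAligned(full, rep(0L, L), 0L,
                                          supplementary = 1L),
                                amp)$reason, "chimera")
  # length deviation: 50 accepted, 51 rejected
  dev50 <- StrandRead("m", "second",
                      paste0(refSequence(amp), strrep("A", 50)))
  a50 <- mkAligned(dev50, c(rep(0L, L), rep(2L, 50L)), 0L)
  expect_true(applyReadFilters(a50, amp)$accept)
  dev51 <- StrandRead("m", "second",
                      paste0(refSequence(amp), strrep("A", 51)))
  a51 <- mkAligned(dev51, c(rep(0L, L), rep(2L, 51L)), 0L)
  expect_equal(applyReadFilters(a51, amp)$reason, "length")
})

test_that("filter outcome equals the conjunction of individual rules", {
  amp <- testAmplicon(4)
  L <- ampLength(amp)
  set.seed(7)
  for (k in 1:25) {
    mq <- sample(c(0L, 59L, 60L, 80L), 1)
    st <- sample(c(0L, 10L, 25L), 1)
    supp <- sample(c(0L, 1L), 1)
    read <- StrandRead("m", "second", substr(refSequence(amp), st + 1, L))
    a <- mkAligned(read, rep(0L, L - st), st, mapq = mq,
                   supplementary = supp)
    res <- applyReadFilters(a, amp)
    manual <- mq >= 60L && st < 20L && supp == 0L &&
      abs((L - st) - L) <= 50L
    expect_equal(res$accept, manual)
  }
})

test_that("unalignable reads are rejected with a reason", {
  amp <- testAmplicon(5)
  junk <- StrandRead("m", "second", strrep("A", 400))
  a <- alignToReference(junk, amp)
  expect_s3_class(a, "alignmentReject")
  expect_equal(a$reason, "unalignable")
})

test_that("projection maps ops to reference coordinates", {
  amp <- testAmplicon(6)
  seqRef <- withSub(refSequence(amp), 123L, "A")
  seqRef <- withIns(seqRef, 300L, "GCT")
  read <- StrandRead("m", "second", seqRef)
  a <- alignToReference(read, amp)
  p <- projectToReference(a, ampLength(amp))
  expect_equal(p$bases[124L], "A")
  refc <- strsplit(refSequence(amp), "")[[1]]
  match_pos <- setdiff(which(!is.na(p$bases) & p$bases != "-"), 124L)
  expect_true(all(p$bases[match_pos] == refc[match_pos]))
  expect_equal(nrow(p$ins), 1L)
  expect_equal(nchar(p$ins$seq), 3L)
})
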