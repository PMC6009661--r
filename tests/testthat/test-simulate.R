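test_that("zero-rate simulation reproduces the reference exactly", {
  amp <- testAmplicon(1)
  m <- simulateMolecule(amp, errorModel(), errorModel(), errorModel(), 42)
  expect_identical(m$second, refSequence(amp))
  expect_identical(m$first, revComp(refSequence(amp)))
  expect_equal(nrow(m$truth), 0L)
})

test_that("RNAP-stage substitutions propagate into both strands", {
  amp <- testAmplicon(2)
  found <- 0L
  for (s in 1:20) {
    m <- simulateMolecule(amp, errorModel(subRates = 2e-3),
                          errorModel(), errorModel(), s)
    tr <- m$truth[m$truth$type == "substitution", ]
    for (k in seq_len(nrow(tr))) {
      p <- tr$ref_pos[k] + 1L
      expect_equal(substr(m$second, p, p), tr$observed[k])
      expect_equal(substr(revComp(m$first), p, p), tr$observed[k])
      found <- found + 1L
    }
  }
  expect_gt(found, 5L)
})

test_that("injected event counts follow the binomial expectation", {
  amp <- testAmplicon(3)
  rate <- 1e-3
  n <- 200L
  L <- ampLength(amp)
  ds <- simulateDataset(amp, n, rt1 = errorModel(subRates = rate), seed = 17)
  k <- sum(ds$truth$type == "substitution")
  mu <- n * L * rate
  expect_lt(abs(k - mu), 3 * sqrt(mu))
  expect_true(all(ds$truth$stage == "RT1"))
})

test_that("stage-pure injections never leak into other stage truth", {
  amp <- testAmplicon(4)
  em <- errorModel(subRates = 1e-3, delRate = 2e-4, insRate = 2e-4)
  z <- errorModel()
  rt2only <- simulateDataset(amp, 100, rnap = z, rt1 = z, rt2 = em, seed = 5)
  expect_true(all(rt2only$truth$stage == "RT2"))
  rnaponly <- simulateDataset(amp, 100, rnap = em, rt1 = z, rt2 = z, seed = 6)
  expect_true(all(rnaponly$truth$stage == "RNAP"))
  # RNAP events are template errors: both strands carry them
  expect_false(any(rnaponly$truth$stage == "RT2"))
})

test_that("subread noise matches the requested raw error rate", {
  amp <- testAmplicon(5)
  seqc <- refSequence(amp)
  clean <- simulateSubreads(seqc, 5, 0, seed = 1)
  expect_equal(length(clean), 5L)
  expect_true(all(clean == seqc))
  noisy <- simulateSubreads(seqc, 30, 0.1, seed = 2)
  d <- vapply(noisy, function(s) editDistance(seqc, s), 0L)
  mu <- nchar(seqc) * 0.1   # each injected event costs about one edit
  expect_lt(abs(mean(d) - mu), 4 * sd(d) / sqrt(length(d)) + 0.05 * mu)
  one <- simulateSubreads(seqc, 1, 0.1, seed = 3)
  expect_equal(length(one), 1L)
})

test_that("chimera construction follows the prefix/suffix contract", {
  expect_equal(makeChimera("AAAA", "CCCC", 2), "AACC")
  expect_equal(makeChimera("ACGT", "ACGT", 2), "ACGT")
  expect_equal(makeChimera("AAAA", "CCCC", 0), "CCCC")
})

test_that("dataset simulation is reproducible from the global seed", {
  amp <- testAmplicon(6)
  em <- errorModel(subRates = 1e-3, delRate = 1e-4)
  a <- simulateDataset(amp, 30, rnap = em, seed = 9)
  b <- simulateDataset(amp, 30, rnap = em, seed = 9)
  expect_identical(a$truth, b$truth)
  expect_identical(readSequence(a$molecules[[7]]$first),
                   readSequence(b$molecules[[7]]$first))
  c <- simulateDataset(amp, 30, rnap = em, seed = 10)
  expect_false(identical(a$truth, c$truth))
})

test_that("slippage gains and losses whole repeat units at repeat loci", {
  amp <- insertRepeat(testAmplicon(7), "GCT", 5, 250)
  em <- errorModel(slippageRate = 0.05)
  ds <- simulateDataset(amp, 100, rnap = em, seed = 21)
  tr <- ds$truth
  expect_gt(nrow(tr), 5L)
  expect_true(all(tr$type %in% c("insertion", "deletion")))
  gct <- tr[tr$length == 3L, ]
  expect_gt(nrow(gct), 0L)
  # left-aligned to the repeat run start (within one unit of the planted run)
  runStart <- findTandemRepeats(refSequence(amp))
  runStart <- runStart[runStart$unitLength == 3L & runStart$copies >= 5L, ]
  expect_true(all(vapply(gct$ref_pos, function(p)
    any(abs(p - runStart$start) <= 3L), TRUE)))
  ins <- gct[gct$type == "insertion", ]
  if (nrow(ins)) {
    units <- unique(ins$observed)
    expect_true(all(units %in% c("GCT", "CTG", "TGC")))
  }
})

test_that("context-biased substitution injection honours prevWeights", {
  amp <- testAmplicon(8)
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  m["A", "T"] <- 5e-3
  em <- errorModel(subRates = m, prevWeights = c(A = 0, C = 1, G = 0, T = 0))
  ds <- simulateDataset(amp, 200, rnap = em, seed = 31)
  tr <- ds$truth
  expect_gt(nrow(tr), 20L)
  prevBase <- substring(refSequence(amp), tr$ref_pos, tr$ref_pos)
  expect_true(all(prevBase == "C"))
  expect_true(all(tr$expected == "A" & tr$observed == "T"))
})
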