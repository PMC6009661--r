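test_that("generated references respect length, run cap and determinism", {
  amp <- generateReference(500, maxHomopolymer = 3, seed = 1)
  expect_s4_class(amp, "Amplicon")
  expect_equal(ampLength(amp), 500L)
  expect_lte(maxRun(refSequence(amp)), 3L)
  expect_identical(refSequence(generateReference(500, maxHomopolymer = 3,
                                                 seed = 1)),
                   refSequence(amp))
  expect_false(identical(refSequence(generateReference(500, seed = 2)),
                         refSequence(amp)))
  expect_true(validObject(amp))
})

test_that("all-4-mer references contain every 4-mer (independent scan)", {
  amp <- generateReference(600, maxHomopolymer = 4, requireAll4mers = TRUE,
                           seed = 3)
  core <- analyzableSequence(amp)
  # exhaustive census by direct substring extraction, no package code
  obs <- unique(substring(core, 1:(nchar(core) - 3), 4:nchar(core)))
  expect_equal(length(obs), 256L)
  expect_lte(maxRun(refSequence(amp)), 4L)
})

test_that("infeasible 4-mer constraints error unless relaxed", {
  expect_error(generateReference(600, maxHomopolymer = 3,
                                 requireAll4mers = TRUE, seed = 1),
               "infeasible|relaxFourMers")
  amp <- generateReference(700, maxHomopolymer = 3, requireAll4mers = TRUE,
                           relaxFourMers = TRUE, seed = 1)
  core <- analyzableSequence(amp)
  obs <- unique(substring(core, 1:(nchar(core) - 3), 4:nchar(core)))
  feasible <- sum(vapply(allKmers(4), function(k) maxRun(k) <= 3, TRUE))
  expect_gte(length(obs), feasible)
  expect_lte(maxRun(refSequence(amp)), 3L)
})

test_that("amplicon invariants are enforced", {
  expect_error(Amplicon("x", strrep("ACGB", 50)), "alphabet")
  expect_error(Amplicon("x", strrep("ACGT", 10)), "100")
  expect_error(Amplicon("x", strrep("ACGT", 50),
                        primer5 = c(0L, 30L), primer3 = c(20L, 200L)),
               "overlap")
})

test_that("analyzable region excludes exactly the primer intervals", {
  amp <- generateReference(500, seed = 4, primerLen = 20)
  m <- analyzableMask(amp)
  expect_equal(sum(m), 460L)
  expect_false(any(m[1:20]))
  expect_false(any(m[481:500]))
  expect_equal(analyzableLength(amp), nchar(analyzableSequence(amp)))
})

test_that("insertRepeat plants tandem units and shifts the 3' primer", {
  amp <- generateReference(500, seed = 2)
  rep4 <- insertRepeat(amp, "GCT", 4, 200)
  expect_equal(substr(refSequence(rep4), 201, 212), strrep("GCT", 4))
  expect_equal(ampLength(rep4), 512L)
  expect_equal(primer3(rep4), primer3(amp) + 12L)
  expect_identical(refSequence(insertRepeat(amp, "GCT", 0, 200)),
                   refSequence(amp))
  expect_error(insertRepeat(amp, "GCT", 2, 5), "analyzable")
  run8 <- insertRepeat(amp, "A", 8, 300)
  expect_gte(maxRun(refSequence(run8)), 8L)
})

test_that("tandem repeat finder locates planted repeats", {
  amp <- insertRepeat(generateReference(500, seed = 6), "GCT", 5, 250)
  reps <- findTandemRepeats(refSequence(amp))
  gct <- reps[reps$unit %in% c("GCT", "CTG", "TGC") & reps$copies >= 5, ]
  expect_gte(nrow(gct), 1L)
  expect_true(any(abs(gct$start - 250) <= 3))
})
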