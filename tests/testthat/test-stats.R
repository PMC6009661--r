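mkEvents <- function(n, template = "t1", strand = "first",
                     type = "substitution", pair = "rA->rG", pos = 100L) {
  if (n == 0L) return(DuplexFidelity:::.emptyEvents())
  data.frame(molecule_id = sprintf("m%d", seq_len(n)), strand = strand,
             type = type, ref_pos = pos, expected = "A", observed = "G",
             length = 1L, rnap_pair = pair, rt_pair = "dT->dC",
             event_qual = 93L, context = "", template = template,
             stringsAsFactors = FALSE)
}

test_that("rates divide event counts by total bases", {
  ev <- mkEvents(5)
  r <- computeRates(ev, totals = 1e5, by = "type")
  expect_equal(r$rate, 5e-5)
  expect_equal(r$n_events, 5L)
  expect_error(computeRates(ev, totals = data.frame(template = "t2",
                                                    n_bases = 1)),
               "cover")
  expect_error(computeRates(ev, totals = data.frame(template = "t1",
                                                    n_bases = 0)),
               "zero")
})

test_that("template mean and SD match hand computation", {
  rates <- c(50, 60, 55, 59) * 1e-6
  ev <- do.call(rbind, lapply(1:4, function(i)
    mkEvents(c(50L, 60L, 55L, 59L)[i], template = sprintf("t%d", i))))
  totals <- data.frame(template = sprintf("t%d", 1:4), n_bases = 1e6)
  r <- computeRates(ev, totals, by = "strand")
  s <- rateSummary(r, by = "strand")
  expect_equal(s$mean_rate, mean(rates))
  expect_equal(s$sd_rate, sd(rates))
  expect_equal(s$n_templates, 4L)
  # a template with no events contributes rate 0
  s0 <- rateSummary(r, by = "strand", templates = sprintf("t%d", 1:5))
  expect_equal(s0$mean_rate, mean(c(rates, 0)))
})

test_that("fold change follows (M - S)/S with documented edge cases", {
  expect_equal(foldChange(1e-4, 1e-4), 0)
  expect_equal(foldChange(2e-4, 1e-4), 1)
  expect_equal(foldChange(0, 1e-4), -1)
  expect_warning(fc <- foldChange(1e-4, 0), "undefined")
  expect_true(is.na(fc))
  tbl <- foldChangeTable(
    data.frame(subtype = c("rA->rG", "rA->rU"), rate = c(3e-4, 1e-4)),
    data.frame(subtype = c("rA->rG", "rA->rU"), rate = c(1e-4, 1e-4)))
  expect_equal(tbl$fold[tbl$subtype == "rA->rG"], 2)
  expect_equal(tbl$fold[tbl$subtype == "rA->rU"], 0)
})

test_that("condition comparison matches the textbook Welch t-test", {
  a <- c(10, 11, 10, 11) * 1e-6
  b <- c(30, 31, 30, 31) * 1e-6
  res <- compareConditions(a, b, nComparisons = 1L)
  # independent hand computation of Welch t
  tHand <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(res$statistic, tHand)
  expect_true(res$significant)
  # identical vectors: t = 0, p = 1, not significant
  same <- compareConditions(a, a)
  expect_equal(same$p.value, 1)
  expect_false(same$significant)
  # Bonferroni can flip the verdict without changing p
  b2 <- c(12, 13, 12, 13) * 1e-6
  one <- compareConditions(a, b2, nComparisons = 1L)
  many <- compareConditions(a, b2, nComparisons = 1e4)
  expect_true(one$significant)
  expect_equal(many$p.value, one$p.value)
  expect_gt(many$p.value, many$alphaAdjusted)
  expect_false(many$significant)
  expect_error(compareConditions(1, b), "replicates")
})

test_that("indel size distribution bins 1/2/3/>=4 as percentages", {
  ev <- rbind(
    data.frame(strand = "first", type = "deletion",
               length = c(1L, 1L, 2L, 4L)),
    data.frame(strand = "first", type = "substitution", length = 1L))
  d <- indelSizeDistribution(ev)
  del <- d[d$type == "deletion", ]
  expect_equal(c(del$s1, del$s2, del$s3, del$s4plus), c(50, 25, 0, 25))
  expect_equal(del$n_events, 4L)
  insr <- d[d$type == "insertion", ]
  expect_true(insr$empty)
  expect_equal(insr$s1 + insr$s2 + insr$s3 + insr$s4plus, 0)
})

test_that("hotspot ranking is count-descending with position tie-break", {
  amp <- testAmplicon(21)
  ev <- data.frame(type = "substitution",
                   ref_pos = c(40L, 50L, 60L, 70L, 80L),
                   stringsAsFactors = FALSE)
  h <- rankHotspots(ev, amp, topK = 3L)
  expect_equal(h$substitution$ref_pos, c(40L, 50L, 60L))  # ties: lowest first
  spike <- rbind(ev, data.frame(type = "substitution",
                                ref_pos = rep(70L, 9L)))
  h2 <- rankHotspots(spike, amp, topK = 3L)
  expect_equal(h2$substitution$ref_pos[1], 70L)
  expect_equal(h2$substitution$count[1], 10L)
  expect_equal(nrow(h2$deletion), 0L)
})

test_that("context profile reports RNA-alphabet flank frequencies", {
  amp <- testAmplicon(22)
  ref <- refSequence(amp)
  # substitution events at every analyzable A preceded by C
  prevC <- which(strsplit(ref, "")[[1]] == "A" &
                   c("x", head(strsplit(ref, "")[[1]], -1)) == "C") - 1L
  prevC <- prevC[prevC >= 23L & prevC <= 470L]
  ev <- data.frame(type = "substitution", ref_pos = prevC,
                   stringsAsFactors = FALSE)
  cp <- contextProfile(ev, amp, window = 3L)
  expect_equal(unname(cp$freq["-1", "C"]), 1)
  expect_equal(unname(rowSums(cp$freq)), rep(1, 6), tolerance = 1e-12)
  expect_equal(cp$n_events, length(prevC))
  # events too close to the reference end are excluded and counted
  evEdge <- data.frame(type = "substitution", ref_pos = c(1L, prevC),
                       stringsAsFactors = FALSE)
  cpe <- contextProfile(evEdge, amp, window = 3L)
  expect_equal(cpe$n_excluded, 1L)
})

test_that("subtype rates sum to the total substitution rate", {
  set.seed(12)
  pairs <- c("rA->rG", "rA->rU", "rC->rU", "rG->rA")
  ev <- do.call(rbind, lapply(pairs, function(p)
    mkEvents(sample(5:20, 1), pair = p)))
  tot <- computeRates(ev, 1e6, by = "type")
  bySub <- computeRates(ev, 1e6, by = "rnap_pair")
  expect_equal(sum(bySub$rate), tot$rate[tot$type == "substitution"])
})
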