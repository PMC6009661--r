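# Independent oracles used across the test suite. These deliberately share no
# code with the package implementation.

# Full (unbanded) overlap affine-gap DP, score only: free leading/trailing
# gaps on both sequences, gap of length k costs open + k * ext.
oracleOverlapScore <- function(ref, read, match = 2, mismatch = -4,
                               open = 6, ext = 1) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(read, "")[[1]]
  m <- length(a); n <- length(b)
  NEG <- -1e9
  H <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  H[1, ] <- 0
  H[, 1] <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(H[m + 1, ], H[, n + 1])
}

# complement-table enumeration of the dual substitution labels: for each of
# the 12 reference/cDNA mismatch pairs, derive the equivalent RNA polymerase
# and reverse transcriptase substitutions from first principles
oracleClassifyAll <- function() {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rna <- function(b) sub("T", "U", b)
  out <- list()
  for (ref in names(comp)) {
    for (cdna in names(comp)) {
      if (cdna == comp[[ref]]) next  # correct incorporation, not an error
      # scenario 1: RNAP miswrote the RNA base as X, RT copied faithfully,
      # so the cDNA shows comp(X): X = comp(cdna)
      rnap <- sprintf("r%s->r%s", rna(ref), rna(comp[[cdna]]))
      # scenario 2: RNA was correct (base = ref), RT misincorporated cdna
      # across it; the RT template base is comp(ref)... rendered from the
      # cDNA synthesis perspective: template comp(ref) -> product cdna
      rt <- sprintf("d%s->d%s", comp[[ref]], cdna)
      out[[paste0(ref, ">", cdna)]] <- c(rnap = rnap, rt = rt)
    }
  }
  out
}

# unit-cost edit distance via base R (C implementation), used as an
# independent distance oracle
editDistance <- function(a, b) as.integer(adist(a, b))

# shared small reference fixture
testAmplicon <- function(seed = 1, length = 500) {
  generateReference(length, maxHomopolymer = 3, seed = seed)
}

# a StrandRead pair for a molecule whose strand sequences are given in
# reference frame, with saturated qualities
refFramePair <- function(id, firstRefFrame, secondSeq, qual = 93L,
                         passes = 30L) {
  list(id = id,
       first = StrandRead(id, "first", revComp(firstRefFrame), qual, passes),
       second = StrandRead(id, "second", secondSeq, qual, passes))
}

# substitute one base (0-based position) in a sequence string
withSub <- function(seq, pos0, base) {
  substr(seq, pos0 + 1, pos0 + 1) <- base
  seq
}

# delete len bases at 0-based position
withDel <- function(seq, pos0, len) {
  paste0(substr(seq, 1, pos0), substr(seq, pos0 + len + 1, nchar(seq)))
}

# insert a string before 0-based position
withIns <- function(seq, pos0, ins) {
  paste0(substr(seq, 1, pos0), ins, substr(seq, pos0 + 1, nchar(seq)))
}

# construct an AlignedStrand with prescribed slots (for filter tests)
mkAligned <- function(read, ops, refStart, mapq = 60L,
                      orientation = "as-is", supplementary = 0L) {
  new("AlignedStrand", read = read, ops = as.integer(ops),
      refStart = as.integer(refStart),
      refEnd = as.integer(refStart + sum(ops != 2L)),
      mapq = as.integer(mapq), orientation = orientation,
      supplementaryCount = as.integer(supplementary), score = 0)
}
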