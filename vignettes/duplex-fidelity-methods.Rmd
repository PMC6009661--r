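---
title: "Strand-resolved fidelity measurement: models, filters and design choices"
author: "DuplexFidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved fidelity measurement: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DuplexFidelity)
```

## The measurement problem

When RNA is reverse-transcribed and the resulting cDNA is copied into a
second DNA strand, the double-stranded product carries three layers of
replication errors:

1. **RNA synthesis errors** — the RNA polymerase misincorporates while
   transcribing the DNA template. These mutations are part of the template
   that the reverse transcriptase copies, so they end up in *both* DNA
   strands.
2. **First-strand (cDNA) errors** — the reverse transcriptase
   misincorporates against the RNA. The second strand is copied from the
   cDNA, so these too appear in both strands. Layers 1 and 2 are therefore
   indistinguishable from the final product and are reported together as the
   cumulative *first-strand error rate*, with each observed mismatch carrying
   the two equivalent labels that could have produced it (e.g. a cDNA C
   opposite a reference A is `rA->rG / dT->dC`).
3. **Second-strand errors** — misincorporation while copying the cDNA into
   the second strand. These produce a mismatch *between* the two DNA strands
   and uniquely isolate reverse-transcriptase fidelity on a DNA template.

Single-molecule circular consensus sequencing reads both strands of each
molecule many times, which makes the layer structure observable: a
first-strand error is a position where both strands agree on a non-reference
base (duplex confirmation), a second-strand error is a position where the
second strand disagrees with a first strand that matches the reference, and
anything else at a discrepant locus is discordant and excluded from both
classes. `callDuplexErrors()` implements exactly this partition, so every
discrepant locus is counted once or deliberately logged as dropped.

Because consensus and sequencing artifacts on the two strands are
independent, duplex confirmation suppresses them quadratically; that is what
lets per-base error rates in the 1e-5 range be measured from reads whose raw
per-pass accuracy is only ~90-95%.

## Reference amplicons

`generateReference()` builds synthetic amplicons with the statistical
properties of the artificial templates such assays use: an analyzable core
that contains **every overlapping 4-mer** (a seeded order-4 de Bruijn-style
walk, re-verified by an exhaustive scan) so that sequence-context analyses
see all contexts, a **homopolymer cap** (default: no run longer than 3; 4 is
the minimum compatible with covering homopolymeric 4-mers), and **primer
regions** at both ends that are excluded from all error computations. The
default primer length is 20 bases per end, i.e. 40 excluded bases in total;
the flanking-primer interpretation is configurable because the total could
also be read as 40 per end. `insertRepeat()` plants a tandem repeat (such as
a GCT triplet run) in the analyzable region to make slippage observable.

## The simulator and what it does (not) emulate

`simulateMolecule()` applies three independent `errorModel()`s in the causal
order of the assay: RNA synthesis, then first-strand synthesis (whose
substitution matrix is specified in the cDNA frame and complement-transformed
internally), then second-strand synthesis on a copy of the cDNA state. Every
injected event is logged with its stage, type, left-aligned 0-based
reference position and a slippage flag — the truth data that all recovery
tests audit against.

The error model is intentionally minimal but covers the features the
pipeline must be robust to:

* substitutions with a full 4x4 (expected base, observed base) rate matrix,
  optionally multiplied by a preceding-base weight (`prevWeights`) to
  emulate sequence-context-biased misincorporation;
* deletions and insertions with a configurable size distribution, inserted
  bases uniform over A/C/G/T;
* whole-unit slippage at tandem repeats (unit length 1-6; slippage is
  applied at loci with at least four tandem copies, long enough for strand
  misalignment), the mechanism behind triplet insertions at triplet
  repeats;
* chimeric molecules formed by template switching at two independent
  breakpoints, which changes the product length;
* per-pass raw subread noise (60% substitutions, 20% single-base deletions,
  20% single-base insertions of the total raw error rate).

A "modification" is represented purely as a different per-stage error model
(e.g. an elevated adenosine substitution row for an m6A-like template);
the chemistry itself is invisible at this level. The simulator does **not**
model polymerase kinetics, quality-dependent error profiles, position- or
GC-dependent coverage, or modification-dependent processivity — so passing
recovery tests demonstrate that the *computational* pipeline is unbiased
under its stated assumptions, not that any laboratory protocol is.

One global seed fans out deterministically (molecule *i* of a data set uses
`(seed * 1000003 + i) mod (2^31 - 1)`), so any single molecule can be
regenerated in isolation.

## Consensus building

`buildConsensus()` is a deliberately simple majority-vote consensus — the
industrial arrow/HMM polishing used by real single-molecule pipelines is out
of scope, and externally produced consensus reads can be supplied instead.
Subreads are aligned pairwise (banded affine-gap alignment) to a draft — the
lexicographically smallest among the longest subreads, which makes the
result invariant to subread order — and each draft column is voted: the
winning symbol is the most frequent base or gap, with ties resolved in favor
of a base and then by the fixed order A < C < G < T. Voting is repeated with
the emerging consensus as the new draft (at most four rounds) because a
noisy initial draft leaves indel-placement ambiguity that a single vote
cannot resolve. Insertions relative to the draft are restored when at least
30% of the covering reads carry one at the same left-aligned junction (at
least 2 reads), a threshold that separates the support observed for genuine
bases (~40%+) from coincidental noise placements (up to ~25-30%);
low-coverage terminal columns are trimmed as draft overhang.

Per-base quality is the Phred-scaled column agreement
`min(93, round(-10 log10(max(1 - f, 1e-9.3))))` with `f` the agreeing
fraction, capped at the conventional maximum of 93. Two consequences matter:

* quality saturates at 93 **only on unanimous columns**, so the strict
  QUAL = 93 event filter is appropriate for noiseless or externally polished
  consensus reads, while majority-vote consensus from noisy subreads should
  be analyzed at a lower `qualThreshold` (the recovery analyses in this
  package use 0 and rely on duplex confirmation for specificity);
* at 20 passes the consensus is empirically exact for essentially all
  molecules at 5% raw error, and for roughly 96-99% of molecules at 10% raw
  error, where dense noise around repeats can defeat simple column votes.
  This is the accuracy floor of the majority-vote contract, not of the
  pipeline's statistics, which are audited end to end at 5% raw error.

## Alignment and read filters

`alignToReference()` is a banded overlap (free end-gap) affine-gap aligner
(match +2, mismatch -4, gap open -6, gap extension -1; a length-k gap costs
`open + k*ext`). First-strand reads are reverse-complemented into reference
frame before alignment. Indel runs are **left-aligned** against the
reference afterwards — mandatory, because duplex confirmation matches indels
between strands by reference coordinate, and the simulator normalizes its
truth positions with the same rule. On instances small enough to enumerate,
the aligner provably returns the optimal score (the test suite carries an
independent full-DP oracle). The band half-width (default 50) comfortably
covers the coordinate drift of reads whose indel content is a fraction of a
percent; tests that align 20 noisy subreads per strand use 24-30.

`applyReadFilters()` applies the read-acceptance cascade in fixed order,
recording the first failing rule: mapping quality at least 60 (internal
unique alignments carry a sentinel 60; external SAM keeps the aligner's
MAPQ); the alignment must start inside the 5'-primer interval and end inside
the 3'-primer interval (spanning reads only); no supplementary alignments
(split mapping marks chimeras); and the read length must be within 50 bases
of the expected length (default: the amplicon length — the per-amplicon
reading of "expected read length", configurable). All boundaries are
inclusive on the accepting side: 60 passes, deviation 50 passes, 15 passes
of consensus coverage pass. The accept/reject outcome is independent of rule
order; only the recorded reason depends on it.

Chimeras formed at unequal breakpoints change the product length and are
caught by the length rule even when the alignment itself still spans the
reference (the large indel is absorbed); equal-breakpoint chimeras between
identical templates are invisible, and are also harmless here because the
templates are identical.

## Error attribution rules

For each molecule whose two strands both survive the filters, the two
alignments are projected into reference coordinates and compared
position-wise:

* **first-strand substitution**: both strands carry the identical
  non-reference base; requires per-strand quality at or above
  `qualThreshold` on both strands; labelled with the equivalent pair from
  `classifySubstitution()`;
* **second-strand substitution**: the second strand differs from a first
  strand that matches the reference; labelled (expected base -> observed
  base) in second-strand frame;
* **indels**: per-base gaps are collapsed into maximal runs (a multi-base
  indel is one event); runs are matched between strands by their left-aligned
  start coordinate. An indel present in both strands with different lengths
  becomes a first-strand event of the shared length plus a second-strand
  event for the difference — this keeps the partition property (every
  discrepant locus is assigned to exactly one class or logged as
  discordant). Deletion event quality is the minimum quality of the read
  bases flanking the gap; insertion quality the minimum over inserted bases.
* **discordant loci** — both strands differ from the reference in different
  ways, or a first-strand discrepancy is unconfirmed — are counted in
  neither class and logged with a reason. How such loci should be tallied is
  genuinely underdetermined; dropping and logging them is the conservative
  choice and is exercised by the test suite.

Positions inside the primer intervals are never called. The rate denominator
is the number of analyzable reference positions covered by both strands of
accepted molecules: deletions consume denominator bases, insertions do not.

## Statistics

`computeRates()` divides event counts by analyzable sequenced bases per
template; `rateSummary()` averages across templates and reports the standard
deviation, the form in which per-enzyme results are quoted.
`foldChange()` implements the modified-vs-unmodified normalization
`(M - S)/S` (0 = no change, -1 = complete suppression, undefined at S = 0).
`compareConditions()` is a two-sided Welch t-test on per-template rates —
Welch rather than pooled because four replicate templates give no power to
verify equal variances — with significance declared at `alpha /
nComparisons` (Bonferroni). `indelSizeDistribution()` bins collapsed indel
events at 1/2/3/>=4 bases; `rankHotspots()` ranks reference positions by
event count per error type (ties to the lower coordinate) and returns the
top three with context; `contextProfile()` tabulates the reference bases at
offsets -W..+W around substitution events in the RNA alphabet (default W =
3), excluding and counting events whose window leaves the reference.

## Numerical and scale choices

The simulation-backed analyses in the tests and the study script use ~500 bp
amplicons with 460 analyzable bases, 2 000-2 300 molecules per condition
(about 1e6 analyzable duplex bases, enough for 3-sigma binomial checks on
rates down to 5e-5), 20-pass subreads at 5% raw error, and four replicate
templates for cross-template statistics. These sizes put every stochastic
check comfortably above its detection floor while keeping a full run in the
minutes range on one core.

## Known limitations

* The consensus caller is a majority-vote stand-in with the accuracy floor
  described above; real pipelines should feed externally polished consensus
  reads (FASTQ or SAM/BAM) into `runCall()` and use the strict QUAL = 93
  event filter.
* Quality values of the majority-vote consensus are agreement-based, not
  calibrated error probabilities.
* Stage attribution cannot, even in principle, separate RNA-polymerase from
  first-strand reverse-transcriptase errors; the package reports the dual
  labels rather than pretending to resolve them.
* Errors on bases inserted by an earlier stage are not re-mutated by later
  stages in the simulator (a second-order effect at the modelled rates).
* When two events land within a few bases of each other in one molecule,
  the optimal alignment may represent the cluster by an equivalent
  decomposition (for instance two single-base deletions as one two-base
  deletion plus a substitution). Strand attribution, the affected loci and
  the event count are unaffected; only the per-event parse is ambiguous.
  Event coordinates are normalized against the reference alone (leftmost
  equivalent placement) so that unique representations always agree between
  strands and with any annotation.
* The chimera rate default in examples (1%) is a placeholder; template
  switching rates are not quantified by the assay this package models.
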