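---
title: "Polishing CCS reads and recalibrating base qualities with partial-order graph cuts"
author: "ccspolish authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polishing CCS reads and recalibrating base qualities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccspolish)
```

## The problem

PacBio circular consensus sequencing (CCS/HiFi) reads a circularised DNA
molecule many times and collapses the passes into one consensus read.  The
consensus is very accurate, but the *quality scores* attached to it are
not: a large fraction of bases is reported at the Phred ceiling of Q93
(error probability $5\times10^{-10}$) while, measured against a
near-perfect truth set, those bases validate at roughly Q45.  For genome
assembly this hardly matters; for calling a somatic variant seen in a
*single* read it is fatal, because the per-base error probability must be
trusted at face value.

`ccspolish` addresses both halves of the problem: it *polishes* the
consensus sequence using the subreads it came from, and it *recalibrates*
each base's quality with a small supervised model whose inputs summarise
the evidence the subreads actually provide.

## Parallel bases via a cut of the ranked POA graph

All subreads and the consensus read are aligned into one partial-order
alignment (POA) graph: nodes carry single bases, and each edge weight
counts the sequences that traverse that transition.  A new sequence is
added by global dynamic programming against the DAG (on a single-path
graph this reduces exactly to Needleman–Wunsch, which is how the aligner
is tested), reusing a node on a matching base and otherwise creating a
*parallel* node at the locus.

Virtual source and sink nodes bracket every aligned sequence.  This
bookkeeping gives the central invariant: after topological ranking, **any
cut between consecutive ranks is crossed by exactly `numSequences` units
of edge weight** — every aligned sequence crosses every full cut exactly
once.

For a consensus base ("calling base") the parallel-base counts are read
off the cut placed directly in front of its node:

* the calling node's incoming edge weights count toward its own base;
* every other crossing edge $(u, v)$ with $\mathrm{rank}(u) <
  \mathrm{rank}(\text{calling}) < \mathrm{rank}(v)$ is attributed to
  $\mathrm{base}(u)$, the parallel node carrying the alternative;
* if $u$ is a direct parent of the calling node (or the virtual source),
  the sequences on that edge skip the locus entirely and are counted as
  gaps.

If the forward tally does not reach `numSequences`, a mirrored pass over
the cut *behind* the calling base is used, and if neither is complete the
elementwise maximum is kept and flagged — incomplete tallies are rare
under global alignment and are surfaced rather than silently trusted.

```{r worked-example}
g <- buildPoa("TAGGCTA",
              c("TAGGCTA", "TAGGCTA", "TAGGCTA", "TAGGCTA", "TAGGAA"))
identifyParallelBases(g, backbone(g)[5])
```

Five sequences support the C, one variant subread carries an A (and skips
the following T), and the cut accounts for all six sequences.

### Two tie-breaks that the cut depends on

Two determinism rules are load-bearing, and both were chosen so that the
cut semantics stay anchored to loci:

* **Topological ties rank later-created nodes first.**  A parallel node is
  always created after the backbone node it competes with; ranking it
  first keeps same-locus alternatives on the *upstream* side of the cut in
  front of the backbone base, where the attribution rule can see them.
  With the opposite order the alternative's crossing edge would start at a
  direct parent of the calling node and be mis-attributed to a gap.
* **Traceback prefers match > deletion > mismatch > insertion.**  A
  substitution immediately followed by a deletion is score-tied with a
  deletion immediately followed by a substitution under any linear-gap
  scoring.  Preferring the deletion when walking back anchors the
  substituted base on the locus it contests instead of its downstream
  neighbour, so the parallel node appears where the evidence is.

## Correction rules

Three corrections are applied, each base receiving exactly one origin tag
so the categories stay disjoint:

1. the heaviest-path POA consensus (maximum total edge weight from source
   to sink) is aligned back to the consensus read; where it substitutes a
   base the base is replaced (`POA_SUB`), where it deletes one the base is
   removed (`POA_DEL`);
2. at positions the consensus left untouched, an alternative base with a
   *strictly* higher parallel count than the original replaces it
   (`PARALLEL`).  Ties keep the original.  A gap majority is never applied
   as a deletion: deletions come only from the consensus path.  Consensus
   insertions are ignored — the corrections are substitution/deletion
   only.

Parallel counts are computed once, on the original backbone, before any
deletion shifts positions; re-cutting after consensus deletions is a
possible refinement that is deliberately not done (single polishing pass).

## The calibration model

Each polished base is summarised by ~35 features: one-hot trinucleotide
context (with explicit end pads), the original consensus quality, the
five parallel counts both raw and as fractions of their total (so the
signal is depth-invariant), mean subread inter-pulse duration and pulse
width over *matched* subread bases at the locus (missing kinetics are
encoded as 0 with a presence bit), and the four per-read SNR channels.

The default model is a feed-forward network with two ReLU hidden layers
(64 and 32 units) and a sigmoid output, trained with binary cross-entropy
(Adam, minibatches of 512, default learning rate $2\times10^{-3}$) and
early stopping on a held-out split taken *by molecule*, so bases of one
read never straddle the split.  Labels are 1 for a base that matches the
reference (or a germline variant) and 0 otherwise.  A logistic-regression
baseline sits behind the same interface and is used as a sanity check in
the tests.

Class weighting (inverse class frequency, the default) is useful because
errors are rare, but a weighted loss shifts the optimal output away from
the true conditional probability: the optimum is
$p_w = w_1\pi/(w_1\pi + w_0(1-\pi))$.  Predictions are therefore
analytically inverted back to $\pi$ before use, which keeps the output a
calibrated probability; without this correction class weighting and
calibration would be mutually exclusive.  The probability converts to a
Phred score as $Q = \mathrm{round}(-10\log_{10}(1-\pi))$, clamped to the
working range $[1, 93]$.

Everything is plain matrix arithmetic seeded from one integer, so a fit
is bit-reproducible; the model serialises to a single JSON file carrying
its feature schema and refuses to load against a different schema.

## The simulator and what it does (not) emulate

The synthetic-molecule generator drives every test: a uniform random
reference, `nPasses` independently mutated passes (substitutions 1.5%,
insertions 5%, deletions 4% per base by default — skewed towards indels
as in real PacBio passes; indels are single-base), alternating
forward/reverse orientations with reverse passes stored
reverse-complemented and kinetics reversed, lognormal inter-pulse
durations (meanlog 2.0, sdlog 0.5) and pulse widths (1.8, 0.4) in frames,
per-read SNR from a normal (10, 2) truncated at 0.1, and consensus errors
planted as substitutions at 0.02% to mirror the error-rate magnitude of
raw HiFi consensus reads.  Error-bearing bases draw kinetics with a +0.5
meanlog shift so the feature is informative by construction.  Cohorts
share one reference, plant heterozygous germline variants (each molecule
carries the ALT with probability 1/2) and single-molecule somatic
variants, and emit full truth tables.  Per-molecule RNG streams derive
from (master seed, molecule index).

Deliberately *not* emulated: homopolymer-dependent indel rates, chimeric
molecules, adapter artefacts, partial (incomplete) passes, and multi-base
indels.  Tests passing on this generator therefore demonstrate the
algorithmic contracts — cut conservation, oracle equivalence, correction
behaviour, calibration recovery — not performance on real instrument
data.

A second, feature-level generator (`simulateFeatureSet()`) produces
labelled feature vectors whose true error probability is a *known*
logistic function of the supporting-count fraction and the nominal
quality, centred so the bulk of bases sit at a few percent error
(Q ≈ 6–16).  It exists to test parameter recovery and Phred calibration
of the model with an exact ground truth, and its strata control
(`errorScale`) perturbs the agreement distribution — i.e. the features —
so a fixed model must see noisier strata as lower quality.

## Numerical and interface choices

* Integer scoring, match +2 / mismatch −4 / gap −4 (linear), global on
  both ends; subreads are treated as full passes.
* `N` bases score as a mismatch against everything.
* All internal coordinates are 1-based within R objects; file formats use
  their native conventions.
* Effective-quality summaries floor the real-valued Phred (45.5 → 45);
  zero-mismatch bins report the one-sided bound $-10\log_{10}(1/n)$,
  flagged, never infinity.
* The maximum validated Q requires a configurable per-bin support
  (default $10^5$ bases; desk-scale analyses pass a smaller threshold
  explicitly).
* The consensus read counts as one of the aligned sequences by default
  (`buildPoa(countCcs = FALSE)` gives the other convention).
* Problem sizes used by the shipped tests and validation runs are
  desk-scale by design: molecules of 120–300 bases, cohorts of tens of
  molecules, feature sets of $10^5$–$3\times10^5$ bases.  All the
  algorithmic properties being checked are size-invariant.

## Known limitations

* The cut attributes an alternative by the node *upstream* of the
  crossing edge; a parallel node that happens to rank after the calling
  base (possible only with unusually long parallel chains) is counted as
  a gap.  The path-tracking oracle in the test suite uses the same
  attribution semantics, so this is a documented semantic, not a silent
  bug.
* Insertion alternatives (bases present in subreads but absent from the
  consensus) are tallied into no category and never proposed as
  insertions.
* One polishing pass only; positions are not re-cut after deletions.
* Alignment DP memory is O(nodes × sequence length); the implementation
  targets desk-scale molecules (up to a few kilobases), not banded or
  SIMD operation.
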