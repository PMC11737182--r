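# ccspolish

Consensus polishing and base-quality recalibration for PacBio circular
consensus sequencing (CCS/HiFi) reads.

CCS reads are built from many sequencing passes over one circularised
molecule. The consensus sequence is excellent, but its Phred quality
scores are not trustworthy at the top of the scale: bases reported at
Q93 (error probability $5\times10^{-10}$) empirically validate at about
Q45. That gap is irrelevant for assembly but fatal for somatic variant
calling from single reads, where the stated per-base error probability
is the whole argument. `ccspolish` is aimed at people building or
validating single-molecule variant-calling pipelines: it corrects
consensus bases that the subreads outvote and replaces the quality
scores with calibrated ones.

## What it computes

1. **Parallel bases by a topological graph cut.** The consensus read and
   its subreads are aligned into one partial-order alignment (POA)
   graph $G$: nodes carry bases, an edge's weight counts the sequences
   using that transition, virtual source/sink nodes bracket every
   sequence. After topological ranking, the counts of the alternative
   ("parallel") bases at a consensus base $c$ are read off the cut in
   front of $c$'s node: incoming edge weights of $c$ count toward
   $\mathrm{base}(c)$, and every other crossing edge $(u,v)$ with
   $\mathrm{rank}(u) < \mathrm{rank}(c) < \mathrm{rank}(v)$ counts
   toward $\mathrm{base}(u)$ — or toward the gap category when $u$ is a
   direct parent of $c$ (the sequence skips the locus). Every full cut
   is crossed by exactly `numSequences` units of weight, so the tally
   accounts for every sequence.
2. **Polishing.** The heaviest source-to-sink path of $G$ is aligned
   back to the consensus: substitutions (`POA_SUB`) and deletions
   (`POA_DEL`) are applied. Remaining bases whose parallel counts
   strictly favour an alternative are replaced (`PARALLEL`).
3. **Recalibration.** Per base, a feed-forward network (64/32 ReLU
   hidden units, sigmoid output, class-weighted cross-entropy with
   analytic prior correction) maps trinucleotide context, original
   quality, parallel counts, mean subread kinetics (inter-pulse
   duration, pulse width) and per-read SNR to a correctness
   probability $\pi$, reported as
   $Q = \mathrm{round}(-10\log_{10}(1-\pi))$ clamped to $[1, 93]$.
4. **Validation.** Reliability binning of predicted versus observed
   quality ($Q_{obs} = -10\log_{10}(\text{mismatches}/\text{bases})$),
   maximum validated Q, error-rate tables, substitution-by-context
   tables, and expected somatic burden arithmetic.

A synthetic-molecule simulator with complete ground truth (passes with
stated substitution/indel rates, alternating orientations, lognormal
kinetics, planted consensus errors, germline/somatic variants) makes the
whole pipeline testable offline; fixtures round-trip through standard
BAM/FASTA/FASTQ/VCF/TSV.

## Worked example

The six-sequence textbook case: five sequences carry a C, one variant
subread carries an A and skips the next base. The cut in front of the C
accounts for all six sequences:

```r
library(ccspolish)
g <- buildPoa("TAGGCTA",
              c("TAGGCTA", "TAGGCTA", "TAGGCTA", "TAGGCTA", "TAGGAA"))
identifyParallelBases(g, backbone(g)[5])
#> A C G T -
#> 1 5 0 0 0
#> attr(,"total")
#> [1] 6
#> attr(,"complete")
#> [1] TRUE
#> attr(,"direction")
#> [1] "forward"
```

C keeps its 5 supporting sequences, the alternative A has 1, no sequence
skips the locus, and the total equals the number of aligned sequences —
so the evidence is complete and the C stands (5 > 1).

End to end on a simulated molecule with two planted consensus errors:

```r
sm <- simulateMolecule(refLength = 120, nPasses = 8,
                       ccsErrorRate = 0.02, seed = 4)
res <- polishMolecule(sm$molecule)
res$polished
#> PolishedRead: 120 bases (POA_SUB 2, POA_DEL 0, PARALLEL 0)
```

Both planted errors were corrected by the POA-consensus substitution
rule (sensitivity 1, specificity 1 against the molecule's truth table
via `tallyCorrections()`). Training and applying a calibration model:

```r
fs <- simulateFeatureSet(2e5, seed = 1)
model <- trainCalibrationModel(fs$features, fs$labels,
                               molecule = fs$molecule, epochs = 60)
run <- runPolishPipeline(list(sm$molecule), model = model,
                         out = "polished.fastq")
```

A thin CLI over the same functions lives at `inst/cli/ccspolish`
(subcommands `simulate`, `train`, `polish`, `validate`).

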