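---
title: "Classifying read overlaps before contig construction"
author: "OverlapCorrect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying read overlaps before contig construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Overlap-layout-consensus assembly equates pairwise read alignments with
genomic overlaps. In repeat-rich genomes that equation is wrong often
enough to matter: reads from different repeat copies align well but
cover disjoint genome intervals, and such repeat-induced false overlaps
either fragment unitigs (every affected read becomes an ambiguous branch)
or misjoin them. This package frames the correction as supervised
classification. Each candidate overlap p_i is summarised by a feature
vector x_i; a classifier C: x -> {true, false} is trained on candidates
whose labels are known from read source coordinates, and applied to a new
read set before the contigger runs.

The package covers the whole loop: simulation of ground-truth data,
candidate detection, feature extraction, training/prediction, filtering,
a minimal unitig contigger, and reference-relative evaluation.

## Candidate detection

`findOverlapCandidates()` seeds pairs by shared canonical 14-mers and
resolves each seed-implied offset with a banded ends-free (dovetail or
containment) alignment, scoring match +1, mismatch -2, gap -3 per base.
The band starts at 12 bp and doubles while the optimum touches its edge,
so the result is effectively unbanded. A candidate is kept when it spans
at least 30 alignment columns with a disagreement rate of at most 6%.
The disagreement rate counts mismatches plus gap *bases* over alignment
columns; whether gap bases or gap events should enter that rate is not
fixed by the hash-overlap convention we emulate, and counting bases is
the stricter and better-defined choice (a sensitivity check simply
re-runs detection with a different `maxError`). Among equal-scoring
alignments the smallest |a_hang|, then the fewer gap events, wins --
determinism over elegance. Containments are reported, not suppressed;
the assembly stage handles them.

The overlapper is checked against an exhaustive independent oracle
(optimal ends-free alignment for every pair and orientation via
`Biostrings::pairwiseAlignment`) on small read sets; at desk scale the
candidate sets are identical.

## Non-comparative features

`buildKmerModel()` counts all canonical k-mers in the read set (k = 16
by default, configurable to 17; k must fit in 31 bp). Normalised
frequency is count / expected coverage. When the coverage is not given
it is estimated as total read bases over a genome-size estimate, which
itself defaults to the number of distinct canonical k-mers -- adequate
for the low error rates simulated here, but an underestimate of coverage
when error k-mers inflate the distinct count; passing the known coverage
is preferred.

Per overlap, the k-mers of *both* reads' overlap substrings are pooled
as a multiset (so the statistics cannot change when the reads of a pair
swap roles), sorted, and summarised by nearest-rank (lower) quartiles --
no interpolation, so the reported values are always observed
frequencies. The overrepresentation threshold (1.5 x mean frequency)
uses the mean over distinct k-mers of the whole model: a per-overlap
mean would make the threshold self-referential in exactly the repeat
regions the feature is meant to flag. Overlaps shorter than k yield
missing statistics rather than zeros. A per-read (rather than pooled)
quartile variant would also be defensible; the pooled reading keeps the
swap invariance exact.

## The comparative score

`comparativeEvidence()` maps both reads of each candidate to every
genome of a related-strain panel (`mapReadToGenome()`: canonical 16-mer
seeds voting for diagonals, then a banded fitting alignment of the full
read; hits need 80% identity and coverage). Because the fitting
alignment always aligns the whole read, hit coverage is 1 by
construction and the identity threshold does the filtering.

All placement combinations (hit of A, hit of B) are enumerated per
genome. A combination is *overlapping* when the strand relationship
matches the candidate's orientation and the implied offset agrees with
the candidate's a_hang within 30 bp -- "same location" needs a number,
and 30 bp (the minimum overlap length) absorbs indel drift without
conflating neighbouring repeat copies. Each combination scores the
summed matching bases of its two hits; maxima are taken across the whole
panel (per-genome-then-global and pooled maxima coincide). The score is

    +log2(max_ovl - max_nonovl + 1)   if the best co-placement wins,
    -log2(max_nonovl - max_ovl + 1)   if it loses,
     0                                 on a tie.

The negative sign on the second branch makes the score antisymmetric;
without it the feature could not separate concordant from discordant
placements at all. When a genome yields only one class of combination
the other maximum is treated as 0 ("no support"). When either read maps
nowhere in the panel the score is *missing*, never 0 -- 0 specifically
means a tie, and classifiers receive the missing value as such.

Panel composition is the caller's responsibility; `estimateIdentity()`
offers a coarse k-mer-based identity estimate for cutoff-style selection
(e.g. excluding strains above 97% or 91% identity).

## Ground truth and classification

`labelOverlaps()` labels a candidate true when some placement pair of
its reads intersects by at least 30 bp (the detectable minimum -- a
shorter genomic intersection cannot support a 30-column alignment) on
the same genome with strands consistent with the candidate's
orientation. Orientation consistency matters: co-located reads on
inconsistent strands (inverted repeats) are not usable assembly
overlaps.

`trainClassifier()` offers four algorithms, all deterministic given a
seed:

* `decision_tree` -- rpart with information-gain splits, minimum leaf 2,
  grown with cp = 0 and pruned at the cross-validation-minimal
  complexity; surrogate splits route rows with missing comparative
  scores.
* `naive_bayes_gaussian` / `naive_bayes_kde` -- a small shared engine
  with per-class Gaussian or kernel-density (normal-reference bandwidth)
  feature densities. A missing feature simply omits that likelihood
  term. Degenerate features (zero variance) fall back to a narrow
  Gaussian.
* `random_forest` -- 100 bagged trees with feature subsampling; since
  the forest cannot accept missing values, training medians are imputed
  and a missingness indicator column is added, which keeps "unmapped"
  distinguishable from any numeric score.

Class imbalance is preserved as observed -- no reweighting or
resampling -- so the classifier optimises the frequencies it will see in
production. Support vector machines are deliberately absent.

The pipeline's default filter is the random forest: on the standard
benchmark it has uniformly lower false-negative and false-positive rates
than the pruned tree (seed 1: FNR 0.0101 vs 0.0118, FPR 0.0378 vs
0.0397), and false negatives are the expensive error here -- each one
removes a true edge exactly where the graph is thinnest, inside repeats.
The decision tree remains the reference algorithm for the cross-genome
transfer check and is a fine choice when an interpretable model is
wanted.

## Assembly and evaluation

`buildOverlapGraph()` removes contained reads, converts dovetails to
directed edges between oriented reads, and removes transitive edges
(implied by two shorter edges within a 10 bp slack -- enough for indel
drift at the simulated rates, configurable). `buildContigs()` chains
reads whose oriented nodes have in- and out-degree at most one; a read
incident to any branch joins no path and is emitted as a singleton --
conservative, unitig-style behaviour that trades contiguity for safety.

Consensus is a per-column majority vote (ties alphabetical), computed
properly: a draft is spliced from the path reads using the exact
alignment extensions, every read is realigned to its draft window with a
banded fitting alignment, and votes (including deletion votes) are
tallied per draft column. Naive position-arithmetic voting loses ~7%
identity at 0.3% read indel rates because per-read coordinate drift
misaligns the columns; the realigned vote restores ~99.8% consensus
identity, with the residual dominated by unrecoverable draft deletions.

`n50()` implements the reference-relative N50: the largest contig length
at which contigs that long or longer sum to half the reference (the
equivalent "first length where the descending cumulative sum reaches
half" form is used internally; a threshold-scanning oracle confirms
equality on fuzzed inputs). `pctGenomeMatched()` cuts contigs into
500 bp windows, maps them to the reference at >= 95% identity and >=
100 bp, and reports the fraction of reference positions covered at least
once; window-based localisation approximates DNADIFF-style local
alignment well at these scales. Misassembly flagging is limited to
contigs whose window placements are non-colinear (strand flips or jumps
beyond 2 kb).

## The simulator and the standard benchmark

`simulateGenome()` draws a uniform-random background -- the planted
repeat families are then the *only* homology, which makes ground truth
unambiguous but omits the low-complexity and skewed-composition sequence
of real genomes. Reads are sampled uniformly with normal lengths,
substitution and length-1 indel errors (no flowgram/homopolymer
structure, no quality values, no paired ends); related strains are
derived by independent per-base substitution plus rare short indels, so
the panel lacks real structural variation. Passing tests on these data
show the machinery is correct and the effect directions are real; they
do not certify performance on any particular real genome.

The standard benchmark (`standardBenchmarkConfig()`, used by
`makeBenchmark()`) is a 200 kb genome with a 1.5 kb x 6-copy family at
1% divergence and a 400 bp x 10-copy exact family, 10x coverage of
400 +/- 40 bp reads at 1% substitution / 0.3% indel error, and a
two-genome panel at 8% and 9% divergence -- repeat-rich enough to induce
thousands of false overlaps, small enough for minutes-scale runs. Train
and test sides are simulated independently (they share no 31-mer). The
problem sizes in the test suite follow this configuration; the unit
tests use smaller genomes (2.5-20 kb) chosen so each property is checked
in seconds.

On this benchmark the qualitative findings are: false overlaps carry
higher normalised k-mer quartiles and lower comparative scores than true
ones; a classifier trained on one genome transfers to the other at
accuracy above 0.98; and filtering raises N50 at essentially unchanged
genome coverage. The comparative arm contributes most of the N50 gain;
the non-comparative arm alone does not reliably beat the uncorrected
control at this scale (its errors concentrate in exactly the repeat
regions that limit contiguity), which mirrors the weak non-comparative
result on the Sanger-read dataset the method was originally evaluated
on.

## Numerical choices and degenerate inputs

* Alignment scoring: +1/-2/-3 linear; bands double on edge contact, so
  banding never changes an optimum, only the time to find it.
* Quartiles: nearest-rank lower; overlap regions shorter than k give NA.
* Comparative score: offset tolerance 30 bp; absent combination class
  counts 0; both-reads-unmapped gives NA (propagated, never imputed).
* Ties in consensus voting are alphabetical; N wins only uncovered
  columns.
* Empty inputs: empty overlap tables, empty feature tables and empty
  prediction sets round-trip and predict to empty outputs; an all-false
  prediction set assembles to singletons with a warning.
* Coordinates are 0-based half-open in every on-disk format; in-memory
  placements and hits are standard 1-based GRanges.

## Known limitations

* The k-mer genome-size estimate (and hence default coverage) is biased
  by sequencing errors; supply the expected coverage when known.
* Exact repeat copies are information-theoretically indistinguishable
  from the overlap alone; candidates wholly inside them are classified
  by prior frequency, and contigs still break there. Only spanning reads
  or longer-range information could resolve them.
* The contigger is deliberately minimal: no scaffolding, no quality
  values, no iterative error correction; it exists to measure the effect
  of overlap filtering, not to compete with production assemblers.
* `KmerFrequencyModel` holds its counts behind an external pointer and
  is not serialisable; rebuild it from the reads (seconds) rather than
  saving it.
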