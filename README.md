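# OverlapCorrect

Machine-learning overlap correction for overlap-layout-consensus (OLC)
genome assembly.

## The problem

OLC assemblers first compute all pairwise alignments between sequencing
reads and treat each alignment as evidence that the two reads overlap on
the genome. That inference fails in repeats: two reads from *different*
copies of a repeat align beautifully but do not overlap, and feeding such
repeat-induced false overlaps to the contigger either fragments the
assembly or misjoins it. `OverlapCorrect` treats the question *given that
an alignment exists, do the reads really overlap?* as a supervised
classification problem.

For a set of read pairs **P** = {p\_1, ..., p\_N}, each pair is described
by a feature vector **x**\_i and a classifier C: **x** → y ∈ {true, false}
is trained on pairs with known labels y\_i (from reads whose source
coordinates on a finished genome are known) and applied to a new read set
before contig construction. Features per candidate overlap:

* **Alignment statistics** — percent mismatch (mismatches / overlap
  columns), percent identity, overlap length, mismatch and gap counts.
* **k-mer frequency statistics** — count all canonical k-mers in the read
  set (k = 16 by default), normalise each count by the expected coverage,
  and report the first/second/third quartile frequency of the k-mers in
  the overlap region, the fraction of overrepresented k-mers (normalised
  frequency > 1.5 × mean) and the number of singleton k-mers. Unique
  sequence has normalised frequency ≈ 1; repeats sit well above it.
* **Comparative-genomics score** — map both reads to a panel of related
  genomes (seed-and-extend, 16-mers, ≥ 80% identity and coverage),
  enumerate all placement combinations per genome, and score each
  combination by its total matching bases. With s\_ovl the best
  co-placement (same locus, offset consistent with the candidate) and
  s\_nonovl the best discordant placement, the score is
  log2(max s\_ovl − max s\_nonovl + 1) if the co-placement wins, the
  negated mirror if it loses, 0 on a tie, and undefined if either read
  does not map.

Candidates predicted false are removed; a minimal unitig-style contigger
(containment removal, transitive reduction, non-branching paths,
majority-vote consensus) assembles the rest, and the result is scored by
reference-relative N50 (the largest contig length at which contigs that
long or longer sum to half the reference) and the percent of the
reference matched by contigs.

Classifiers available: C4.5-style decision tree, Gaussian and
kernel-density naive Bayes, and random forest. A simulator generates
repeat-rich genomes, diverged related strains and error-bearing reads
with known coordinates, so the whole pipeline can be exercised at desk
scale.

## Worked example

Train on one simulated genome, correct and assemble an independently
simulated one (two 200 kb genomes, a 1.5 kb × 6 repeat family at 1%
divergence and a 400 bp × 10 exact family, 10× coverage of 400 ± 40 bp
reads, panel of two related genomes at ~92%/91% identity; a few minutes
on one CPU):

```r
library(OverlapCorrect)
bench <- makeBenchmark(seed = 1)
res <- runPipeline(bench, coverage = 10)
print(res$metrics)
#> Overlap classification metrics
#>   actual true/false: 45947 / 9739
#>   TP 45481  FP 368  TN 9371  FN 466
#>   accuracy: 0.9850
#>   false positive rate: 0.0378
#>   false negative rate: 0.0101
res$uncorrected@n50   # 19049
res$corrected@n50     # 19225
res$corrected@pctMatched  # 99.96
```

(With `algorithm = "decision_tree"` the same benchmark gives accuracy
0.9833 and a false-negative rate of 0.0118.) The corrected assembly has a higher
N50 than the uncorrected control at unchanged genome coverage: removing
repeat-induced overlaps turns ambiguous branch reads back into unique
chains. Individual stages are exposed as `findOverlapCandidates()`,
`buildKmerModel()`/`noncompFeatures()`, `comparativeEvidence()`,
`labelOverlaps()`, `trainClassifier()`/`predictLabels()`,
`filterOverlaps()`, `buildOverlapGraph()`/`buildContigs()` and
`evaluateAssembly()`; a command-line front end lives in
`inst/scripts/overlap-correct.R`.

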