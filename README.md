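# isokit

Alternative-splicing detection and expression utilities for full-length
transcript sets.

Long-read (e.g. PacBio isoform-level) sequencing yields full-length
transcripts without a genome assembly. isokit implements the
computational stages such a project needs as a reusable R package:

- **AS detection from pairwise alignments** (`classify_pair`,
  `detect_events`): two isoforms differing by one internal splicing
  event align as exactly two HSPs — back-to-back on the *continuous*
  isoform, leaving an *AS gap* on the other. Events are called when the
  two HSPs share an orientation, abut or overlap by < 5 bp on the
  continuous side, cover ≥ 95% of it, and leave a gap > 100 bp that is
  ≥ 100 bp from both ends.
- **An internal BLAST-like HSP finder** (`local_align`, `find_hsps`,
  `all_vs_all`): exact affine-gap Smith–Waterman in C++ with
  deterministic tie-breaking, iterative query masking, minus-strand
  search, and BLAST-style splitting at long internal gaps so AS gaps
  are never bridged by one alignment. External BLAST tabular output
  (`read_blast_tabular`) is accepted interchangeably.
- **Greedy redundancy clustering** (`cluster_greedy`): CD-HIT-style
  semantics at `-c 0.95 -G 0 -aL 0.00 -aS 0.99`.
- **Run/assembly QC** (`filter_reads`, `length_stats`, `run_summary`):
  ≥ 50 bp / ≥ 0.75 accuracy filters, N50, truncated mean lengths.
- **Expression utilities** (`fpkm`, `sample_correlation`, `ddct`):
  FPKM with exact reconstruction, replicate Pearson correlation,
  2^−ΔΔCt relative quantification.
- **A seeded isoform simulator** (`make_gene`, `make_isoform_pair`,
  `simulate_isoforms`, `simulate_counts`) whose truth records let the
  whole pipeline be verified end to end, and a CLI (`inst/exec/isokit`)
  exposing every stage.

## Worked example

Simulate two genes with a skipped exon each, then recover the events
from sequence alone:

```r
library(isokit)

sim <- simulate_isoforms(2, "exon_skipping", seed = 42)
sim$truth
#>     isoform_a    isoform_b    event_type gapped_isoform gap_len gap_start gap_end detectable
#> 1 gene42_full gene42_skip2 exon_skipping              a     264       249     512       TRUE
#> 2 gene43_full gene43_skip2 exon_skipping              a     239       244     482       TRUE

ev <- detect_events(all_vs_all(sim$transcripts),
                    transcript_lengths(sim$transcripts))
ev[, c("qid", "sid", "continuous_role", "gap_start", "gap_end", "gap_len")]
#>           qid          sid continuous_role gap_start gap_end gap_len
#> 1 gene42_full gene42_skip2         subject       249     512     264
#> 2 gene43_full gene43_skip2         subject       244     482     239
```

The detected gap intervals equal the truth intervals exactly; the
simulator certifies (by a junction score-walk check) that no alignment
can extend an HSP across a true block boundary, so recovery is
deterministic. Clustering and QC work on the same objects:

```r
cl <- cluster_greedy(c(a = sim$transcripts[[1]], b = sim$transcripts[[1]],
                       c = sim$transcripts[[3]]))
cl$members
#>   cluster_id representative member identity coverage_shorter
#> 1          1              c      c        1                1
#> 2          2              a      a        1                1
#> 3          2              a      b        1                1

length_stats(c(4000, 3000, 3000, 2000, 1000))[c("n50", "mean_len")]
#> $n50
#> [1] 3000
#> $mean_len
#> [1] 2600
```

The same operations are available from the command line:

```sh
inst/exec/isokit simulate --genes 2 --seed 42 --out-fasta sim.fa --out-truth truth.tsv
inst/exec/isokit detect-as --fasta sim.fa --out events.tsv
inst/exec/isokit cluster --fasta sim.fa --out clusters.tsv --reps reps.fa
```

## Testing and reproducing results

The test suite (testthat, edition 3) contains per-module unit tests,
property-based tests against independent oracles — a literal
brute-force re-check of the AS criteria and Biostrings'
`pairwiseAlignment` as an alignment-score oracle — and an acceptance
suite (`tests/testthat/test-acceptance.R`) with one block per headline
claim:

```r
testthat::test_dir("tests/testthat", package = "isokit",
                   load_package = "installed")
```

A standalone acceptance report against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

writes the main computed quantities as JSON: the bundled run-statistics
arithmetic (per-library truncated mean subread lengths 1676/2927/3378,
totals 3,847,562 subreads and 450,876 polymerase reads),
detector-vs-brute-force agreement over 10,000 seeded HSP
configurations (1.0), exact recovery on 50 detectable and 50
non-detectable simulated gene models (50/50 exact, 0 spurious),
the gap/flank/overlap decision boundaries, clustering behavior and
threshold monotonicity, and the expression identities (FPKM
reconstruction error ~1e-14, calibrator relative expression exactly 1,
duplicate-sample correlation 1).

See `vignettes/isokit-methods.Rmd` for the methods behind each stage,
including the rationale for BLAST-style HSP splitting and the
simulator's boundary-determinism guarantee.
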