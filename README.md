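# bacplex

Post-processing, scaffolding and evaluation of multiplexed BAC shotgun
assemblies.

## The problem

Hierarchical (clone-by-clone) sequencing of large, repeat-rich plant genomes
multiplexes hundreds of individually barcoded BAC clones in a single
short-read lane. Turning the deconvoluted reads into clean per-clone
assemblies requires a chain of steps that no single assembler provides:

* **Read QC** — quality trimming of each mate, removal of *E. coli* host
  reads, and removal of vector-backbone reads *except* those originating
  within 2 kb of the cloning site (these carry the insert/vector junction
  and let the insert boundaries be flagged later);
* **Contig post-processing** — clipping residual vector off contig ends
  ("BAC end" flagging), discarding contigs under 500 bp, read-back coverage
  estimation, and a trimmed-mean coverage filter: after setting aside the
  10% lowest-coverage contigs, contigs below half the mean coverage of the
  rest are removed as cross-well contamination; a final screen clips or
  removes contigs matching known contaminants (identity ≥ 90%, ≥ 100 bp);
* **Mate-pair preprocessing and deconvolution** — duplicate-pair removal,
  Nextera junction-adapter clipping (keep the bases 5′ of the adapter; drop
  mates ≤ 15 bp and their partners), and assignment of unbarcoded mate
  pairs to clones by unique mapping against the concatenated draft
  assemblies (library σ is fixed at 50% of the estimated insert mean);
* **Iterative scaffolding** — an SSPACE-style greedy link graph per clone:
  links supported by fewer than *k* pairs are dropped (*k* = 10 for the
  MiSeq library, 20 for HiSeq), competing links within a 0.7 support ratio
  mark an end ambiguous, joins insert `max(round(gap), 1)` Ns with
  `gap = insert_mean − d_A − d_B`; libraries are applied sequentially with
  re-deconvolution between rounds;
* **Evaluation** — Plantagora-style misassembly calls on reference
  alignments (flanks on different strands, or > 1 kb apart, or overlapping
  by > 1 kb ⇒ global; same strand within 1 kb ⇒ local), genome fraction as
  the covered share of the insert, 21-mer abundance masking of repeats, and
  identity-stratified overlap of masked repeats with WGS alignments.

A deterministic simulator generates complete synthetic experiments —
genome with planted repeat families, vector, host, clone inserts, paired-end
and mate-pair reads with errors, duplicates, adapter read-through and
cross-well contamination, plus fragmented draft contigs with planted
misassemblies — with per-read and per-contig ground truth, so every stage
is testable end to end without downloads.

## Worked example

```r
library(bacplex)
res <- runBacPipeline(simulationConfig(seed = 1))
res$summary
```

```
   bac nContigs contigL50 nScaffolds scaffoldL50 genomeFraction nGlobal nLocal
1 bac1        5     27122          1      139146       96.25634       2      0
2 bac2        5     27753          1      141491       96.15030       0      1
3 bac3        5     20469          1      106219       69.47017       1      0
4 bac4        5     27950          1      144336       96.76020       1      1
...
```

Each of the eight simulated clones starts from five draft contigs
(contig L50 ≈ 27 kb) and ends as a single scaffold (L50 ≈ 140 kb) after the
two mate-pair rounds. The planted events are recovered by the evaluator:
the inversion in `bac1` yields two global (strand) breakpoints, the 500 bp
relocation in `bac2` a single local call, and the 40 kb relocation in
`bac3` a global (distance) call — the latter also depresses that clone's
genome fraction to ~70% because 40 kb of its insert is genuinely absent
from the contigs. Per-contig decisions are in
`res$perBac$bac1$post$report`, scaffold layouts in `res$scaffold$layouts`.

A thin shell front end (`inst/scripts/bacplex`) exposes the same functions
as `simulate`, `read-qc`, `mp-prep`, `stats` and `evaluate` subcommands.

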