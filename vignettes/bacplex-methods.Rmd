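---
title: "Methods: multiplexed BAC assembly post-processing and scaffolding"
author: "bacplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed BAC assembly post-processing and scaffolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`bacplex` implements the computational half of a multiplexed BAC
(bacterial artificial chromosome) sequencing workflow: hundreds of
individually barcoded clones, each carrying a ~100–150 kb genomic insert in
a vector backbone propagated in *E. coli*, are pooled on one short-read
lane; reads are deconvoluted per clone, assembled per clone with an
external assembler, and then cleaned, scaffolded with pooled long-insert
mate-pair libraries, and evaluated against reference inserts. The external
assembler itself is out of scope — the package consumes its contigs (and
the simulator fabricates them with known truth).

A single coordinate convention is used everywhere: intervals are 0-based
half-open, on the query's forward strand and on the target; strand `-`
means the query aligns reverse-complemented. All alignments travel through
one `data.frame` layout (`alignmentTable()`), so externally produced SAM or
PAF can replace the internal mapper at every consuming step.

# The internal mapper

All screening, coverage and deconvolution steps need a read mapper, but
none of the modelled rules depends on a specific aligner beyond
presence/absence of a confident hit. The internal mapper is a deliberately
small seed-and-extend design: exact 21-mer seeds from three anchor
positions per query (both strands) located with Aho–Corasick matching
(`Biostrings::matchPDict`), every implied placement scored by ungapped
comparison in a small compiled kernel, hits below 90% identity suppressed,
and `score = matches`. Extension is ungapped because the simulator (and
every rule downstream) is substitution-only; indel-containing real data
would be served by supplying external SAM/PAF. Mapping quality is a pure
uniqueness flag: 60 for a unique best placement, 0 when the best score is
tied — mirroring the common "mapq 0 = multi-mapped" convention that the
downstream `mapq >= 1` (uniqueness) and `mapq >= 40` (insert estimation)
filters consume. Intermediate values are not modelled. With a per-base
error rate *e*, a read is findable unless all three 21-mer anchors carry an
error (probability about `(1-(1-e)^21)^3`, roughly 1 in 10^3 at
*e* = 0.005), which sets the small irreducible loss seen in the recovery
tests. E-value-based screens in the original protocols are replaced by the
database-size-independent pair (identity ≥ 0.9, aligned length ≥ 50 bp)
for read screens.

Long references (vector, contaminants) are located on contigs by tiling
them into overlapping windows (`tileMap()`, 500/250 bp for the vector,
100/50 bp would suit shorter contaminants; merged per contig). The merged
boundary can miss the true junction by up to one window step; terminal
windows that hang off a contig end are clipped and score on the overlap
only, so clip boundaries land within ~250 bp of truth. The evaluation
helpers account for this by translating truth alignments through the
recorded per-side clip amounts.

# Read QC

Quality trimming is modified-Mott: with error limit `L = 0.05`, each base
contributes `L - 10^(-Q/10)` and the kept read is the contiguous window
maximizing the running sum (ties: smallest start, then largest end; empty
if no window is positive). The external trimmer used in the original
protocol is proprietary and its algorithm unspecified; modified-Mott is the
standard, oracle-checkable equivalent and the 0.05 limit is the common
default. Host hits drop a read; vector hits drop it unless the hit
interval intersects ±2 kb around the cloning-site coordinate (the simplest
testable reading of "originating up to 2 kb up or downstream of the
cloning site"); reads hitting both host and vector are dropped as host
(conservative). Only pairs with both mates surviving and non-empty
continue.

# Contig post-processing

The cascade order is fixed: vector clip → length filter (≥ 500 bp) →
read-back coverage → coverage filter → contaminant screen → final length
filter. Vector hits intersecting a terminal 1 kb zone are clipped together
with everything between hit and contig end and the corresponding BAC-end
flag is set; the 1 kb end-zone quantifies "almost exclusively at the ends"
and is configurable. Coverage is summed full read length of reads
best-hitting the contig divided by contig length. The coverage filter sets
aside the `floor(0.10 n)` lowest-coverage contigs (ties broken by id),
takes the arithmetic mean *m* of the rest, and removes every contig
(including the set-aside ones) strictly below `safety × 0.5 × m`. The
source protocol states this threshold in two slightly different forms
(half the trimmed mean; 90% of half the average); the default
`safety = 1.0` matches the worked example (threshold 153 at trimmed-mean
coverage 306), and `safety = 0.9` selects the other variant. The screen for
known contaminants clips qualifying terminal hits (identity ≥ 90%,
≥ 100 bp), removes contigs with internal hits, and removes anything under
500 bp after clipping.

# Mate pairs, deconvolution, scaffolding

Duplicates are exact-sequence pairs (both mates byte-identical); the first
occurrence is kept and duplicate removal runs before adapter clipping.
Junction-adapter clipping finds the leftmost occurrence of the adapter or
its reverse complement with ≤ 2 mismatches and keeps the bases 5′ of it —
the junction marks the circularization point, so bases beyond it belong to
the distal fragment end. Mates shorter than 16 bp afterwards ("> 15 bp
kept") drop their whole pair. The survivor-length rule is applied after
every truncation, including quality trimming.

Deconvolution assigns a pair to a clone only when every best-scoring
alignment of each mate lies on that clone's contigs and neither mate is
tied; otherwise the pair is `unmapped`, `ambiguous` (any tie) or
`cross_bac` (untied mates on different clones) — every input pair receives
exactly one verdict. Insert size is estimated from pairs mapping to the
same contig with mapq ≥ 40 on both mates, as the mean outer span, and the
library σ is then *defined* as half the mean rather than measured.

Scaffolding builds one link per informative pair between the contig ends
the mates point toward (forward mate → tail, reverse mate → head), with
per-pair gap `insert_mean − d_A − d_B` where `d` is the distance from the
mate's outermost aligned base to the linked end. Greedy joining takes
links in decreasing support (lexicographic tie-break), discards support
below `k` (10 for the MiSeq-like library, 20 for HiSeq-like), skips a link
whose ends have a competitor above the 0.7 support ratio (the ratio is not
stated in the source protocol; SSPACE's own default fills the gap),
refuses cycles and reused ends, and renders gaps as
`max(round(gap_mean), 1)` Ns — negative estimates become a single N and
the raw estimate is kept in the layout; overlap merging is deliberately
not attempted, since the modelled workflow introduces gaps only as N
runs. Libraries are applied strictly sequentially with re-deconvolution
against the current assemblies between rounds, each clone scaffolded
independently; bit-for-bit agreement with SSPACE is not claimed —
correctness is judged against fixture truth.

# Evaluation

Misassembly calls follow the Plantagora classes on length-filtered
(≥ 100 bp) reference alignments sorted by query start: different flank
strands → global (strand); signed inner-boundary separation (> 0 gap,
< 0 overlap) beyond 1 kb → global (distance/overlap); otherwise local.
"Over 1 kb" is read strictly, so a separation of exactly 1000 bp is
local. The "two or more distinct alignments cover the position"
precondition is interpreted as "the position is a boundary between
consecutive alignments of the query". Per-base indel counts are out of
scope — the coordinate model does not carry base-level alignment columns.
Genome fraction is the covered share of the reference insert (interval
union). Repeat masking marks every base under at least one 21-mer whose
canonical form (lexicographic min of k-mer and reverse complement) reaches
the abundance threshold in a reference index; identity-stratified overlap
reports, per threshold from 80 to 99%, the masked bases covered by at
least one alignment at or above it, which is non-increasing by
construction.

# The simulator and what it does (not) show

The generator is fully deterministic under its seed and records ground
truth for every read, pair and contig. Defaults model the study
conditions: a 2 Mb genome carrying three repeat families (8 copies of 3 kb
at 85/92/98% copy identity), 8 clones with 145 ± 5 kb inserts, a 7.5 kb
vector with a recorded cloning site, a 50 kb host decoy, paired-end
fragments of 500 ± 50 bp at 2 × 100 bp, mate-pair libraries at
5.5 kb/2 × 250 (MiSeq-like) and 6 kb/2 × 100 (HiSeq-like) with the 38 bp
Nextera junction adapter, substitution errors at 0.5%, 5% duplicate pairs,
5% cross-well contamination, 8% vector and 8% host reads and 3%
uniformly low-quality pairs — values taken from the modelled experiment
where stated and otherwise set once to common Illumina magnitudes. Inserts
are placed in jittered non-overlapping slots, like clones spaced along a
minimum tiling path: heavy insert overlap would make mate pairs
legitimately unassignable, which is exactly the behaviour the ambiguity
tests pin down on purpose-built shared-sequence fixtures instead. Draft
contigs are insert substrings separated by ~800 bp unassembled gaps;
cross-contamination contigs are windows of a neighbouring clone sized so
their read-back coverage sits near 10% of native depth; planted events
(a 2 kb inversion, 500 bp and 40 kb relocations, a 1.5 kb duplication)
exercise each misassembly class, and are kept away from contig ends so
clip-adjusted truth stays exact.

Simulations are substitution-only, with flat quality profiles, no indels,
no PCR bias, no optical-duplicate geometry and no chimeric reads. Passing
tests therefore demonstrate the correctness of the implemented rules and
their interaction, not robustness to artefacts the generator does not
emulate; real libraries would additionally stress the ungapped extension
assumption of the internal mapper.

# Problem sizes and numerical choices

The end-to-end suite runs 8 clones at 25× paired-end depth (~18 000 pairs
per clone), 900 MiSeq-like and 1500 HiSeq-like mate pairs per clone —
sizes chosen so every true adjacency expects ≈ 27 (MiSeq) and ≈ 54
(HiSeq) truth-spanning pairs, comfortably above k while keeping the whole
run around a minute. Property suites use 1000 random length multisets
(L50), 10 000 random quality strings (trimming) and 1000 random alignment
configurations (misassembly classes) against exhaustive oracles. Exact
floating-point ties in the trimming objective are possible with repeated
quality values; the tie-break (smallest start, then largest end) is part
of the contract, and the oracle comparison falls back to
objective-equality when the optimum is degenerate within 10⁻⁸.

# Known limitations

No gap filling, contig extension or overlap-merging of contigs; no
probabilistic rescue of ambiguous pairs; BAM is accepted only via SAM
text; mapq is binary by design; repeat masking requires the k-mer index to
fit in memory as a table; and the misassembly evaluator assumes collinear
segment alignments of each query (as produced by standard whole-contig
aligners), not arbitrary split mappings.
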