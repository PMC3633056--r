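---
title: "Merging draft assemblies from read alignments: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging draft assemblies from read alignments: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`asmmerge` merges a trusted *master* assembly `M` with a secondary *slave*
assembly `S` of the same genome, using only the alignments of a shared
read set against each assembly. This vignette explains the model, the
parameters that matter, the synthetic data the tests rest on, and the
design decisions taken where the procedure was genuinely open.

## The evidence model

The central assumption is that **regions assembled from the same reads
represent the same genomic locus**. Since most short-read assemblers do
not expose their read layout, the layout is approximated by aligning the
reads back to each assembly — an analysis step most projects perform
anyway. Repeats corrupt this approximation (a read from either copy of a
near-perfect repeat is placed arbitrarily), so only *uniquely aligned*
reads enter the analysis: the primary record of a mapped read that is not
flagged secondary or supplementary, has mapping quality above zero, and
carries no alternative-hit (`XA`) tag. Reads inside perfect repeats are
ambiguous and drop out by construction, which is the main reason perfect
repeats generate no spurious merges.

Two reads on one contig are *adjacent* when their intervals overlap or
abut (`begin(r2) <= end(r1) + 1` and symmetrically). A *frame* is a
maximal chain of pairwise-adjacent reads, identified by its interval; a
*block* is a pair of frames, one per assembly, carrying the same read
sequence. Blocks are built in one streaming pass over the position-sorted
slave alignments against a hash of the master's unique reads, so memory
scales with the set of currently open blocks, not the genome. A block is
*discordant* when a strict majority of its reads map with opposite
orientations on the two frames; an exact tie counts as concordant, so an
orientation flip is never triggered without majority evidence.

### Block filtering

Similar-but-distinct regions (diverged repeat copies, paralogs) still
attract some shared reads and would create false links. Two filters
remove them:

* **Coverage ratio.** For each frame, `BC` sums the aligned bases of the
  block's own reads inside the frame and `GC` the aligned bases of *all*
  unique reads there. A block is kept iff
  `max(BC_M/GC_M, BC_S/GC_S) >= T_c`. The *maximum* is deliberate: at a
  heterozygous locus one assembler may report both alleles (ratio near
  0.5) while the other collapses them (ratio near 1); the max keeps such
  blocks while a repeat-induced block scores low on both sides.
* **Frame length.** A block passes if one frame reaches
  `min(0.3 * contig_length, T_l)`. A failing block survives if a sibling
  block between the same contig pair passes, or if it is the only block
  between the two contigs — small blocks can still witness an insertion
  or deletion by one assembly.

## The two graphs

The **contigs graph** is bipartite: one vertex per contig carrying
blocks, one edge per contig pair sharing them, weighted
`w_e = max(r+, r-)/(r+ + r-)` where `r+`/`r-` count reads in concordant
and discordant blocks (hence `w_e` is always in `[0.5, 1]`; values near 1
mean a clear orientation relation). A vertex weight is the mean of its
incident edge weights, each weighted by the read count of the blocks the
edge represents. Orientation propagates greedily: the heaviest vertex of
each component seeds its native block order; repeatedly the heaviest
processed vertex orients its unvisited neighbors (a discordant-majority
edge flips the neighbor, a tie does not), its edges are removed and the
remaining weights recomputed. Ties between vertices are broken toward the
master side, then the lowest contig index, which makes the procedure
deterministic and idempotent. This is a heuristic: it optimizes locally
and can, in principle, leave avoidable order contradictions in adversarial
topologies.

The **assemblies graph** has one node per retained block and a directed
edge when one block immediately precedes another on some contig under the
assigned order, labeled with that assembly. With two assemblies each node
has at most two in- and two out-neighbors. Two parallel edges between the
same pair (one per assembly) are the fully concordant case; degree counts
therefore use distinct neighbors.

### Problematic structures

* **2-node cycles** signal a putative inversion: the two blocks lie on
  one master and one slave contig in opposite orders. If at least
  `min_inversion_evidence` read pairs are mapped with invalid relative
  orientation across the interval on exactly one assembly, that assembly
  carries the inversion and the other's sequence is kept; otherwise the
  master is kept. The resolved cycle's nodes then drop *all* their edges
  of the losing assembly. Keeping only the opposing cycle edge would
  leave residual forks at the cycle's neighbors; dropping the losing
  side's edges linearizes the region along the winning assembly's order,
  which is exactly the sequence the decision selected.
* **Bifurcations** (a node with two distinct successors, one reached via
  a master contig and one via a slave contig) are arbitrated with
  spanning pairs. For the junction on each branch, `n` counts candidate
  reads in the upstream frame whose mate is correctly placed across the
  junction, and `u` those whose expected mate is unmapped, elsewhere or
  misplaced. With `rho = n/(n + u)`, `rho_M >= T_U` and `rho_S <= T_L`
  spots a mis-assembly in the slave (the master path is trusted), the
  mirrored condition spots one in the master, and anything else — a
  repeat, or too little evidence — falls back to the master contigs
  verbatim. The ratio is normalized to `[0, 1]` so it shares the
  thresholds' domain and is defined when `u = 0`; `n + u = 0` fails both
  conditions. A trusted decision also marks the distrusted contig as
  *broken* at that junction, so its tail is not re-emitted into a second
  output contig. Convergent nodes are handled symmetrically on reversed
  edges.
* **Candidate definition.** A candidate read points toward the junction
  and its whole insert window `[m - 3sd, m + 3sd]` must fit inside the
  contig (short contigs contribute no candidates) and lie at or after the
  downstream frame's start. The window is evaluated on the *insert span*
  — leftmost base of the read to the far end of its mate — not on the
  mate's leftmost coordinate, which sits one read length short of the
  insert; for a 180 bp insert library with 101 bp reads a
  leftmost-coordinate window would reject every well-placed pair. This
  also keeps the window consistent with the CE statistic below.
* **Bubbles and larger tangles** (diverge-then-reconverge paths, SCCs of
  three or more nodes, nested cases) are detected but not arbitrated:
  their master contigs are withheld and emitted verbatim. This is the
  conservative stance taken throughout — when in doubt, output the
  master.

## Merging

After pruning, the graph is a disjoint union of simple paths, walked left
to right in per-contig *view* coordinates (native coordinates, mirrored
where the orientation pass flipped a contig):

* Inter-block regions come from the connecting contig, master first when
  both assemblies connect the blocks.
* A master gap bridged by a slave contig is closed only when banded
  semi-global alignments at *both* flanks reach `min_identity`; a failed
  junction splits the output and both sides fall back to master sequence.
  A flank of length zero (the block reaches the contig end) passes
  vacuously — the block itself is the evidence there.
* Within a block, the frame with the better CE statistic is emitted
  verbatim; no base-level consensus is computed, since a consensus of two
  assemblies has no guarantee of being better than either. The CE
  statistic over an interval is `z = (mean_obs - m)/(sd/sqrt(k))` over
  the `k` pairs whose leftmost mate begins in the interval, with the
  observed insert the outer distance; strongly negative `z` means
  compression (e.g. a deletion), positive expansion. "Better" is the
  smaller worst-case `|z|` across libraries — the comparison itself is a
  design choice, as is using the block frame as the evaluation window.
  Ties, including the no-evidence case `k = 0` (sentinel `z = 0`), go to
  the master.
* A contig end is extended with slave sequence only when the slave is
  longer there and the overlapping flank aligns at `min_identity`.
* Master contigs without blocks, and withheld ones, pass through
  verbatim. Output contigs are unscaffolded sequences (no N-gaps), named
  `pctg0001...`; provenance rows tile every output base back to a source
  interval.

### The banded aligner

Junction validation uses an ends-free (semi-global) dynamic program with
linear gap scores (match +1, mismatch −1, gap −1), restricted to a
diagonal band of half-width `|len(a) - len(b)| + band_pad`. Identity is
matches over aligned columns, *including* internal gap columns but
excluding the free end gaps — counting gap columns makes indel-rich
flanks fail the gate, which is the conservative direction. With the band
anchored at the length difference an end-to-end path always exists; if a
degenerate case still fails, the band is widened once and then the
junction is treated as identity 0 (not merged). Traceback preferences
(diagonal, then vertical, then horizontal; endpoint scan order fixed)
make the reported identity deterministic. A separately coded full-matrix
version exists purely as a test reference; the tests require exact score
and identity agreement whenever the band covers the optimum, and anchor
the reference itself against an external overlap aligner.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `B_min` | 10 (profile `large`: 50) | reads | minimum block size at construction |
| `T_c` | 0.75 | fraction | coverage-ratio filter threshold |
| `T_l` | 200 (profile `large`: 500) | bp | frame-length filter threshold |
| `T_U`, `T_L` | 0.9, 0.1 | fraction | bifurcation trust/distrust thresholds on `rho` |
| `min_identity` | 0.95 | fraction | junction identity gate |
| `band_pad` | 64 | bp | extra alignment band half-width |
| `min_inversion_evidence` | 5 | pairs | wrongly-oriented pairs needed to call an inversion |
| `flank_len` | 1000 | bp | maximum flank evaluated at a junction |

`B_min`, `T_c` and `T_l` trade sensitivity against graph complexity: low
`B_min` admits alignment-noise blocks, high `T_l` discards real
indel-witnessing blocks. The bacteria-scale defaults and the `large`
profile are the two shipped presets. `min_inversion_evidence = 5` and
`flank_len = 1000` are this package's own calibrations of quantities the
procedure leaves open ("a minimum number of reads"; an unspecified flank);
both are exposed knobs.

## The synthetic-data generator

The fixture module emulates the tool's inputs exactly: a uniform random
genome with optional planted repeat families; a master/slave pair derived
by cutting the genome at chosen positions and applying engineered events
(inversion, relocation mis-join, deletion, extra split, heterozygous
substitution cluster); paired reads with normal insert sizes (truncated
below at the read length), uniform starts and FR/RF orientation; and
*idealized alignments* produced by inverting the assembly's coordinate
map rather than running an aligner. Reads wholly inside a perfect repeat
copy are emitted with mapping quality 0 (the multi-mapping marker); reads
straddling an event breakpoint or contig end on an assembly are emitted
unmapped there — the simplest consistent rule for what a real aligner
would clip or reject. Optional mask intervals emit selected reads as
unmapped, emulating locally unalignable regions (this is how the tests
create the coverage gaps that separate blocks inside an inverted span and
how they ablate mate evidence).

What the generator does *not* emulate: sequencing errors and quality
profiles, GC-biased coverage, chimeric read pairs, and alignment noise
(soft-clipping heuristics, mapping-quality gradations). Passing tests
therefore demonstrate the algorithmic contracts — block equivalence,
graph invariants, decision logic, identity gates, determinism — on exact
alignments; they do not measure robustness to aligner artifacts on real
data, where parameters like `B_min` and `T_c` carry that burden.

Test problem sizes were chosen to exercise each property at the smallest
scale where it is non-trivial: oracle-equivalence fixtures use 2–3.5 kbp
genomes with at most 500 reads (the brute-force oracle is quadratic);
event-recovery fixtures use 40 kbp genomes at 30x so that mate-pair
evidence counts are comfortably above threshold; the end-to-end scenario
is a 100 kbp genome, master in 8 contigs and slave in 7 with interleaved
gap positions, 30x coverage of 100 bp pairs with 400 +/- 40 bp inserts.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based inclusive `[begin, end]` everywhere;
  conversion happens only at the SAM/FASTA boundary.
* Read identifiers are the read names themselves (with the mate suffix),
  and a duplicate name among unique alignments is fatal; pairs are
  matched by name with `/1`,`/2` suffix stripping and the SAM mate flags.
* A read adjacent to several open blocks joins the earliest-opened one;
  blocks never merge after creation. This makes streaming deterministic;
  it can differ from the connected-components ideal only when a read
  bridges two blocks that interleave on one assembly but not the other —
  a repeat-like situation that the filters target anyway.
* All tie-breaks (vertex selection, edge orientation, CE frame choice,
  concordance) resolve toward "no change" or "master", so reruns are
  byte-identical and the null fixture (identical assemblies, no events)
  reproduces the master sequences exactly.
* `sd = 0` libraries use a tiny floor in the CE denominator so `z` stays
  finite; `k = 0` yields the sentinel `z = 0`, which the master-tie rule
  then absorbs.
* Empty frames, zero-length flanks, contigs without blocks, and an empty
  block set all degrade to the conservative path (master passthrough).

## Known limitations

Only pairwise merges are performed; merging more than two assemblies
means iterating externally with the previous output as the new master.
SCCs larger than two nodes, nested bubbles and bifurcations touching
bubbles are never resolved, only quarantined. The orientation pass is a
greedy heuristic without optimality guarantees. Junction validation sees
at most `flank_len` bases, so a divergence entirely outside that window
cannot block a gap closure. The merged output inherits whichever errors
the chosen frames carry — the method selects between assemblies, it does
not polish them.
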