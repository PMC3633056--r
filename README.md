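# asmmerge

Reference-free merging of two draft genome assemblies using read
alignments.

## The problem

Different short-read assemblers make different mistakes: one produces the
more contiguous assembly, another the more correct one, and neither
dominates across a genome. Assembly reconciliation takes two draft
assemblies of the same genome — a trusted **master** `M` and a secondary
**slave** `S` — and merges them, closing the master's gaps with slave
sequence and correcting putative mis-assemblies, while falling back to the
master wherever the evidence is ambiguous. `asmmerge` is written for
genome-assembly practitioners who already have the (practically mandatory)
BAM/SAM files of their reads aligned back to each assembly.

Unlike reconciliation tools built on whole-assembly alignment, `asmmerge`
never aligns the two assemblies globally. Regions that represent the same
genomic locus are found through the reads: a **block** is a pair of frames
(one interval per assembly) carrying the same ordered run of uniquely
aligned reads — direct evidence that both assemblers reconstructed that
locus from the same data.

## Method sketch

1. **Alignment loading.** Only uniquely aligned reads are kept (primary,
   not secondary/supplementary, mapping quality > 0, no alternative-hit
   tag); multi-mapped reads inside repeats are discarded by construction.
2. **Blocks.** A streaming pass over the position-sorted slave alignments
   chains reads that are adjacent (overlapping or abutting) on *both*
   assemblies into blocks; blocks with fewer than `B_min` reads are
   dropped. Two filters remove spurious blocks: a coverage filter keeps a
   block iff `max(BC_M/GC_M, BC_S/GC_S) >= T_c` (block vs. global coverage
   per frame; the max protects heterozygous loci) and a length filter
   requires a frame of at least `min(0.3 * contig_length, T_l)` bp, with
   exceptions for solitary blocks and blocks next to a passing sibling.
3. **Contigs graph.** Contigs sharing blocks are linked by edges weighted
   `w_e = max(r+, r-) / (r+ + r-)`, where `r+`/`r-` count reads in
   concordant/discordant blocks; a greedy highest-weight-first traversal
   assigns every contig a consistent block order and orientation.
4. **Assemblies graph.** Blocks become nodes; a directed edge records that
   one block immediately precedes another on some contig. Non-linear
   structure flags disagreement: 2-node strongly connected components
   (putative inversions) are arbitrated by wrongly-oriented pair counts;
   bifurcations by the normalized spanning-pair ratio `rho = n/(n+u)`
   against thresholds `T_U`/`T_L`; everything more complex conservatively
   withholds the master contigs verbatim.
5. **Merging.** Maximal disjoint paths of the simplified graph are walked
   left to right. A master gap bridged by a slave contig is closed only if
   banded semi-global alignments at both junction flanks reach 95%
   identity; within a block the frame with the better (smaller absolute)
   CE insert-size statistic `z = (mean_insert_observed - m)/(sd/sqrt(k))`
   is emitted verbatim — no consensus is computed. Master contigs not
   involved in any merge pass through unchanged.

A full synthetic-fixture generator (random genome, split/evented assembly
pair, simulated read pairs, exact coordinate-projected alignments) makes
the entire pipeline testable without external data.

## Worked example

```r
library(asmmerge)

# simulate the complementary-gap scenario: 100 kbp genome, master in 8
# contigs, slave in 7 with interleaved gaps, 30x 100 bp pairs (400 +/- 40)
fx  <- cmd_simulate("fixture", seed = 1)
man <- run_manifest(fx$master, fx$slave, fx$master_alignments,
                    fx$slave_alignments, fx$libraries, recon_config(),
                    out_dir = "fixture/out")
res <- reconcile_assemblies(man, genome_size = 1e5)
res$blocks_built          # 14
res$master_stats$count    # 8    master contigs
res$merged_stats$count    # 1    merged contigs
res$master_stats$ng50     # 12500
res$merged_stats$ng50     # 100000
```

Every master gap is spanned by a slave contig, each junction passes the
identity gate, and the 8 master contigs merge into a single paired contig
identical to the simulated genome. `res$provenance` records, base by base,
which assembly and contig every output interval came from and why
(`master_only`, `slave_fill`, `ce_master`, `ce_slave`, `extension`), and
`res$resolutions` logs every inversion/bifurcation decision with its
evidence counts.

The same pipeline is exposed as a shell tool (`exec/asmmerge`) with
`simulate`, `blocks`, `merge` and `stats` subcommands, mirroring the
two-phase blocks-then-merge workflow; `--profile bacteria` (`B_min` 10,
`T_c` 0.75, `T_l` 200) and `--profile large` (`B_min` 50, `T_l` 500) set
the two shipped parameter presets.

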