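# longbloom

Reference-free transcriptome assembly of long, noisy RNA-seq reads
(Oxford Nanopore cDNA or direct RNA), implemented as an R package with a
C++ core. Long-read transcriptome assembly has to contend with 3–10%
per-base error, heavily 3'-biased read-length truncation, unknown strand
in cDNA libraries, chimeric (fused) reads, and expression spanning several
orders of magnitude. `longbloom` addresses these with a six-stage
workflow:

1. **Alignment-free error correction.** All read *k*-mers (default
   *k* = 25) and their approximate multiplicities are held in a
   Bloom-filter de Bruijn graph. Each read is split into 500 nt tiles; a
   tile-local dynamic threshold separates *weak* (likely erroneous) from
   *solid* k-mers, and anchored runs of weak k-mers are replaced by an
   alternative solid path from the graph when that path aligns to the
   original span at ≥ 70% identity. Passes repeat with half-shifted tiles
   until the read is a fixed point. Short reads can optionally be ingested
   into the same graph to aid correction (hybrid mode).
2. **Digital normalization.** Read depth is approximated by order-3
   randstrobe multiplicities tracked in a counting Bloom filter. Scanning
   reads longest-first, a read whose span (up to 50 nt at each extremity)
   is already covered by strobemers at the target depth (default 3) is
   dropped; otherwise it joins the *minimal longest-reads set* and its
   sub-target strobemer counts are incremented.
3. **Trimming and chimera splitting.** All-vs-all overlaps give each read
   a per-base depth profile (self-inclusive); regions must overlap at
   least two other reads (depth ≥ 3). Undersupported heads/tails are
   trimmed and internal valleys — the signature of chimeric junctions —
   split the read. Contained reads are removed.
4. **Unitig assembly.** Trimmed segments form a string graph of dovetail
   overlaps (both orientations in cDNA mode). Poly(A)-tail / poly(T)-head
   signals prune edges that would extend past a tail or join antisense
   overlapping genes; Myers-style transitive reduction simplifies the
   graph; unambiguous paths are spliced into unitigs.
5. **Polishing.** Error-corrected reads are aligned back to the unitigs
   (affine-gap DP); alignments with > 50 nt indels or < 70% identity are
   discarded — so reads of a different isoform cannot vote a skipped exon
   away — and the survivors drive a per-column pileup consensus.
6. **Transcript extraction.** An overlap graph of polished unitigs is
   annotated with length-normalized read counts (aligned bases / unitig
   length) and the number of reads spanning each overlap. Edges failing a
   one-sided binomial test *P(X ≤ s | n = round(min(c_u, c_v)), p = 0.5) <
   0.05* are removed, unitigs are reoriented by their poly(A) read
   alignments, and transcripts are extracted by count-ordered
   bidirectional greedy extension with path-minimum count decrements.

The package also ships a synthetic transcriptome/read simulator with
ground truth (multi-isoform genes with shared exons, log-uniform
expression, configurable substitution/indel rates, 3'-anchored
truncation, poly(A) tails, random strand, chimera fraction) and a
transcript-level evaluation module reporting, per truth transcript,
complete (≥ 95% of length) / partial / missing reconstruction, and
overall

    recall = 100 · TP / (TP + FN)          TP = complete + partial
    FD     = FP + MA + LI + UC
    FDR    = FD / (FD + TP)
    F1     = TP / [TP + 0.5 · (FD + FN)]
    redundancy = (contigs representing TP) / TP

## Worked example

Simulate a two-gene, four-isoform cDNA library (expression 20/10/8/4x,
~3% error, unknown strand, 2% chimeras), assemble it, and score the
assembly against the simulated truth:

```r
library(longbloom)

cfg   <- simParams(nGenes = 2, isoformsPerGene = c(2, 2), seed = 1)
txome <- simTranscriptome(cfg)
rd    <- simReads(txome$reference, cfg, nReads = 600,
                  expression = setNames(c(20, 10, 8, 4),
                                        names(txome$reference)))

res <- runPipeline(setNames(rd$reads$seq, rd$reads$id), stranded = FALSE)
res$stageCounts
#>       input   corrected  normalized     trimmed     unitigs transcripts
#>         600         600          29          22           5           5

ev <- evaluateAssembly(res$transcripts, txome$reference,
                       truthIds = names(txome$reference),
                       geneMap = setNames(txome$annotation$gene_id,
                                          txome$annotation$transcript_id))
ev$report
#> Transcript assembly evaluation
#>   complete: 4  partial: 0  missing (FN): 0
#>   TP: 4  FP: 0  MA: 0 (intra 0 / inter 0)  LI: 0  UC: 0
#>   recall: 100.0%  FDR: 0.000  F1: 1.000  redundancy: 1.25
```

Normalization kept 29 of 600 corrected reads while preserving every
isoform; all four isoforms are reconstructed to ≥ 95% of their length
with no misassemblies, and the one redundant contig (redundancy 1.25) is
a second, truncated copy of a highly expressed isoform.

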