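---
title: "Assembling transcripts from long noisy reads: methods and design notes"
author: "longbloom"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Assembling transcripts from long noisy reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(longbloom)
```

# The problem and the model

Long-read RNA sequencing yields reads that often span complete
transcripts, which removes the transcript-reconstruction ambiguity that
plagues short-read assembly — but at the price of 3–10% per-base error,
3'-biased truncation (reverse transcription starts from the poly(A) tail
and may not reach the 5' end), unknown strand for cDNA libraries,
chimeric reads fused during library preparation, and per-transcript
coverage spanning orders of magnitude. `longbloom` assembles transcripts
from such reads without a reference genome, in six stages. This vignette
explains each stage's model and assumptions, the parameters that matter,
the numerical choices, and what the bundled simulator does and does not
emulate.

# Stage 1: alignment-free error correction

All k-mers of the input reads (and optionally of accompanying short
reads) are stored with approximate multiplicities in a Bloom-filter de
Bruijn graph (`buildKmerGraph`). The underlying structures are a plain
Bloom filter for membership (no false negatives; false positives at the
analytic rate $(1-e^{-hn/m})^h$) and a counting Bloom filter whose
reported counts are never below the truth and saturate at $2^8-1$
rather than wrapping. Sizing is derived from the expected k-mer count at
a 1% target false-positive rate; hashing is double hashing from one
64-bit hash, reproducible from an integer seed. For unstranded (cDNA)
input, k-mers are collapsed with their reverse complements
(lexicographic minimum); for stranded (dRNA) input they are stored as
read, which is why `k` must be odd in canonical mode (a canonical k-mer
is then never its own reverse complement).

Correction proceeds tile by tile (`tileRead`, default 500 nt): a
read-local threshold separates *weak* from *solid* k-mers, and each
maximal run of weak k-mers flanked by solid anchors is a candidate for
replacement by a solid path found by bounded best-first search in the
graph (priority: maximize the path's minimum multiplicity; at most 64
states expanded; path length capped at 1.5 x span + k). The best
candidate replaces the span only if its identity against the original
span is at least `minPathIdentity` (default 0.70), computed by global
unit-cost alignment — the strictest reproducible choice. Ties between
equal-identity candidates break by higher minimum multiplicity, then
lexicographically, so correction is fully deterministic.

**The dynamic threshold.** Within a tile the multiplicity threshold is
$t = \max(2, \lceil q_{25}/10 \rceil)$ with $q_{25}$ the tile's 25th
multiplicity percentile, refined to the deepest histogram valley below
the tile median *provided the low side of the valley is an error-like
mode* (modal multiplicity at most 2). The guard matters: without it, a
tile shared by two isoforms of different expression has a genuine valley
between the two coverage modes, and the refinement would label the minor
isoform's junction k-mers weak — correction would then rewrite the minor
isoform into the major one. Worked through by hand: multiplicities
$\{1,1,3,3,3,40,40\}$ give $t = 2$ (only the 1's are weak); ninety 20's
with ten 1's give $t=2$; an errorless two-mode tile keeps the percentile
rule.

**Iteration.** Tiling restarts at offset 0 and at half a tile length on
alternating passes, so an error straddling a tile boundary (where its
weak run has no anchor on one side) is corrected by the shifted pass.
Passes repeat until two consecutive passes — one at each offset — make
no edit, so the returned read is a fixed point of the whole procedure:
correcting a corrected read changes nothing. The pass cap
(`maxIterations`, default 12) exists only as a safety net; almost all
reads converge within four passes. A read whose solid k-mer fraction
(multiplicity ≥ 2) remains below 0.1 after correction carries no usable
signal and is discarded with a logged reason, as is any read shorter
than k.

# Stage 2: digital normalization

Deep coverage of highly expressed transcripts dominates the cost of
all-vs-all overlap; normalization reduces every region to a target depth
(default 3) while keeping rare transcripts. Depth is approximated by
**randstrobes** of order 3: a strobemer links three 10 nt strobes, the
first at the anchor position, each next one selected within the window
`[prev_end + 15, prev_end + 50)` by minimizing a hash link
`(h(chain) + h(candidate)) mod 2^40`; the emitted hash chains all strobe
hashes and is therefore order-dependent. Because only the strobes
themselves must match, a mismatch or small indel between strobes leaves
most strobemers intact — the property that makes them usable as an
error-tolerant depth proxy where exact k-mers would fracture. Anchors
are restricted so every selection window fits inside the read, hence
reads shorter than $10 + 2 \times 50 = 110$ nt yield no strobemers and
are conservatively retained.

Reads are examined longest first (ties keep input order). A read is
*represented* if the union of its strobemers' anchor-to-last-strobe
intervals, restricted to strobemers whose counter multiplicity has
reached the target depth, covers the read from 50 nt after its start to
50 nt before its end without a gap. Represented reads are dropped;
unrepresented reads join the retained set and increment exactly those of
their strobemer counts still below the target. Ten identical reads at
target depth 3 therefore retain exactly three. For unstranded input,
strobemers are computed on both the read and its reverse complement
(reverse-strand intervals mapped back into read coordinates) and the
union drives both coverage and counting: reads of both strands then
count toward one depth. Canonicalizing each strobe individually would
break the chained link hash, which is why the two-orientation scheme is
used instead.

# Stage 3: trimming and chimera splitting

All-vs-all overlaps are found by an internal minimizer overlapper
(canonical minimizers, k = 15, window 10; anchors clustered by diagonal
with 100 nt drift tolerance, chained monotonically, split at > 100 nt
anchor gaps, and extended exactly at the ends). On clean data its
dovetail coordinates are exact, so alignment-free unitig splicing can be
byte-faithful. A PAF import path (`readPAF`) lets an external overlapper
be substituted record-for-record.

Each read's per-base depth profile counts the read itself plus every
overlap covering the position; a region is sufficiently covered at depth
≥ 3, i.e. when it overlaps at least two other reads. Maximal sufficiently
covered runs at least 200 nt long are emitted (shorter runs are below
the exon-pair scale and effectively unassemblable); undersupported heads
and tails are thereby trimmed and internal valleys split the read —
chimeric junctions produce exactly such valleys because no genuine read
aligns across them. One numerical subtlety: an alignment that stops at a
junction still pokes 1–3 bases past it wherever the next bases match by
chance, so before profiling, overlap interval ends that are *interior*
to the profiled read are shrunk by 3 nt (`junctionMargin`); ends lying
at the read boundary are untouched, so containment support still counts
to the last base. Without the margin, a junction between two
well-covered fragments would appear spanned. Reads completely contained
in another read are removed, but their overlaps still contribute depth
to the reads containing them.

# Stage 4: unitig assembly

Dovetail overlaps among the trimmed segments form a string graph; in
unstranded mode every segment contributes a vertex per orientation and
every edge a mirror edge, keeping the graph strand-symmetric.
Classification by overhang geometry uses a 25 nt tolerance, absorbing
residual post-correction noise (and most poly(A)-tail length
differences).

**Poly(A) pruning.** A signal-bearing segment — poly(A) tail (≥ 10
signal bases at ≥ 90% purity in the terminal 20 nt) or the symmetric
poly(T) head — has a preferred orientation: tail at the 3' end. Nothing
genuine extends beyond a poly(A) tail, so a vertex in its preferred
orientation loses outgoing edges and one in its anti-preferred
orientation loses incoming edges; edges joining two signal-bearing
segments that cannot both sit in their preferred orientations are
removed as well. This is what resolves the head-to-head geometry of
antisense overlapping genes, which would otherwise fuse into one
chimeric contig.

Transitive reduction is Myers-style: an edge u→w is removed when edges
u→v and v→w exist whose combined extension lengths match u→w's within a
10 nt fuzz (residual indels shift coordinates slightly). Vertices are
untouched and reachability is preserved. Unambiguous paths (each edge
joining out-degree-one to in-degree-one vertices) are spliced — first
vertex verbatim, each successor contributing its suffix beyond the
recorded overlap end — and in unstranded mode each path is emitted once,
oriented by its poly(A) evidence when present and by the lexicographic
minimum of sequence and reverse complement otherwise (determinism).
Inconsistent overlap coordinates (an empty successor suffix) break the
path with a warning rather than corrupting the sequence.

# Stage 5: polishing

Corrected reads are aligned back to each unitig with an affine-gap
overlap aligner (match 2, mismatch −6, gap open 4, extend 2, free end
gaps; both orientations tried; a shared 15-mer prescreen skips hopeless
pairs). Alignments with an indel larger than 50 nt or identity below
0.70 are discarded *before* consensus: a read from an isoform that skips
an exon aligns with that exon as one long deletion, and admitting it
would vote the exon out of the unitig. Two numerical choices protect
this gate. First, the mismatch penalty is deliberately steep: at the
minimap2-like −4, the optimal path across a skipped exon can bridge
through chance matches in the unrelated sequence instead of opening the
long gap — hiding a 200 nt skip behind a reported largest indel of under
20 nt. Second, the largest indel is measured over gap *clusters*: gap
runs separated by aligned islands of at most 10 bases count as one
indel, since the optimal affine path interrupts any long gap wherever a
few bases match by chance.

Consensus is per-column majority with one vote per covering read
(aligned base or deletion); any tie — including a 2-vs-2 split — keeps
the draft base (minimal-change principle), and uncovered columns keep
the draft. An insertion between columns is accepted when more than half
of the reads covering the junction support one, the most common inserted
string being used. Polishing error-free data is the identity.

# Stage 6: transcript extraction

Polished unitigs are overlapped against each other and annotated from
the polishing alignments: each unitig's **length-normalized read count**
is its aligned read bases divided by its length (a read straddling two
unitigs splits its contribution by aligned bases, avoiding
double-counting at overlaps), and each edge's **support** is the number
of reads aligned to both incident unitigs. An edge between unitigs of
counts $c_u, c_v$ with support $s$ is removed when
$P(X \le s \mid n = \mathrm{round}(\min(c_u, c_v)), p = 0.5) < 0.05$
(one-sided exact binomial): far fewer reads span the junction than the
expression of the less-expressed unitig predicts, the signature of a
false overlap between transcripts of different expression magnitude.
Edges with $n < 3$ are kept — too little evidence either way. The test's
$n$, $p$ and sidedness are this package's own formulation and all three
are exposed as arguments.

For unstranded data, each unitig is assigned the orientation that places
poly(A) tails at its 3' end, by a vote over its signal-bearing reads
weighted by aligned bases and restricted to reads whose alignment covers
at least 80% of the read — partial cross-alignments through a region
shared with another gene carry no orientation information and would
otherwise poison the vote. The mirrored graph is collapsed to one vertex
per unitig, edges inconsistent with the assigned orientations are
dropped, and — as in stage 4 — tail-evidenced unitigs lose their
3'-extending edges.

Transcripts are extracted greedily: vertices sorted by count descending
(ties: longer unitig, then id) seed bidirectional extensions that always
move to the highest-count neighbor and stop at a dead end, a vertex
already on the path (cycle rule), or a zero-count vertex. The path is
spliced into a transcript, its vertices are flagged from seeding further
paths (they may still be *traversed* — shared exons require it), and
counts along the path drop by the path minimum, so total counts strictly
decrease and extraction terminates on every finite graph. A seed whose
count has already reached zero is flagged without emission. On the
canonical two-isoform topology (flanks A1/B1 at count 6, A2/B2 at 4,
shared middle M at 10) this recovers both isoforms: A1–M–B1 first
(decrement 6), then A2–M–B2 (decrement 4).

# Evaluation

Assembled contigs are aligned to a reference transcript set (same
affine-gap aligner, both orientations). Only segments at least 100 nt
long, at least 95% identity, with indels smaller than 70 nt are
considered. Contigs whose surviving disjoint segments (less than 50%
mutual overlap on the contig) hit more than one transcript are
misassemblies, intragenic or intergenic by the gene map; ties between
truth-set and non-truth transcripts resolve to the truth set; a contig
whose only credible alignment carries a ≥ 70 nt indel is a large-indel
call (exclusive of TP — each contig lands in exactly one category);
contigs with no credible alignment are unclassified. Each truth
transcript's covered fraction is the *union* of its assigned contigs'
gated alignment intervals (union rather than single-best, so split
reconstructions get credit), giving complete (≥ 95%), partial, or
missing. The summary metrics are recall (percentage of truth transcripts
reconstructed), FD = FP + MA + LI + UC, FDR = FD/(FD+TP),
F1 = TP/[TP + 0.5(FD+FN)], and redundancy = TP-representing contigs per
TP transcript. Degenerate cases: FDR is reported as 0 (with a warning)
when TP + FD = 0, redundancy as NaN when TP = 0.

# The simulator, and what passing tests do and do not show

`simTranscriptome` builds genes from exon pools (4–7 exons of
100–300 nt); the first isoform uses every exon and the others skip
random internal exons, so isoforms of one gene share at least their
first and last exons — exactly the fork and bubble topologies stages 4
and 6 must resolve. Transcripts are intron-free exon concatenations;
genomic alignment is out of scope, so introns would add nothing
testable. `simReads` draws per-transcript read counts from supplied or
log-uniform (1–200x) expression weights and generates each read with a
3'-anchored truncation (full length with probability 0.7, else a
uniform fraction ≥ 0.4 of the transcript), a 10–30 nt poly(A) tail, iid
substitutions/insertions/deletions (defaults 2%/0.5%/0.5%, the ~3%
total typical of current ONT cDNA data), a random strand in cDNA mode,
and a 2% chimera fraction. A chimeric read fuses the 3'-anchored
fragment with a partner fragment starting at a uniformly random internal
position — the template-switch model; anchoring both fragments at the 3'
end would give every chimera of the same transcript pair a
byte-identical junction, letting chimeras certify each other's
junctions, which no real library does. All randomness flows through one
seeded stream: identical seeds give byte-identical FASTA/FASTQ output.

The simulator does **not** emulate: position- or homopolymer-dependent
error profiles, quality-score information (flat qualities are emitted),
internal priming artifacts, paralogous gene families, or intron
retention from unspliced pre-mRNA. Passing tests therefore demonstrate
the algorithmic machinery — correction, normalization coverage
guarantees, junction splitting, strand resolution, expression-guided
isoform separation — under iid noise, not performance on any particular
instrument's error process.

Test problem sizes are chosen to exercise each property at the smallest
scale where it is non-trivial: correction efficacy on 10 transcripts at
20x and 3% substitution error across five seeds; normalization retention
on a 50-transcript log-uniform 1–200x library of 1200 reads; transitive
reduction against a brute-force oracle on 100 random string-graph
instances; and the end-to-end run on a two-gene, four-isoform 600-read
library. `scripts/acceptance.R` reruns the main computations at these
sizes from a single seed.

# Known limitations

* Depth-based chimera splitting needs the junction to be *unspanned*;
  its resolution is a few bases (by-chance alignment extension), and a
  junction whose flanks both match a third, genuinely fused-looking read
  cannot be detected at this stage.
* Transcripts shorter than about `minOverlap + minSegment` (≈ 350 nt at
  defaults) sit below the overlap engine's working range and are often
  lost in stages 3–4.
* Isoforms whose distinguishing exon is smaller than the polishing
  indel gate (50 nt) can be merged by consensus when their expression
  ratio is extreme; this is the same trade-off the gate's purpose
  implies (protecting short alternative exons from deletion votes).
* The internal overlapper estimates identity from seed coverage, not
  base-level alignment; workflows needing calibrated overlap identities
  should import PAF from a dedicated aligner.
* Counting Bloom filters only over-count; at extreme load, digital
  normalization may drop a read whose true strobemer depth is below
  target. Structures are sized for a 1% false-positive rate to keep this
  negligible.
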