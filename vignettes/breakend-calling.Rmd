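---
title: "Break-end calling with positional de Bruijn graph assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Break-end calling with positional de Bruijn graph assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakendr)
library(dplyr)
```

## The model

breakendr detects genomic rearrangements as novel adjacencies
(*breakpoints*) between two reference loci. Each side of a breakpoint is a
*break-end*: a position plus a direction, where `+` means the retained
sequence lies at or below the position (the junction faces right) and `-`
means it lies at or above it. A deletion is a `+`/`-` junction, a tandem
duplication `-`/`+`, and an inversion contributes one `++` and one `--`
junction.

Three evidence classes support a breakpoint. *Split reads* (and
indel-containing reads, which are split reads spanning their own alignment
gap) pin the junction to a single base, up to microhomology. *Discordant
pairs* constrain it to an interval determined by the concordant
fragment-size range. *Assemblies* are break-end contigs built from all of
the above plus soft clips and one-end anchors, realigned to locate their
junction(s) precisely.

### Evidence scoring

Every piece of evidence $r$ is scored with the Phred-scaled probability of
observing it **without** any underlying structural variant,
$Q = -10\log_{10}\Pr(r)$ with

$$\Pr(r) = \Pr(M)\,\Pr(r \mid M) + (1 - \Pr(M)) \cdot 1,$$

where $M$ is the event that the mapping is correct,
$\Pr(M) = (1 - 10^{-mapq_a/10})(1 - 10^{-mapq_b/10})$ (single-locus evidence
uses one term), and a mismapped read is uninformative,
$\Pr(r \mid \bar M) = 1$. $\Pr(r\mid M)$ is read off the per-library
empirical distributions collected in the first pass:

* split reads / soft clips: the tail mass of the soft-clip length
  distribution at the observed clip length (measured before split-read
  identification);
* indel reads: the tail mass of the matching insertion- or
  deletion-operation length distribution;
* read pairs: $p_d + (1 - p_d)\,P_{rp}(ifs)$, where $p_d$ is the
  chimeric-fragment rate (fragments more than 10 raw median absolute
  deviations from the median fragment size) and $P_{rp}$ the two-sided
  fragment-size tail mass at the inferred fragment size;
* one-end anchors: $p_u$, the rate of pairs with exactly one read unmapped
  (no fragment size exists, so the fragment term is omitted).

Two conventions deserve comment, because the distributions could plausibly
be read as densities instead. We use *tail masses* throughout: with a
density, the most common fragment size would score as strong SV support,
which is backwards. Unseen values floor at the pseudo-count
$1/(2n_{\mathrm{obs}})$ so empirical zeros never produce infinite scores,
and all scores are capped at `q_max = 100` (perfect qualities otherwise make
the formulas diverge). Mapping quality 255 ("unavailable") is replaced by a
configurable ceiling of 60, since the model needs a finite probability.

Assemblies are scored through their constituent reads: soft clips are
promoted to split reads and one-end anchors to discordant pairs *within the
context of the assembly*, with the anchored mapping quality equal to the
greatest constituent mapping quality and the unanchored mapping quality
taken from the assembly realignment. The assembly score is the maximum of
the promoted constituent terms — an explicit approximation that avoids
summing correlated log terms, and the reason a well-assembled junction can
rescue poorly mapped reads.

### Positional de Bruijn graph assembly

A node of the assembly graph is a pair (k-mer, expected genomic position);
nodes are connected when their k-mers overlap by $k-1$ bases *and* their
positions are adjacent. Every edge therefore advances the position by one
base, the graph is acyclic, and maximal-weight path calling is a linear-time
dynamic program rather than the NP-hard longest-path problem of an ordinary
de Bruijn graph.

Reads are placed at every position consistent with their mapping
information: a soft-clipped read at the single position implied by full
mapping of the read (k-mers fully inside aligned bases are flagged
*anchored*); each read of a discordant pair at every start position at which
the pair would be concordant given its mate's anchor, irrespective of the
read's own mapping; one-end-anchor mates across the whole interval the
mapped read's anchor allows. Node weights accumulate the per-k-mer
Phred weights $w(r,i)$, rounded to the nearest integer so that aggregation
is order-independent and tests can assert exact values. K-mers containing
ambiguous bases are skipped rather than expanded.

Break-ends facing left are assembled by reflecting coordinates (and
reverse-complementing sequence) so a single forward-direction core serves
both graph directions.

Error correction collapses a path A into a heavier alternate path B when
they differ in fewer than 2 bases (Hamming distance over the spelled bases:
bubble paths are equal length by construction, leaves are compared over
their overlap), with A either a simple bubble (shared start and end node) or
a terminal leaf, and shorter than twice the read length. Collapsing remaps
A's support onto B, so total graph weight is conserved — an invariant the
test suite enforces. Batches of node-disjoint collapses are applied per
traversal, deterministically ordered by (position, k-mer).

Contig calling repeatedly extracts the maximal-weight path over unanchored
nodes (anchored-flanked paths first), extends it into flanking anchored
nodes until the anchored length exceeds both the read length and the
unanchored length, and removes all reads supporting any unanchored k-mer of
the path, so each read contributes to exactly one assembly; iteration stops
when no unanchored k-mers remain. Contigs with fewer than 3 supporting
reads, unflanked contigs shorter than the read length, and contigs longer
than `2 * (concordant_hi + read_length)` are filtered (the last bound
suppresses the megabase-scale background paths that fragment-size outliers
would otherwise assemble everywhere).

#### K-mer chaining truncation

A read whose k-mers repeat is *self-intersecting*: placed over an interval,
it supports a path that loops through the repeated k-mer for as long as the
placement window allows. The single read `TAAAAC` with $k = 4$ and five
candidate start positions beginning at 10 produces the maximal-weight path
`TAAAAAAAAC` at position 10 — a pure misassembly. We prevent it by
constraining path calling to *read-supported transitions*: an edge may only
be traversed if some supporting read contains that k-mer transition at that
placement. For the example this restores `TAAAAC`; for a correctly assembled
contig every transition is witnessed by a constituent read and the
constraint changes nothing. We implement truncation as constrained path
calling rather than as a post-hoc cut of the called path because cutting at
the first unsupported transition cannot, in general, reach the best
supported path: the supported path may route through graph nodes that the
unconstrained maximal path skipped. `truncate_contig()` exposes the same
core for a path called with the constraint off.

### Streaming assembly

Because nodes only interact at adjacent positions, the evidence stream
decomposes exactly: a frontier tracks the furthest node position of the
active subgraph, and when the next read's placement starts more than one
position beyond it, no later read can affect any maximal path of the active
subgraph, which is assembled and flushed. Output — contig sequences, start
positions and support sets — is identical to building one whole in-memory
graph, and the test suite asserts this identity on simulated 100 kb
fixtures. The in-memory path is the package's default execution mode; the
streaming contract matters because it is what makes the method scale, and
its observable behaviour is equivalence.

### Variant calling

Realignment turns each contig into breakpoint evidence. The anchored
segment is Smith-Waterman realigned in a window of
`anchor ± (concordant_hi + contig length)` around its expected position
(wide enough to contain any placement consistent with the evidence). A
contig that aligns end-to-end is an artifact unless the alignment contains
an indel, in which case it spans the indel and is kept. Otherwise the
unanchored residue is located genome-wide and any remaining unaligned
stretch is realigned recursively (depth at most 4), yielding one breakpoint
per junction the assembly spans — this is what classifies compound events.
The aligner contract is pluggable; the built-in one combines a windowed
Smith-Waterman, a near-exact genome-wide scan, and an exhaustive
per-chromosome Smith-Waterman fallback for small references, and converts
the score gap between the best and second-best non-overlapping hits into a
mapping-quality equivalent on [0, 60] (single hit: 60).

All breakpoint evidence is the tuple $(s_l, e_l, s_h, e_h, d_l, d_h, w)$.
Within each directional subset, candidate variants are the maximal cliques
of the rectangle-overlap graph, enumerated by an in-order interval sweep per
axis (a brute-force subset enumerator is kept in the test suite as the
oracle). Because a read can support several overlapping cliques, a second
greedy pass assigns each piece of evidence to the highest-scoring variant it
supports (ties to the genomically first), so the summed variant quality
equals the summed assigned evidence weight exactly.

Single-base evidence is expanded to its microhomology interval *before*
clique formation. This matters: aligners and assemblies place a junction at
either edge of its homology, and without expansion one event yields two
separate calls. Homology is annotated per call by sliding the junction while
both sides match the reference, anchored at the junction estimate of the
call's strongest exact evidence (a clique corner can sit off the homology
diagonal when read-pair intervals trim the intersection). The nominal
position is the centre of the homology interval, floored toward the lower
coordinate for even lengths; CIPOS spans the interval. Inexact homology
(IHOMPOS) extends the interval by gapless Smith-Waterman-scored comparison
(match +1, mismatch −4, x-drop 12) up to 300 bp per side; it always contains
the exact interval. A junction with untemplated inserted bases has no
positional ambiguity, so its homology length is zero and the insertion is
embedded in the BND ALT allele.

Calls with quality at least 500 *and* assembly support at both break-ends
are labelled HIGH confidence; everything else is retained as LOW for
analyses that need sensitivity. The 500 default is a configurable choice —
the method itself only defines "high-scoring with reciprocal assembly".

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `concordance_percentile` | 0.995 | fraction | pairs outside the symmetric (1−p)/2 order statistics are discordant |
| `k` | 25 | bp | long enough to be unique in small genomes, short enough for 100 bp reads; limited to 26 by the exact 2-bit packing of k-mers into doubles |
| `min_support` | 3 | reads | minimum assembly support |
| `min_mapq` (realignment) | 10 | Phred | "uniquely aligned" threshold for split reads and contig residues |
| `min_clip` / `min_clip_baseq` | 4 bp / Q5 | | suppress adapter and quality artifacts among extracted clips |
| `max_base_diff` | 2 | bases | error-correction merges paths differing in fewer than this many bases |
| `max_depth` | 4 | junctions | compound realignment recursion bound |
| `qual_threshold` | 500 | Phred | HIGH-confidence quality floor |
| `max_ihom_window` | 300 | bp | inexact homology search window |

Smith-Waterman scoring defaults to match +1, mismatch −4, gap open −6, gap
extend −1 (a gap of length $g$ costs $6 + g$).

## The synthetic-data generator

`sim_genome()` draws i.i.d. bases at a given GC fraction;
`sim_plant_svs()` edits in deletions, insertions, inversions, tandem
duplications and reciprocal translocations, returning an exact
mutated-to-reference segment map and one truth record per junction
(requested deletion microhomology is planted by copying the flank into the
reference, with boundary bases forced to mismatch so the realized homology
is exact). `sim_reads()` draws fragments uniformly with normal
fragment sizes, applies i.i.d. substitution errors, and projects each read
onto the reference through the segment map: junction-crossing reads come
out soft-clipped, junction-spanning pairs discordant, reads inside
untemplated insertions unmapped. Reference-adjacent segment boundaries
(e.g. the second copy of a tandem duplication running onto downstream
sequence) are merged first so reads crossing them are not artificially
split. Base qualities are the Phred equivalent of the error rate with ±5
per-base jitter — enough to exercise the weight formula without a full
quality model.

The default study conditions (used by `sim_sv_dataset()` and the acceptance
tests) are a 100 kb three-chromosome genome carrying a heterozygous 500 bp
deletion with 4 bp of microhomology, a 1 kb tandem duplication, a 2 kb
inversion and a reciprocal translocation, sequenced at 60× with 2×100 bp
reads, fragment size 300 ± 30 bp, and 1% substitution error.

What the simulation does **not** emulate — and hence what passing tests do
not show about real data: indel sequencing errors and alignment wobble,
non-uniform coverage and GC bias, repeat- and SINE-rich reference context
(the generator's genomes are i.i.d., so k = 25 k-mers are almost always
unique), chimeric library artifacts beyond the fragment-size model, and
aligner-specific clipping behaviour (truth alignments are projected through
the segment map, not produced by a real aligner).

## Numerical and design choices

* 1-based, fully closed intervals everywhere, matching SAM/VCF; fragment
  sizes are recomputed as outermost-base spans rather than trusting TLEN.
* Node weights are integer-rounded Phred values so aggregation is exact and
  order-independent; ties in path calling, error correction and greedy
  assignment all break toward the smaller (position, k-mer/coordinate),
  making every stage deterministic.
* Whether error correction compares paths by Hamming or edit distance is a
  genuinely open choice; we use Hamming (bubbles are equal-length by
  definition, leaves are compared over the overlap).
* Metrics exclude duplicate, secondary and supplementary records —
  duplicates would double-count fragments and supplementary alignments
  would contaminate the fragment-size distribution.
* Per-read distributions record the largest clip / indel operation per read
  (zero when absent), so a tail mass is the per-read rate of carrying at
  least such an element.
* Multi-sample calling pools evidence across categories for assembly and
  clique formation and reports support per category; no somatic test is
  applied.
* Problem sizes in the test suite: oracle checks run on graphs of up to 200
  nodes and up to 12 rectangles per directional subset; streaming
  equivalence and end-to-end recovery run on 100 kb genomes at 10–60×, the
  package's intended desk scale.

## Known limitations

* Mate-pair (outward-facing) libraries are rejected; CRAM input is not
  supported; duplicates are expected to be marked upstream.
* Error correction cannot repair errors with no alternate path (coverage-1
  tips) or two errors within one k-mer window (they differ by 2 bases, and
  the merge criterion is strictly fewer than 2).
* The genome-wide residue aligner is exhaustive only for references up to a
  few megabases; larger genomes need the external-aligner adapter path.
* Break-end contigs bound untemplated-insertion detection by the library
  fragment size: insertions longer than the assembly window surface as
  single break-ends, not resolved junctions.
* Score calibration against an external truth set is out of scope; Phred
  scores order calls but are not validated error probabilities.
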