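---
title: "Reference-free repair of supertranscriptome assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free repair of supertranscriptome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A supertranscriptome collapses all splice variants of a gene into one
supertranscript, giving RNA-seq studies of non-model organisms a compact
reference. De novo assemblers produce workable supertranscriptomes but leave
characteristic errors behind: redundant contigs, incomplete (truncated)
supertranscripts, fragmented supertranscripts split over several contigs,
false chimeras fusing unrelated transcripts, and local mis-assemblies
(missing sequence, unsupported insertions, translocations, inversions).

This package repairs those errors using only the evidence carried by the
paired-end reads themselves — no related-species BLAST, no reference
genome. When reads are aligned back to a flawed assembly, each error class
leaves a recognizable signature:

* **incomplete contig** — reads at a boundary whose outward tails are
  soft-clipped, and edge reads whose mates find no home anywhere;
* **fragmented supertranscript** — edge clip consensi that map onto another
  contig, and "read/mate islands": clustered edge reads on one contig whose
  mates cluster on another;
* **false chimera** — soft-clips in the middle of a contig, and abrupt
  changes in per-base coverage;
* **local mis-assembly** — two internal clip clusters pointing away from
  each other at one junction ("crisscross": missing sequence,
  translocation, inversion) or pointing toward each other across a gap
  ("facing": an unsupported insertion whose size equals the clip-point
  distance).

## The iterative procedure

Repair runs as two nested loops. Each **outer iteration** performs, in
order: (1) an **inner iteration** that repeatedly aligns reads, collects
outward edge-clip clusters, builds a consensus from the clipped fragments,
and extends the contig ends — until no contig grows or `inner_max` (30)
passes have run; (2) overlap merging of contigs that were just extended
(the terminal 25 bases of the fresh extension serve as the query; a
full-length 100%-identity hit on another contig is extended at 90% running
identity and the two contigs merged across the terminal overlap); (3) a
fresh full re-alignment; (4) orphan-mate assembly (unmapped mates of
outward edge reads are greedily assembled and stitched to the contig end)
and island-based merging; (5) another full re-alignment; (6) chimera
splitting and local mis-assembly repair. The outer loop stops when a pass
changes no contigs (`error_threshold = 0`) or after `outer_max` (100)
passes. Within the inner loop only reads that are unmapped, ambiguous, or
mapped in the edge zones (two read lengths from a boundary) of recently
extended contigs are re-aligned; every outer stage boundary re-aligns
everything.

At most one structural fix (split or local repair) is applied per contig
per outer pass, at the best-supported site: earlier edits invalidate the
coordinates of later sites, and the iteration re-detects whatever remains.

## The built-in aligner and overlap search

The original tool family delegates read alignment and overlap search to
external programs (a general-purpose read aligner and `blastn`). Here both
are provided internally so that the whole system is a self-contained
package. The read aligner seeds each mate with exact 15-mers, extends the
best diagonals with X-drop scoring (match +1, mismatch −2), soft-clips
unextendable read ends, and reports `mapq = 40 (1 − s2/s1)` capped at 60,
where `s1`/`s2` are the best and second-best placement scores — so a read
placing equally well twice is mapq 0 and removed by the Phred < 20 filter.
The aligner is ungapped: supertranscripts contain no introns, the read
model is substitution-only, and an indel would surface as a clipped tail
and be handled by the same signature machinery. The overlap search uses
exact 11-base words (the conventional nucleotide-BLAST word size) with the
same X-drop extension; hits are ungapped, consistent with the default of
ignoring gapped hits, and are ranked by the composite score
`matches / query length × 100`. Where the thresholds speak of "score" the
composite is used; where they speak of "identity" the per-column identity
of the hit is used.

Pairs mapped in non-FR orientations on one contig (F1F2, R1R2, and
tail-to-tail RF) are removed before signature detection, as are records
below mapq 20. Pairs split across two contigs and reads with unmapped
mates are kept — they are themselves signatures.

## Consensus construction

Clip fragments at a cluster are anchored to the clip point by their own
alignment end, so their mutual layout is known; the consensus is the
per-column majority over the anchored stack, with IUPAC ambiguity codes at
tied columns. Downstream alignment treats an IUPAC base as matching every
base it encodes, so later iterations still map reads across consensus
ambiguities. Two robustness rules apply:

* columns are **clamped to the outward side of the clip point** — overhang
  columns (produced by reads whose extension chance-matched a base or two
  past the true junction) would otherwise overwrite supported contig bases
  at depth 1;
* the outward tail of an extension consensus is **trimmed to columns with
  depth ≥ 2**, so single-read sequencing errors are not locked into the
  contig. A consensus of at most 8 columns may keep depth-1 columns: near
  a true transcript terminus the only remaining evidence is one or two
  short overhangs, and the exposure is bounded by those few bases.

Edge clusters accept clips of one or two bases (the count and 75%-support
thresholds still apply): close to a terminus, short overhangs are the only
signal left, and a hard 3-base floor would leave every extension
permanently short. Internal sites keep the 3-base floor, where single-base
clips really are alignment jitter.

Orphan mates are assembled by a greedy overlap-layout assembler (merge the
pair with the longest suffix–prefix overlap of at least 16 bases at 95%
identity, repeat), and the returned sequence is the column-majority
consensus of the final layout rather than a chain of pairwise picks — at
typical mate depth this removes sequencing errors the same way the clip
consensus does.

## Distinguishing the crisscross cases

A crisscross site (left- and right-pointing clips at one junction) is
ambiguous on its face: the junction may be missing sequence, a displaced
(translocated or inverted) fragment, or a chimeric fusion point. The
package resolves it by evidence, in this order:

1. both flank-trimmed consensi find a ≥ 90% hit elsewhere in the contig →
   the hits bracket a displaced fragment; it is excised and re-inserted at
   the clip point, reverse-complemented for minus-strand hits. At an
   inverted block's junctions the two hits legitimately land on opposite
   strands — one locates the displaced continuation, the other the removal
   junction — and the fix is assembled from that geometry.
2. neither consensus hits, and the "left flank + left consensus" block
   overlaps the "right consensus + right flank" block by ≥ 10 bases at
   ≥ 90% → the junction is missing sequence; the overlap-merged fragment is
   inserted. Merging whole flanking blocks (rather than concatenating raw
   consensi) re-anchors the junction exactly even when the two clip points
   jitter by a couple of bases.
3. otherwise the consensi are unrelated sequences: the junction is
   chimeric and the contig is split there. Split products shorter than
   200 bases are discarded unless they duplicate the larger piece (then
   they are removed as self-chimera repeats); products of at least
   200 bases become new contigs.

Facing sites are classified purely by clip-point order (right-pointing
strictly upstream of left-pointing): the gap between the two points is an
unsupported insertion of exactly that size, which also lets base-scale
junk left by an earlier imperfect edit heal on the next pass.

## Read-backed verification of structural fixes

Chance-matched junction bases are the central numerical hazard of
clip-derived coordinates: when the first bases of a displaced fragment
happen to equal the sequence that follows the clip point, every read
extends over them, and the clip point, the consensus content, and the hit
boundaries all shift by the same run — which no amount of sequence
comparison can detect, because the same chance process generates the
alternatives. The package therefore treats coordinates from consensus
evidence as candidates, not answers:

* candidate spans/removal intervals are enumerated over a small grid of
  boundary offsets (slides along IUPAC-equal runs, the refined hit
  positions ± 2, head/tail trims of a reconstructed insert);
* each candidate is accepted only if every junction it would create is
  **read-supported**: reads currently mapped near the affected regions are
  re-aligned to a ±(read length + 40) window of the repaired sequence
  around the junction, and at least `min_clip_reads` of them must cross it
  by ≥ 12 bases on both sides essentially unclipped and without a single
  mismatch (IUPAC-aware). A junction with base-scale junk never clips a
  crossing read, but it breaks every crossing read's perfect match, so the
  perfect-crossing count collapses exactly when the candidate is wrong;
  sequencing errors only thin the count, which the
  perfect-fraction fallback (≥ 2 perfect and ≥ 50% of crossers) absorbs.
  Reads are gathered from the unfiltered record set, because reads
  crossing a junction under repair often carry a second candidate
  placement and are mapq-ambiguous in the pre-fix contig.

Junction checks are memoized across candidates (each junction's local
context depends on only two of the three candidate offsets), keeping the
whole verification of a site to a few hundred short alignments.

Coverage-based chimera splitting (abrupt ≥ 80% relative change between
consecutive depths, outside one read length of the ends) runs only on
contigs with no clip-derived internal site at all: a junction with clip
evidence belongs to the clip fixers, and the coverage signal would split
zero-coverage inserted segments that the facing-site fixer removes
cleanly. The windowed gradual-change scan is off by default and is only
useful when constituent transcripts differ in expression.

## Parameters

All thresholds follow the documented defaults of the method: edge clip
window 25 bases; 3 reads and 75% support per clip cluster; re-alignment
edge zone 2 × read length; 3 orphan reads with < 25% clipped anchors and a
minimum 50%-of-read-length gain; 5 Ns for terminal joining of unmerged
orphan blocks; 25-base merge seed at 100% identity extended at 90%;
gapped overlap hits ignored; 5-read islands merged across ≥ 10-base
overlaps scoring ≥ 90% within 5% of a read length of the island edge;
10-base internal consensus at ≥ 90% identity; 200-base minimum for new
contigs; 80% abrupt (and windowed) coverage thresholds with a read-length
end-ignore zone; mapq ≥ 20; redundancy identity 0.95; inner cap 30, outer
cap 100, error threshold 0. Redundancy removal is on by default;
the benchmark runs disable it because the generator enforces mutual
dissimilarity. Implementation-specific knobs (aligner k-mer 15, minimum
placement score 20, 3-base internal jitter floor, 5-base clip pooling,
greedy-assembly overlap 16 at 95%) are documented in
`?default_parameters`.

## The synthetic benchmark

`roast_simulate()` builds the whole test harness in code: i.i.d. random
supertranscripts (400 contigs of 1–3 kb by default, pairwise dissimilarity
enforced by rejection), seven error types injected on disjoint contigs
(terminal deletions of 10–30%; cuts at 40–60% of length; chimeras fusing
the 40–60% prefix of one contig to the complementary suffix of another;
internal deletions and insertions of 30–70% of a read length;
translocated/inverted blocks of 20–30% of contig length), and paired-end
reads simulated from the error-free reference: uniform fragment positions,
lengths uniform on 250–500, FR mates of 100 bp, substitution-only errors
at 0.5%, constant Q30 qualities. All outputs are bit-reproducible per
seed.

Positions of internal errors keep a margin of 1.5 read lengths from the
contig ends, and translocation/inversion destinations stay at least two
read lengths from the excision site, so each injected error presents the
internal signature of its own class rather than overlapping an edge or a
sibling junction. One error is injected per contig; the published error
counts relative to assembly sizes imply the same sparsity.

What the generator deliberately does not emulate: splice structure and
exon boundaries (reads are simulated directly from supertranscripts, so
the splice-junction exclusion list is empty, matching how the method is
configured on such data); expression heterogeneity (uniform by default —
a two-level abundance option exists to exercise coverage-based chimera
detection); indel sequencing errors; quality-score decay; genuine
biological chimeras. Passing the benchmark therefore demonstrates the
correctness of the signature→repair machinery under the stated read
model, not performance on real libraries, where coverage is uneven and
alignment noise is richer.

Because fragment start positions are uniform, coverage ramps to zero over
the last fragment-length of every transcript, and the very last bases of
a terminus are covered only by reads whose fragment ends exactly at the
boundary. Terminal extension therefore typically stalls within a dozen
bases of the true end — the reason incomplete-contig recovery is scored
as ≥ 90% of the deleted bases rather than exact restoration, and a
behavior real libraries share.

## Recovery scoring

`score_recovery()` applies one fixed-if rule per error type: incomplete
contigs and missing sequence are fixed if ≥ 90% of the deleted bases are
present, in place, in the mapped final contig; fragmented contigs,
translocations and inversions require the final sequence to be identical
to the original; unsupported insertions require every inserted base gone
(the final contig equals the original); a chimera is fixed when both
sequences that produced it are fully restored, each on its own final
contig (the split products are extended by the ordinary machinery toward
the full originals, so restoration is checked by full-length containment).
A position holding an IUPAC code whose set covers the original base counts
as recovered: the code is the honest representation of a tied consensus
column and retains the original base. The scorer follows contigs through
the contig map (splits, merges, renames) and is calibrated in the test
suite: it reports 0% on the unrepaired assembly and 100% for the pre-error
assembly under the truth mapping.

## Numerical choices and degenerate inputs

Positions are 0-based half-open internally; FASTA/SAM I/O converts at the
boundary. Clip points within 5 bases pool to the modal point (smallest on
ties). Crisscross pairing accepts the left-pointing cluster at most 10
bases left of the right-pointing one. All tie-breaks (hit ranking, contig
processing order, merge order) are deterministic, and the repair pipeline
itself contains no randomness — only the simulator consumes the seed.
Contigs shorter than the seed word simply produce no hits; clusters at
junctions already explained by the adjacent sequence (within 3 bases of
slippage) are left alone rather than split. Merged contigs adopt the id
`a+b`; split products `id.1`/`id.2`; orphan blocks `id.orphN` with an
`orphan-derived` tag and a recorded partner, joined with 5 Ns at the end
of the run if still unmerged.

Each contig carries a per-base provenance vector (assembler-original vs
read-derived). Overlap merges resolve column disagreements in favour of
the original base — the practical proxy for "higher read support",
because in a fragment merge one side of the overlap is always the
partner's untouched original sequence — and emit the IUPAC union on
equal-provenance ties.

## Scope and limitations

The SAM ingestion hook accepts externally produced alignments for the
first pass (including spliced alignments, whose `N` junctions feed the
exon-boundary exclusion list); later passes re-align internally, since
iterative repair requires re-mapping against edited contigs. Redundancy
removal compares every contig against the longest-first representatives
with the overlap search, which is quadratic in contig count and intended
for assembly-scale, not read-scale, inputs. The command-line interface
(`inst/cli/roast.R`) is a thin wrapper over `roast_run()`,
`roast_simulate()` and `score_recovery()`; library use is equivalent.

Known limitations: crisscross sites where exactly one consensus has a
self-hit are deliberately left unrepaired until more evidence accumulates
(editing only the matched fragment risks a wrong excision); inversions or
translocations whose displaced fragment lands within two read lengths of
its origin can present merged signatures and may not be repaired; repairs
near junctions supported by fewer than `min_clip_reads` perfect crossing
reads are withheld by design. These show up as honest residual error
rather than mis-repair.
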