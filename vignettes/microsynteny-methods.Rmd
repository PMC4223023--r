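---
title: "Refining syntenic regions: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining syntenic regions: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsynteny)
```

## The problem

Whole-genome comparisons between two species usually start from a set of
*syntenic regions*: pairs of large chromosomal intervals, one per species,
descended from a common ancestral sequence. Such regions are defined to be as
long as possible, which deliberately ignores the small-scale shuffling inside
them. `microsynteny` refines these regions into *maximal blocks of perfectly
conserved gene order*, making every internal micro-rearrangement — a local
translocation or an inversion of a handful of genes — and every external
translocation of genes between regions explicit.

The package works gene-wise. Its inputs are two per-species gene tables, a
syntenic-region pair table, and a pairwise ortholog table with percent
identities (the shape of an ENSEMBL-Compara export). Its outputs are (a) a
table of refined regions — each input region's collinear *backbone* plus one
new region per rearranged block — and (b) the set of *syntenic one-to-one
ortholog pairs* supporting them.

## From raw orthologs to syntenic one-to-one pairs

Gene duplications make real ortholog sets messy: besides clean one-to-one
links there are one-to-many and many-to-many groups. Because downstream block
detection needs a permutation (each gene at most one partner), groups are
resolved in four steps, applied per syntenic region to the connected
components of the bipartite link graph:

1. **Grouping.** Components are computed over the links whose two endpoints
   both lie in the region. Genes with no in-region link are set aside (they
   are the candidates for external translocation detection).
2. **One-to-many reduction.** A group with a single gene on one side keeps
   only the link with the highest combined identity (the mean of the two
   directional percent identities); all other genes are removed.
3. **Symmetrization.** An n-vs-m group with n > m drops the n − m genes with
   the lowest average identity to their linked partners.
4. **Positional splitting.** A now-symmetric group is split by genomic rank:
   the i-th gene on one side is paired with the i-th on the other,
   regardless of which links existed. Order, not identity, defines the
   syntenic (positional) ortholog among co-orthologs.

Genes overlapping another gene of the same species in the same region are
excluded before grouping — overlapping annotations make the rank order
ambiguous, and removing *all* participants is the only symmetric choice.
Every removal is reported with a reason
(`overlap_excluded`, `no_ortholog`, `one_to_many_loser`, `asymmetry_trim`),
so the gene accounting is conserved: paired + removed = input.

Ties in identity rankings are broken by the smaller genomic rank distance
between the two genes, then lexicographic id — determinism matters because
byte-identical outputs under a fixed seed are part of the package's contract.

## Breakpoints, strips and block peeling

Within one region, order the resolved pairs by the species-A coordinate and
let `pi[i]` be the rank of pair i's B-gene among the region's B-genes. A
*breakpoint* lies after position i whenever `|pi[i+1] - pi[i]| != 1`: the two
A-adjacent genes' orthologs are not adjacent in B. The maximal runs without
internal breakpoints ("strips") are exactly the segments whose pi values are
consecutive and strictly monotone — ascending (conserved order) or
descending (reversed order). Strips are a property of the pair set, not of
which species is called A: the strip decomposition is identical from both
sides, which is what makes reference symmetry attainable at all.

A rearrangement that relocated a segment leaves a breakpoint at each of its
ends, so the strips delimited by breakpoints are the candidate blocks; the
remaining question is, at each breakpoint, *which* adjacent segment moved.
The classical answer compares the two segments delimited by three adjacent
breakpoints (or region ends) and declares the shorter one the block. That
rule is ambiguous in two situations: when a short conserved flank abuts a
longer inverted run, the flank is "shorter" yet clearly not the displaced
part; and a pure translocation is observationally symmetric (moving segment
X rightwards over Y is the same event as moving Y leftwards over X).

`microsynteny` therefore selects the segment to peel by *displacement*, with
the shorter-segment comparison as the tie-break:

1. peel the strip whose removal most reduces the breakpoint count (the
   displaced segment heals its donor site and its insertion site; a flank
   heals at most one);
2. on ties, prefer a reversed-order (descending) strip — an inverted segment
   — over conserved-order strips;
3. then fewer gene pairs (the shorter-segment rule proper);
4. then the smaller combined bp span across the two species;
5. then the lexicographically smallest member gene-id set.

After each extraction ranks are recomputed and detection reruns, to a
fixpoint with no breakpoints. Iterating matters: it lets a small block nested
inside a larger rearranged segment be peeled first, after which its host
becomes a clean strip itself — so nested blocks are reported as blocks, not
as noise. Each extraction removes at least one pair, so at most n rounds
run. Every tie-break above is invariant under exchanging the two species;
the non-symmetric alternatives (e.g. span in species A only, or "the
downstream segment") would break the guarantee that swapping the reference
genome yields the same blocks.

The backbone that remains is strictly monotone — the *original* refined
region. A wholly reversed region (annotated in opposite orientation) has a
descending identity permutation, no breakpoints, and is left untouched.

**Classification.** A multi-gene block is an *inversion* iff its gene order
runs against the backbone's direction; for the usual same-orientation
backbone this is simply a descending run. Strand relations provide a
cross-check: inside translocated blocks the two species' strands agree with
the backbone's dominant strand relation, inside inversions they flip. When
order and strand disagree, order wins and the conflict is logged — order is
the primary signal of the whole method, and annotation strands are the
noisier channel. A single-gene block carries no order signal, so there the
strand relation relative to the backbone's dominant relation decides.

**External translocations.** After internal resolution, a gene with no
ortholog inside its own region whose link partner (i) sits in a different
region and (ii) is itself internally unpaired forms an external pair;
requiring both endpoints to be unpaired preserves the one-to-one invariant.
Maximal runs of consecutive external pairs joining the same two regions in a
consistent direction merge into one external region. Ambiguous candidates
are resolved by highest combined identity, logged. Genes that have both
in-region and out-of-region orthologs are handled internally only; they are
never paired externally.

Derived regions are named `<parent>_<k>` in species-A coordinate order, with
the species-A region as the parent for external blocks, and span exactly
their member genes in each species.

## Comparing feature tracks over ortholog pairs

Given any positional feature in BED form (peaks, repeats, signal), each gene
is reduced to one number:

* unweighted track — the fraction of the gene's bases covered by the union
  of the elements (in [0, 1]);
* weighted track (numeric column 4) — the overlap-length-weighted sum of
  element weights divided by the *full* gene length.

The weighted denominator is deliberately the full gene length, with
uncovered bases contributing zero, so that a weight of 1 everywhere
degenerates exactly to the unweighted case; averaging over covered bases
only would not have that property. Overlapping weighted elements sum.

Each species' vector is standardized to Z-scores using the population
standard deviation (denominator n; at genome scale the difference from the
sample SD is irrelevant, fixed for determinism), and every ortholog pair is
scored by `d_i = |z_A,i - z_B,i|`; the vector mean is the compact
between-track similarity. The construction is symmetric in the species and
invariant under positive rescaling of either track — Z-scoring absorbs
scale, so differing assay units between the two species do not matter.

For independent tracks the null is analytic: z-scores are approximately
standard normal, the difference of two independent standard normals has
variance 2, and `E|z_A - z_B| = 2/sqrt(pi) ≈ 1.1284`. Significance against a
randomized control (per chromosome, same element count and length multiset,
uniform starts, overlaps allowed — the simplest null that preserves the
marginal track structure) is assessed by a one-sided Wilcoxon rank-sum test
(normal approximation with tie correction), alternative "real differences
smaller than random".

## k-mer sequence distance

Region sequences are compared by their overlapping 6-mer profiles: the
distance is the sum over all 6-mers of the absolute count difference
(Manhattan distance on count vectors). Counting is case-insensitive; windows
containing a non-ACGT symbol are dropped and their number reported. The
distance is computed on raw counts, not frequencies, so sequences of very
different lengths are far apart by design; an optional normalization by the
total window count is available (off by default) where a length-adjusted
score is wanted. k is capped at 12 (the dense 4^k count table would
otherwise not fit); the default k = 6 balances specificity against profile
sparsity at the multi-megabase region scale.

## What the synthetic generator emulates — and what it does not

`simulate_genome_pair()` builds the study conditions used throughout the
tests: species A collinear, species B an order-identical copy, log-normal
gene lengths with means 59.8 kb (A) and 44.3 kb (B), link identities uniform
in [60, 100], regions of ~50 genes. `plant_rearrangements()` then applies:

* **internal translocations** — a run of at most 5 B-genes relocated within
  its region; the insertion point always jumps over *more* genes than the
  run contains. A pure translocation is observationally symmetric (the
  jumped-over segment "moved" the other way), so without this margin exact
  recovery of the planted run would be ill-posed, not merely hard;
* **inversions** — a run reversed in place with strands flipped; a
  single-gene inversion is relocated with its strand flipped, the only form
  that leaves any signal;
* **external translocations** — a run moved into a different region's
  interval;
* **duplications** — an extra B-copy (one-to-many group) or an extra A-gene
  (asymmetric 3-vs-2 many-to-many group), with the planted copy's
  identities drawn in [60, 80] against [85, 100] for the true pair, so the
  intended loser is unambiguous.

Event footprints are pairwise disjoint with a one-gene buffer, and planted
blocks stay shorter than half their region so the shorter-segment tie-break
points at them rather than at the backbone.

Matched feature tracks mix a shared standard-normal latent signal with
independent noise, `w = 10 + sqrt(c)·L + sqrt(1-c)·e`, emitted as one
weighted BED element spanning each gene; at conservation c = 1 the per-gene
values are bit-identical between species, at c = 0 they are independent and
reproduce the 2/sqrt(pi) null.

The generator does **not** emulate: overlapping gene annotations beyond the
planted cases, unassigned (synteny-free) chromosomes, nested or entangled
events, gene loss, assembly gaps, or any nucleotide-level evolution. Passing
the planted-recovery suite therefore demonstrates the algorithmic contract —
exact recovery of disjoint, recoverable events and reference symmetry — not
robustness to every pathology of real annotation pipelines, where overlap
exclusion and removed duplicates visibly shorten blocks.

## Numerical and interface choices

* Gene/region/ortholog TSVs are 1-based inclusive; BED is 0-based half-open,
  converted at the I/O boundary.
* A gene belongs to the region containing its midpoint — a deterministic
  single home for boundary-straddling genes, which region definitions leave
  unspecified.
* Duplicate ortholog rows merge keeping the per-direction maximum identity,
  with a warning.
* Gene order is by start coordinate, ties by end then id.
* Output files are sorted, carry `#` provenance headers echoing the full
  configuration (tool version, command, options, seed), and are
  byte-identical across runs on identical input; the headers contain no
  timestamps.
* All randomness flows through R's RNG; every generator takes an explicit
  `seed`.

## Problem sizes used by the test suite

The shipped tests run the exhaustive peeling sweep over all 5,913
permutations of up to 7 genes; planted recovery and reference symmetry over
1,000 seeded fixtures of 20 regions × 50 genes with up to 10 internal and 2
external events each; duplication resolution over 200 fixtures; the track
null on 10,000 ortholog pairs (tolerance 0.03 around 2/sqrt(pi)); the k-mer
oracle on 500 pairs of 10 kb sequences; and one 356-region × 55-gene
refinement as a scale check. These sizes mirror the human–mouse-scale inputs
the method targets while keeping a full run comfortably on a single CPU.

## Known limitations

* A collinear block interrupted by a pair of genes without orthologs is
  reported as fragments on either side: unresolved genes are invisible to
  ranking by design, and no gap-bridging is attempted.
* Blocks are defined per region pair; multi-genome comparison and
  rearrangement-distance minimization (Hannenhalli–Pevzner style) are out of
  scope.
* The external-translocation step links exactly two regions per block;
  chains across three or more regions resolve greedily by identity.
* Strand annotations are trusted only as a secondary signal; consistently
  wrong strands in an annotation will be logged but not corrected.
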