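---
title: "Graph-based repeat clustering: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based repeat clustering: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatgraph)
```

## The problem and the model

In a genome sampled far below 1x coverage, single-copy sequence is hit by at
most a handful of reads, so genuine read overlaps are rare. A sequence family
present in hundreds or thousands of copies, however, is sampled over and over:
its reads overlap massively, and the number of reads it contributes is, in
expectation, proportional to the fraction of the genome the family occupies.
`repeatgraph` exploits both facts. Reads become vertices of an undirected
graph; an edge connects two reads whose best pairwise alignment has at least
90% identity over at least 55% of the longer read's length, with the alignment
score as edge weight. Reads with no admitted overlap ("singlets") are presumed
single- or low-copy and set aside. Repeat families then appear as densely
connected subgraphs, and a cluster's read count divided by the total number of
analyzed reads estimates the family's genomic proportion.

Transitive closure (connected components) is too coarse a clustering: a single
chimeric or conserved-motif read can bridge two unrelated families. The
partitioning therefore maximizes *modularity*. For a partition assigning
vertex $i$ to community $c_i$,

$$Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_i k_j}{2m}\right]
      \delta(c_i, c_j),$$

where $A_{ij}\in\{0,1\}$ is the adjacency matrix, $k_i$ the degree of vertex
$i$ and $m$ the number of edges: the observed within-community edge fraction
minus its expectation in a random graph with the same degree sequence (the
null term $k_ik_j/2m$ is analytic, so no random graph is ever simulated).
Putting every vertex in one community gives exactly $Q = 0$; a good division
gives $Q$ well above 0. Optimization is greedy agglomeration in the style of
Clauset, Newman and Moore: starting from singleton communities, the
edge-connected pair with the largest $\Delta Q$ is merged, with sparse
per-pair $\Delta Q$ bookkeeping and a lazy max-heap, until one community per
connected component remains. The partition finally reported is the merge level
with maximal $Q$. Because only edge-connected pairs are merge candidates
(merging unconnected communities always has $\Delta Q < 0$), every cluster is
contained in exactly one connected component — components can only be *split*,
never bridged, which is precisely the refinement that separates chimeric
components into their constituent families.

Two deliberate conventions: modularity is computed on the *unweighted* graph
($A_{ij}\in\{0,1\}$) — alignment scores serve as layout attraction, not as
modularity weights (a weighted mode would conflate overlap length with copy
number); and ties are resolved deterministically. Equal $\Delta Q$ pairs merge
the pair whose union contains the smallest vertex id (then the smaller partner
id); equal-$Q$ dendrogram levels resolve to the level with *fewer* communities,
since the coarser partition is the more interpretable one and the finer one
adds no modularity. With those rules the whole pipeline is a pure function of
its inputs and seeds.

## Overlap detection

The all-to-all similarity search is a seeded aligner built for this package.
Candidate pairs are read pairs sharing at least one exact 18-mer on either
strand (`N` never seeds); each candidate is then aligned with a full
Smith-Waterman with affine gaps — match $+1$, mismatch $-3$, a gap of length
$L$ costing $5 + 2L$ — on the seeded orientation(s), keeping the best-scoring
alignment per unordered pair. Reads of a few hundred nucleotides make the
full $O(L_aL_b)$ dynamic program cheap, so no banding or x-drop heuristic is
needed and the seeded search is *exactly* as sensitive as an unrestricted
local alignment whenever a seed exists; the test suite asserts equality of
the admitted edge set with an independent full-alignment oracle
(`Biostrings::pairwiseAlignment`) under the same scoring. Identity is matches
over alignment columns (gap columns count, the BLAST convention); span is the
alignment footprint on the longer read; the admission denominator is the
longer read's *full* length, and both admission comparisons are inclusive.
Word size 18 bounds sensitivity: at the 90% identity floor a 55 nt overlap
still contains an exact 18-mer with high probability (~38 windows, each clean
with probability $0.9^{18} \approx 0.15$), and the identity filter, not the
seed, is the effective threshold. Hits are reported from 85% identity so that
the stricter 90%/55% edge admission can be re-applied (or relaxed) without
realignment.

## Cluster characterization

Each cluster is summarized by its induced subgraph: size, edges, maximal
degree, unweighted diameter (hop count — diameters of read graphs are small
integers and edge weights would only obscure them), density
$2m/(n(n-1))$, mean edge score/identity, and the modularity of the cluster's
own best internal re-division (near 0 for homogeneous clusters, high when a
cluster would split further at a finer level).

Graph shape separates repeat classes before any annotation. Tandem repeats
with monomer shorter than the read give near-complete "star" graphs: every
read pair overlaps in phase, so density is high and the diameter tiny.
Monomers several times the read length give rings: reads sort themselves
around the monomer cycle, with diameter set by the monomer-to-read-length
ratio. Dispersed elements several kilobases long give elongated threads with
branching and loops at structural variants. The classifier is a rule cascade
on these signatures (thresholds in `shape_config()`, all heuristic and
config-exposed): clusters under 20 reads are unclassified; density $\ge 0.05$
with diameter $\le 10$ is `satellite-short`; otherwise high circularity
separates rings, split by mean edge identity ($\ge$ 0.96 means a conserved
rDNA-like unit, below means a diverged satellite); otherwise diameter
$\ge \max(0.5\sqrt{n},\ 20)$ is `linear-dispersed`. Circularity is the mean
vertex eccentricity over the diameter: on a cycle every vertex's farthest
vertex is a diameter away (ratio 1), on a path the ratio averages ~0.75. This
replaces spanning-tree-based proxies, which we found unable to distinguish a
ring from a *thick* linear thread — parallel read paths give high cycle rank
without any global cycle, whereas the eccentricity profile is flat only on
genuinely circular structures.

Structural variants are quantified by read counting in graph branches:
`subset_read_fraction()` takes the reads on a designated branch (e.g. spanning
a deletion junction) and divides by the reads covering the same region — the
branch plus its designated alternative when one is supplied, the whole cluster
otherwise. Both denominators are offered because either convention is
defensible; the branch-vs-branch form is the one whose expectation equals the
variant copy fraction.

Annotation, when a repeat library is supplied, reuses the same aligner at
relaxed stringency (identity $\ge$ 0.7 over $\ge$ 0.3 of the *read*, word
size 12), because library consensus sequences diverge from genomic copies;
a cluster is labeled by the class hitting most of its reads, or `NA` below
10% labeled reads.

The 3D Fruchterman-Reingold layout (via igraph, attraction scaled by edge
weight normalized to the subgraph maximum) is provided for figures and
coordinate export; all quantitative claims in the package rest on graph
statistics, never on visual layout.

## The simulator: what it emulates, and what it does not

`simulate_genome()` + `sample_reads()` generate the study conditions every
end-to-end test runs under: tandem satellite arrays (independently diverged
monomer copies), dispersed LTR-retrotransposon-like elements (identical
terminal repeats within a copy, optional internal-deletion subpopulations at
specified copy fractions), rDNA-like conserved tandem units, and i.i.d.
uniform background; reads are drawn uniformly over positions and strands at a
fixed length with i.i.d. substitution errors, and every read carries a truth
record (family, copy, variant, coordinates, strand).

The reference scenario (`default_repeat_families()`) places a 50 bp-monomer
satellite at 8%, a 510 bp-monomer satellite at 6% and a 5 kb LTR-like element
at 4% of a 2 Mb genome, sampled at 0.1x with 100 nt reads and 1% error —
copy divergence 2% (1% for the younger LTR family), values typical of plant
satellite families and young retrotransposon families. At these settings
pairwise within-family identities (~94-96%) sit clearly above the 90%
admission floor, so recovery tests exercise the clustering, not the aligner's
sensitivity limit. A useful closed form: a background read acquires a
qualifying neighbour at rate $2 \cdot 45 \cdot c/L$ per nt (offset $\le 45$ of
a 100 nt read at coverage $c$), so at 0.1x about 91% of background reads are
expected to remain singlets — the property tests assert this pooled across
seeds because the per-seed value sits within sampling noise of the bound.

The variant-quantification scenario (`deletion_variant_families()`) uses 2400
copies of a 5 kb element, 13% of them carrying a 500 nt deletion, sampled at
0.5x: sized so that roughly 700 reads span the breakpoint, putting the
binomial standard error of the recovered fraction near 0.012.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: homopolymer indel errors (a substitution-only model
suffices to exercise identity-based admission; an indel mode exists in the
error model's future-work list), read-length distributions (fixed length by
default), nested insertions, paralogous subfamily phylogenies, and library
contamination. Real 454 datasets also carry orders of magnitude more reads;
the package's graph sizes here are desk-scale by design, and the problem
sizes stated above (2 Mb / 2,000 reads; 13 Mb / 65,000 reads for the variant
scenario) are the ones the shipped tests and the acceptance script run at.

## Numerical and degenerate-input conventions

Modularity bookkeeping is validated two ways: the per-community form
$\sum_c (l_c/m - (d_c/2m)^2)$ against the literal double sum (tolerance
1e-12), and the incremental $Q$ after every greedy merge against from-scratch
recomputation (1e-10). Dendrogram $Q$ ties use a 1e-12 window. Degenerate
inputs follow explicit contracts: empty read sets, edgeless graphs and
disconnected subgraphs passed to diameter/agglomeration raise errors;
single-vertex subgraphs report density 0 with a warning and lay out at the
origin; duplicate admitted pairs collapse to one edge keeping the maximum
weight; zero-length reads and duplicate ids are parse errors naming the
offending record.

## Known limitations

Exact all-pairs BFS diameters and $O(n^2)$ layout repulsion are fine at
desk scale but not at millions of reads; the agglomeration's sparse
$\Delta Q$ structure is the only stage engineered for large graphs. Shape
thresholds are heuristics tuned to separate clear exemplars and will
misclassify intermediate topologies (a dense, well-covered long-monomer ring
can satisfy the satellite rule first). Genome-proportion estimates inherit
the usual caveat that duplicate-read removal and cluster admission both
slightly deflate highly identical families.
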