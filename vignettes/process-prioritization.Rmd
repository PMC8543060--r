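---
title: "Methods: network-based prioritization of biological processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based prioritization of biological processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agnet)
```

## The model

An associative gene network pipeline asks: *given everything a knowledge
base records about a biological process — which other processes plug into
the same molecular machinery?* The data structure is a heterogeneous
knowledge graph: vertices are typed (gene, protein, metabolite, microRNA,
process, trait, disease), edges carry a relation label and a provenance tag
(text-mined literature vs. factual database). `agnet` treats all edges as
undirected for connectivity purposes: the prioritization score below counts
*connections*, not directions, so relation directionality is retained only
as a label. Self-loops are rejected at load time — a vertex's score should
reflect links *to other vertices* — and parallel edges between the same pair
(different relation types) count once for connectivity, because the link
count is defined over vertices, not edge records. This distinct-neighbour
convention is a deliberate choice; the alternative (counting each relation
type separately) would make the score depend on how finely a curation
pipeline splits relation vocabulary.

**Reconstruction.** The network of a seed process consists of every
gene/protein vertex directly adjacent to it (any relation type, optionally
filtered by provenance), plus all retained graph edges among those members.
There is no multi-hop expansion. Members are restricted to the kinds `gene`
and `protein`; other entity kinds and process vertices never become members
— processes enter only as scored candidates. Gene and protein vertices for
the same locus are *not* merged: no id-mapping rule is assumed, so a
knowledge graph that distinguishes them will count them separately.

**Cross-talk centrality.** For a network with `M` members, candidate `i`
scores `CTC_i = N_i / M`, where `N_i` is the number of distinct members
adjacent to `i` in the knowledge graph. `N_i` is the candidate's degree
centrality restricted to the network; dividing by `M` makes scores
comparable across networks of different size. Although the degree-centrality
view is usually presented for the network's own vertices, the pipeline
scores *any* process vertex against the `M` members — the seed itself
trivially scores 1, so it is usually excluded from the candidate list.

**Significance.** The null model is sampling `M` genes without replacement
from the `N_U` annotated genes of the knowledge base; a candidate with `K`
annotated genes then has a hypergeometric number of members by chance, and
the reported p-value is the inclusive upper tail `P(X >= N_i)`. The sampling
frame is a modelling decision, since "annotated universe" is not uniquely
defined: `agnet` takes `N_U` = distinct gene/protein vertices with at least
one process link anywhere in the graph and `K` = the candidate's distinct
gene/protein neighbours; both are overridable through the `universe`
argument of `prioritize()`. Candidates with `K = 0` are skipped rather than
given p = 1: a process with no annotated genes cannot be drawn into any
network, so a "test" of it is meaningless. Because candidate processes share
network genes, their p-values are dependent in an unstructured way;
q-values therefore use Benjamini–Yekutieli (valid under arbitrary
dependence, at the price of the harmonic factor `c(m)`), applied across
*all* scored candidates of one run, not only the eventually significant
ones. The significance filter is strict (`q < alpha`), with `alpha` in
(0, 1] and 0.05 the conventional default; note a q-value of exactly 1 is
never significant, at any alpha.

**Ranking.** Candidates are ordered by CTC descending, ties broken by
q-value ascending, then id lexicographically. The tie-break is a convention
(any fixed one gives deterministic, reproducible tables); breaking CTC ties
by significance puts the better-supported process first.

## Semantic clustering

Significant processes are grouped by what they *mean*, not how they link:
pairwise Wang similarity over the ontology DAG, then Markov clustering.

The Wang measure assigns each term an S-value map over `{term} ∪
ancestors`: the term itself contributes 1, and an ancestor contributes the
maximum over paths of the product of per-edge weights (`w_is_a = 0.8`,
`w_part_of = 0.6`, the measure's standard constants; both configurable).
Similarity of two terms is the sum of both terms' S-values over their
*common* ancestors, normalised by the two S-value totals — 1 for identical
terms, 0 for terms sharing no ancestor. The implementation is dynamic
programming over a topological order of the ancestor subgraph; an
exhaustive path-enumeration oracle in the test suite confirms the DP on
small DAGs. Similarity is computed on the significant set only (the set
being characterised), not on all candidate pairs. Processes present in the
knowledge graph but missing from the ontology release get similarity 0 to
everything, with a warning — dictionary and ontology versions drift in
practice and that should degrade, not crash, a run.

MCL runs on the full weighted similarity matrix: column-normalise (the unit
diagonal is the self-loop, weight configurable), then iterate expansion
(matrix square by default) and inflation (element-wise power 2.0 followed by
column renormalisation), pruning entries below 1e-5, until the iterate
changes by less than 1e-8 or 200 iterations elapse (non-convergence warns
and clusters the last iterate; with these defaults it converges in well
under 50 iterations on every matrix the suite generates). No hard similarity
threshold is applied by default — Wang similarities already live in [0, 1]
and a threshold would add an unstated parameter — but `sim_threshold` exists
for sparsification. Attractors (nodes retaining diagonal mass) define
clusters; overlapping attractor systems merge; a node left unattached joins
its most similar already-clustered neighbour or becomes a singleton. Labels
are renumbered 1..k by first appearance, so the output is deterministic and
permutation-equivariant (permuting the input permutes the partition, not
its structure). Zero between-block similarity can never be bridged by
expansion, so disconnected similarity components are structurally guaranteed
separate clusters.

Cluster *counts* on real data depend on the inflation parameter and on the
similarity structure of whatever ontology release is used; they are
descriptive output, not a validated quantity.

## Multi-condition comparison

`compare_networks()` takes two or more rankings, derives each condition's
significant set at a shared alpha, and reports: the intersection of all
sets (`common_all`), every pairwise intersection, and each condition's
*specific* set — significant in exactly that condition. Specific sets are
by construction pairwise disjoint and disjoint from the common core.
Matching is by term id, never by name string.

## The synthetic-data generator

`make_knowledge_graph()` emulates the regime such pipelines operate in:

- a designated seed process annotated to a fraction (default 0.9) of the
  `n_genes` network-eligible genes;
- planted candidate processes linked to the seed's members by Bernoulli
  draws at a target fraction (`planted_ctc`) — the known signal;
- decoy processes linked to every gene at a background rate (default 0.05);
- gene–gene interaction edges at 0.02 per pair;
- crucially, `n_background_genes` (default 200) annotated genes *outside*
  the seed network, receiving decoy annotations only. Real knowledge bases
  are genome-scale: a reconstructed network of a few hundred members sits
  inside an annotated universe of thousands, and the upper-tail
  hypergeometric is only informative in that `M << N_U` regime. With no
  background universe (`M ≈ N_U`) even a candidate linked to 80 % of the
  members is unremarkable — the draw nearly exhausts the urn — and the
  q-value correctly refuses to flag it. The default of 200 (universe
  roughly 3x the network) is a deliberately conservative stand-in for that
  ratio; the planted-recovery study below is insensitive to it once the
  universe is a few times the network.

`make_comparison_fixture()` adds the multi-condition structure: each
condition owns exclusive genes (default 40) plus a shared block (default
20); common planted processes link to every condition's genes, specific
ones only to one condition's *exclusive* genes (so they cannot leak into
another network through the shared block), decoys to everything, and a
catch-all process annotates the background pool.

One integer seeds a single RNG stream per fixture (`withr::with_seed`), and
all serialisations are canonically ordered, so identical seeds give
byte-identical files.

What the generator does **not** emulate: literature-mining noise (spurious
or missing edges correlated with publication volume), scale-free degree
structure, correlated annotations between semantically related processes,
or realistic ontology topology. Passing tests therefore demonstrate the
statistical machinery is correct and the planted signal is recoverable
under clean conditions — not that any particular biological ranking is
right.

## Numerical and design notes

- Hypergeometric tails come from `stats::phyper(..., lower.tail = FALSE)`
  (inclusive upper tail via `N_i - 1`); BY from `stats::p.adjust`. Both are
  cross-checked in the tests against exhaustive enumeration and a
  from-definition step-up implementation, respectively.
- Degenerate inputs: an empty candidate list, an empty network (`M = 0`),
  fewer than two comparison conditions, and a cyclic ontology are hard
  errors; an over-strict provenance filter that empties a network reports
  exactly that.
- Duplicate knowledge-graph records collapse to one edge; conflicting kind
  declarations keep the first and warn; unknown kinds map to `other`.
- All CLI outputs are written to a temp file and atomically renamed, so an
  interrupted run leaves no partial file.
- Study sizes used by the test suite and the acceptance script — 200 random
  graphs of up to 50 genes for the CTC oracle, every sampling frame up to
  `N_U = 12` for the hypergeometric enumeration, 1,000 random p-vectors of
  length up to 200 for BY, DAGs of up to 30 (properties) / 15 (path-
  enumeration oracle) terms for Wang, 20-node planted 3-block matrices for
  MCL, and 100 seeded replicates of the 100-gene planted-signal study —
  are the package's chosen benchmark sizes: small enough to enumerate
  exhaustively where an oracle demands it, large enough that the stochastic
  checks are stable across seeds.

## Limitations

- Only direct seed neighbours form a network; diffusion or multi-hop
  variants are out of scope.
- The universe specification materially affects p-values; users comparing
  against other enrichment tools should align frames before comparing
  q-values.
- MCL cluster counts are parameter-sensitive; treat them as exploratory
  structure, not inference.
- No information-content similarities (Resnik/Lin) and no
  molecular-function/cellular-component namespaces unless terms from them
  are passed explicitly.
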