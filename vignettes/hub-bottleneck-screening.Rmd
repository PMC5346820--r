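---
title: "Hub–bottleneck screening of PPI networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-bottleneck screening of PPI networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppipanel)
```

## The procedure

`ppipanel` implements the interactome screening route to a candidate
protein panel. The input is an exported, evidence-scored interaction table
(a STRING-style TSV) over a fixed gene universe for a disease of interest.
The pipeline is:

1. **Filter.** Keep interactions with confidence score ≥ `score_cutoff`
   (default 0.5), drop self-loops, collapse duplicate unordered pairs
   keeping the maximum score. The score is used only for inclusion: the
   analyzed graph is undirected, simple and unweighted, so all distances
   are hop counts. The node set is the supplied universe, which is why
   genes with no surviving interaction remain visible as isolated nodes —
   the component decomposition (isolated / pairs / main component) is part
   of the result, not an artifact to discard.
2. **Centralities.** Degree K, betweenness BC and closeness CC per node.
3. **Screen.** The `top_k = 20` highest-degree nodes are hubs; hubs with
   K ≥ 60 and BC ≥ 0.03 (both inclusive) are hub–bottlenecks. The panel
   subnetwork is the subgraph induced on them.
4. **Enrich.** Hypergeometric enrichment of the panel against a GMT term
   collection with attribution-percentage and minimum-gene filters, kappa
   grouping, and a deterministic group-naming rule.

## Centrality definitions and numerics

Betweenness sums, over all node pairs excluding the focal node, the
fraction of shortest paths passing through it as an *interior* vertex
(endpoints never count). It is computed by dependency accumulation over the
BFS geodesic DAG — one BFS per source, accumulating
δ(v) = Σ_{w: v ∈ pred(w)} σ(v)/σ(w) · (1 + δ(w)) in reverse BFS order —
never by explicit path enumeration; enumeration appears only as the
independent oracle in the test suite, where both routes agree to
well below 1e−9 on random graphs of up to 25 nodes. All quantities are
ratios of small integers, so the package's own tests compare at absolute
tolerance 1e−9 or tighter.

Normalization divides by (N−1)(N−2)/2, the number of pairs a node can lie
between. `scope = "component"` (the default) takes N as the size of the
node's own connected component; this matches how network-analyzer tools
report BC when the object of interest is a main connected component, and
it is the convention under which the documented [0,1] bounds hold
regardless of how many isolated nodes the universe contributes. Whole-graph
normalization is available for comparison (`scope = "graph"`). Components
with fewer than three nodes get BC = 0.

Closeness is per-component: CC(v) = (m−1)/Σ d(v,u) within a component of
size m ≥ 2, and 0 for isolated nodes. The phrase "paths that pass through
a node" in informal statements of closeness is read as the standard
definition (paths *from* the node); the harmonic variant is out of scope.
Under these conventions adding isolated nodes perturbs nobody else's K, BC
or CC — a property the test suite checks directly.

Determinism everywhere comes from sorted node labels, not seeds: rerunning
the pipeline on the same inputs is byte-identical.

## Ordering and tie-breaking

The centrality table is sorted by degree descending, ties broken by BC
descending then name ascending. The screening functions, however,
*preserve the row order of the table they are given*: when the input is a
published, printed table, its printed order is authoritative, and
re-sorting tied rows by a different secondary key would silently permute
it. `select_hubs()` therefore stably takes the first `top_k` rows of a
degree-sorted table, and applies the BC-then-name tie-break only inside a
tied degree group that straddles the top-k boundary, where some
deterministic rule is unavoidable (none is prescribed by convention, so
this one is flagged here as an implementation decision). Threshold
comparisons in `select_hub_bottlenecks()` are inclusive (≥) — forced by
the reference panel, where one member passes at BC exactly equal to the
0.03 threshold on the printed two-decimal value.

Both routes — a printed table with rounded centralities, and the
full-precision table computed end-to-end — flow through the same screening
code, with the table as the interface.

## Enrichment

The test is the right-tailed hypergeometric: with k of the term's K genes
in a query of n genes drawn from a background of N,
p = P(X ≥ k). It is evaluated through the hypergeometric tail in
`stats::phyper`, which works in log space internally; the test suite
checks it against a direct combinatorial sum for every parameter set with
N ≤ 30 and against exhaustive enumeration of all C(N, n) draws at tiny N.
Filters follow the ClueGO conventions: category presets of ≥ 4 genes and
≥ 4% attribution for pathways, ≥ 2 genes and ≥ 3% for molecular functions
(where sources disagree on the MF percentage, the methods-level statement
of 3% is taken), with attribution = 100·k/K computed on the term's genes
within the background. The p < 0.001 bound is applied to *raw* p-values by
default because that is what the reference procedure reports;
Benjamini–Hochberg is available behind `p_adjust = "BH"` rather than being
switched on silently.

Two open choices are parameterized rather than guessed. The background
universe is never stated in the reference procedure; the default is the
union of all term genes (the conventional fallback), and every analysis in
this package passes the background explicitly. The grouping criterion
("similar enrichments") is likewise unspecified; the package uses Cohen's
kappa between hit-membership indicator vectors over the query, merging
pairs with kappa ≥ 0.4 (ClueGO's documented default) by single linkage.
Saturated identical vectors get kappa 1 by convention (the chance-agreement
denominator vanishes there). Groups are named after the member with the
most hits, ties broken by higher attribution percentage, then
lexicographically — the published naming rule plus a final deterministic
tie-break.

## What the synthetic generator emulates

`synthetic_spec()` encodes the study conditions the pipeline is validated
under. Defaults: 200 genes, of which 57 stay isolated and 2 form a pair,
leaving a 141-node main component — the decomposition of the reference
network. The main component is built constructively (never
rejection-sampled, so the requested counts hold exactly and generation is
fast and non-flaky): three communities of ~46 nodes, each a random
spanning tree (guaranteeing connectivity) plus independent edges at
`intra_edge_prob = 0.15`; two planted intra-community hubs wired to degree
35; and two planted bridge nodes, each attached to 20 members of its two
flanking communities and constituting the *only* connection between them.
Retained-edge scores are Uniform(0.5, 1); 300 decoy records score below
the cutoff and must vanish at the filter step, and a few above-cutoff
self-loops exercise self-loop removal.

The planted parameters create a three-regime degree/betweenness structure
with wide margins:

* background nodes: degree ≈ 8 (rarely above ~18), BC small;
* intra-community hubs: degree ≥ 35, but BC bounded by their community's
  share of pairs (≲ 0.11);
* bridges: degree ≈ 40 and BC ≥ 0.44 *structurally* — a bridge separates
  its ~47-node community from the remaining ~92 main-component nodes, so
  47·92 pair geodesics are forced through it out of 140·139/2.

The planted screen thresholds reported in the ground truth
(`degree_min = 25`, `bc_min = 0.30`) sit between those regimes, so the
dual-threshold screen recovers exactly the planted bridges; the recovery
rate across seeds is one of the quantities `scripts/acceptance.R`
recomputes. The generator makes no attempt to match a real STRING degree
distribution — it targets the structural features the screen keys on
(heavy right tail, cut-vertex bottlenecks, exact component counts), which
is also what passing tests do and do not certify about real exports.
Real networks add correlated evidence scores, overlapping communities and
bottlenecks that are not clean cut vertices; on such data the screen still
runs, but no ground truth exists to score it against.

Annotation generation plants one term containing 6 of the 7 query genes in
a 30-gene term over a ~200-gene background (p ≈ 5·10⁻⁵, attribution 20%),
against 200 background terms of 10–60 uniformly drawn genes; planted
signals survive the pathway filters by construction while background terms
pass only at the false-positive rate of the exact test.

## Problem sizes and run times

The validation suite runs at deliberately small scale: betweenness
oracle-equivalence on graphs of ≤ 25 nodes (where exhaustive geodesic
enumeration is exact and quick), recovery studies over 20 seeds of the
200-node generator, and enrichment false-positive accounting over 20 × 200
background terms. These sizes give binomially tight checks (e.g. a ≥ 19/20
recovery criterion) while keeping the whole suite in the minutes range on
one CPU; the pipeline itself is O(V·E) per centrality pass and handles the
141-node main component in about two seconds in pure R.

## Known limitations

* Distances are unweighted hop counts; weighted or directed variants of
  the centralities are out of scope by design.
* Printed centrality tables carry two-decimal values; screening on them
  reproduces published panels, but recomputing the underlying floats
  requires the original database snapshot, which no implementation can
  recover.
* Enrichment results depend entirely on the supplied GMT snapshot; the
  package ships no ontology data.
* Grouping is single-linkage on pairwise kappa: long similarity chains can
  merge dissimilar terms, which is inherent to the clustering rule rather
  than a defect of the implementation.
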