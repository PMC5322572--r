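---
title: "Network fingerprints: model, parameters and design choices"
author: "netFingerprint maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network fingerprints: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biological interaction networks — pathway maps, protein–protein interaction
subgraphs, regulatory modules — are hard to compare directly: purely
topological measures ignore what the genes do, and purely annotation-based
measures ignore how they are wired. The network fingerprint places a query
network in a common coordinate system: a curated set of well-studied
*basic networks* $P = (P_1, \dots, P_n)$ (in practice, pathway maps grouped
into a handful of categories). The query $G$ becomes the vector
$S = (s_1, \dots, s_n)$ with $s_i = \mathrm{sim}(G, P_i)$, a spectrum-like
profile that can be ranked, plotted and compared across queries.

## The similarity model

Each coordinate is computed in three stages.

**Merging.** $G_1 = \{V_1, E_1\}$ and $G_2 = \{V_2, E_2\}$ are pooled into
$G_m = (V_1 \cup V_2,\; E_1 \cup E_2)$: nodes with the same gene identifier
collapse into one node inheriting all interactions, and duplicate edges
collapse into one. Every merged node carries a provenance label — only in
$G_1$, only in $G_2$, or shared.

**Semantic weighting and clustering.** Gene pairs are weighted with Resnik
semantic similarity derived from Gene Ontology annotations: for terms,
$\mathrm{sim}(t_1, t_2) = \mathrm{IC}(\mathrm{MICA}(t_1, t_2))$ where
$\mathrm{IC}(t) = -\ln\big(n_t / n_\mathrm{root}\big)$ is computed from the
annotation corpus itself after ancestor closure, and MICA is the most
informative common ancestor. Gene-level similarity lifts term similarity
over the two genes' term sets, either as a plain maximum (the default) or
as a bidirectional best-match average (`combine = "bma"`); the printed form
of the source equations is ambiguous on this point, so both are available.
Affinity propagation (AP) then groups the merged nodes. AP runs on the
**semantically weighted adjacency** of $G_m$ — semantic similarity on merged
edges, zero elsewhere — so the partition reflects both wiring and function.
This choice is load-bearing: the node labels, provenance and full semantic
matrix are all invariant under edge rewiring, so if AP instead consumed the
all-pairs semantic matrix, the degree-preserving null below would be
degenerate (every randomized draw would reproduce the observed score
exactly, and no standardization would be possible). Weighting the adjacency
is also what makes the merged network's topology enter the score at all.

**Cluster scoring.** For cluster $k$, let $V_k^1$ be its members present
only in $G_1$ and $V_k^2$ those present only in $G_2$ (shared nodes are
excluded from both sides by default; the `sharedOnBothSides` flag counts
them on both). The local score is the bidirectional best-match average

$$
LS_k = \frac{\sum_{i \in V_k^1} \max_{j \in V_k^2} S_m(i,j)
       + \sum_{j \in V_k^2} \max_{i \in V_k^1} S_m(i,j)}
       {n(V_k^1) + n(V_k^2)},
$$

where $S_m$ here is the *full* semantic similarity between cluster members,
regardless of adjacency — a cluster rewards cross-network functional
correspondence wherever AP has placed the nodes. A cluster with an empty
side scores 0 and still counts in the mean (it marks missing cross-network
correspondence; `skipOneSided` excludes such clusters instead). The global,
raw similarity is the arithmetic mean of $LS_k$ over all clusters. A direct
consequence: a network merged with itself has every node shared, all
only-sides empty, and raw score exactly 0 — the score measures
correspondence between the *distinct* parts of the two networks, bridged by
what they share.

**Standardization.** Raw scores depend on network size and degree structure.
Each coordinate is therefore z-scored against a null distribution obtained
by Maslov–Sneppen degree-preserving rewiring: repeated double-edge swaps
that conserve the node set and every node's degree while destroying the
correlation between wiring and function. Node labels (hence annotations and
the semantic matrix) are untouched; only the wiring is randomized, and by
default both the query and the reference are rewired each draw (the
`rewireMode` flag restricts rewiring to one side; which side the original
procedure rewired is not recoverable, so it is exposed rather than guessed).
With observed score $s$ and null scores $s^{(1)}, \dots, s^{(B)}$,
$z = (s - \bar{s}) / \hat{\sigma}$ using the sample standard deviation. A
zero-spread null returns 0 at the mean and a signed-infinity sentinel
otherwise.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nperm` | 100 | randomized networks per coordinate; the dominant cost, raise for tighter z-scores |
| `swapsPerEdge` | 10 | swap attempts per edge per draw (conventional mixing heuristic) |
| `combine` | `"max"` | gene-level term-set combiner (`"bma"` alternative) |
| `preference` | `"median"` | AP preference; median off-diagonal similarity of the matrix AP receives |
| `damping` | 0.9 | AP message damping in [0.5, 1) |
| `maxIter`, `convIter` | 1000, 50 | AP sweep budget and stability window |
| `rewireMode` | `"both"` | which side the null rewires |
| `namespace` | biological_process | ontology namespace; BP term similarity is the best-validated choice for this task |

Information content uses natural logarithms throughout and the annotation
file itself as the corpus (after ancestor closure), keeping the pipeline
self-contained with no external frequency tables. `part_of` relationships
count as parent edges by default (toggleable), all evidence codes are
accepted by default (an exclusion list, e.g. `"IEA"`, is available), and
unannotated genes score 0 rather than being dropped, which keeps the node
set aligned with the topology; their count is logged.

## Numerical and degeneracy choices

Node order is sorted lexicographically before any matrix is built, and AP
ties break toward the lowest index, so results are permutation-invariant
and bitwise reproducible at a fixed seed. AP adds a seeded jitter of
relative magnitude 1e-12 to break exact ties (skipped for an all-zero
input, whose natural fixed point — every node its own exemplar — is
reported via the component fallback). When message passing finds no stable
exemplar set within `maxIter` sweeps, the partition falls back to connected
components of the positive-similarity graph with a logged note. The master
seed is split into per-permutation streams, so enlarging `nperm` never
perturbs earlier draws. Networks with fewer than two edges cannot be
rewired and are returned unchanged with a warning.

## What the synthetic generator emulates

The package is developed and tested entirely offline against generated
fixtures, so the generator defines the study conditions:

* `makeToyOntology`: single-root random-attachment DAGs with a configurable
  number of disjoint top-level branches and guaranteed depth ≥ 3 from 15
  terms up — enough structure for informative MICA lookups.
* `makeAnnotations`: leaf-biased term draws, mimicking the fact that
  curators annotate to specific terms more often than to general ones.
* `makeNetworkPair` / `makeRefsetScenario`: networks with planted functional
  modules — dense within-module wiring (p = 0.85) against a sparse
  background (p = 0.08), each module annotated from one ontology
  sub-branch. *Related* networks share nodes and module anchors from a
  common top-level branch; *unrelated* ones use disjoint branches, whose
  cross-branch Resnik similarity is exactly 0 (the MICA is the root).

The acceptance scenario uses 12-node networks in 3 modules of 4, with the
related reference sharing 6 of the query's 12 nodes — two bridge nodes per
module, the regime of closely related pathway maps, which commonly share
around half their genes. Two bridges per module were chosen because a
single bridge makes mixed query/reference clusters depend on one exemplar
choice, which is exactly the instability the method is *not* trying to
measure. Problem sizes (53-term ontology, ≤ 24-node merges, `nperm = 100`,
5 scenario seeds) keep a full acceptance run in the minutes range on one
CPU; they were chosen as the smallest sizes at which the planted signal is
unambiguous.

What passing these tests does *not* show: real pathway maps are larger,
scale-free-ish rather than modular-Bernoulli, annotated with correlated
evidence (not independent draws), and their identifier spaces require
mapping layers this package deliberately omits (node identity is exact
string equality). The fixtures validate the machinery and its statistical
logic, not biological effect sizes; fingerprint values on real data carry
the stochastic variability of the rewiring null, so repeated runs differ
slightly unless the seed is pinned.

## Known limitations

* Standardization dominates runtime — each coordinate costs `nperm + 1`
  merge/cluster/score evaluations. The per-pair semantic matrix is computed
  once and shared across all rewired draws (labels are wiring-invariant),
  which is the main optimization.
* Edge direction and weights are discarded: the merge-and-score machinery
  is defined over unordered node pairs.
* Infinite z-scores (zero-spread nulls) are reported as sentinels, not
  suppressed; they typically indicate a reference with no semantic overlap
  with the query.
* No live pathway-database client is included; reference sets are loaded
  from files via a manifest, which keeps runs reproducible and testable.
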