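# netFingerprint

Network fingerprints for annotated biological networks.

## What problem this solves

Biological networks — pathway maps, protein–protein interaction subgraphs,
disease modules — accumulate faster than they can be interpreted, and
comparing them is awkward: topological indices ignore gene function, while
annotation-overlap statistics ignore wiring. `netFingerprint`
characterizes a query network by systematic comparison against a reference
set of well-studied *basic networks* (e.g. curated pathway maps, grouped
into categories). Given references `P = (P1, …, Pn)`, the query `G`
becomes the spectrum-like vector

```
S = (s1, …, sn),   si = sim(G, Pi)
```

where each coordinate combines functional and topological evidence:

1. **Merge** `G` and `Pi` by gene name: `Gm = (V1 ∪ V2, E1 ∪ E2)`, with
   per-node provenance (only-query / only-reference / shared).
2. **Weight** node pairs with Resnik semantic similarity
   (`IC(t) = −ln(n_t / n_root)` from ancestor-closed Gene Ontology
   annotations; gene-level similarity via max or best-match-average over
   term sets), and **cluster** the merged nodes with affinity propagation
   on the semantically weighted adjacency.
3. **Score** each cluster `k` by the bidirectional best-match average
   between its query-only and reference-only members,

   `LSk = [ Σ_{i∈Vk1} max_{j∈Vk2} Sm(i,j) + Σ_{j∈Vk2} max_{i∈Vk1} Sm(i,j) ] / (n(Vk1)+n(Vk2))`,

   average over clusters (the raw score), and **standardize** against a
   null of Maslov–Sneppen degree-preserving rewirings:
   `si = (raw − mean(null)) / sd(null)`, with `nperm = 100` draws by
   default.

The package ships readers/writers for OBO ontologies, GAF 2.x annotations,
edge-list / GraphML / KGML-subset network files, grouped reference-set
management with a manifest format, fingerprint export/comparison/plot
tables, and a synthetic-fixture generator (`makeToyOntology`,
`makeAnnotations`, `makeNetworkPair`, `makeRefsetScenario`) so the entire
pipeline runs and is tested fully offline.

## Worked example

```r
library(netFingerprint)

## a self-contained scenario: toy ontology + annotations, a 12-node query,
## and 4 reference networks of which exactly one ("R1") is planted as
## related (shares half the query's nodes and its ontology branch)
sc <- makeRefsetScenario(seed = 1)
fp <- calcFingerprint(sc$query, sc$refset, sc$ontology, nperm = 100, seed = 1)
fpTable(fp)
```

```
       group name      raw null_mean   null_sd standardized n_clusters
1  signaling   R1 2.606642 0.9144012 0.5434483     3.113896          3
2  signaling   R2 0.000000 0.0000000 0.0000000     0.000000          6
3 metabolism   R3 0.000000 0.0000000 0.0000000     0.000000          6
4 metabolism   R4 0.000000 0.0000000 0.0000000     0.000000          6
```

The planted related reference `R1` stands out at `z ≈ 3.1`: its observed
merge scores 2.61 while degree-preserving rewiring of both networks yields
only 0.91 ± 0.54 — the wiring-function correlation is real signal, not a
size effect. The unrelated references share no genes and sit on disjoint
ontology branches, so raw and null scores are exactly 0 and their
coordinates standardize to 0. `topFraction(fp, 0.1)` returns the top
decile of coordinates, `plotData(fp)`/`plotFingerprint(fp)` produce the
group-colored overview, and `compareFingerprints()` contrasts several
queries over one reference set.

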