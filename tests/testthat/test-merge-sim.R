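## Merging, semantic weighting and cluster-wise similarity scoring.

test_that("merging follows union semantics with provenance", {
  g <- bioNetwork("g", edges = cbind(c("a", "b"), c("b", "c")))
  self <- mergeNetworks(g, g)
  expect_identical(mergedOrder(self), c("a", "b", "c"))
  expect_identical(networkEdges(mergedNetwork(self)), networkEdges(g))
  expect_true(all(mergedProvenance(self) == "shared"))

  h <- bioNetwork("h", edges = cbind("x", "y"))
  disjoint <- mergeNetworks(g, h)
  expect_identical(length(mergedOrder(disjoint)), 5L)
  expect_false(any(mergedProvenance(disjoint) == "shared"))
  expect_error(mergeNetworks(g, bioNetwork("empty")), "empty")
})

test_that("merge size obeys inclusion-exclusion and provenance matches the planted overlap", {
  toy <- makeToyOntology(nTerms = 30L, seed = 4L)
  for (seed in 1:6) {
    frac <- c(0, 0.3, 0.5, 0.8, 1, 0.25)[seed]
    pair <- makeNetworkPair(10L, 12L, frac, TRUE, toy$dag, seed = seed)
    m <- mergeNetworks(pair$g1, pair$g2)
    v1 <- networkNodes(pair$g1)
    v2 <- networkNodes(pair$g2)
    expect_identical(length(mergedOrder(m)),
                     length(v1) + length(v2) - length(intersect(v1, v2)))
    expect_setequal(names(mergedProvenance(m))[mergedProvenance(m) == "shared"],
                    pair$ledger$shared)
  }
})

test_that("merge commutes up to provenance relabeling", {
  toy <- makeToyOntology(nTerms = 25L, seed = 9L)
  pair <- makeNetworkPair(9L, 11L, 0.4, TRUE, toy$dag, seed = 2L)
  ab <- mergeNetworks(pair$g1, pair$g2)
  ba <- mergeNetworks(pair$g2, pair$g1)
  expect_identical(mergedOrder(ab), mergedOrder(ba))
  expect_identical(networkEdges(mergedNetwork(ab)), networkEdges(mergedNetwork(ba)))
  swap <- c(only_g1 = "only_g2", only_g2 = "only_g1", shared = "shared")
  expect_identical(unname(swap[mergedProvenance(ab)]),
                   unname(mergedProvenance(ba)))
})

test_that("semantic matrices equal element-wise gene similarity, both combiners", {
  for (seed in 21:23) {
    inst <- randomInstance(seed, n1 = 6L, n2 = 6L)
    m <- mergeNetworks(inst$pair$g1, inst$pair$g2)
    for (combine in c("max", "bma")) {
      S <- simValues(semanticMatrix(m, inst$ont, combine = combine))
      expect_identical(rownames(S), mergedOrder(m))
      expect_equal(S, t(S), tolerance = 1e-12)
      closed <- geneTerms(inst$ont@annotations)
      for (i in mergedOrder(m)) {
        for (j in mergedOrder(m)) {
          expect_equal(S[i, j],
                       oracleGeneSim(inst$parents, icValues(inst$ont@ic),
                                     closed, i, j, combine = combine),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("unannotated merges give a zero semantic matrix", {
  dag <- ontologyDAG(list(r = character(0), a = "r"))
  ann <- closeAnnotations(dag, annotationTable(list(zz = "a")))
  ont <- ontologySet(dag, ann)
  g <- bioNetwork("g", edges = cbind("n1", "n2"))
  h <- bioNetwork("h", edges = cbind("n2", "n3"))
  m <- mergeNetworks(g, h)
  expect_message(S <- semanticMatrix(m, ont), "unannotated")
  expect_true(all(simValues(S) == 0))
})

test_that("local similarity has its closed forms and matches the double loop", {
  ## hand-built two-node cluster: LS = (s + s) / 2 = s
  nodes <- c("a", "b", "s1")
  S <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  S["a", "b"] <- S["b", "a"] <- 2
  sim <- new("SemanticMatrix", values = S, combine = "max")
  merged <- new("MergedNetwork",
                network = bioNetwork("m", nodes = nodes),
                provenance = c(a = "only_g1", b = "only_g2", s1 = "shared"),
                order = nodes)
  oneCluster <- new("ClusterAssignment",
                    labels = c(a = 1L, b = 1L, s1 = 2L),
                    exemplars = c("a", "s1"), nClusters = 2L, converged = TRUE)
  expect_identical(localSimilarity(1L, oneCluster, sim, merged), 2)
  ## a cluster of shared-only nodes has both sides empty
  expect_identical(localSimilarity(2L, oneCluster, sim, merged), 0)
  expect_error(localSimilarity(5L, oneCluster, sim, merged), "unknown cluster")
  ## counting shared nodes on both sides activates the s1 cluster diagonal-free
  expect_identical(
    localSimilarity(2L, oneCluster, sim, merged, sharedOnBothSides = TRUE),
    unname(S["s1", "s1"]))

  for (seed in 24:26) {
    inst <- randomInstance(seed, n1 = 8L, n2 = 8L, overlapFrac = 0.25)
    det <- rawSimilarity(inst$pair$g1, inst$pair$g2, inst$ont,
                         seed = seed, details = TRUE)
    Sv <- simValues(det$sim)
    prov <- mergedProvenance(det$merged)
    lab <- clusterLabels(det$clusters)
    ls <- vapply(seq_len(nClusters(det$clusters)), function(k) {
      localSimilarity(k, det$clusters, det$sim, det$merged)
    }, numeric(1))
    want <- vapply(seq_len(nClusters(det$clusters)), function(k) {
      oracleLocalSimilarity(names(lab)[lab == k], prov, Sv)
    }, numeric(1))
    expect_equal(ls, want, tolerance = 1e-12)
    expect_true(all(ls >= 0))
    ## global score is exactly the mean over clusters
    expect_equal(globalSimilarity(det$clusters, det$sim, det$merged),
                 mean(want), tolerance = 1e-12)
    expect_equal(det$score, mean(want), tolerance = 1e-12)
  }
})

test_that("global similarity averages local scores and can skip one-sided clusters", {
  nodes <- c("a", "b", "c", "d")
  S <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  S["a", "b"] <- S["b", "a"] <- 1
  S["c", "d"] <- S["d", "c"] <- 3
  sim <- new("SemanticMatrix", values = S, combine = "max")
  merged <- new("MergedNetwork",
                network = bioNetwork("m", nodes = nodes),
                provenance = c(a = "only_g1", b = "only_g2",
                               c = "only_g1", d = "only_g2"),
                order = nodes)
  cl <- new("ClusterAssignment", labels = c(a = 1L, b = 1L, c = 2L, d = 2L),
            exemplars = c("a", "c"), nClusters = 2L, converged = TRUE)
  expect_identical(globalSimilarity(cl, sim, merged), 2) # mean of 1 and 3
  ## with a one-sided third cluster the default mean dilutes, skip excludes
  cl3 <- new("ClusterAssignment", labels = c(a = 1L, b = 1L, c = 2L, d = 3L),
             exemplars = c("a", "c", "d"), nClusters = 3L, converged = TRUE)
  expect_equal(globalSimilarity(cl3, sim, merged), 1 / 3)
  expect_identical(globalSimilarity(cl3, sim, merged, skipOneSided = TRUE), 1)
})

test_that("raw similarity of a fully shared self-comparison is zero", {
  inst <- randomInstance(31L)
  expect_identical(rawSimilarity(inst$pair$g1, inst$pair$g1, inst$ont, seed = 1L), 0)
})

test_that("raw similarity separates related from unrelated planted pairs", {
  toy <- makeToyOntology(nTerms = 40L, seed = 41L, nRootChildren = 3L)
  rel <- makeNetworkPair(10L, 10L, 0.3, TRUE, toy$dag, seed = 42L)
  unrel <- makeNetworkPair(10L, 10L, 0, FALSE, toy$dag, seed = 42L)
  annBoth <- c(rel$annotations,
               unrel$annotations[setdiff(names(unrel$annotations),
                                         names(rel$annotations))])
  ont <- ontologySet(toy$dag, annotationTable(annBoth, dag = toy$dag))
  sRel <- rawSimilarity(rel$g1, rel$g2, ont, seed = 7L)
  sUnrel <- rawSimilarity(unrel$g1, unrel$g2, ont, seed = 7L)
  expect_lt(sUnrel, 0.1)
  expect_gt(sRel, sUnrel)
})

test_that("raw similarity is label-symmetric and invariant to input node order", {
  inst <- randomInstance(51L, n1 = 8L, n2 = 9L, overlapFrac = 0.3)
  g1 <- inst$pair$g1
  g2 <- inst$pair$g2
  expect_equal(rawSimilarity(g1, g2, inst$ont, seed = 3L),
               rawSimilarity(g2, g1, inst$ont, seed = 3L), tolerance = 1e-12)
  ## shuffling the stored node/edge order changes nothing (canonical sorting)
  shuf <- withSeed(99L, {
    e <- networkEdges(g1)
    perm <- sample.int(nrow(e))
    bioNetwork(networkName(g1), sample(networkNodes(g1)),
               e[perm, c(2L, 1L), drop = FALSE])
  })
  expect_equal(rawSimilarity(shuf, g2, inst$ont, seed = 3L),
               rawSimilarity(g1, g2, inst$ont, seed = 3L), tolerance = 1e-12)
})

test_that("cluster assignments export as a node/cluster/exemplar/provenance table", {
  inst <- randomInstance(61L, n1 = 6L, n2 = 6L)
  det <- rawSimilarity(inst$pair$g1, inst$pair$g2, inst$ont, seed = 2L,
                       details = TRUE)
  path <- tempfile(fileext = ".tsv")
  exportClusters(det$clusters, det$merged, path)
  tab <- utils::read.delim(path)
  expect_identical(nrow(tab), length(mergedOrder(det$merged)))
  expect_identical(sort(unique(tab$cluster)), seq_len(nClusters(det$clusters)))
  expect_true(all(tab$provenance %in% c("only_g1", "only_g2", "shared")))
})
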