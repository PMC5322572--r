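## Independent brute-force oracles used to cross-check the package's
## similarity machinery. Deliberately written as plain recursive/looping
## code over raw parent maps and annotation lists, sharing nothing with the
## package internals they verify.

## all ancestors of a term (including itself), by repeated parent lookup
oracleAncestors <- function(parents, t) {
  seen <- character(0)
  frontier <- t
  while (length(frontier)) {
    nxt <- character(0)
    for (x in frontier) {
      if (x %in% seen) next
      seen <- c(seen, x)
      nxt <- c(nxt, parents[[x]])
    }
    frontier <- nxt
  }
  sort(unique(seen))
}

## ancestor closure of every gene's term set
oracleClosure <- function(parents, geneTerms) {
  lapply(geneTerms, function(ts) {
    sort(unique(unlist(lapply(ts, oracleAncestors, parents = parents))))
  })
}

## IC by scanning all genes per term: ic = -ln(n_t / n_root)
oracleIC <- function(parents, geneTerms, root) {
  closed <- oracleClosure(parents, geneTerms)
  closed <- closed[lengths(closed) > 0L]
  terms <- sort(unique(unlist(closed)))
  nRoot <- sum(vapply(closed, function(ts) root %in% ts, logical(1L)))
  ic <- vapply(terms, function(t) {
    nT <- sum(vapply(closed, function(ts) t %in% ts, logical(1L)))
    -log(nT / nRoot)
  }, numeric(1L))
  names(ic) <- terms
  ic[ic < 0] <- 0
  ic
}

## max IC over the intersection of brute-force ancestor sets
oracleResnik <- function(parents, ic, t1, t2) {
  if (!(t1 %in% names(ic)) || !(t2 %in% names(ic))) return(0)
  common <- intersect(oracleAncestors(parents, t1), oracleAncestors(parents, t2))
  common <- common[common %in% names(ic)]
  if (!length(common)) 0 else max(ic[common])
}

## exhaustive double loop over the genes' term sets
oracleGeneSim <- function(parents, ic, geneTerms, g1, g2, combine = "max") {
  t1 <- geneTerms[[g1]]
  t2 <- geneTerms[[g2]]
  if (is.null(t1) || !length(t1) || is.null(t2) || !length(t2)) return(0)
  M <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      M[i, j] <- oracleResnik(parents, ic, t1[i], t2[j])
    }
  }
  if (combine == "max") return(max(M))
  rowBest <- numeric(length(t1))
  colBest <- numeric(length(t2))
  for (i in seq_along(t1)) rowBest[i] <- max(M[i, ])
  for (j in seq_along(t2)) colBest[j] <- max(M[, j])
  (sum(rowBest) + sum(colBest)) / (length(t1) + length(t2))
}

## cluster local score by explicit double loop over only-G1 x only-G2 members
oracleLocalSimilarity <- function(members, provenance, S) {
  v1 <- members[provenance[members] == "only_g1"]
  v2 <- members[provenance[members] == "only_g2"]
  if (!length(v1) || !length(v2)) return(0)
  tot <- 0
  for (i in v1) {
    best <- -Inf
    for (j in v2) best <- max(best, S[i, j])
    tot <- tot + best
  }
  for (j in v2) {
    best <- -Inf
    for (i in v1) best <- max(best, S[i, j])
    tot <- tot + best
  }
  tot / (length(v1) + length(v2))
}

## a small random study instance: toy DAG, annotated genes, planted network
## pair; used by oracle-equivalence loops
randomInstance <- function(seed, nTerms = 40L, n1 = 10L, n2 = 12L,
                           overlapFrac = 0.3, related = TRUE) {
  toy <- makeToyOntology(nTerms = nTerms, seed = seed, nRootChildren = 3L)
  pair <- makeNetworkPair(n1, n2, overlapFrac, related, toy$dag, seed = seed + 1L)
  ann <- annotationTable(pair$annotations, closed = FALSE, dag = toy$dag)
  list(dag = toy$dag, parents = toy$ledger$parents, pair = pair,
       ann = ann, ont = ontologySet(toy$dag, ann))
}

## reference affinity propagation: scikit-learn, precomputed affinity.
## Returns integer labels (0-based from python, shifted to 1-based).
sklearnAP <- function(S, preference, damping = 0.9, maxIter = 1000L,
                      convIter = 50L) {
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  utils::write.table(S, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.cluster import AffinityPropagation",
    "S = np.loadtxt(sys.argv[1], delimiter=',')",
    "ap = AffinityPropagation(affinity='precomputed',",
    sprintf("    preference=%.17g, damping=%.17g, max_iter=%d,", preference,
            damping, maxIter),
    sprintf("    convergence_iter=%d, random_state=0).fit(S)", convIter),
    "np.savetxt(sys.argv[2], ap.labels_, fmt='%d')"
  ), py)
  status <- system2("python", c(py, fin, fout), stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("reference AP run failed")
  scan(fout, what = integer(), quiet = TRUE) + 1L
}

## partitions equal up to label renaming (same co-membership structure)
samePartition <- function(a, b) {
  length(a) == length(b) && all(outer(a, a, "==") == outer(b, b, "=="))
}
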