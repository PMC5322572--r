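## Synthetic ontologies, annotations and networks with planted structure.
## Every generator is deterministic given (seed, parameters) and returns a
## ledger recording the planted ground truth; files are written through the
## package's public writers so the format code is exercised by construction.

## terms whose ancestor set contains t (includes t itself)
termDescendants <- function(dag, t) {
  anc <- termAncestors(dag)
  names(anc)[vapply(anc, function(a) t %in% a, logical(1L))]
}

termDepths <- function(dag) {
  anc <- termAncestors(dag)
  parents <- termParents(dag)
  depth <- stats::setNames(rep(NA_real_, length(parents)), names(parents))
  depth[dagRoot(dag)] <- 0
  ## parents precede children in ancestor-set size order
  for (t in names(sort(lengths(anc)))) {
    if (is.na(depth[t])) depth[t] <- min(depth[parents[[t]]]) + 1
  }
  depth
}

#' Generate a random toy ontology
#'
#' Single-root random-attachment DAG: the root gets `nRootChildren`
#' children (disjoint top-level branches), remaining terms attach to an
#' existing non-root term with probability weight increasing in depth (so
#' `nTerms >= 15` always reaches depth >= 3, with a short chain planted as
#' a guarantee), and occasionally gain a second parent within the same
#' branch. Reproducible byte-for-byte from `(seed, parameters)`.
#'
#' @param nTerms total number of terms (>= 3).
#' @param maxChildren attachment capacity per term.
#' @param seed integer seed.
#' @param nRootChildren number of top-level branches.
#' @param obo optional path; when given the ontology is also written as OBO.
#' @return list with elements `dag` ([OntologyDAG-class]) and `ledger`
#'   (seed, parameters, parent map).
#' @export
makeToyOntology <- function(nTerms = 50L, maxChildren = 3L, seed = 1L,
                            nRootChildren = 3L, obo = NULL) {
  nTerms <- as.integer(nTerms)
  if (nTerms < 3L) stop("nTerms must be at least 3")
  nRootChildren <- min(as.integer(nRootChildren), nTerms - 1L)
  ids <- sprintf("TOY:%07d", seq_len(nTerms))
  root <- ids[1L]
  parents <- stats::setNames(vector("list", nTerms), ids)
  parents[[root]] <- character(0)
  depth <- stats::setNames(numeric(nTerms), ids)
  branch <- stats::setNames(character(nTerms), ids)
  nChild <- stats::setNames(integer(nTerms), ids)
  for (k in seq_len(nRootChildren)) {
    t <- ids[1L + k]
    parents[[t]] <- root
    depth[t] <- 1
    branch[t] <- t
    nChild[root] <- nChild[root] + 1L
  }
  withSeed(seed, {
    for (k in seq_len(nTerms)[-seq_len(nRootChildren + 1L)]) {
      t <- ids[k]
      pool <- ids[2L:(k - 1L)]
      open <- pool[nChild[pool] < maxChildren]
      if (!length(open)) open <- pool[which.min(nChild[pool])]
      if (k == nRootChildren + 2L) {
        p <- ids[2L] # planted chain start: guarantees depth >= 3 ...
      } else if (k == nRootChildren + 3L) {
        p <- ids[nRootChildren + 2L] # ... via root-child -> k+2 -> k+3
      } else {
        w <- (depth[open] + 1)^2
        p <- open[sample.int(length(open), 1L, prob = w)]
      }
      parents[[t]] <- p
      depth[t] <- depth[p] + 1
      branch[t] <- branch[p]
      nChild[p] <- nChild[p] + 1L
      ## occasional second parent, kept within the same top-level branch
      sib <- pool[branch[pool] == branch[t] & pool != p & nChild[pool] < maxChildren]
      if (length(sib) && stats::runif(1L) < 0.2) {
        p2 <- sib[sample.int(length(sib), 1L)]
        parents[[t]] <- sort(c(p, p2))
        depth[t] <- min(depth[t], depth[p2] + 1)
        nChild[p2] <- nChild[p2] + 1L
      }
    }
  })
  dag <- ontologyDAG(parents, namespace = "biological_process")
  if (!is.null(obo)) writeOBO(dag, obo)
  list(dag = dag,
       ledger = list(seed = seed, nTerms = nTerms, maxChildren = maxChildren,
                     nRootChildren = nRootChildren, parents = parents))
}

#' Generate random gene annotations
#'
#' Assigns each gene `termsPerGene` distinct terms sampled from
#' `candidates` (default: all non-root terms) with a leaf bias (leaves get
#' three times the weight of internal terms). The ledger records the exact
#' assignments, so a written GAF can be checked against it after reload.
#'
#' @param dag an [OntologyDAG-class].
#' @param genes non-empty character vector of gene identifiers.
#' @param termsPerGene terms drawn per gene (capped at the candidate count).
#' @param seed integer seed.
#' @param gaf optional path; when given a GAF 2.1 file is also written.
#' @param candidates optional term pool to draw from.
#' @return list with elements `annotations` (direct
#'   [AnnotationTable-class]) and `ledger`.
#' @export
makeAnnotations <- function(dag, genes, termsPerGene = 3L, seed = 1L,
                            gaf = NULL, candidates = NULL) {
  if (!length(genes)) stop("gene list is empty")
  if (is.null(candidates)) candidates <- setdiff(termIds(dag), dagRoot(dag))
  candidates <- intersect(candidates, termIds(dag))
  hasChild <- unique(unlist(termParents(dag), use.names = FALSE))
  w <- ifelse(candidates %in% hasChild, 1, 3)
  k <- min(as.integer(termsPerGene), length(candidates))
  gt <- withSeed(seed, {
    out <- lapply(genes, function(g) {
      sort(candidates[sample.int(length(candidates), k, prob = w)])
    })
    stats::setNames(out, genes)
  })
  ann <- annotationTable(gt, closed = FALSE, dag = dag)
  if (!is.null(gaf)) writeGAF(ann, gaf)
  list(annotations = ann,
       ledger = list(seed = seed, termsPerGene = termsPerGene,
                     assignments = geneTerms(ann)))
}

## Bernoulli edges with planted modules: dense within a module, sparse
## between; every node is given at least one edge so edge-list round trips
## lose nothing, and at least two edges exist overall (rewirability).
modularEdges <- function(moduleOf, pWithin, pBetween) {
  nodes <- names(moduleOf)
  n <- length(nodes)
  from <- character(0)
  to <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- if (moduleOf[i] == moduleOf[j]) pWithin else pBetween
      if (stats::runif(1L) < p) {
        from <- c(from, nodes[i])
        to <- c(to, nodes[j])
      }
    }
  }
  edges <- cbind(from, to)
  deg <- table(factor(as.vector(edges), levels = nodes))
  for (v in nodes[deg == 0L]) {
    mates <- setdiff(nodes[moduleOf == moduleOf[v]], v)
    if (!length(mates)) mates <- setdiff(nodes, v)
    edges <- rbind(edges, c(v, mates[sample.int(length(mates), 1L)]))
  }
  if (nrow(edges) < 2L && n >= 3L) {
    edges <- rbind(edges, c(nodes[1L], nodes[2L]), c(nodes[2L], nodes[3L]))
  }
  edges
}

#' Generate a pair of networks with planted overlap and shared function
#'
#' Emulates the structure the fingerprint method detects: two networks
#' whose node sets overlap by `overlapFrac` of the smaller network, with
#' planted functional modules (dense within-module wiring) whose
#' annotations come from a common top-level ontology branch when
#' `related = TRUE`, or from two disjoint branches when `related = FALSE`.
#' Module anchors are index-aligned across the pair in the related case,
#' so corresponding modules carry semantically close annotations.
#'
#' @param n1,n2 node counts.
#' @param overlapFrac fraction of the smaller node set shared, in `[0, 1]`.
#' @param related draw both networks' annotations from one ontology branch.
#' @param dag an [OntologyDAG-class] with at least two top-level branches.
#' @param seed integer seed.
#' @param moduleSize target module size.
#' @param pWithin,pBetween within/between-module edge probabilities.
#' @param termsPerGene annotation terms per gene.
#' @param names2 character pair of network names.
#' @return list with elements `g1`, `g2` ([BioNetwork-class]),
#'   `annotations` (named list gene -> terms) and `ledger` (planted overlap
#'   set, module and anchor maps, parameters).
#' @export
makeNetworkPair <- function(n1, n2, overlapFrac, related, dag, seed = 1L,
                            moduleSize = 4L, pWithin = 0.85, pBetween = 0.08,
                            termsPerGene = 3L, names2 = c("G1", "G2")) {
  if (overlapFrac < 0 || overlapFrac > 1) stop("overlapFrac must lie in [0, 1]")
  nShared <- round(overlapFrac * min(n1, n2))
  shared <- if (nShared) sprintf("sh%03d", seq_len(nShared)) else character(0)
  only1 <- if (n1 > nShared) sprintf("a%03d", seq_len(n1 - nShared)) else character(0)
  only2 <- if (n2 > nShared) sprintf("b%03d", seq_len(n2 - nShared)) else character(0)
  nodes1 <- c(shared, only1)
  nodes2 <- c(shared, only2)

  depth <- termDepths(dag)
  branches <- termParents(dag)
  topBranches <- names(branches)[vapply(branches, function(p)
    identical(p, dagRoot(dag)), logical(1L))]
  if (length(topBranches) < 2L) stop("ontology needs at least two top-level branches")
  sizes <- vapply(topBranches, function(b) length(termDescendants(dag, b)), integer(1L))
  ord <- topBranches[order(-sizes)]
  branch1 <- ord[1L]
  branch2 <- if (related) ord[1L] else ord[2L]

  pickAnchors <- function(b) {
    sub <- termDescendants(dag, b)
    deep <- sub[depth[sub] >= 2]
    if (!length(deep)) deep <- sub
    deep[order(-depth[deep], deep)][seq_len(min(3L, length(deep)))]
  }
  anchors1 <- pickAnchors(branch1)
  anchors2 <- if (related) anchors1 else pickAnchors(branch2)

  out <- withSeed(seed, {
    mod1 <- stats::setNames(rep(seq_len(ceiling(n1 / moduleSize)), length.out = n1), nodes1)
    mod2 <- stats::setNames(rep(seq_len(ceiling(n2 / moduleSize)), length.out = n2), nodes2)
    anchorOf1 <- anchors1[(mod1 - 1L) %% length(anchors1) + 1L]
    anchorOf2 <- anchors2[(mod2 - 1L) %% length(anchors2) + 1L]
    names(anchorOf1) <- nodes1
    names(anchorOf2) <- nodes2
    drawTerms <- function(anchor) {
      cand <- termDescendants(dag, anchor)
      k <- min(termsPerGene, length(cand))
      sort(cand[sample.int(length(cand), k)])
    }
    anns <- list()
    for (g in nodes1) anns[[g]] <- drawTerms(anchorOf1[[g]])
    for (g in setdiff(nodes2, nodes1)) anns[[g]] <- drawTerms(anchorOf2[[g]])
    e1 <- modularEdges(mod1, pWithin, pBetween)
    e2 <- modularEdges(mod2, pWithin, pBetween)
    list(anns = anns, e1 = e1, e2 = e2, mod1 = mod1, mod2 = mod2,
         anchorOf1 = anchorOf1, anchorOf2 = anchorOf2)
  })
  list(
    g1 = bioNetwork(names2[1L], nodes = nodes1, edges = out$e1, quiet = TRUE),
    g2 = bioNetwork(names2[2L], nodes = nodes2, edges = out$e2, quiet = TRUE),
    annotations = out$anns,
    ledger = list(seed = seed, n1 = n1, n2 = n2, overlapFrac = overlapFrac,
                  related = related, shared = shared,
                  modules = list(g1 = out$mod1, g2 = out$mod2),
                  anchors = list(g1 = out$anchorOf1, g2 = out$anchorOf2),
                  pWithin = pWithin, pBetween = pBetween)
  )
}

## Deterministic scenario ontology: root, four top-level branches, three
## anchor terms per branch, three leaves per anchor (53 terms, depth 3).
scenarioOntology <- function() {
  ids <- sprintf("TOY:%07d", seq_len(53L))
  parents <- stats::setNames(vector("list", 53L), ids)
  parents[[ids[1L]]] <- character(0)
  for (b in seq_len(4L)) parents[[ids[1L + b]]] <- ids[1L]
  for (b in seq_len(4L)) {
    for (a in seq_len(3L)) {
      anchor <- 5L + (b - 1L) * 3L + a
      parents[[ids[anchor]]] <- ids[1L + b]
      for (l in seq_len(3L)) {
        leaf <- 17L + (anchor - 6L) * 3L + l
        parents[[ids[leaf]]] <- ids[anchor]
      }
    }
  }
  ontologyDAG(parents, namespace = "biological_process")
}

#' Generate the planted-reference scenario
#'
#' Builds a complete offline test bed in `dir`: a structured toy ontology
#' (four disjoint top-level branches), one query network, and a reference
#' set of four networks of which exactly one (`R1`) is related to the query
#' -- it shares a third of the query's nodes and draws its module
#' annotations from the same ontology branch, while `R2`-`R4` use the three
#' other branches and share no nodes. All artifacts are written through the
#' public writers (OBO, GAF, edge list, GraphML, KGML, manifest) and read
#' back through the public readers, so every format is exercised; the
#' returned objects come from the readers.
#'
#' Networks have 12 nodes in 3 modules of 4; wiring is modular (within
#' p = 0.85, between p = 0.08) so that topology correlates with function,
#' which is exactly the signal degree-preserving rewiring destroys.
#'
#' @param seed integer seed.
#' @param dir output directory (default: fresh temporary directory).
#' @return list with elements `query` ([BioNetwork-class]), `refset`
#'   ([ReferenceNetworkSet-class]), `ontology` ([OntologySet-class]),
#'   `files` (paths) and `ledger` (marks `R1` as the related reference and
#'   records shared nodes, anchors and parameters).
#' @export
makeRefsetScenario <- function(seed = 1L, dir = tempfile("nfp-scenario-")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- scenarioOntology()
  oboPath <- file.path(dir, "toy.obo")
  writeOBO(dag, oboPath)

  nNodes <- 12L
  nModules <- 3L
  nSharedQ <- 6L
  pWithin <- 0.85
  pBetween <- 0.08
  termsPerGene <- 3L
  branchOf <- function(i) sprintf("TOY:%07d", 1L + i) # top-level branch i
  anchorsOf <- function(i) sprintf("TOY:%07d", 5L + (i - 1L) * 3L + seq_len(3L))
  leavesOf <- function(anchor) {
    a <- as.integer(sub("TOY:", "", anchor)) - 5L
    sprintf("TOY:%07d", 17L + (a - 1L) * 3L + seq_len(3L))
  }

  sharedNodes <- sprintf("sh%02d", seq_len(nSharedQ))
  nets <- list(
    query = c(sharedNodes, sprintf("q%02d", seq_len(nNodes - nSharedQ))),
    R1 = c(sharedNodes, sprintf("r1x%02d", seq_len(nNodes - nSharedQ))),
    R2 = sprintf("r2x%02d", seq_len(nNodes)),
    R3 = sprintf("r3x%02d", seq_len(nNodes)),
    R4 = sprintf("r4x%02d", seq_len(nNodes))
  )
  branchIdx <- c(query = 1L, R1 = 1L, R2 = 2L, R3 = 3L, R4 = 4L)

  built <- withSeed(seed, {
    anns <- list()
    edges <- list()
    modules <- list()
    for (nm in names(nets)) {
      nodes <- nets[[nm]]
      mod <- stats::setNames(rep(seq_len(nModules), length.out = length(nodes)), nodes)
      anchors <- anchorsOf(branchIdx[[nm]])
      for (g in nodes) {
        if (!is.null(anns[[g]])) next # shared gene already annotated by query
        cand <- c(anchors[mod[[g]]], leavesOf(anchors[mod[[g]]]))
        anns[[g]] <- sort(cand[sample.int(length(cand), termsPerGene)])
      }
      edges[[nm]] <- modularEdges(mod, pWithin, pBetween)
      modules[[nm]] <- mod
    }
    list(anns = anns, edges = edges, modules = modules)
  })

  gafPath <- file.path(dir, "toy.gaf")
  writeGAF(annotationTable(built$anns, closed = FALSE, dag = dag), gafPath)

  mkNet <- function(nm) bioNetwork(nm, nodes = nets[[nm]],
                                   edges = built$edges[[nm]], quiet = TRUE)
  queryPath <- file.path(dir, "query.txt")
  writeNetwork(mkNet("query"), queryPath, "edgelist")
  refset0 <- referenceNetworkSet(
    group = c("signaling", "signaling", "metabolism", "metabolism"),
    name = c("R1", "R2", "R3", "R4"),
    networks = lapply(c("R1", "R2", "R3", "R4"), mkNet)
  )
  manifest <- writeRefset(refset0, dir,
                          formats = c("edgelist", "graphml", "kgml", "edgelist"))

  dagBack <- loadOBO(oboPath)
  ont <- ontologySet(dagBack, loadGAF(gafPath, dagBack))
  list(
    query = readNetwork(queryPath, "edgelist", name = "query"),
    refset = loadRefset(manifest),
    ontology = ont,
    files = list(dir = dir, obo = oboPath, gaf = gafPath, query = queryPath,
                 manifest = manifest),
    ledger = list(seed = seed, related = "R1", sharedNodes = sharedNodes,
                  branchIdx = branchIdx, modules = built$modules,
                  annotations = built$anns, nNodes = nNodes,
                  pWithin = pWithin, pBetween = pBetween,
                  termsPerGene = termsPerGene)
  )
}
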