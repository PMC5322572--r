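## Network merging, semantic weighting, and cluster-wise similarity scoring.

#' Merge two networks by gene name
#'
#' Union semantics: nodes and edges of both networks are pooled, common
#' nodes (same identifier) collapse into a single node inheriting all
#' interactions, and common edges (same unordered endpoint pair) collapse
#' into one edge. Every merged node carries its provenance: present only in
#' the first network, only in the second, or shared. The node order is
#' sorted, fixing matrix indexing deterministically.
#'
#' @param g1,g2 non-empty [BioNetwork-class] objects.
#' @return a [MergedNetwork-class].
#' @export
mergeNetworks <- function(g1, g2) {
  if (length(networkNodes(g1)) == 0L) stop("first network is empty")
  if (length(networkNodes(g2)) == 0L) stop("second network is empty")
  n1 <- networkNodes(g1)
  n2 <- networkNodes(g2)
  nodes <- sort(union(n1, n2))
  edges <- normalizeEdges(rbind(networkEdges(g1), networkEdges(g2)))$edges
  prov <- ifelse(nodes %in% n1 & nodes %in% n2, "shared",
                 ifelse(nodes %in% n1, "only_g1", "only_g2"))
  names(prov) <- nodes
  net <- new("BioNetwork",
             name = paste(networkName(g1), networkName(g2), sep = "+"),
             nodes = nodes, edges = edges)
  new("MergedNetwork", network = net, provenance = prov, order = nodes)
}

#' Semantic similarity matrix of a merged network
#'
#' Resnik gene similarity for every node pair of the merged network, over
#' its fixed node order. Symmetric by construction; the diagonal holds gene
#' self-similarities. Unannotated genes yield zero rows and columns (their
#' count is reported once rather than one warning per pair).
#'
#' @param merged a [MergedNetwork-class].
#' @param ont an [OntologySet-class].
#' @param combine gene-level combiner, `"max"` (default) or `"bma"`.
#' @return a [SemanticMatrix-class].
#' @export
semanticMatrix <- function(merged, ont, combine = c("max", "bma")) {
  combine <- match.arg(combine)
  genes <- mergedOrder(merged)
  gt <- geneTerms(ont@annotations)[genes]
  names(gt) <- genes
  annotated <- lengths(gt) > 0L
  if (any(!annotated)) {
    message(sprintf("semanticMatrix: %d of %d genes unannotated (zero rows)",
                    sum(!annotated), length(genes)))
  }
  terms <- unique(unlist(gt, use.names = FALSE))
  TM <- resnikTermMatrix(ont@ic, ont@dag, terms)
  n <- length(genes)
  S <- matrix(0, n, n, dimnames = list(genes, genes))
  idx <- which(annotated)
  for (a in seq_along(idx)) {
    i <- idx[a]
    ti <- gt[[i]]
    for (b in a:length(idx)) {
      j <- idx[b]
      v <- combineTermSim(TM[ti, gt[[j]], drop = FALSE], combine)
      S[i, j] <- S[j, i] <- v
    }
  }
  new("SemanticMatrix", values = S, combine = combine)
}

## Weighted adjacency: semantic similarity restricted to merged-network
## edges (zero elsewhere, zero diagonal). This is the matrix clustering
## operates on, so that wiring -- and hence degree-preserving rewiring --
## shapes the partition.
maskByAdjacency <- function(S, merged) {
  ord <- mergedOrder(merged)
  A <- matrix(0, length(ord), length(ord), dimnames = list(ord, ord))
  e <- networkEdges(mergedNetwork(merged))
  if (nrow(e)) {
    i <- match(e[, 1L], ord)
    j <- match(e[, 2L], ord)
    A[cbind(i, j)] <- S[cbind(i, j)]
    A[cbind(j, i)] <- S[cbind(j, i)]
  }
  A
}

#' Local similarity of one cluster
#'
#' For cluster `k`, let `V1` be its members present only in the first
#' network and `V2` its members present only in the second. The local score
#' is the bidirectional best-match average
#' `LS_k = (sum_{i in V1} max_{j in V2} S(i,j) +
#'          sum_{j in V2} max_{i in V1} S(i,j)) / (|V1| + |V2|)`,
#' the full semantic similarity being used regardless of adjacency. A
#' cluster with an empty side (no cross-network correspondence) scores 0.
#'
#' @param k cluster id.
#' @param clusters a [ClusterAssignment-class].
#' @param sim a [SemanticMatrix-class].
#' @param merged the [MergedNetwork-class] the clustering was computed on.
#' @param sharedOnBothSides count shared-provenance nodes on both sides
#'   (default `FALSE`: shared nodes are excluded from both).
#' @return non-negative number.
#' @export
localSimilarity <- function(k, clusters, sim, merged, sharedOnBothSides = FALSE) {
  lab <- clusterLabels(clusters)
  if (!k %in% seq_len(nClusters(clusters))) stop("unknown cluster id: ", k)
  prov <- mergedProvenance(merged)
  members <- names(lab)[lab == k]
  v1 <- members[prov[members] == "only_g1"]
  v2 <- members[prov[members] == "only_g2"]
  if (sharedOnBothSides) {
    sh <- members[prov[members] == "shared"]
    v1 <- c(v1, sh)
    v2 <- c(v2, sh)
  }
  if (length(v1) == 0L || length(v2) == 0L) return(0)
  S <- simValues(sim)
  sub <- S[v1, v2, drop = FALSE]
  (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) / (length(v1) + length(v2))
}

#' Global similarity of a clustered merge
#'
#' Arithmetic mean of the local similarity over all clusters; the raw
#' (unstandardized) similarity between the two merged networks.
#'
#' @inheritParams localSimilarity
#' @param skipOneSided drop clusters with an empty side from the mean
#'   instead of letting them contribute 0 (default `FALSE`).
#' @return non-negative number.
#' @export
globalSimilarity <- function(clusters, sim, merged, skipOneSided = FALSE,
                             sharedOnBothSides = FALSE) {
  K <- nClusters(clusters)
  if (K < 1L) stop("no clusters")
  ls <- vapply(seq_len(K), localSimilarity, numeric(1L),
               clusters = clusters, sim = sim, merged = merged,
               sharedOnBothSides = sharedOnBothSides)
  if (skipOneSided) {
    lab <- clusterLabels(clusters)
    prov <- mergedProvenance(merged)
    twoSided <- vapply(seq_len(K), function(k) {
      m <- names(lab)[lab == k]
      any(prov[m] == "only_g1") && any(prov[m] == "only_g2")
    }, logical(1L))
    if (!any(twoSided)) return(0)
    ls <- ls[twoSided]
  }
  mean(ls)
}

#' Raw similarity between two networks
#'
#' The unstandardized similarity score: merge the networks, weight node
#' pairs semantically, cluster the nodes by affinity propagation on the
#' semantically weighted adjacency, and average the cluster-wise
#' bidirectional best-match scores. Deterministic at a fixed seed.
#'
#' Clustering runs on the weighted adjacency (semantic similarity on merged
#' edges, zero elsewhere) so that topology shapes the partition; the
#' cluster scores themselves use the full semantic matrix over cluster
#' members regardless of adjacency.
#'
#' @param g1,g2 non-empty [BioNetwork-class] objects.
#' @param ont an [OntologySet-class].
#' @param combine gene-level similarity combiner (`"max"`/`"bma"`).
#' @param preference,damping,maxIter,convIter affinity-propagation
#'   parameters, see [apCluster()].
#' @param seed integer seed for the clustering tie-break jitter.
#' @param skipOneSided,sharedOnBothSides cluster-scoring options, see
#'   [globalSimilarity()] and [localSimilarity()].
#' @param sim optional precomputed [SemanticMatrix-class] over the merged
#'   node order (node labels are wiring-invariant, so one matrix serves all
#'   rewired draws of the same pair).
#' @param details return intermediate objects instead of just the score.
#' @return the score, or with `details = TRUE` a list with elements
#'   `score`, `clusters`, `merged`, `sim`.
#' @export
rawSimilarity <- function(g1, g2, ont, combine = c("max", "bma"),
                          preference = "median", damping = 0.9,
                          maxIter = 1000L, convIter = 50L, seed = 1L,
                          skipOneSided = FALSE, sharedOnBothSides = FALSE,
                          sim = NULL, details = FALSE) {
  combine <- match.arg(combine)
  merged <- mergeNetworks(g1, g2)
  if (is.null(sim)) {
    sim <- semanticMatrix(merged, ont, combine = combine)
  } else {
    if (!identical(rownames(simValues(sim)), mergedOrder(merged))) {
      stop("precomputed similarity matrix does not match the merged node order")
    }
  }
  A <- maskByAdjacency(simValues(sim), merged)
  clusters <- apCluster(A, preference = preference, damping = damping,
                        maxIter = maxIter, convIter = convIter, seed = seed)
  score <- globalSimilarity(clusters, sim, merged, skipOneSided = skipOneSided,
                            sharedOnBothSides = sharedOnBothSides)
  if (details) {
    list(score = score, clusters = clusters, merged = merged, sim = sim)
  } else {
    score
  }
}

#' Export a cluster assignment as TSV
#'
#' Writes one row per node with its cluster id, the cluster exemplar, and
#' the node's merge provenance.
#'
#' @param clusters a [ClusterAssignment-class].
#' @param merged the matching [MergedNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportClusters <- function(clusters, merged, path) {
  lab <- clusterLabels(clusters)
  utils::write.table(
    data.frame(node = names(lab), cluster = unname(lab),
               exemplar = clusterExemplars(clusters)[lab],
               provenance = unname(mergedProvenance(merged)[names(lab)]),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
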