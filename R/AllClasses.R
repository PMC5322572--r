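#' @import methods
NULL

## ---------------------------------------------------------------------------
## Ontology side
## ---------------------------------------------------------------------------

#' OntologyDAG: a single-namespace ontology term graph
#'
#' Holds the term graph of one ontology namespace as a child-to-parent map.
#' The graph must be acyclic with a single root (a unique parentless term);
#' ancestor sets (each term included in its own set) are precomputed at
#' construction time, which makes annotation closure and Resnik lookups cheap.
#'
#' @slot parents named list; for each term, the character vector of its
#'   parent terms (`is_a`, optionally `part_of`). The root maps to
#'   `character(0)`.
#' @slot ancestors named list; for each term, all ancestors including itself.
#' @slot namespace single string, e.g. `"biological_process"`.
#' @slot root the root term identifier.
#' @slot altIds named character vector mapping secondary identifiers to
#'   canonical ones (may be empty).
#' @export
setClass("OntologyDAG",
  representation(
    parents   = "list",
    ancestors = "list",
    namespace = "character",
    root      = "character",
    altIds    = "character"
  )
)

setValidity("OntologyDAG", function(object) {
  msg <- character(0)
  terms <- names(object@parents)
  if (is.null(terms) || anyDuplicated(terms)) {
    msg <- c(msg, "parents must be a uniquely named list")
  }
  allParents <- unique(unlist(object@parents, use.names = FALSE))
  if (!all(allParents %in% terms)) {
    msg <- c(msg, "every parent must itself be a term")
  }
  nRoot <- sum(lengths(object@parents) == 0L)
  if (nRoot != 1L) msg <- c(msg, "graph must have exactly one parentless term (the root)")
  if (length(object@root) != 1L || !(object@root %in% terms)) {
    msg <- c(msg, "root must be a single known term")
  }
  if (!setequal(names(object@ancestors), terms)) {
    msg <- c(msg, "ancestors must cover exactly the term set")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OntologyDAG from a child-to-parent map
#'
#' Performs a topological sort (detecting cycles), identifies the unique
#' root, and precomputes the reflexive ancestor set of every term.
#'
#' @param parents named list mapping each term to a character vector of its
#'   parent terms; the root maps to an empty vector. Terms that only appear
#'   as parents are added automatically as roots-in-waiting (an error unless
#'   exactly one parentless term results).
#' @param namespace namespace label stored on the object.
#' @param altIds optional named character vector of alternate identifiers.
#' @return an [OntologyDAG-class] object.
#' @examples
#' dag <- ontologyDAG(list(r = character(0), a = "r", b = "r"), "biological_process")
#' termAncestors(dag)[["a"]]
#' @export
ontologyDAG <- function(parents, namespace = "biological_process",
                        altIds = character(0)) {
  terms <- names(parents)
  extra <- setdiff(unique(unlist(parents, use.names = FALSE)), terms)
  if (length(extra)) {
    parents <- c(parents, stats::setNames(rep(list(character(0)), length(extra)), extra))
    terms <- names(parents)
  }
  parents <- lapply(parents, function(p) sort(unique(as.character(p))))
  ## Kahn topological sort, root first
  indeg <- stats::setNames(lengths(parents), terms) # parents remaining to place
  order <- character(0)
  ready <- names(indeg)[indeg == 0L]
  childMap <- split(
    rep(terms, lengths(parents)),
    unlist(parents, use.names = FALSE)
  )
  while (length(ready)) {
    ready <- sort(ready)
    t <- ready[1L]
    ready <- ready[-1L]
    order <- c(order, t)
    for (ch in childMap[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) != length(terms)) {
    stop("ontology graph contains a cycle")
  }
  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L) {
    stop("ontology graph must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  }
  anc <- vector("list", length(terms))
  names(anc) <- terms
  for (t in order) {
    ps <- parents[[t]]
    anc[[t]] <- sort(unique(c(t, unlist(anc[ps], use.names = FALSE))))
  }
  new("OntologyDAG",
    parents = parents, ancestors = anc,
    namespace = namespace, root = roots, altIds = altIds
  )
}

#' AnnotationTable: gene-to-term annotation sets
#'
#' @slot geneTerms named list mapping gene identifiers to character vectors
#'   of term identifiers.
#' @slot closed logical; `TRUE` after ancestor closure
#'   (see [closeAnnotations()]).
#' @export
setClass("AnnotationTable",
  representation(geneTerms = "list", closed = "logical")
)

setValidity("AnnotationTable", function(object) {
  msg <- character(0)
  if (is.null(names(object@geneTerms)) || anyDuplicated(names(object@geneTerms))) {
    msg <- c(msg, "geneTerms must be a uniquely named list")
  }
  if (length(object@closed) != 1L) msg <- c(msg, "closed must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationTable
#'
#' @param geneTerms named list of per-gene term identifier vectors.
#' @param closed whether the sets are already ancestor-closed.
#' @param dag optional [OntologyDAG-class]; when given, every annotated term
#'   is checked for membership in the graph.
#' @return an [AnnotationTable-class] object.
#' @export
annotationTable <- function(geneTerms, closed = FALSE, dag = NULL) {
  geneTerms <- lapply(geneTerms, function(x) sort(unique(as.character(x))))
  if (!is.null(dag)) {
    unknown <- setdiff(unique(unlist(geneTerms, use.names = FALSE)), termIds(dag))
    if (length(unknown)) {
      stop("annotated term(s) not in ontology: ", paste(unknown, collapse = ", "))
    }
  }
  new("AnnotationTable", geneTerms = geneTerms, closed = closed)
}

#' ICTable: per-term information content
#'
#' Information content in natural-log units: `ic[t] = -ln(n_t / n_root)`
#' where `n_t` counts annotated genes whose ancestor-closed term set contains
#' `t`. Terms no gene reaches are absent. `ic[root] = 0` by construction.
#'
#' @slot ic named numeric vector of non-negative information contents.
#' @slot corpusSize number of annotated genes at the root.
#' @export
setClass("ICTable", representation(ic = "numeric", corpusSize = "integer"))

setValidity("ICTable", function(object) {
  msg <- character(0)
  if (is.null(names(object@ic))) msg <- c(msg, "ic must be named by term")
  if (any(object@ic < -1e-12)) msg <- c(msg, "information content must be non-negative")
  if (length(object@corpusSize) != 1L || object@corpusSize < 1L) {
    msg <- c(msg, "corpusSize must be a positive count")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Network side
## ---------------------------------------------------------------------------

#' BioNetwork: a named undirected gene network
#'
#' Edges are stored canonically: two character columns, endpoints sorted
#' within each row, unique rows in lexicographic order, no self-loops.
#' Isolated nodes are allowed.
#'
#' @slot name network name.
#' @slot nodes character vector of gene identifiers (sorted, unique).
#' @slot edges two-column character matrix of unordered node pairs.
#' @export
setClass("BioNetwork",
  representation(name = "character", nodes = "character", edges = "matrix")
)

setValidity("BioNetwork", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  else if (nrow(e)) {
    if (!all(e %in% object@nodes)) msg <- c(msg, "edge endpoint not in node set")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L])) msg <- c(msg, "edge endpoints must be sorted within rows")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r"))) msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BioNetwork
#'
#' Normalizes the edge set (drops self-loops and duplicate edges, reporting
#' the counts), adds edge endpoints missing from `nodes`, and sorts nodes.
#'
#' @param name network name.
#' @param nodes character vector of node identifiers (may be empty when all
#'   nodes appear in edges).
#' @param edges two-column character matrix (or empty).
#' @param quiet suppress the dropped-edge log message.
#' @return a [BioNetwork-class] object.
#' @examples
#' bioNetwork("toy", edges = cbind(c("a", "b"), c("b", "c")))
#' @export
bioNetwork <- function(name, nodes = character(0),
                       edges = matrix(character(0), 0L, 2L), quiet = FALSE) {
  norm <- normalizeEdges(edges)
  nodes <- sort(unique(c(as.character(nodes), as.vector(norm$edges))))
  if ((norm$selfLoops || norm$duplicates) && !quiet) {
    message(sprintf("network '%s': dropped %d self-loop(s) and %d duplicate edge(s)",
                    name, norm$selfLoops, norm$duplicates))
  }
  new("BioNetwork", name = as.character(name), nodes = nodes, edges = norm$edges)
}

#' ReferenceNetworkSet: an ordered, grouped collection of basic networks
#'
#' The entry order is the coordinate system of every fingerprint computed
#' against the set, so it is preserved exactly by all selection operations.
#'
#' @slot group character vector of group labels, one per entry.
#' @slot name character vector of network names, one per entry;
#'   `(group, name)` pairs are unique.
#' @slot networks list of [BioNetwork-class] objects.
#' @export
setClass("ReferenceNetworkSet",
  representation(group = "character", name = "character", networks = "list")
)

setValidity("ReferenceNetworkSet", function(object) {
  msg <- character(0)
  n <- length(object@name)
  if (length(object@group) != n || length(object@networks) != n) {
    msg <- c(msg, "group, name and networks must have equal length")
  }
  if (anyDuplicated(paste(object@group, object@name, sep = "\r"))) {
    msg <- c(msg, "(group, name) pairs must be unique")
  }
  if (n && !all(vapply(object@networks, is, logical(1L), "BioNetwork"))) {
    msg <- c(msg, "networks must all be BioNetwork objects")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceNetworkSet
#'
#' @param group,name parallel character vectors.
#' @param networks list of [BioNetwork-class] objects.
#' @return a [ReferenceNetworkSet-class] object.
#' @export
referenceNetworkSet <- function(group = character(0), name = character(0),
                                networks = list()) {
  new("ReferenceNetworkSet",
    group = as.character(group), name = as.character(name),
    networks = networks
  )
}

## ---------------------------------------------------------------------------
## Merge / clustering side
## ---------------------------------------------------------------------------

#' MergedNetwork: union of two networks with node provenance
#'
#' The merged graph `G_m = (V1 u V2, E1 u E2)` after name-based node
#' identification, with every node tagged `"only_g1"`, `"only_g2"` or
#' `"shared"`, and a fixed (sorted) node order used for all matrices.
#'
#' @slot network the union [BioNetwork-class].
#' @slot provenance named character vector over the node order.
#' @slot order character vector fixing matrix row/column order.
#' @export
setClass("MergedNetwork",
  representation(network = "BioNetwork", provenance = "character", order = "character")
)

setValidity("MergedNetwork", function(object) {
  msg <- character(0)
  if (!setequal(object@order, object@network@nodes)) {
    msg <- c(msg, "order must enumerate the merged node set")
  }
  if (!identical(names(object@provenance), object@order)) {
    msg <- c(msg, "provenance must be named by the node order")
  }
  if (!all(object@provenance %in% c("only_g1", "only_g2", "shared"))) {
    msg <- c(msg, "provenance values must be only_g1/only_g2/shared")
  }
  if (length(msg)) msg else TRUE
})

#' SemanticMatrix: pairwise gene semantic similarity over a merged network
#'
#' Symmetric non-negative matrix of Resnik gene similarities over the node
#' order of a [MergedNetwork-class]; the diagonal holds gene
#' self-similarities.
#'
#' @slot values numeric matrix with node dimnames.
#' @slot combine the gene-level combiner used (`"max"` or `"bma"`).
#' @export
setClass("SemanticMatrix", representation(values = "matrix", combine = "character"))

setValidity("SemanticMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12))) msg <- c(msg, "matrix must be symmetric")
  if (any(v < -1e-12)) msg <- c(msg, "similarities must be non-negative")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v))) {
    msg <- c(msg, "matrix must carry identical row/column node names")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: affinity-propagation clustering result
#'
#' @slot labels named integer vector, node to cluster id (1..K).
#' @slot exemplars character vector of exemplar nodes, one per cluster id.
#' @slot nClusters number of clusters.
#' @slot converged whether message passing reached a stable exemplar set
#'   (otherwise the connected-component fallback partition is reported).
#' @export
setClass("ClusterAssignment",
  representation(labels = "integer", exemplars = "character",
                 nClusters = "integer", converged = "logical")
)

setValidity("ClusterAssignment", function(object) {
  msg <- character(0)
  k <- object@nClusters
  if (length(object@exemplars) != k) msg <- c(msg, "one exemplar per cluster required")
  if (length(object@labels) && (min(object@labels) < 1L || max(object@labels) > k)) {
    msg <- c(msg, "labels must lie in 1..nClusters")
  }
  ex <- object@exemplars
  if (k && !all(ex %in% names(object@labels))) {
    msg <- c(msg, "exemplars must be labeled nodes")
  } else if (k && !all(object@labels[ex] == seq_len(k))) {
    msg <- c(msg, "each exemplar must carry its own cluster label")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Randomization / result side
## ---------------------------------------------------------------------------

#' NullDistribution: similarity scores of degree-preserving rewired networks
#'
#' @slot scores numeric vector of length `nperm`.
#' @slot mean,sd summary statistics (sample sd, n - 1 denominator).
#' @slot nperm number of randomized draws.
#' @slot seed master seed the draws were split from.
#' @export
setClass("NullDistribution",
  representation(scores = "numeric", mean = "numeric", sd = "numeric",
                 nperm = "integer", seed = "integer")
)

setValidity("NullDistribution", function(object) {
  msg <- character(0)
  if (length(object@scores) != object@nperm) {
    msg <- c(msg, "scores length must equal nperm")
  }
  if (length(msg)) msg else TRUE
})

#' Fingerprint: a network fingerprint against a reference set
#'
#' One row per reference network, in reference-set order: the raw merged
#' similarity, the rewired-null mean and sd, the standardized score (the
#' fingerprint coordinate), and the cluster count of the observed merge.
#'
#' @slot group,refName per-entry reference labels.
#' @slot raw,nullMean,nullSd,standardized per-entry numeric results.
#' @slot nClusters per-entry observed cluster counts.
#' @slot queryName name of the query network.
#' @slot nperm,seed run parameters.
#' @slot params snapshot of the remaining tuning parameters.
#' @export
setClass("Fingerprint",
  representation(
    group = "character", refName = "character",
    raw = "numeric", nullMean = "numeric", nullSd = "numeric",
    standardized = "numeric", nClusters = "integer",
    queryName = "character", nperm = "integer", seed = "integer",
    params = "list"
  )
)

setValidity("Fingerprint", function(object) {
  n <- length(object@refName)
  same <- c(
    length(object@group), length(object@raw), length(object@nullMean),
    length(object@nullSd), length(object@standardized), length(object@nClusters)
  )
  if (any(same != n)) "per-reference slots must have equal length" else TRUE
})
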