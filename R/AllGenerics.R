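#' @include AllClasses.R
NULL

## -- ontology accessors ------------------------------------------------------

#' Accessors for ontology objects
#'
#' @param dag an [OntologyDAG-class].
#' @return `termIds`: character vector of terms; `termParents`,
#'   `termAncestors`: named lists (ancestor sets include the term itself);
#'   `dagRoot`, `dagNamespace`: single strings.
#' @name ontology-accessors
NULL

#' @rdname ontology-accessors
#' @export
termIds <- function(dag) names(dag@parents)

#' @rdname ontology-accessors
#' @export
termParents <- function(dag) dag@parents

#' @rdname ontology-accessors
#' @export
termAncestors <- function(dag) dag@ancestors

#' @rdname ontology-accessors
#' @export
dagRoot <- function(dag) dag@root

#' @rdname ontology-accessors
#' @export
dagNamespace <- function(dag) dag@namespace

#' Accessors for annotation tables and IC tables
#'
#' @param x an [AnnotationTable-class] or [ICTable-class].
#' @return `geneTerms`: named list of per-gene term sets; `isClosed`:
#'   logical; `icValues`: named numeric vector; `icCorpusSize`: integer.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
geneTerms <- function(x) x@geneTerms

#' @rdname annotation-accessors
#' @export
isClosed <- function(x) x@closed

#' @rdname annotation-accessors
#' @export
icValues <- function(x) x@ic

#' @rdname annotation-accessors
#' @export
icCorpusSize <- function(x) x@corpusSize

## -- network accessors -------------------------------------------------------

#' Accessors for BioNetwork objects
#'
#' @param net a [BioNetwork-class].
#' @return `networkName`: string; `networkNodes`: character vector;
#'   `networkEdges`: two-column character matrix.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
networkName <- function(net) net@name

#' @rdname network-accessors
#' @export
networkNodes <- function(net) net@nodes

#' @rdname network-accessors
#' @export
networkEdges <- function(net) net@edges

#' Accessors for reference network sets
#'
#' @param refset a [ReferenceNetworkSet-class].
#' @return `refGroups`, `refNames`: character vectors in entry order;
#'   `refNetworks`: list of [BioNetwork-class] objects.
#' @name refset-accessors
NULL

#' @rdname refset-accessors
#' @export
refGroups <- function(refset) refset@group

#' @rdname refset-accessors
#' @export
refNames <- function(refset) refset@name

#' @rdname refset-accessors
#' @export
refNetworks <- function(refset) refset@networks

#' @describeIn refset-accessors number of reference networks.
#' @export
setMethod("length", "ReferenceNetworkSet", function(x) length(x@name))

## -- merged / similarity accessors -------------------------------------------

#' Accessors for merged networks and similarity matrices
#'
#' @param x a [MergedNetwork-class], [SemanticMatrix-class] or
#'   [ClusterAssignment-class].
#' @return `mergedNetwork`: the union [BioNetwork-class];
#'   `mergedProvenance`: named character vector (`only_g1`/`only_g2`/
#'   `shared`); `mergedOrder`: node order; `simValues`: numeric matrix;
#'   `clusterLabels`: named integer vector; `clusterExemplars`: character
#'   vector; `nClusters`: integer; `apConverged`: logical.
#' @name merged-accessors
NULL

#' @rdname merged-accessors
#' @export
mergedNetwork <- function(x) x@network

#' @rdname merged-accessors
#' @export
mergedProvenance <- function(x) x@provenance

#' @rdname merged-accessors
#' @export
mergedOrder <- function(x) x@order

#' @rdname merged-accessors
#' @export
simValues <- function(x) x@values

#' @rdname merged-accessors
#' @export
clusterLabels <- function(x) x@labels

#' @rdname merged-accessors
#' @export
clusterExemplars <- function(x) x@exemplars

#' @rdname merged-accessors
#' @export
nClusters <- function(x) x@nClusters

#' @rdname merged-accessors
#' @export
apConverged <- function(x) x@converged

## -- null / fingerprint accessors --------------------------------------------

#' Accessors for null distributions
#'
#' @param x a [NullDistribution-class].
#' @return `nullScores`: numeric vector; `nullMean`, `nullSd`: numbers.
#' @name null-accessors
NULL

#' @rdname null-accessors
#' @export
nullScores <- function(x) x@scores

#' @rdname null-accessors
#' @export
nullMean <- function(x) x@mean

#' @rdname null-accessors
#' @export
nullSd <- function(x) x@sd

#' Fingerprint table accessor
#'
#' @param fp a [Fingerprint-class].
#' @return data frame with columns `group`, `name`, `raw`, `null_mean`,
#'   `null_sd`, `standardized`, `n_clusters`, in reference-set order.
#' @export
fpTable <- function(fp) {
  data.frame(
    group = fp@group, name = fp@refName, raw = fp@raw,
    null_mean = fp@nullMean, null_sd = fp@nullSd,
    standardized = fp@standardized, n_clusters = fp@nClusters,
    stringsAsFactors = FALSE
  )
}

#' @describeIn fpTable number of reference coordinates.
#' @param x a [Fingerprint-class].
#' @export
setMethod("length", "Fingerprint", function(x) length(x@refName))

## -- show methods ------------------------------------------------------------

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms, namespace '%s', root %s\n",
              length(object@parents), object@namespace, object@root))
})

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d genes, %d distinct terms, %s\n",
              length(object@geneTerms),
              length(unique(unlist(object@geneTerms, use.names = FALSE))),
              if (object@closed) "ancestor-closed" else "direct annotations"))
})

setMethod("show", "ICTable", function(object) {
  cat(sprintf("ICTable: %d terms with IC, corpus of %d genes, max IC %.3f\n",
              length(object@ic), object@corpusSize,
              if (length(object@ic)) max(object@ic) else NA_real_))
})

setMethod("show", "BioNetwork", function(object) {
  cat(sprintf("BioNetwork '%s': %d nodes, %d edges\n",
              object@name, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "ReferenceNetworkSet", function(object) {
  cat(summarizeRefset(object), sep = "\n")
})

setMethod("show", "MergedNetwork", function(object) {
  tab <- table(factor(object@provenance, c("only_g1", "only_g2", "shared")))
  cat(sprintf("MergedNetwork: %d nodes (%d only G1, %d only G2, %d shared), %d edges\n",
              length(object@order), tab[["only_g1"]], tab[["only_g2"]],
              tab[["shared"]], nrow(object@network@edges)))
})

setMethod("show", "SemanticMatrix", function(object) {
  cat(sprintf("SemanticMatrix: %d x %d, combine = %s, max = %.3f\n",
              nrow(object@values), ncol(object@values), object@combine,
              if (length(object@values)) max(object@values) else NA_real_))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d nodes in %d clusters (%s)\n",
              length(object@labels), object@nClusters,
              if (object@converged) "converged" else "component fallback"))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: nperm = %d, mean = %.4f, sd = %.4f\n",
              object@nperm, object@mean, object@sd))
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint of '%s' against %d reference networks (nperm = %d, seed = %d)\n",
              object@queryName, length(object@refName), object@nperm, object@seed))
  if (length(object@refName)) {
    top <- utils::head(topFraction(object, 1), 5L)
    cat("top coordinates:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s/%s  %.4f\n", top$group[i], top$name[i], top$standardized[i]))
    }
  }
})
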