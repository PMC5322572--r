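## Degree-preserving rewiring and z-score standardization.

#' Degree-preserving random rewiring of a network
#'
#' Maslov-Sneppen randomization: repeated double-edge swaps (pick edges
#' (a,b) and (c,d), replace with (a,d) and (c,b) unless a self-loop or
#' duplicate edge would result). Node set and every node's degree are
#' conserved exactly; only the wiring is randomized. The number of swap
#' attempts is `swapsPerEdge * |E|` (default 10 per edge, the conventional
#' mixing heuristic).
#'
#' @param net a [BioNetwork-class] with at least 2 edges (fewer: returned
#'   unchanged with a warning, no swap is possible).
#' @param swapsPerEdge swap attempts per edge.
#' @param seed integer seed.
#' @return a rewired [BioNetwork-class].
#' @references Maslov S, Sneppen K (2002) Specificity and stability in
#'   topology of protein networks. Science 296:910-913.
#' @export
rewireNetwork <- function(net, swapsPerEdge = 10L, seed = 1L) {
  m <- nrow(networkEdges(net))
  if (m < 2L) {
    warning("fewer than 2 edges; returning the network unchanged", call. = FALSE)
    return(net)
  }
  g <- asIgraph(net)
  g2 <- withSeed(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = swapsPerEdge * m)))
  fromIgraph(g2, networkName(net))
}

#' Null distribution of the similarity score under rewiring
#'
#' Recomputes the raw similarity `nperm` times with the query and/or
#' reference network rewired (degree-preserving), leaving node labels --
#' and hence all annotations and the semantic matrix -- untouched. The
#' master seed is split into per-permutation streams, so earlier draws are
#' unchanged when `nperm` grows. Both networks are rewired by default,
#' removing topological bias from either side.
#'
#' @param query,ref [BioNetwork-class] objects.
#' @param ont an [OntologySet-class].
#' @param nperm number of randomized draws (>= 2); 100 by default.
#' @param seed master integer seed.
#' @param rewireMode which side to rewire: `"both"` (default), `"query"`,
#'   or `"ref"`.
#' @param swapsPerEdge swap attempts per edge, see [rewireNetwork()].
#' @param sim optional precomputed [SemanticMatrix-class] (labels are
#'   wiring-invariant, so the observed pair's matrix is reused).
#' @param ... further arguments passed to [rawSimilarity()].
#' @return a [NullDistribution-class].
#' @export
nullDistribution <- function(query, ref, ont, nperm = 100L, seed = 1L,
                             rewireMode = c("both", "query", "ref"),
                             swapsPerEdge = 10L, sim = NULL, ...) {
  rewireMode <- match.arg(rewireMode)
  nperm <- as.integer(nperm)
  if (nperm < 2L) stop("nperm must be at least 2")
  if (is.null(sim)) {
    sim <- semanticMatrix(mergeNetworks(query, ref), ont)
  }
  scores <- vapply(seq_len(nperm), function(p) {
    sp <- permSeed(seed, p)
    q2 <- if (rewireMode %in% c("both", "query")) {
      suppressWarnings(rewireNetwork(query, swapsPerEdge, permSeed(sp, 1L)))
    } else query
    r2 <- if (rewireMode %in% c("both", "ref")) {
      suppressWarnings(rewireNetwork(ref, swapsPerEdge, permSeed(sp, 2L)))
    } else ref
    rawSimilarity(q2, r2, ont, sim = sim, seed = sp, ...)
  }, numeric(1L))
  new("NullDistribution", scores = scores, mean = mean(scores),
      sd = stats::sd(scores), nperm = nperm, seed = as.integer(seed))
}

#' Standardize an observed score against a null distribution
#'
#' `z = (observed - mean(null)) / sd(null)` with the sample (n - 1)
#' standard deviation. A degenerate null (sd = 0) yields 0 when the
#' observed score equals the null mean and a signed infinity sentinel
#' otherwise, with a warning.
#'
#' @param observed observed raw similarity.
#' @param null a [NullDistribution-class].
#' @return the standardized score (one fingerprint coordinate).
#' @export
standardize <- function(observed, null) {
  if (null@nperm < 1L || !length(null@scores)) stop("empty null distribution")
  if (null@sd == 0) {
    if (observed == null@mean) return(0)
    warning("null distribution has zero spread; returning signed infinity",
            call. = FALSE)
    return(sign(observed - null@mean) * Inf)
  }
  (observed - null@mean) / null@sd
}

#' Export a null distribution as TSV
#'
#' One row per permutation (`permutation`, `score`), for audit.
#'
#' @param null a [NullDistribution-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportNull <- function(null, path) {
  utils::write.table(
    data.frame(permutation = seq_len(null@nperm), score = null@scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
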