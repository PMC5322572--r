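## Affinity propagation clustering (Frey & Dueck message passing).

#' Affinity propagation clustering of a similarity matrix
#'
#' Standard responsibility/availability message passing with damping on a
#' (possibly asymmetric) similarity matrix. The shared preference is placed
#' on the diagonal; `preference = "median"` uses the median off-diagonal
#' similarity, the conventional choice yielding a moderate number of
#' clusters. A deterministic, seeded jitter of relative magnitude 1e-12
#' breaks exact ties (skipped for an all-zero input, whose natural fixed
#' point is all-zero messages). Convergence means the exemplar set was
#' stable for `convIter` consecutive sweeps; on non-convergence (including
#' the no-exemplar case) the partition falls back to the connected
#' components of the positive-similarity graph, with a logged note.
#'
#' After convergence, exemplars are refined by maximizing within-cluster
#' similarity sums and points reassigned to their best exemplar, ties going
#' to the lowest index; cluster ids are renumbered by exemplar node order.
#'
#' @param sim square numeric similarity matrix (rows/columns named by item)
#'   or a [SemanticMatrix-class].
#' @param preference `"median"` or a number placed on the diagonal; lower
#'   values yield fewer clusters.
#' @param damping message damping factor in `[0.5, 1)`.
#' @param maxIter maximum number of message-passing sweeps.
#' @param convIter sweeps of exemplar stability required for convergence.
#' @param seed seed for the tie-break jitter.
#' @return a [ClusterAssignment-class].
#' @references Frey BJ, Dueck D (2007) Clustering by passing messages
#'   between data points. Science 315:972-976.
#' @export
apCluster <- function(sim, preference = "median", damping = 0.9,
                      maxIter = 1000L, convIter = 50L, seed = 1L) {
  S <- if (is(sim, "SemanticMatrix")) simValues(sim) else sim
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("sim must be a square matrix")
  n <- nrow(S)
  if (n < 2L) stop("affinity propagation needs at least 2 items")
  if (damping < 0.5 || damping >= 1) stop("damping must lie in [0.5, 1)")
  nodes <- rownames(S)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  off <- S[row(S) != col(S)]
  pref <- if (identical(preference, "median")) stats::median(off) else as.numeric(preference)
  W <- S
  diag(W) <- pref
  scale <- max(abs(W))
  if (scale > 0) {
    W <- W + withSeed(seed, matrix(stats::rnorm(n * n), n, n)) * (1e-12 * scale)
  }

  R <- A <- matrix(0, n, n)
  idx <- seq_len(n)
  Eold <- rep(FALSE, n)
  stable <- 0L
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    ## responsibilities
    AS <- A + W
    m1i <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(idx, m1i)]
    AS[cbind(idx, m1i)] <- -Inf
    m2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- W - m1
    Rnew[cbind(idx, m1i)] <- W[cbind(idx, m1i)] - m2
    R <- damping * R + (1 - damping) * Rnew
    ## availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    Anew <- matrix(colSums(Rp), n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew

    E <- (diag(A) + diag(R)) > 0
    if (identical(E, Eold)) stable <- stable + 1L else { stable <- 0L; Eold <- E }
    if (stable >= convIter && any(E)) { converged <- TRUE; break }
  }

  if (converged) {
    I <- which(Eold)
    K <- length(I)
    cl <- max.col(W[, I, drop = FALSE], ties.method = "first")
    cl[I] <- seq_len(K)
    for (k in seq_len(K)) { # exemplar refinement, lowest index on ties
      ii <- which(cl == k)
      I[k] <- ii[which.max(colSums(W[ii, ii, drop = FALSE]))]
    }
    cl <- max.col(W[, I, drop = FALSE], ties.method = "first")
    cl[I] <- seq_len(K)
    ord <- order(I)
    relabel <- integer(K)
    relabel[ord] <- seq_len(K)
    labels <- relabel[cl]
    exemplars <- nodes[I[ord]]
  } else {
    message("apCluster: no stable exemplar set after ", maxIter,
            " sweeps; falling back to connected components of the ",
            "positive-similarity graph")
    pos <- (S > 0 | t(S) > 0)
    diag(pos) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(pos, mode = "max")
    comp <- igraph::components(g)$membership
    ## renumber components by their lowest member index
    firsts <- vapply(seq_len(max(comp)), function(c) min(which(comp == c)), integer(1L))
    relabel <- integer(max(comp))
    relabel[order(firsts)] <- seq_len(max(comp))
    labels <- relabel[comp]
    exemplars <- nodes[vapply(seq_len(max(labels)),
                              function(c) min(which(labels == c)), integer(1L))]
  }
  labels <- stats::setNames(as.integer(labels), nodes)
  new("ClusterAssignment", labels = labels, exemplars = exemplars,
      nClusters = length(exemplars), converged = converged)
}
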