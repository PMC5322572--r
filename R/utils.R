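#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic per-index stream splitting: the seed of draw `i` depends only
#' on `(seed, i)`, so increasing the number of permutations never perturbs
#' earlier draws. Values stay strictly below 2^31 (valid R integer seeds).
#' Arithmetic is exact in doubles (products stay below 2^53).
#'
#' @param seed master integer seed.
#' @param i stream index (positive integer).
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
permSeed <- function(seed, i) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  v <- (s * 48271) %% m
  v <- (v + (as.numeric(i) * 16807) %% m) %% m
  v <- (v * 69621 + 1) %% m
  as.integer(if (v == 0) 1 else v)
}

## canonical undirected edge matrix: 2 columns, endpoint-sorted rows, unique,
## lexicographic row order, self-loops removed. Returns list with the matrix
## and counts of dropped self-loops / duplicates.
normalizeEdges <- function(edges) {
  edges <- as.matrix(edges)
  dimnames(edges) <- NULL
  if (length(edges) == 0L) {
    return(list(edges = matrix(character(0), 0L, 2L), selfLoops = 0L, duplicates = 0L))
  }
  if (ncol(edges) != 2L) stop("edge matrix must have two columns")
  storage.mode(edges) <- "character"
  self <- edges[, 1L] == edges[, 2L]
  nSelf <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  swap <- edges[, 1L] > edges[, 2L]
  tmp <- edges[swap, 1L]
  edges[swap, 1L] <- edges[swap, 2L]
  edges[swap, 2L] <- tmp
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  dup <- duplicated(key)
  nDup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  ord <- order(edges[, 1L], edges[, 2L], method = "radix")
  list(edges = edges[ord, , drop = FALSE], selfLoops = nSelf, duplicates = nDup)
}
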