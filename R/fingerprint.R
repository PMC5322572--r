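## Pipeline orchestration: fingerprints, ranking, export, comparison.

utils::globalVariables(c("index", "standardized", "group"))

#' Compute a network fingerprint
#'
#' For each reference network in order: raw merged similarity (see
#' [rawSimilarity()]), rewired-network null distribution (see
#' [nullDistribution()]), and z-score standardization. The resulting vector
#' of standardized scores, one coordinate per reference network, is the
#' fingerprint of the query. Standardization is the dominant cost
#' (`nperm + 1` similarity evaluations per reference), so per-reference
#' progress and timings are logged.
#'
#' @param query a [BioNetwork-class].
#' @param refset a non-empty [ReferenceNetworkSet-class].
#' @param ont an [OntologySet-class].
#' @param nperm number of randomized networks for standardization
#'   (default 100).
#' @param seed master integer seed; the run is fully deterministic given
#'   identical inputs and seed.
#' @param combine gene similarity combiner (`"max"`/`"bma"`).
#' @param rewireMode which side the null rewires (`"both"`/`"query"`/`"ref"`).
#' @param swapsPerEdge rewiring intensity.
#' @param preference,damping,maxIter,convIter clustering parameters, see
#'   [apCluster()].
#' @param skipOneSided,sharedOnBothSides cluster scoring options, see
#'   [globalSimilarity()].
#' @param verbose log per-reference progress (default `TRUE`).
#' @return a [Fingerprint-class].
#' @export
calcFingerprint <- function(query, refset, ont, nperm = 100L, seed = 1L,
                            combine = c("max", "bma"),
                            rewireMode = c("both", "query", "ref"),
                            swapsPerEdge = 10L, preference = "median",
                            damping = 0.9, maxIter = 1000L, convIter = 50L,
                            skipOneSided = FALSE, sharedOnBothSides = FALSE,
                            verbose = TRUE) {
  combine <- match.arg(combine)
  rewireMode <- match.arg(rewireMode)
  n <- length(refset)
  if (n == 0L) stop("reference network set is empty")
  nperm <- as.integer(nperm)
  raw <- nm <- nsd <- std <- numeric(n)
  ncl <- integer(n)
  for (i in seq_len(n)) {
    refName <- refNames(refset)[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      rs <- permSeed(seed, 1000000 + i)
      det <- rawSimilarity(query, refNetworks(refset)[[i]], ont,
                           combine = combine, preference = preference,
                           damping = damping, maxIter = maxIter,
                           convIter = convIter, seed = rs,
                           skipOneSided = skipOneSided,
                           sharedOnBothSides = sharedOnBothSides,
                           details = TRUE)
      nd <- nullDistribution(query, refNetworks(refset)[[i]], ont,
                             nperm = nperm, seed = rs,
                             rewireMode = rewireMode,
                             swapsPerEdge = swapsPerEdge, sim = det$sim,
                             preference = preference, damping = damping,
                             maxIter = maxIter, convIter = convIter,
                             skipOneSided = skipOneSided,
                             sharedOnBothSides = sharedOnBothSides)
      list(det = det, nd = nd)
    }, error = function(e) {
      stop("reference '", refName, "': ", conditionMessage(e), call. = FALSE)
    })
    raw[i] <- res$det$score
    nm[i] <- nullMean(res$nd)
    nsd[i] <- nullSd(res$nd)
    std[i] <- standardize(raw[i], res$nd)
    ncl[i] <- nClusters(res$det$clusters)
    if (verbose) {
      message(sprintf(
        "[%d/%d] %s/%s: raw=%.4f null=%.4f+/-%.4f z=%.3f clusters=%d (%.1fs)",
        i, n, refGroups(refset)[i], refName, raw[i], nm[i], nsd[i], std[i],
        ncl[i], proc.time()[["elapsed"]] - t0))
    }
  }
  new("Fingerprint",
      group = refGroups(refset), refName = refNames(refset),
      raw = raw, nullMean = nm, nullSd = nsd, standardized = std,
      nClusters = ncl, queryName = networkName(query), nperm = nperm,
      seed = as.integer(seed),
      params = list(combine = combine, rewireMode = rewireMode,
                    swapsPerEdge = swapsPerEdge, preference = preference,
                    damping = damping, maxIter = maxIter,
                    convIter = convIter, skipOneSided = skipOneSided,
                    sharedOnBothSides = sharedOnBothSides))
}

#' Top fraction of a fingerprint
#'
#' Entries sorted by standardized score, descending, ties broken by
#' reference order; returns the first `ceiling(fraction * n)` rows (e.g.
#' `fraction = 0.1` for the top decile).
#'
#' @param fp a non-empty [Fingerprint-class].
#' @param fraction number in (0, 1].
#' @return data frame with columns `group`, `name`, `standardized`.
#' @export
topFraction <- function(fp, fraction) {
  n <- length(fp)
  if (n == 0L) stop("empty fingerprint")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  ord <- order(-fp@standardized, seq_len(n)) # stable: ties keep entry order
  k <- ceiling(fraction * n)
  data.frame(group = fp@group[ord], name = fp@refName[ord],
             standardized = fp@standardized[ord],
             stringsAsFactors = FALSE)[seq_len(k), , drop = FALSE]
}

fmtNum <- function(x) {
  ifelse(is.infinite(x), ifelse(x > 0, "inf", "-inf"), sprintf("%.17g", x))
}

parseNum <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x == "inf"] <- Inf
  out[x == "-inf"] <- -Inf
  out
}

#' Export / import a fingerprint
#'
#' Writes the per-reference table as TSV (columns `group`, `name`, `raw`,
#' `null_mean`, `null_sd`, `standardized`, `n_clusters`) plus a JSON
#' sidecar `<path>.json` holding query name, nperm, seed and the parameter
#' snapshot. Numbers use full precision and infinite sentinels serialize as
#' `"inf"`/`"-inf"`, so `importFingerprint(exportFingerprint(fp))`
#' reconstructs an identical object.
#'
#' @param fp a [Fingerprint-class].
#' @param path TSV output path.
#' @return `exportFingerprint`: `path` invisibly; `importFingerprint`: a
#'   [Fingerprint-class].
#' @export
exportFingerprint <- function(fp, path) {
  tab <- data.frame(
    group = fp@group, name = fp@refName, raw = fmtNum(fp@raw),
    null_mean = fmtNum(fp@nullMean), null_sd = fmtNum(fp@nullSd),
    standardized = fmtNum(fp@standardized), n_clusters = fp@nClusters,
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(query_name = fp@queryName, nperm = fp@nperm, seed = fp@seed,
               params = fp@params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname exportFingerprint
#' @export
importFingerprint <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) stop("fingerprint table has no rows: ", path)
  need <- c("group", "name", "raw", "null_mean", "null_sd", "standardized",
            "n_clusters")
  if (!all(need %in% names(tab))) {
    stop("fingerprint table must have columns: ", paste(need, collapse = ", "))
  }
  metaPath <- paste0(path, ".json")
  if (!file.exists(metaPath)) stop("missing metadata sidecar: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  params <- as.list(meta$params)
  params$swapsPerEdge <- as.integer(params$swapsPerEdge)
  params$maxIter <- as.integer(params$maxIter)
  params$convIter <- as.integer(params$convIter)
  new("Fingerprint",
      group = tab$group, refName = tab$name, raw = parseNum(tab$raw),
      nullMean = parseNum(tab$null_mean), nullSd = parseNum(tab$null_sd),
      standardized = parseNum(tab$standardized),
      nClusters = as.integer(tab$n_clusters),
      queryName = meta$query_name, nperm = as.integer(meta$nperm),
      seed = as.integer(meta$seed), params = params)
}

#' Compare fingerprints computed against the same reference set
#'
#' Stacks the standardized vectors into a long table suitable for overlay
#' plotting and computes the pairwise Euclidean distance and Pearson
#' correlation matrices between fingerprint vectors. All fingerprints must
#' share the same `(group, name)` reference sequence.
#'
#' @param fps list of [Fingerprint-class] objects (>= 2).
#' @return list with elements `long` (data frame `query_name`, `group`,
#'   `reference_name`, `standardized`), `euclidean` and `pearson`
#'   (query-by-query matrices).
#' @export
compareFingerprints <- function(fps) {
  if (!is.list(fps) || length(fps) < 2L) stop("need a list of at least 2 fingerprints")
  key <- function(fp) paste(fp@group, fp@refName, sep = "\r")
  ref <- key(fps[[1L]])
  for (fp in fps[-1L]) {
    if (!identical(key(fp), ref)) {
      stop("fingerprints were computed against different reference sets")
    }
  }
  qn <- make.unique(vapply(fps, function(fp) fp@queryName, character(1L)))
  M <- do.call(rbind, lapply(fps, function(fp) fp@standardized))
  rownames(M) <- qn
  colnames(M) <- fps[[1L]]@refName
  long <- do.call(rbind, lapply(seq_along(fps), function(i) {
    data.frame(query_name = qn[i], group = fps[[i]]@group,
               reference_name = fps[[i]]@refName,
               standardized = fps[[i]]@standardized,
               stringsAsFactors = FALSE)
  }))
  eu <- as.matrix(stats::dist(M))
  pe <- suppressWarnings(stats::cor(t(M)))
  dimnames(eu) <- dimnames(pe) <- list(qn, qn)
  list(long = long, euclidean = eu, pearson = pe)
}

#' Plot-ready fingerprint table
#'
#' One row per reference with a plotting index; per-group index blocks are
#' contiguous (groups ordered by first appearance, original order within a
#' group), so groups render as colored blocks along the x axis.
#'
#' @param fp a non-empty [Fingerprint-class].
#' @return data frame with columns `index`, `name`, `group`, `standardized`.
#' @export
plotData <- function(fp) {
  if (length(fp) == 0L) stop("empty fingerprint")
  ord <- order(match(fp@group, unique(fp@group)), seq_len(length(fp)))
  data.frame(index = seq_len(length(fp)), name = fp@refName[ord],
             group = fp@group[ord], standardized = fp@standardized[ord],
             stringsAsFactors = FALSE)
}

#' Plot a fingerprint (best effort)
#'
#' Lollipop-style overview of the standardized scores, colored by reference
#' group. Requires ggplot2; the tabular contract is [plotData()].
#'
#' @param fp a [Fingerprint-class].
#' @return a ggplot object.
#' @export
plotFingerprint <- function(fp) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotFingerprint requires the ggplot2 package; use plotData() instead")
  }
  d <- plotData(fp)
  ggplot2::ggplot(d, ggplot2::aes(x = index, y = standardized, color = group)) +
    ggplot2::geom_segment(ggplot2::aes(xend = index, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference network", y = "standardized similarity",
                  title = fp@queryName) +
    ggplot2::theme_minimal()
}
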