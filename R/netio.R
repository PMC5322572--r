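## Network readers/writers and grouped reference-set management.

## BioNetwork <-> igraph conversion (igraph backs GraphML I/O and rewiring)
asIgraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net@nodes), name = net@nodes)
  if (nrow(net@edges)) {
    g <- igraph::add_edges(g, rbind(match(net@edges[, 1L], net@nodes),
                                    match(net@edges[, 2L], net@nodes)))
  }
  g
}

fromIgraph <- function(g, name, quiet = TRUE) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  e <- igraph::as_edgelist(g, names = TRUE)
  bioNetwork(name, nodes = nodes, edges = e, quiet = quiet)
}

#' Read a network file
#'
#' Supported formats: plain two-column whitespace-separated edge lists
#' (`'#'` comments), GraphML, and a KGML subset (KEGG pathway XML; `entry`
#' elements of type `gene` and `relation` elements). Edge direction is
#' discarded; duplicate and self edges are dropped with a logged count.
#' Multi-gene KGML entries are split on whitespace into individual gene
#' nodes and, by convention, connected as a clique (toggle with
#' `expandClique`).
#'
#' @param path network file path.
#' @param format one of `"edgelist"`, `"graphml"`, `"kgml"`.
#' @param name network name; defaults to the file base name (for KGML the
#'   pathway `title`/`name` attribute when present).
#' @param expandClique KGML only: connect genes within one multi-gene entry
#'   (default `TRUE`).
#' @return a [BioNetwork-class].
#' @export
readNetwork <- function(path, format = c("edgelist", "graphml", "kgml"),
                        name = NULL, expandClique = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read network file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  net <- switch(format,
    edgelist = {
      lines <- readLines(path, warn = FALSE)
      lines <- trimws(sub("#.*$", "", lines))
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "\\s+")
      if (!length(parts)) stop("empty network: ", path)
      if (any(lengths(parts) != 2L)) {
        stop("edge list must have exactly two columns per line: ", path)
      }
      edges <- do.call(rbind, parts)
      bioNetwork(name, edges = edges, quiet = FALSE)
    },
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      g <- igraph::as_undirected(g, mode = "collapse")
      fromIgraph(g, name, quiet = FALSE)
    },
    kgml = readKGML(path, name = name, expandClique = expandClique)
  )
  if (length(networkNodes(net)) == 0L) stop("empty network: ", path)
  net
}

readKGML <- function(path, name = NULL, expandClique = TRUE) {
  doc <- xml2::read_xml(path)
  title <- xml2::xml_attr(xml2::xml_root(doc), "title")
  if (!is.na(title) && nzchar(title)) name <- title
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
  ids <- xml2::xml_attr(entries, "id")
  genes <- strsplit(trimws(xml2::xml_attr(entries, "name")), "\\s+")
  names(genes) <- ids
  edges <- matrix(character(0), 0L, 2L)
  if (expandClique) {
    for (gs in genes) {
      if (length(gs) > 1L) {
        edges <- rbind(edges, t(utils::combn(gs, 2L)))
      }
    }
  }
  rels <- xml2::xml_find_all(doc, ".//relation")
  e1 <- xml2::xml_attr(rels, "entry1")
  e2 <- xml2::xml_attr(rels, "entry2")
  for (k in seq_along(rels)) {
    a <- genes[[e1[k]]]
    b <- genes[[e2[k]]]
    if (is.null(a) || is.null(b)) next # relation touching a non-gene entry
    edges <- rbind(edges, as.matrix(expand.grid(a, b, stringsAsFactors = FALSE)))
  }
  bioNetwork(name, nodes = unlist(genes, use.names = FALSE), edges = edges,
             quiet = FALSE)
}

#' Write a network file
#'
#' Inverse of [readNetwork()]; all three formats round-trip through the
#' reader. Note that the edge-list format cannot represent isolated nodes.
#'
#' @param net a [BioNetwork-class].
#' @param path output path.
#' @param format one of `"edgelist"`, `"graphml"`, `"kgml"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("edgelist", "graphml", "kgml")) {
  format <- match.arg(format)
  switch(format,
    edgelist = {
      e <- networkEdges(net)
      iso <- setdiff(networkNodes(net), as.vector(e))
      if (length(iso)) {
        warning("edge-list format drops ", length(iso), " isolated node(s)",
                call. = FALSE)
      }
      writeLines(c(paste0("# ", networkName(net)), paste(e[, 1L], e[, 2L])), path)
    },
    graphml = igraph::write_graph(asIgraph(net), path, format = "graphml"),
    kgml = {
      nodes <- networkNodes(net)
      idx <- stats::setNames(seq_along(nodes), nodes)
      e <- networkEdges(net)
      lines <- c(
        "<?xml version=\"1.0\"?>",
        sprintf("<pathway name=\"path:%s\" title=\"%s\">",
                networkName(net), networkName(net)),
        sprintf("  <entry id=\"%d\" name=\"%s\" type=\"gene\"/>",
                idx, nodes),
        sprintf("  <relation entry1=\"%d\" entry2=\"%d\" type=\"PPrel\"/>",
                idx[e[, 1L]], idx[e[, 2L]]),
        "</pathway>"
      )
      writeLines(lines, path)
    }
  )
  invisible(path)
}

#' Load a grouped reference network set from a manifest
#'
#' The manifest is a tab-separated file with a header and columns
#' `group`, `name`, `path`, `format`; network paths are resolved relative
#' to the manifest's directory. Entry order is preserved exactly: it is the
#' coordinate order of every fingerprint computed against the set.
#' Reference collections are typically organized in a handful of curated
#' categories (pathway databases use up to seven, e.g. metabolism, genetic
#' information processing, cellular processes).
#'
#' @param manifest manifest file path.
#' @return a [ReferenceNetworkSet-class].
#' @export
loadRefset <- function(manifest) {
  if (!file.exists(manifest)) stop("cannot read manifest: ", manifest)
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("group", "name", "path", "format")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(paste(tab$group, tab$name, sep = "\r"))) {
    stop("duplicate (group, name) pair in manifest")
  }
  base <- dirname(manifest)
  nets <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base, tab$path[i])
    if (!file.exists(p)) stop("missing network file: ", tab$path[i])
    nets[[i]] <- readNetwork(p, format = tab$format[i], name = tab$name[i])
  }
  referenceNetworkSet(tab$group, tab$name, nets)
}

#' Subset a reference set by group or by network name
#'
#' Both selections keep the original relative entry order and are
#' idempotent; they error on unknown labels rather than silently returning
#' fewer entries.
#'
#' @param refset a [ReferenceNetworkSet-class].
#' @param groups,names character vectors of labels to keep.
#' @return a [ReferenceNetworkSet-class].
#' @export
selectGroup <- function(refset, groups) {
  unknown <- setdiff(groups, refGroups(refset))
  if (length(unknown)) stop("unknown group(s): ", paste(unknown, collapse = ", "))
  keep <- refGroups(refset) %in% groups
  referenceNetworkSet(refGroups(refset)[keep], refNames(refset)[keep],
                      refNetworks(refset)[keep])
}

#' @rdname selectGroup
#' @export
selectNetworks <- function(refset, names) {
  unknown <- setdiff(names, refNames(refset))
  if (length(unknown)) stop("unknown network name(s): ", paste(unknown, collapse = ", "))
  keep <- refNames(refset) %in% names
  referenceNetworkSet(refGroups(refset)[keep], refNames(refset)[keep],
                      refNetworks(refset)[keep])
}

#' Summarize a reference network set
#'
#' @param refset a [ReferenceNetworkSet-class].
#' @return character vector: one header line with group/network counts, then
#'   one line per entry with node and edge counts.
#' @export
summarizeRefset <- function(refset) {
  n <- length(refset)
  head <- sprintf("ReferenceNetworkSet: %d groups, %d networks",
                  length(unique(refGroups(refset))), n)
  if (n == 0L) return(head)
  lines <- vapply(seq_len(n), function(i) {
    net <- refNetworks(refset)[[i]]
    sprintf("  [%d] %s/%s: %d nodes, %d edges", i, refGroups(refset)[i],
            refNames(refset)[i], length(networkNodes(net)),
            nrow(networkEdges(net)))
  }, character(1L))
  c(head, lines)
}

#' Write a reference set to disk with a manifest
#'
#' Writes each member network in the requested format plus a manifest TSV
#' that [loadRefset()] reads back; used by the fixture generator.
#'
#' @param refset a [ReferenceNetworkSet-class].
#' @param dir output directory (created if needed).
#' @param formats per-entry file format (recycled).
#' @return the manifest path, invisibly.
#' @export
writeRefset <- function(refset, dir, formats = "edgelist") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(refset)
  formats <- rep_len(formats, n)
  ext <- c(edgelist = "txt", graphml = "graphml", kgml = "xml")
  files <- sprintf("%s.%s", refNames(refset), ext[formats])
  for (i in seq_len(n)) {
    writeNetwork(refNetworks(refset)[[i]], file.path(dir, files[i]), formats[i])
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(group = refGroups(refset), name = refNames(refset),
               path = files, format = formats, stringsAsFactors = FALSE),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(manifest)
}
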