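## Ontology parsing, information content and Resnik semantic similarity.

#' Load an OBO ontology restricted to one namespace
#'
#' Reads an OBO 1.2/1.4 flat file, keeps the `[Term]` stanzas of the
#' requested namespace, drops obsolete terms, and records `alt_id` mappings
#' so annotation files using secondary identifiers still resolve. Parent
#' links follow `is_a` and, optionally, `relationship: part_of`.
#'
#' @param path OBO file path.
#' @param namespace namespace to keep (default `"biological_process"`).
#' @param includePartOf include `part_of` relationships as parent edges
#'   (default `TRUE`, common ontology practice).
#' @return an [OntologyDAG-class].
#' @seealso [writeOBO()], [loadGAF()]
#' @export
loadOBO <- function(path, namespace = "biological_process",
                    includePartOf = TRUE) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file: ", path)
  bounds <- c(starts, length(lines) + 1L)
  id <- ns <- character(0)
  obsolete <- logical(0)
  parents <- list()
  alt <- character(0)
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    body <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    field <- function(tag) sub(paste0("^", tag, ":\\s*"), "",
                               grep(paste0("^", tag, ":"), body, value = TRUE))
    tid <- field("id")[1L]
    if (is.na(tid) || !nzchar(tid)) next
    tns <- field("namespace")[1L]
    isa <- sub("\\s*!.*$", "", field("is_a"))
    if (includePartOf) {
      rel <- sub("\\s*!.*$", "", field("relationship"))
      po <- grep("^part_of\\s+", rel, value = TRUE)
      isa <- c(isa, sub("^part_of\\s+", "", po))
    }
    id <- c(id, tid)
    ns <- c(ns, if (is.na(tns)) "" else tns)
    obsolete <- c(obsolete, any(grepl("^true", field("is_obsolete"))))
    parents[[tid]] <- trimws(isa)
    for (a in field("alt_id")) alt[trimws(a)] <- tid
  }
  keep <- !obsolete & ns == namespace
  if (!any(keep)) stop("namespace '", namespace, "' absent from ", path)
  kept <- id[keep]
  parents <- lapply(parents[kept], function(p) intersect(p, kept))
  alt <- alt[alt %in% kept]
  ontologyDAG(parents, namespace = namespace, altIds = alt)
}

#' Write an ontology as an OBO file
#'
#' Emits one `[Term]` stanza per term with `id`, `name`, `namespace` and
#' `is_a` lines; output round-trips through [loadOBO()].
#'
#' @param dag an [OntologyDAG-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in termIds(dag)) {
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: term ", t),
             paste0("namespace: ", dagNamespace(dag)),
             paste0("is_a: ", termParents(dag)[[t]]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Load gene annotations from a GAF 2.x file
#'
#' Tab-separated GAF rows (comment lines start with `!`): column 2 is the
#' gene identifier, 4 the qualifier, 5 the term, 7 the evidence code and 9
#' the aspect. Rows with a `NOT` qualifier are excluded, term identifiers
#' are mapped through the ontology's `alt_id` table, and terms absent from
#' the ontology are dropped.
#'
#' @param path GAF file path.
#' @param dag companion [OntologyDAG-class].
#' @param excludeEvidence character vector of evidence codes to drop
#'   (e.g. `"IEA"`); default none.
#' @return an [AnnotationTable-class] with `closed = FALSE`.
#' @export
loadGAF <- function(path, dag, excludeEvidence = character(0)) {
  if (!file.exists(path)) stop("cannot read GAF file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) stop("zero usable annotations in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 15L)
  if (length(bad)) {
    stop(sprintf("malformed GAF line %d: expected >= 15 tab-separated fields, got %d",
                 bad[1L], length(fields[[bad[1L]]])))
  }
  gene <- vapply(fields, `[[`, character(1L), 2L)
  qualifier <- vapply(fields, `[[`, character(1L), 4L)
  term <- vapply(fields, `[[`, character(1L), 5L)
  evidence <- vapply(fields, `[[`, character(1L), 7L)
  keep <- !vapply(strsplit(qualifier, "|", fixed = TRUE),
                  function(q) "NOT" %in% q, logical(1L))
  keep <- keep & !(evidence %in% excludeEvidence)
  alt <- dag@altIds
  mapped <- ifelse(term %in% names(alt), alt[term], term)
  keep <- keep & mapped %in% termIds(dag)
  if (!any(keep)) stop("zero usable annotations in ", path)
  annotationTable(split(mapped[keep], gene[keep]), closed = FALSE, dag = dag)
}

#' Write annotations as a GAF 2.1 file
#'
#' @param ann an [AnnotationTable-class] (direct annotations).
#' @param path output file path.
#' @param aspect single-letter GO aspect written in column 9 (default `"P"`).
#' @param evidence evidence code written in column 7 (default `"IEA"`).
#' @return `path`, invisibly.
#' @export
writeGAF <- function(ann, path, aspect = "P", evidence = "IEA") {
  gt <- geneTerms(ann)
  rows <- unlist(lapply(names(gt), function(g) {
    vapply(gt[[g]], function(t) {
      paste(c("TOYDB", g, g, "", t, "TOY_REF:0000001", evidence, "",
              aspect, "", "", "gene", "taxon:0000", "20240101", "TOYDB",
              "", ""), collapse = "\t")
    }, character(1L))
  }), use.names = FALSE)
  writeLines(c("!gaf-version: 2.1", rows), path)
  invisible(path)
}

#' Ancestor-close an annotation table
#'
#' Replaces each gene's term set by the union of the terms and all their
#' ancestors in the ontology. Idempotent; a prerequisite for information
#' content (a gene annotated to a term is implicitly annotated to every
#' generalization of it).
#'
#' @param dag an [OntologyDAG-class].
#' @param ann an [AnnotationTable-class].
#' @return a closed [AnnotationTable-class].
#' @export
closeAnnotations <- function(dag, ann) {
  anc <- termAncestors(dag)
  gt <- geneTerms(ann)
  unknown <- setdiff(unique(unlist(gt, use.names = FALSE)), termIds(dag))
  if (length(unknown)) {
    stop("annotated term(s) not in ontology: ", paste(unknown, collapse = ", "))
  }
  closed <- lapply(gt, function(ts) sort(unique(unlist(anc[ts], use.names = FALSE))))
  annotationTable(closed, closed = TRUE)
}

#' Compute per-term information content
#'
#' `ic[t] = -ln(n_t / n_root)` where `n_t` is the number of genes whose
#' ancestor-closed term set contains `t` and `n_root` is the size of the
#' annotated corpus (every closed gene reaches the root). Terms reached by
#' no gene are absent from the table.
#'
#' @param dag an [OntologyDAG-class].
#' @param closedAnn an ancestor-closed [AnnotationTable-class].
#' @return an [ICTable-class] (natural-log units).
#' @export
computeIC <- function(dag, closedAnn) {
  if (!isClosed(closedAnn)) stop("annotations must be ancestor-closed first")
  gt <- geneTerms(closedAnn)
  gt <- gt[lengths(gt) > 0L]
  counts <- table(unlist(gt, use.names = FALSE))
  root <- dagRoot(dag)
  if (!root %in% names(counts)) stop("no gene is annotated at the root; empty corpus")
  nRoot <- as.integer(counts[[root]])
  ic <- -log(as.numeric(counts) / nRoot)
  names(ic) <- names(counts)
  ic[ic < 0] <- 0 # guard exact-zero rounding
  new("ICTable", ic = ic, corpusSize = nRoot)
}

#' Resnik similarity between two terms
#'
#' Information content of the most informative common ancestor (MICA), each
#' term counting as its own ancestor. Returns 0 when the only shared
#' ancestor is the root or when either term lacks information content.
#'
#' @param ic an [ICTable-class].
#' @param dag an [OntologyDAG-class].
#' @param t1,t2 term identifiers.
#' @return non-negative number.
#' @export
resnikTermSim <- function(ic, dag, t1, t2) {
  anc <- termAncestors(dag)
  if (!t1 %in% names(anc)) stop("unknown term: ", t1)
  if (!t2 %in% names(anc)) stop("unknown term: ", t2)
  v <- icValues(ic)
  if (!(t1 %in% names(v)) || !(t2 %in% names(v))) return(0)
  common <- intersect(anc[[t1]], anc[[t2]])
  vals <- v[common[common %in% names(v)]]
  if (!length(vals)) 0 else max(vals)
}

## Resnik similarity matrix over a set of terms (rows = cols = terms).
## Used internally to vectorize gene-level similarity.
resnikTermMatrix <- function(ic, dag, terms) {
  anc <- termAncestors(dag)
  v <- icValues(ic)
  n <- length(terms)
  M <- matrix(0, n, n, dimnames = list(terms, terms))
  hasIC <- terms %in% names(v)
  for (i in seq_len(n)) {
    if (!hasIC[i]) next
    ai <- anc[[terms[i]]]
    for (j in i:n) {
      if (!hasIC[j]) next
      common <- intersect(ai, anc[[terms[j]]])
      vals <- v[common[common %in% names(v)]]
      if (length(vals)) M[i, j] <- M[j, i] <- max(vals)
    }
  }
  M
}

## gene-level combiner over a precomputed term-pair similarity submatrix
combineTermSim <- function(sub, combine) {
  if (combine == "max") return(max(sub))
  ## best-match average, bidirectional
  (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) / (nrow(sub) + ncol(sub))
}

#' Resnik similarity between two genes
#'
#' Lifts term-level Resnik similarity to gene pairs over the genes'
#' (preferably ancestor-closed) term sets. `combine = "max"` takes the
#' maximum over the term cross product; `combine = "bma"` the bidirectional
#' best-match average. A gene without annotations scores 0 (with a warning).
#'
#' @param ic an [ICTable-class].
#' @param dag an [OntologyDAG-class].
#' @param ann an [AnnotationTable-class].
#' @param g1,g2 gene identifiers.
#' @param combine `"max"` (default) or `"bma"`.
#' @return non-negative number.
#' @export
geneSim <- function(ic, dag, ann, g1, g2, combine = c("max", "bma")) {
  combine <- match.arg(combine)
  gt <- geneTerms(ann)
  t1 <- gt[[g1]]
  t2 <- gt[[g2]]
  if (is.null(t1) || !length(t1) || is.null(t2) || !length(t2)) {
    warning("unannotated gene scored 0: ",
            paste(c(g1, g2)[c(!length(t1), !length(t2))], collapse = ", "),
            call. = FALSE)
    return(0)
  }
  terms <- unique(c(t1, t2))
  M <- resnikTermMatrix(ic, dag, terms)
  combineTermSim(M[t1, t2, drop = FALSE], combine)
}

#' Bundle ontology handles for similarity computations
#'
#' Convenience container pairing an ontology with (closed) annotations and
#' their information content, the three handles every similarity stage
#' needs. Annotations are closed and IC computed automatically when not
#' supplied in final form.
#'
#' @slot dag an [OntologyDAG-class].
#' @slot annotations a closed [AnnotationTable-class].
#' @slot ic an [ICTable-class].
#' @export
setClass("OntologySet",
  representation(dag = "OntologyDAG", annotations = "AnnotationTable", ic = "ICTable")
)

setValidity("OntologySet", function(object) {
  if (!isClosed(object@annotations)) "annotations must be ancestor-closed" else TRUE
})

#' @describeIn OntologySet-class construct from a DAG and (direct or closed)
#'   annotations; closes and computes IC as needed.
#' @param dag an [OntologyDAG-class].
#' @param ann an [AnnotationTable-class].
#' @param ic optional precomputed [ICTable-class].
#' @export
ontologySet <- function(dag, ann, ic = NULL) {
  if (!isClosed(ann)) ann <- closeAnnotations(dag, ann)
  if (is.null(ic)) ic <- computeIC(dag, ann)
  new("OntologySet", dag = dag, annotations = ann, ic = ic)
}

setMethod("show", "OntologySet", function(object) {
  show(object@dag)
  show(object@annotations)
  show(object@ic)
})
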