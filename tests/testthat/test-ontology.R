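## Ontology parsing, annotation closure, information content, Resnik.

miniOBO <- function(...) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", ...), path)
  path
}

test_that("loadOBO keeps the requested namespace, drops obsolete terms, maps alt_id", {
  path <- miniOBO(
    "[Term]", "id: T:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: T:2", "name: a", "namespace: biological_process",
    "alt_id: T:9", "is_a: T:1 ! root", "",
    "[Term]", "id: T:3", "name: b", "namespace: biological_process",
    "is_a: T:1", "",
    "[Term]", "id: T:4", "name: gone", "namespace: biological_process",
    "is_a: T:1", "is_obsolete: true", "",
    "[Term]", "id: T:5", "name: other", "namespace: molecular_function", "",
    "[Typedef]", "id: part_of", "name: part of"
  )
  dag <- loadOBO(path)
  expect_setequal(termIds(dag), c("T:1", "T:2", "T:3"))
  expect_identical(dagRoot(dag), "T:1")
  expect_length(termParents(dag)[["T:1"]], 0)
  expect_identical(unname(dag@altIds["T:9"]), "T:2")
  expect_error(loadOBO(path, namespace = "cellular_component"), "absent")
})

test_that("part_of relationships are parent edges only when requested", {
  path <- miniOBO(
    "[Term]", "id: T:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: T:2", "name: a", "namespace: biological_process",
    "is_a: T:1", "",
    "[Term]", "id: T:3", "name: c", "namespace: biological_process",
    "is_a: T:1", "relationship: part_of T:2 ! a"
  )
  with_po <- loadOBO(path, includePartOf = TRUE)
  without <- loadOBO(path, includePartOf = FALSE)
  expect_setequal(termParents(with_po)[["T:3"]], c("T:1", "T:2"))
  expect_identical(termParents(without)[["T:3"]], "T:1")
})

test_that("a cyclic parent map is rejected", {
  expect_error(
    ontologyDAG(list(r = character(0), a = c("r", "b"), b = "a")),
    "cycle"
  )
})

test_that("toy ontologies round-trip through OBO write/load", {
  for (seed in c(3L, 11L)) {
    obo <- tempfile(fileext = ".obo")
    toy <- makeToyOntology(nTerms = 50L, seed = seed, obo = obo)
    back <- loadOBO(obo)
    expect_identical(termParents(back), termParents(toy$dag))
    expect_identical(dagRoot(back), dagRoot(toy$dag))
  }
})

test_that("loadGAF keeps usable rows, skips NOT qualifiers, rejects malformed lines", {
  dag <- ontologyDAG(list(r = character(0), a = "r", b = "r"))
  gafRow <- function(gene, term, qual = "", evidence = "IEA") {
    paste(c("DB", gene, gene, qual, term, "REF", evidence, "", "P", "", "",
            "gene", "taxon:1", "20240101", "DB"), collapse = "\t")
  }
  path <- tempfile()
  writeLines(c("!gaf-version: 2.1",
               gafRow("geneA", "a"),
               gafRow("geneA", "zzz"),          # unknown term dropped
               gafRow("geneB", "b", qual = "NOT"),
               gafRow("geneB", "a", evidence = "EXP")), path)
  ann <- loadGAF(path, dag)
  expect_identical(geneTerms(ann), list(geneA = "a", geneB = "a"))
  expect_false(isClosed(ann))

  annNoExp <- loadGAF(path, dag, excludeEvidence = "EXP")
  expect_identical(names(geneTerms(annNoExp)), "geneA")

  bad <- tempfile()
  writeLines(c("!gaf-version: 2.1", "geneA\ta"), bad)
  expect_error(loadGAF(bad, dag), "malformed")

  empty <- tempfile()
  writeLines(c("!gaf-version: 2.1", gafRow("geneC", "nope")), empty)
  expect_error(loadGAF(empty, dag), "zero usable")
})

test_that("synthetic GAF files reload to exactly the generated assignments", {
  toy <- makeToyOntology(nTerms = 30L, seed = 5L)
  gaf <- tempfile(fileext = ".gaf")
  made <- makeAnnotations(toy$dag, sprintf("g%02d", 1:20), termsPerGene = 3L,
                          seed = 7L, gaf = gaf)
  back <- loadGAF(gaf, toy$dag)
  expect_identical(geneTerms(back), made$ledger$assignments)
  expect_length(geneTerms(back), 20L)
  expect_true(all(lengths(geneTerms(back)) == 3L))
})

test_that("annotation closure matches brute-force transitive closure and is idempotent", {
  ## chain DAG: leaf at depth 3 closes to 4 terms
  chain <- ontologyDAG(list(r = character(0), a = "r", b = "a", c = "b"))
  ann <- annotationTable(list(g1 = "c", g2 = "r"))
  closed <- closeAnnotations(chain, ann)
  expect_identical(geneTerms(closed)$g1, c("a", "b", "c", "r"))
  expect_identical(geneTerms(closed)$g2, "r")
  expect_true(isClosed(closed))
  expect_identical(geneTerms(closeAnnotations(chain, closed)), geneTerms(closed))

  for (seed in 1:4) {
    inst <- randomInstance(seed)
    closed <- closeAnnotations(inst$dag, inst$ann)
    expect_identical(geneTerms(closed),
                     oracleClosure(inst$parents, geneTerms(inst$ann)))
  }
  expect_error(closeAnnotations(chain, annotationTable(list(g = "missing"))),
               "not in ontology")
})

test_that("information content has the closed-form values and matches a recount", {
  dag <- ontologyDAG(list(r = character(0), a = "r", b = "r"))
  ## 1 of 4 genes reaches 'a': ic = ln 4; all genes reach root: ic = 0
  ann <- closeAnnotations(dag, annotationTable(
    list(g1 = "a", g2 = "b", g3 = "b", g4 = "b")))
  ic <- computeIC(dag, ann)
  expect_equal(unname(icValues(ic)["a"]), log(4), tolerance = 1e-12)
  expect_identical(unname(icValues(ic)["r"]), 0)
  expect_identical(icCorpusSize(ic), 4L)

  for (seed in 5:8) {
    inst <- randomInstance(seed)
    closed <- closeAnnotations(inst$dag, inst$ann)
    ic <- computeIC(inst$dag, closed)
    want <- oracleIC(inst$parents, geneTerms(inst$ann), dagRoot(inst$dag))
    expect_equal(icValues(ic)[sort(names(want))], want[sort(names(want))],
                 tolerance = 1e-12)
  }
})

test_that("IC is monotone along every specialization edge", {
  for (seed in 2:5) {
    inst <- randomInstance(seed)
    ic <- icValues(inst$ont@ic)
    for (t in names(ic)) {
      for (p in termParents(inst$dag)[[t]]) {
        if (p %in% names(ic)) expect_gte(ic[[t]], ic[[p]])
      }
    }
  }
})

test_that("Resnik term similarity is the MICA information content", {
  dag <- ontologyDAG(list(r = character(0), a = "r", b = "r", a1 = "a"))
  ann <- closeAnnotations(dag, annotationTable(
    list(g1 = "a1", g2 = "a", g3 = "b", g4 = "b")))
  ic <- computeIC(dag, ann)
  ## a term is its own ancestor
  expect_equal(resnikTermSim(ic, dag, "a1", "a1"), unname(icValues(ic)["a1"]))
  ## siblings whose only common ancestor is the root score 0
  expect_identical(resnikTermSim(ic, dag, "a", "b"), 0)
  expect_error(resnikTermSim(ic, dag, "a", "nope"), "unknown term")

  for (seed in 9:12) {
    inst <- randomInstance(seed)
    ic <- inst$ont@ic
    terms <- termIds(inst$dag)
    pairs <- withSeed(seed, cbind(sample(terms, 25L, replace = TRUE),
                                  sample(terms, 25L, replace = TRUE)))
    for (k in seq_len(nrow(pairs))) {
      got <- resnikTermSim(ic, inst$dag, pairs[k, 1L], pairs[k, 2L])
      want <- oracleResnik(inst$parents, icValues(ic), pairs[k, 1L], pairs[k, 2L])
      expect_equal(got, want, tolerance = 1e-12)
      ## bounded by the less informative term
      both <- c(pairs[k, 1L], pairs[k, 2L])
      if (all(both %in% names(icValues(ic)))) {
        expect_lte(got, min(icValues(ic)[both]) + 1e-12)
      }
    }
  }
})

test_that("gene similarity matches the exhaustive term-pair loop and is symmetric", {
  for (seed in 13:16) {
    inst <- randomInstance(seed)
    closed <- geneTerms(inst$ont@annotations)
    genes <- names(closed)
    pick <- withSeed(seed, cbind(sample(genes, 12L, replace = TRUE),
                                 sample(genes, 12L, replace = TRUE)))
    for (k in seq_len(nrow(pick))) {
      for (combine in c("max", "bma")) {
        got <- geneSim(inst$ont@ic, inst$dag, inst$ont@annotations,
                       pick[k, 1L], pick[k, 2L], combine = combine)
        want <- oracleGeneSim(inst$parents, icValues(inst$ont@ic), closed,
                              pick[k, 1L], pick[k, 2L], combine = combine)
        expect_equal(got, want, tolerance = 1e-12)
        rev <- geneSim(inst$ont@ic, inst$dag, inst$ont@annotations,
                       pick[k, 2L], pick[k, 1L], combine = combine)
        expect_equal(got, rev, tolerance = 1e-12)
      }
    }
  }
})

test_that("gene self-similarity and degenerate annotation cases behave", {
  dag <- ontologyDAG(list(r = character(0), a = "r", b = "r"))
  ann <- closeAnnotations(dag, annotationTable(
    list(g1 = c("a", "b"), g2 = "r", g3 = "r", g4 = "b")))
  ic <- computeIC(dag, ann)
  ## self-similarity under max = the gene's most informative term
  expect_equal(geneSim(ic, dag, ann, "g1", "g1"),
               max(icValues(ic)[geneTerms(ann)$g1]))
  ## genes annotated only to the root score 0
  expect_identical(geneSim(ic, dag, ann, "g2", "g3"), 0)
  ## unannotated genes score 0 with a warning
  expect_warning(out <- geneSim(ic, dag, ann, "g1", "ghost"), "unannotated")
  expect_identical(out, 0)
})
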