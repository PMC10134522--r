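obo_fixture <- function(extra = character()) {
  c("format-version: 1.2",
    "",
    "[Term]", "id: GO:R", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:A", "name: a", "namespace: biological_process",
    "is_a: GO:R ! root", "",
    "[Term]", "id: GO:B", "name: b", "namespace: biological_process",
    "is_a: GO:R", "",
    "[Term]", "id: GO:C", "name: c", "namespace: biological_process",
    "is_a: GO:A", "relationship: part_of GO:B", "",
    extra)
}

test_that("OBO parsing builds the expected DAG and excludes obsolete terms", {
  dag <- read_obo(obo_fixture(), "BP")
  expect_s3_class(dag, "go_dag")
  expect_equal(nrow(dag$terms), 4L)
  expect_equal(nrow(dag$edges), 4L)
  expect_equal(dag$root, "GO:R")
  expect_setequal(dag$parents[["GO:C"]], c("GO:A", "GO:B"))
  expect_equal(sort(dag$relations[["GO:C"]]), c("is_a", "part_of"))

  with_obsolete <- read_obo(obo_fixture(c(
    "[Term]", "id: GO:X", "name: gone", "namespace: biological_process",
    "is_a: GO:A", "is_obsolete: true", "")), "BP")
  expect_equal(nrow(with_obsolete$terms), 4L)
  expect_false("GO:X" %in% with_obsolete$terms$id)
})

test_that("alt_id entries resolve to the canonical term", {
  dag <- read_obo(obo_fixture(c(
    "[Term]", "id: GO:D", "name: d", "namespace: biological_process",
    "alt_id: GO:OLD", "is_a: GO:A", "",
    "[Term]", "id: GO:E", "name: e", "namespace: biological_process",
    "is_a: GO:OLD", "")), "BP")
  expect_equal(dag$parents[["GO:E"]], "GO:D")
  expect_equal(unname(dag$alt_ids["GO:OLD"]), "GO:D")
})

test_that("cycles, missing parents and unknown namespaces are hard errors", {
  cyc <- c("format-version: 1.2", "",
           "[Term]", "id: GO:R", "name: r", "namespace: biological_process", "",
           "[Term]", "id: GO:A", "name: a", "namespace: biological_process",
           "is_a: GO:R", "is_a: GO:C", "",
           "[Term]", "id: GO:C", "name: c", "namespace: biological_process",
           "is_a: GO:A", "")
  expect_error(read_obo(cyc, "BP"), "cycle")
  expect_error(read_obo(obo_fixture(c(
    "[Term]", "id: GO:E", "name: e", "namespace: biological_process",
    "is_a: GO:MISSING", "")), "BP"), "missing")
  expect_error(read_obo(obo_fixture(), "XX"), "namespace")
})

test_that("cross-namespace edges are dropped, not kept", {
  dag <- read_obo(obo_fixture(c(
    "[Term]", "id: GO:M", "name: m", "namespace: molecular_function", "",
    "[Term]", "id: GO:E", "name: e", "namespace: biological_process",
    "is_a: GO:A", "is_a: GO:M", "")), "BP")
  expect_equal(dag$parents[["GO:E"]], "GO:A")
  expect_false("GO:M" %in% dag$terms$id)
})

test_that("ancestor closure matches brute-force BFS on random DAGs", {
  for (seed in 1:6) {
    dag <- random_dag(sample(20:200, 1L), seed = seed)
    for (term in sample(dag$terms$id, 12L)) {
      expect_setequal(term_ancestors(dag, term), oracle_closure(dag, term))
    }
  }
  expect_error(term_ancestors(demo_ontology(), "GO:NOPE"), "unknown term")
})

test_that("closure on the demonstration DAG matches hand results", {
  dag <- demo_ontology()
  expect_setequal(term_ancestors(dag, "GO:C"),
                  c("GO:C", "GO:A", "GO:B", "GO:R"))
  expect_setequal(term_ancestors(dag, "GO:D"), c("GO:D", "GO:A", "GO:R"))
  expect_equal(term_ancestors(dag, "GO:R"), "GO:R")
})

test_that("propagation closes term sets and refuses double application", {
  dag <- demo_ontology()
  ann <- demo_annotations()
  prop <- propagate_annotations(ann, dag)
  sets <- split(prop$ann$term, prop$ann$gene)
  expect_setequal(sets$g1, c("GO:C", "GO:A", "GO:B", "GO:R"))
  expect_setequal(sets$g2, c("GO:D", "GO:A", "GO:R"))
  expect_setequal(sets$g3, c("GO:B", "GO:R"))
  expect_true(prop$propagated)
  expect_error(propagate_annotations(prop, dag), "already propagated")

  # root-only annotation is unchanged by propagation
  root_only <- go_annotations(tibble::tibble(gene = "g", term = "GO:R"), dag)
  expect_equal(propagate_annotations(root_only, dag)$ann$term, "GO:R")
})

test_that("propagation is idempotent as a closure map", {
  dag <- random_dag(60, seed = 11)
  ann <- random_corpus(dag, 10, seed = 12)
  once <- propagate_annotations(ann, dag)
  again <- go_annotations(once$ann, dag, propagated = FALSE)
  twice <- propagate_annotations(again, dag)
  expect_equal(dplyr::arrange(once$ann, gene, term),
               dplyr::arrange(twice$ann, gene, term))
})

test_that("information content matches hand counts on the demonstration DAG", {
  dag <- demo_ontology()
  ic <- compute_ic(propagate_annotations(demo_annotations(), dag), dag)
  icv <- setNames(ic$ic, ic$term)
  pv <- setNames(ic$p, ic$term)
  expect_equal(pv[["GO:R"]], 1)
  expect_equal(icv[["GO:R"]], 0)
  expect_equal(pv[["GO:A"]], 2 / 3)
  expect_equal(icv[["GO:A"]], log(3 / 2))
  expect_equal(pv[["GO:C"]], 1 / 3)
  expect_equal(icv[["GO:C"]], log(3))
  expect_equal(ic_max(ic), log(3))
})

test_that("unannotated terms get undefined IC and empty corpora error", {
  dag <- go_dag(
    terms = tibble::tibble(id = c("GO:R", "GO:A", "GO:Z"),
                           name = c("r", "a", "z"), namespace = "BP"),
    edges = tibble::tibble(child = c("GO:A", "GO:Z"), parent = "GO:R",
                           relation = "is_a"))
  ann <- propagate_annotations(
    go_annotations(tibble::tibble(gene = "g1", term = "GO:A"), dag), dag)
  ic <- compute_ic(ann, dag)
  expect_true(is.na(ic$ic[ic$term == "GO:Z"]))
  expect_equal(ic$p[ic$term == "GO:Z"], 0)
  expect_error(compute_ic(demo_annotations(), demo_ontology()), "propagated")
})

test_that("IC is monotone non-decreasing from root to leaves along edges", {
  for (seed in 21:24) {
    dag <- random_dag(80, seed = seed)
    ann <- propagate_annotations(random_corpus(dag, 12, seed + 100), dag)
    ic <- compute_ic(ann, dag)
    pv <- setNames(ic$p, ic$term)
    icv <- setNames(ic$ic, ic$term)
    for (i in seq_len(nrow(dag$edges))) {
      child <- dag$edges$child[[i]]; parent <- dag$edges$parent[[i]]
      expect_lte(pv[[child]], pv[[parent]])
      if (!is.na(icv[[child]]) && !is.na(icv[[parent]])) {
        expect_gte(icv[[child]], icv[[parent]])
      }
    }
  }
})

test_that("MICA agrees with exhaustive closure-intersection search", {
  dag <- demo_ontology()
  ic <- compute_ic(propagate_annotations(demo_annotations(), dag), dag)
  expect_equal(mica(dag, ic, "GO:C", "GO:D"),
               list(term = "GO:A", ic = log(3 / 2)))
  expect_equal(mica(dag, ic, "GO:C", "GO:C"),
               list(term = "GO:C", ic = log(3)))
  expect_equal(mica(dag, ic, "GO:D", "GO:B"), list(term = "GO:R", ic = 0))

  for (seed in 31:33) {
    rdag <- random_dag(40, seed = seed)
    ann <- propagate_annotations(random_corpus(rdag, 10, seed + 50), rdag)
    ric <- compute_ic(ann, rdag)
    orc <- oracle_ic(rdag, random_corpus(rdag, 10, seed + 50)$ann)
    pairs <- t(utils::combn(sample(rdag$terms$id, 8L), 2L))
    for (i in seq_len(nrow(pairs))) {
      got <- mica(rdag, ric, pairs[i, 1L], pairs[i, 2L])
      want <- oracle_mica_ic(rdag, orc$ic, pairs[i, 1L], pairs[i, 2L])
      expect_equal(got$ic, want$ic, tolerance = 1e-12)
      expect_equal(got$term, want$term)
    }
  }
})

test_that("OBO writer round-trips through the parser", {
  dag <- demo_ontology()
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, path)
  back <- read_obo(path, "BP")
  expect_setequal(back$terms$id, dag$terms$id)
  expect_equal(dplyr::arrange(back$edges, child, parent),
               dplyr::arrange(dag$edges, child, parent))
})
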