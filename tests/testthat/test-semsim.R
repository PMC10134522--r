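t1_context <- function() {
  dag <- demo_ontology()
  ann <- demo_annotations()
  ic <- compute_ic(propagate_annotations(ann, dag), dag)
  list(dag = dag, ann = ann, ic = ic)
}

test_that("the five measures reproduce the hand-computed toy values", {
  ctx <- t1_context()
  sim <- function(m, t1 = "GO:C", t2 = "GO:D") {
    term_similarity(ctx$dag, t1, t2, m, ic = ctx$ic)
  }
  expect_equal(sim("resnik"), log(3 / 2) / log(3), tolerance = 1e-12)
  expect_equal(sim("lin"), 2 * log(3 / 2) / (2 * log(3)), tolerance = 1e-12)
  expect_equal(sim("rel"), 2 * log(3 / 2) * (1 / 3) / (2 * log(3)),
               tolerance = 1e-12)
  expect_equal(sim("jiang"), 0)
  expect_equal(sim("wang"), 2.88 / 5.48, tolerance = 1e-12)

  # identity and root-MICA corner cases
  expect_equal(sim("resnik", "GO:C", "GO:C"), 1)
  expect_equal(sim("lin", "GO:C", "GO:C"), 1)
  expect_equal(sim("jiang", "GO:C", "GO:C"), 1)
  expect_equal(sim("wang", "GO:C", "GO:C"), 1)
  expect_equal(sim("rel", "GO:C", "GO:C"), 1 * (1 - 1 / 3),
               tolerance = 1e-12)
  expect_equal(sim("lin", "GO:D", "GO:B"), 0)
  expect_equal(sim("resnik", "GO:D", "GO:B"), 0)
})

test_that("raw Resnik is retrievable and errors when only the root is annotated", {
  ctx <- t1_context()
  expect_equal(term_similarity(ctx$dag, "GO:C", "GO:D", "resnik",
                               ic = ctx$ic, normalize = FALSE),
               log(3 / 2), tolerance = 1e-12)
  root_only <- compute_ic(
    propagate_annotations(
      go_annotations(tibble::tibble(gene = "g", term = "GO:R"), ctx$dag),
      ctx$dag),
    ctx$dag)
  expect_error(term_similarity(ctx$dag, "GO:R", "GO:R", "resnik",
                               ic = root_only),
               "ic_max")
})

test_that("Wang profiles carry the hand-derived S-values", {
  dag <- demo_ontology()
  pc <- wang_profile(dag, "GO:C")
  expect_equal(pc$s[["GO:C"]], 1)
  expect_equal(pc$s[["GO:A"]], 0.8)
  expect_equal(pc$s[["GO:B"]], 0.6)
  expect_equal(pc$s[["GO:R"]], 0.64)
  expect_equal(pc$sv, 3.04)
  pd <- wang_profile(dag, "GO:D")
  expect_equal(pd$sv, 2.44)
  expect_equal(wang_profile(dag, "GO:R")$sv, 1)

  expect_equal(wang_similarity(wang_profile(dag, "GO:D"),
                               wang_profile(dag, "GO:B")),
               1.44 / 4.24, tolerance = 1e-12)
  expect_error(
    wang_similarity(wang_profile(dag, "GO:C"),
                    wang_profile(dag, "GO:D",
                                 weights = c(is_a = 0.9, part_of = 0.6))),
    "different relation weights")
})

test_that("aggregators reproduce the worked 2x3 example and degenerate cases", {
  m <- rbind(c(0.9, 0.2, 0.1), c(0.4, 0.6, 0.3))
  expect_equal(aggregate_scores(m, "max"), 0.9)
  expect_equal(aggregate_scores(m, "avg"), mean(m))
  expect_equal(aggregate_scores(m, "rcmax"), 0.75)
  expect_equal(aggregate_scores(m, "bma"), 0.66)

  for (method in c("max", "avg", "rcmax", "bma")) {
    expect_equal(aggregate_scores(matrix(0.42), method), 0.42)
  }
  expect_equal(aggregate_scores(diag(3), "max"), 1)
  expect_equal(aggregate_scores(diag(3), "bma"), 1)
  expect_equal(aggregate_scores(diag(3), "rcmax"), 1)
  expect_error(aggregate_scores(matrix(numeric(0), 0, 0), "max"), "empty")
})

test_that("gene pair similarity matches the single-entry matrix cases", {
  ctx <- t1_context()
  expect_equal(
    gene_pair_similarity(ctx$dag, ctx$ann, "g1", "g2", "lin", "max",
                         ic = ctx$ic),
    0.36907, tolerance = 1e-4)
  for (m in c("lin", "wang", "jiang")) {
    expect_equal(gene_pair_similarity(ctx$dag, ctx$ann, "g1", "g1", m, "max",
                                      ic = ctx$ic), 1)
  }
  expect_equal(
    gene_pair_similarity(ctx$dag, ctx$ann, "g1", "g3", "wang", "bma"),
    3.04 / 4.84, tolerance = 1e-12)
  expect_error(
    gene_pair_similarity(ctx$dag, ctx$ann, "g1", "missing", "lin", "max",
                         ic = ctx$ic),
    "missing")
})

test_that("all five measures match brute-force oracles on random DAGs", {
  for (seed in 41:44) {
    dag <- random_dag(sample(20:60, 1L), seed)
    direct <- random_corpus(dag, 12, seed + 500)
    ic <- compute_ic(propagate_annotations(direct, dag), dag)
    orc <- oracle_ic(dag, direct$ann)
    defined <- names(orc$ic)[!is.na(orc$ic)]
    terms <- sample(defined, min(10L, length(defined)))

    tsm <- lapply(c("resnik", "lin", "rel", "jiang", "wang"), function(m) {
      gostrat:::term_set_similarity(dag, terms, m,
                                    ic = if (m != "wang") ic)
    })
    names(tsm) <- c("resnik", "lin", "rel", "jiang", "wang")

    for (i in seq_along(terms)) {
      for (j in seq_along(terms)) {
        for (m in c("resnik", "lin", "rel", "jiang")) {
          expect_equal(tsm[[m]][i, j],
                       oracle_ic_measure(dag, orc, terms[[i]], terms[[j]], m),
                       tolerance = 1e-12)
        }
        expect_equal(tsm$wang[i, j],
                     oracle_wang_sim(dag, terms[[i]], terms[[j]]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("measures are symmetric and bounded in [0, 1] on random DAGs", {
  for (seed in 51:53) {
    dag <- random_dag(50, seed)
    direct <- random_corpus(dag, 15, seed + 600)
    ic <- compute_ic(propagate_annotations(direct, dag), dag)
    defined <- ic$term[!is.na(ic$ic)]
    terms <- sample(defined, 8L)
    for (m in c("resnik", "lin", "rel", "jiang", "wang")) {
      tsm <- gostrat:::term_set_similarity(dag, terms, m,
                                           ic = if (m != "wang") ic)
      expect_equal(tsm, t(tsm))
      expect_true(all(tsm >= -1e-12 & tsm <= 1 + 1e-12))
    }
  }
})

test_that("similarity is zero across annotation-disjoint subtrees", {
  spec <- synthetic_spec(n_branches = 3L, depth = 4L, genes_per_group = 5L,
                         terms_per_gene = 2L, leak = 0, seed = 7L)
  dag <- make_toy_ontology(spec)
  sim <- make_group_annotations(dag, spec)
  S <- gene_similarity(sim$genes$gene, dag, sim$annotations,
                       measure = "lin", aggregator = "max")
  groups <- sim$genes$group
  cross <- S$matrix[outer(groups, groups, "!=")]
  expect_equal(max(abs(cross)), 0)
  R <- gene_similarity(sim$genes$gene, dag, sim$annotations,
                       measure = "resnik", aggregator = "bma")
  expect_equal(max(abs(R$matrix[outer(groups, groups, "!=")])), 0)
})

test_that("gene similarity matrix has input order, unit diagonal and exclusions", {
  ctx <- t1_context()
  S <- gene_similarity(c("g1", "g2", "g3"), ctx$dag, ctx$ann,
                       measure = "lin", aggregator = "max")
  expect_equal(rownames(S$matrix), c("g1", "g2", "g3"))
  expect_equal(unname(diag(S$matrix)), rep(1, 3))
  expect_equal(S$matrix["g1", "g2"], 0.36907, tolerance = 1e-4)
  expect_equal(S$matrix, t(S$matrix))

  # unknown gene goes to the exclusion list, duplicates collapse with warning
  S2 <- gene_similarity(c("g1", "g2", "ghost"), ctx$dag, ctx$ann,
                        measure = "lin", aggregator = "max")
  expect_equal(S2$excluded$gene, "ghost")
  expect_equal(nrow(S2$matrix), 2L)
  expect_warning(
    S3 <- gene_similarity(c("g1", "g1", "g2"), ctx$dag, ctx$ann,
                          measure = "lin", aggregator = "max"),
    "duplicated")
  expect_equal(nrow(S3$matrix), 2L)
  expect_error(
    gene_similarity(c("g1", "ghost"), ctx$dag, ctx$ann, "lin", "max"),
    "fewer than 2")
})

test_that("gene-level similarity is symmetric under every aggregator", {
  dag <- random_dag(40, seed = 61)
  direct <- random_corpus(dag, 10, seed = 62)
  for (agg in c("max", "avg", "rcmax", "bma")) {
    S <- gene_similarity(unique(direct$ann$gene), dag, direct,
                         measure = "lin", aggregator = agg)
    expect_equal(S$matrix, t(S$matrix))
    expect_true(all(S$matrix >= -1e-12 & S$matrix <= 1 + 1e-12))
  }
})

test_that("similarity matrix TSV + sidecar round-trips", {
  ctx <- t1_context()
  genes <- tibble::tibble(gene = c("g1", "g2", "g3"),
                          label = c("ASD", "ASD", "ID"))
  S <- gene_similarity(genes, ctx$dag, ctx$ann, "wang", "bma")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_sim(S, path)
  back <- read_gene_sim(path)
  expect_equal(back$matrix, S$matrix)
  expect_equal(back$genes$label, genes$label)
  expect_equal(back$measure, "wang")
  expect_equal(back$aggregator, "bma")
})

test_that("tidy and glance expose pairs and summary", {
  ctx <- t1_context()
  S <- gene_similarity(c("g1", "g2", "g3"), ctx$dag, ctx$ann, "lin", "max")
  td <- tidy(S)
  expect_equal(nrow(td), 6L)  # 3 diagonal + 3 upper pairs
  expect_true(all(c("gene1", "gene2", "similarity") %in% names(td)))
  gl <- glance(S)
  expect_equal(gl$n_genes, 3L)
  expect_equal(gl$measure, "lin")
})
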