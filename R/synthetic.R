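#' Specification for synthetic ontology + annotation fixtures
#'
#' Describes a toy corpus: a rooted DAG with `n_branches` disjoint `is_a`
#' chains of `depth` terms under a common root, and groups of genes whose
#' direct annotations concentrate on one branch each. With probability
#' `leak` an annotation is replaced by a term drawn uniformly from a
#' foreign branch, degrading the group structure continuously from perfect
#' separation (`leak = 0`) to none (`leak = 1`).
#'
#' @param n_branches Number of branches (gene groups).
#' @param depth Terms per branch.
#' @param genes_per_group Genes per group.
#' @param terms_per_gene Direct annotations per gene (must not exceed
#'   `depth`).
#' @param leak Per-annotation probability of drawing from a foreign
#'   branch, in `[0, 1]`.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_branches = 4L, depth = 6L, genes_per_group = 25L,
                           terms_per_gene = 4L, leak = 0.05, seed = 1L) {
  spec <- list(n_branches = as.integer(n_branches), depth = as.integer(depth),
               genes_per_group = as.integer(genes_per_group),
               terms_per_gene = as.integer(terms_per_gene),
               leak = as.numeric(leak), seed = as.integer(seed))
  if (spec$n_branches < 1L) abort_config("n_branches must be >= 1")
  if (spec$depth < 1L || spec$genes_per_group < 1L || spec$terms_per_gene < 1L) {
    abort_config("all synthetic counts must be >= 1")
  }
  if (spec$leak < 0 || spec$leak > 1) abort_config("leak must be in [0, 1]")
  structure(spec, class = "synthetic_spec")
}

branch_term_ids <- function(branch, depth) {
  sprintf("GO:B%dT%d", branch, seq_len(depth))
}

#' Generate a toy ontology
#'
#' One root plus `n_branches` disjoint `is_a` chains of `depth` terms
#' (`1 + n_branches * depth` terms in total). With `cross_links = TRUE`
#' each branch's deepest term additionally gets a `part_of` parent at the
#' top of the next branch, exercising multi-parent ancestor closure.
#'
#' @param spec A [synthetic_spec()].
#' @param cross_links Add one `part_of` cross-edge per branch.
#' @return A [go_dag()].
#' @export
make_toy_ontology <- function(spec, cross_links = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  root <- "GO:ROOT"
  ids <- c(root, unlist(lapply(seq_len(spec$n_branches), branch_term_ids,
                               depth = spec$depth)))
  edges <- list()
  for (b in seq_len(spec$n_branches)) {
    terms <- branch_term_ids(b, spec$depth)
    edges[[b]] <- tibble(
      child = terms,
      parent = c(root, terms[-length(terms)]),
      relation = "is_a"
    )
  }
  edges <- bind_rows(edges)
  if (cross_links && spec$n_branches > 1L) {
    cross <- tibble(
      child = vapply(seq_len(spec$n_branches), function(b)
        branch_term_ids(b, spec$depth)[spec$depth], ""),
      parent = vapply(seq_len(spec$n_branches), function(b)
        branch_term_ids(b %% spec$n_branches + 1L, 1L), ""),
      relation = "part_of"
    )
    edges <- bind_rows(edges, cross)
  }
  terms <- tibble(id = ids,
                  name = c("synthetic root",
                           sprintf("synthetic term %s", ids[-1L])),
                  namespace = "BP")
  go_dag(terms, edges)
}

#' Generate group-structured gene annotations
#'
#' Gene `i` of group `g` draws `terms_per_gene` distinct terms from branch
#' `g`; each draw is independently replaced by a uniformly chosen term of a
#' foreign branch with probability `leak`. True group labels are returned
#' for external validation (e.g. adjusted Rand index against recovered
#' clusters).
#'
#' @param dag A [make_toy_ontology()] graph.
#' @param spec The matching [synthetic_spec()].
#' @return A list: `annotations` (unpropagated [go_annotations()]),
#'   `genes` (tibble `gene`, `group`).
#' @export
make_group_annotations <- function(dag, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$terms_per_gene > spec$depth) {
    abort_config("terms_per_gene (%d) exceeds branch depth (%d)",
                 spec$terms_per_gene, spec$depth)
  }
  set.seed(spec$seed)
  rows <- list()
  genes <- list()
  for (g in seq_len(spec$n_branches)) {
    own <- branch_term_ids(g, spec$depth)
    for (i in seq_len(spec$genes_per_group)) {
      gene <- sprintf("gene_%02d_%03d", g, i)
      terms <- sample(own, spec$terms_per_gene)
      if (spec$leak > 0 && spec$n_branches > 1L) {
        leak_hit <- runif(spec$terms_per_gene) < spec$leak
        for (j in which(leak_hit)) {
          foreign <- sample(setdiff(seq_len(spec$n_branches), g), 1L)
          terms[[j]] <- sample(branch_term_ids(foreign, spec$depth), 1L)
        }
      }
      rows[[length(rows) + 1L]] <- tibble(gene = gene, term = unique(terms))
      genes[[length(genes) + 1L]] <- tibble(gene = gene, group = g)
    }
  }
  list(annotations = go_annotations(bind_rows(rows), dag),
       genes = bind_rows(genes))
}

#' Generate planted Gaussian blobs
#'
#' Isotropic Gaussian blobs with centres spaced `spacing` apart along the
#' first axis — known cluster structure for validating clustering,
#' silhouette and outlier-refinement behaviour.
#'
#' @param k Number of blobs (>= 1).
#' @param n_per_blob Points per blob.
#' @param sigma Isotropic standard deviation (> 0).
#' @param spacing Distance between consecutive centres.
#' @param seed Integer seed.
#' @param dim Dimensionality (default 2).
#' @return A list: `coords` (matrix with point ids), `labels` (integer blob
#'   of origin), `centers`.
#' @export
make_planted_points <- function(k, n_per_blob, sigma, spacing, seed = 1L,
                                dim = 2L) {
  if (k < 1L) abort_config("k must be >= 1")
  if (sigma <= 0) abort_config("sigma must be > 0")
  set.seed(seed)
  centers <- matrix(0, k, dim)
  centers[, 1L] <- (seq_len(k) - 1L) * spacing
  coords <- do.call(rbind, lapply(seq_len(k), function(b) {
    sweep(matrix(rnorm(n_per_blob * dim, sd = sigma), n_per_blob, dim),
          2L, centers[b, ], "+")
  }))
  rownames(coords) <- sprintf("p%03d", seq_len(nrow(coords)))
  colnames(coords) <- paste0("dim_", seq_len(dim))
  list(coords = coords, labels = rep(seq_len(k), each = n_per_blob),
       centers = centers)
}

#' Write a synthetic corpus to disk
#'
#' Emits the OBO ontology, the two-column annotation TSV and the gene list
#' TSV (`gene`, `label` = true group) in the exact dialects the package
#' readers consume, so synthetic fixtures round-trip through the file
#' interface.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @param cross_links Passed to [make_toy_ontology()].
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_synthetic_corpus <- function(spec, dir, cross_links = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dag <- make_toy_ontology(spec, cross_links = cross_links)
  sim <- make_group_annotations(dag, spec)
  paths <- c(obo = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             genes = file.path(dir, "genes.tsv"))
  write_obo(dag, paths[["obo"]])
  write_annotations_tsv(sim$annotations, paths[["annotations"]])
  readr::write_tsv(
    tibble(gene = sim$genes$gene, label = paste0("group", sim$genes$group)),
    paths[["genes"]])
  invisible(paths)
}

#' Five-term demonstration DAG
#'
#' The worked fixture used throughout the documentation and tests: root
#' `GO:R`; `GO:A` and `GO:B` are children of the root; `GO:C` is `is_a`
#' child of `GO:A` and `part_of` `GO:B`; `GO:D` is `is_a` child of `GO:A`.
#' With direct annotations g1 -> C, g2 -> D, g3 -> B it yields the
#' hand-checkable IC values `IC(A) = ln(3/2)`, `IC(C) = ln 3`.
#'
#' @return A [go_dag()] with five terms.
#' @export
demo_ontology <- function() {
  go_dag(
    terms = tibble(id = c("GO:R", "GO:A", "GO:B", "GO:C", "GO:D"),
                   name = c("root", "process A", "process B",
                            "process C", "process D"),
                   namespace = "BP"),
    edges = tibble(
      child = c("GO:A", "GO:B", "GO:C", "GO:C", "GO:D"),
      parent = c("GO:R", "GO:R", "GO:A", "GO:B", "GO:A"),
      relation = c("is_a", "is_a", "is_a", "part_of", "is_a"))
  )
}

#' Direct annotations for the demonstration DAG
#'
#' @return An unpropagated [go_annotations()] on [demo_ontology()]:
#'   g1 -> GO:C, g2 -> GO:D, g3 -> GO:B.
#' @export
demo_annotations <- function() {
  go_annotations(
    tibble(gene = c("g1", "g2", "g3"), term = c("GO:C", "GO:D", "GO:B")),
    demo_ontology()
  )
}
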