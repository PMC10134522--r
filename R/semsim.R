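SIM_MEASURES <- c("resnik", "lin", "rel", "jiang", "wang")
AGGREGATORS <- c("max", "avg", "rcmax", "bma")

#' Default Wang relation contribution factors
#'
#' Semantic contribution per edge type used by the Wang measure: 0.8 for
#' `is_a`, 0.6 for `part_of` (the weights of the original graph-based
#' method; configurable in every Wang entry point).
#' @export
wang_default_weights <- c(is_a = 0.8, part_of = 0.6)

#' Semantic similarity between two ontology terms
#'
#' Scores a term pair with one of five measures. Resnik, Lin, Rel and Jiang
#' derive from the information content of the most informative common
#' ancestor (MICA); Wang propagates semantic contributions down the DAG.
#' All scores lie in `[0, 1]`: the raw Resnik score (an unbounded IC) is
#' normalised by the namespace IC maximum unless `normalize = FALSE`.
#'
#' \describe{
#'   \item{resnik}{`IC(MICA) / IC_max` (raw: `IC(MICA)`)}
#'   \item{lin}{`2 IC(MICA) / (IC(t1) + IC(t2))`, 0 when both terms are the root}
#'   \item{rel}{`2 IC(MICA) (1 - p(MICA)) / (IC(t1) + IC(t2))`}
#'   \item{jiang}{`1 - min(1, IC(t1) + IC(t2) - 2 IC(MICA))`}
#'   \item{wang}{shared semantic-value fraction of the two ancestor closures}
#' }
#'
#' @param dag A [go_dag()].
#' @param t1,t2 Term ids.
#' @param measure One of `"resnik"`, `"lin"`, `"rel"`, `"jiang"`, `"wang"`.
#' @param ic IC table from [compute_ic()] (required for all but `"wang"`).
#' @param wang_weights Named relation weights for the Wang measure.
#' @param normalize For Resnik: divide by the namespace `ic_max` (default).
#' @return A similarity score.
#' @export
term_similarity <- function(dag, t1, t2, measure = "rel", ic = NULL,
                            wang_weights = wang_default_weights,
                            normalize = TRUE) {
  measure <- match_enum(tolower(measure), SIM_MEASURES, "measure")
  if (measure == "wang") {
    return(wang_similarity(wang_profile(dag, t1, wang_weights),
                           wang_profile(dag, t2, wang_weights)))
  }
  if (is.null(ic)) abort_data("measure '%s' requires an IC table", measure)
  icv <- ic_vector(ic)
  for (t in c(t1, t2)) {
    if (is.na(icv[[t]])) {
      abort_data("term %s has undefined IC (no annotated gene)", t)
    }
  }
  m <- mica(dag, ic, t1, t2)
  ic_pair_score(measure, icv[[t1]], icv[[t2]], m$ic,
                p_mica = p_vector(ic)[[m$term]],
                ic_max = ic_max(ic), normalize = normalize)
}

ic_pair_score <- function(measure, ic1, ic2, mica_ic, p_mica, ic_max,
                          normalize = TRUE) {
  switch(measure,
    resnik = {
      if (!normalize) return(mica_ic)
      if (ic_max == 0) {
        abort_numeric("ic_max is 0 (only the root is annotated); cannot normalise Resnik")
      }
      mica_ic / ic_max
    },
    lin = {
      denom <- ic1 + ic2
      if (denom == 0) 0 else 2 * mica_ic / denom
    },
    rel = {
      denom <- ic1 + ic2
      if (denom == 0) 0 else 2 * mica_ic * (1 - p_mica) / denom
    },
    jiang = 1 - min(1, ic1 + ic2 - 2 * mica_ic)
  )
}

#' Wang semantic-value profile of a term
#'
#' Computes the S-value of every term in the ancestor closure: the term
#' itself has S-value 1 and each ancestor `a` gets the best weighted
#' contribution `max_c w(c -> a) * S(c)` over its in-closure children `c`.
#' The semantic value `SV` is the sum of all S-values.
#'
#' @param dag A [go_dag()].
#' @param term A term id.
#' @param weights Named vector of relation contribution factors.
#' @return A `wang_profile` list with elements `term`, `s` (named S-values),
#'   `sv` and `weights`.
#' @export
wang_profile <- function(dag, term, weights = wang_default_weights) {
  closure <- term_ancestors(dag, term)
  unknown <- setdiff(unique(unlist(dag$relations[closure])), names(weights))
  if (length(unknown)) {
    abort_data("no Wang weight for relation(s): %s",
               paste(unknown, collapse = ", "))
  }
  s <- setNames(rep(-Inf, length(closure)), closure)
  s[[term]] <- 1

  # process children before parents: order closure by decreasing closure size
  # is not safe; use topological order of the induced subgraph instead
  ord <- closure_topo_order(dag, closure)
  for (child in ord) {
    ps <- dag$parents[[child]]
    rl <- dag$relations[[child]]
    keep <- ps %in% closure
    for (j in which(keep)) {
      cand <- weights[[rl[[j]]]] * s[[child]]
      if (cand > s[[ps[[j]]]]) s[[ps[[j]]]] <- cand
    }
  }
  structure(list(term = term, s = s, sv = sum(s), weights = weights),
            class = "wang_profile")
}

# Topological order (children first) of the sub-DAG induced by `closure`.
closure_topo_order <- function(dag, closure) {
  if (length(closure) == 1L) return(closure)
  sub <- dag$edges[dag$edges$child %in% closure &
                     dag$edges$parent %in% closure, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = closure))
  names(igraph::topo_sort(g, mode = "out"))
}

#' Wang similarity of two term profiles
#'
#' Implements the Wang score: the S-values that the two closures assign to
#' their shared terms, summed and divided by the two semantic values.
#' Profiles must have been built with identical relation weights.
#'
#' @param p1,p2 [wang_profile()] objects.
#' @return A score in `(0, 1]`.
#' @export
wang_similarity <- function(p1, p2) {
  stopifnot(inherits(p1, "wang_profile"), inherits(p2, "wang_profile"))
  if (!identical(p1$weights[sort(names(p1$weights))],
                 p2$weights[sort(names(p2$weights))])) {
    abort_data("wang profiles were built with different relation weights")
  }
  shared <- intersect(names(p1$s), names(p2$s))
  sum(p1$s[shared] + p2$s[shared]) / (p1$sv + p2$sv)
}

#' Aggregate a term-pair similarity matrix into a gene-pair score
#'
#' Collapses the `|terms(A)| x |terms(B)|` matrix of term similarities into
#' a single score: `max` takes the largest entry, `avg` the mean of all
#' entries, `rcmax` the larger of the mean row maxima and mean column
#' maxima, and `bma` (best-match average) the sum of row and column maxima
#' divided by the total number of rows plus columns.
#'
#' @param m Numeric matrix of term-pair similarities (non-empty).
#' @param method One of `"max"`, `"avg"`, `"rcmax"`, `"bma"`.
#' @return A scalar score.
#' @export
#' @examples
#' m <- rbind(c(0.9, 0.2, 0.1), c(0.4, 0.6, 0.3))
#' aggregate_scores(m, "bma")  # 0.66
aggregate_scores <- function(m, method = c("max", "avg", "rcmax", "bma")) {
  method <- match_enum(tolower(method[[1L]]), AGGREGATORS, "aggregator")
  m <- as.matrix(m)
  if (!length(m)) abort_data("cannot aggregate an empty similarity matrix")
  row_max <- apply(m, 1L, max)
  col_max <- apply(m, 2L, max)
  switch(method,
    max = max(m),
    avg = mean(m),
    rcmax = max(mean(row_max), mean(col_max)),
    bma = (sum(row_max) + sum(col_max)) / (nrow(m) + ncol(m))
  )
}

# Pairwise similarity matrix over a fixed term set, shared by all gene pairs.
# Returns a |terms| x |terms| symmetric matrix.
term_set_similarity <- function(dag, terms, measure, ic = NULL,
                                wang_weights = wang_default_weights) {
  n <- length(terms)
  out <- matrix(0, n, n, dimnames = list(terms, terms))
  if (measure == "wang") {
    profiles <- lapply(terms, wang_profile, dag = dag, weights = wang_weights)
    for (i in seq_len(n)) {
      for (j in i:n) {
        out[i, j] <- out[j, i] <- wang_similarity(profiles[[i]], profiles[[j]])
      }
    }
    return(out)
  }
  icv <- ic_vector(ic)
  pv <- p_vector(ic)
  icm <- ic_max(ic)
  clos <- all_closures(dag)[terms]
  for (i in seq_len(n)) {
    for (j in i:n) {
      common <- intersect(clos[[i]], clos[[j]])
      cic <- icv[common]
      cic <- cic[!is.na(cic)]
      mica_ic <- max(cic)
      best <- sort(names(cic)[cic == mica_ic])[[1L]]
      out[i, j] <- out[j, i] <- ic_pair_score(
        measure, icv[[terms[[i]]]], icv[[terms[[j]]]], mica_ic,
        p_mica = pv[[best]], ic_max = icm)
    }
  }
  out
}

#' Functional similarity of one gene pair
#'
#' Builds the term-pair similarity matrix over the two genes' direct
#' annotations and aggregates it. Symmetric in its gene arguments for all
#' four aggregators.
#'
#' @param dag A [go_dag()].
#' @param ann A [go_annotations()] object (direct annotations).
#' @param g1,g2 Gene ids present in `ann`.
#' @param measure,aggregator See [term_similarity()] and
#'   [aggregate_scores()].
#' @param ic IC table (computed on the fly from `ann` if `NULL` and needed).
#' @param wang_weights Relation weights for the Wang measure.
#' @return A scalar similarity in `[0, 1]`.
#' @export
gene_pair_similarity <- function(dag, ann, g1, g2, measure = "rel",
                                 aggregator = "max", ic = NULL,
                                 wang_weights = wang_default_weights) {
  measure <- match_enum(tolower(measure), SIM_MEASURES, "measure")
  if (is.null(ic) && measure != "wang") {
    ic <- compute_ic(if (ann$propagated) ann else
                       propagate_annotations(ann, dag), dag)
  }
  sets <- gene_term_sets(ann, unique(c(g1, g2)), measure, ic)
  if (length(sets$dropped_genes)) {
    abort_data("gene '%s' has no usable annotation", sets$dropped_genes[[1L]])
  }
  tsm <- term_set_similarity(dag, unique(unlist(sets$sets)), measure, ic,
                             wang_weights)
  aggregate_scores(tsm[sets$sets[[g1]], sets$sets[[g2]], drop = FALSE],
                   aggregator)
}

# Direct term sets per gene, with undefined-IC terms removed for IC-based
# measures. Returns list(sets = named list, dropped_genes = chr, reasons).
gene_term_sets <- function(ann, genes, measure, ic) {
  tab <- ann$ann[ann$ann$gene %in% genes, , drop = FALSE]
  sets <- split(tab$term, factor(tab$gene, levels = genes))
  reasons <- character()
  if (measure != "wang") {
    defined <- ic$term[!is.na(ic$ic)]
    sets <- lapply(sets, intersect, y = defined)
  }
  empty <- vapply(sets, length, 0L) == 0L
  annotated <- genes %in% unique(ann$ann$gene)
  reasons <- ifelse(!annotated, "unannotated",
                    "no annotation with defined IC")[empty]
  list(sets = sets[!empty], dropped_genes = genes[empty],
       reasons = reasons)
}
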