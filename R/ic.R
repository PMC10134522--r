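#' Information content of ontology terms
#'
#' For each term, the occurrence probability `p(t)` is the number of
#' distinct genes annotated to `t` after true-path propagation divided by
#' the number of genes annotated to the namespace root, and the information
#' content is `IC(t) = -ln p(t)`. Rare (specific) terms therefore carry high
#' IC; the root has `p = 1`, `IC = 0`. Terms with no annotated gene get
#' `p = 0` and an undefined (`NA`) IC and are excluded from similarity
#' calculations downstream.
#'
#' @param ann A propagated [go_annotations()] object with at least one gene.
#' @param dag The companion [go_dag()].
#' @return A tibble with columns `term`, `n_genes`, `p`, `ic` (natural-log
#'   units), carrying attributes `ic_max` (largest finite IC) and
#'   `n_root` (the probability denominator).
#' @export
#' @examples
#' dag <- demo_ontology()
#' ann <- go_annotations(
#'   data.frame(gene = c("g1", "g2", "g3"), term = c("GO:C", "GO:D", "GO:B")),
#'   dag
#' )
#' compute_ic(propagate_annotations(ann, dag), dag)
compute_ic <- function(ann, dag) {
  if (!inherits(ann, "go_annotations")) abort_data("ann must be go_annotations")
  if (!ann$propagated) abort_data("compute_ic requires propagated annotations")
  if (!nrow(ann$ann)) abort_data("empty annotation set")

  counts <- dplyr::count(ann$ann, .data$term, name = "n_genes")
  out <- left_join(tibble(term = dag$terms$id), counts, by = "term")
  out$n_genes[is.na(out$n_genes)] <- 0L
  n_root <- out$n_genes[out$term == dag$root]
  if (n_root == 0L) abort_data("no gene reaches the namespace root")
  out$p <- out$n_genes / n_root
  out$ic <- ifelse(out$p > 0, -log(out$p), NA_real_)
  ic_max <- max(out$ic, na.rm = TRUE)

  structure(out, class = c("gostrat_ic", class(out)),
            ic_max = ic_max, n_root = n_root, namespace = dag$namespace)
}

#' Largest finite information content in an IC table
#'
#' @param ic A table from [compute_ic()].
#' @return A scalar, the normalisation constant for the Resnik measure.
#' @export
ic_max <- function(ic) attr(ic, "ic_max", exact = TRUE)

# fast lookup vectors
ic_vector <- function(ic) setNames(ic$ic, ic$term)
p_vector <- function(ic) setNames(ic$p, ic$term)

#' Most informative common ancestor of two terms
#'
#' Intersects the ancestor closures of `t1` and `t2` (each closure includes
#' the term itself, so `mica(t, t)` is `t`) and returns the common ancestor
#' with the largest defined IC. Ties are broken by lexicographic term id so
#' the result is deterministic.
#'
#' @param dag A [go_dag()].
#' @param ic A table from [compute_ic()] on the same namespace.
#' @param t1,t2 Term ids in `dag`.
#' @return A list with elements `term` and `ic`.
#' @export
mica <- function(dag, ic, t1, t2) {
  common <- intersect(term_ancestors(dag, t1), term_ancestors(dag, t2))
  icv <- ic_vector(ic)[common]
  icv <- icv[!is.na(icv)]
  if (!length(icv)) abort_data("no common ancestor with defined IC for %s/%s",
                               t1, t2)
  best <- max(icv)
  cands <- sort(names(icv)[icv == best])
  list(term = cands[[1L]], ic = unname(best))
}

#' Write an IC table as TSV
#'
#' @param ic A table from [compute_ic()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ic_tsv <- function(ic, path) {
  readr::write_tsv(as_tibble(ic)[, c("term", "p", "ic")], path)
  invisible(path)
}
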