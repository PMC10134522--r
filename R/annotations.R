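#' Gene annotation sets
#'
#' A `go_annotations` object pairs a gene-to-term table with the namespace it
#' is restricted to and a flag saying whether the true-path rule has been
#' applied. Construct one directly from a data frame, or from a file with
#' [read_annotations()].
#'
#' @param x A data frame with character columns `gene` and `term` (one row
#'   per direct annotation).
#' @param dag The companion [go_dag()]; all terms must exist in it.
#' @param propagated Whether `x` is already closed under the ancestor
#'   relation (normally `FALSE`; [propagate_annotations()] sets it).
#' @param excluded Optional tibble (`gene`, `reason`) of genes dropped
#'   upstream, carried along for reporting.
#'
#' @return A `go_annotations` object.
#' @export
go_annotations <- function(x, dag, propagated = FALSE, excluded = NULL) {
  x <- as_tibble(x)[, c("gene", "term")]
  unknown <- setdiff(unique(x$term), dag$terms$id)
  if (length(unknown)) {
    abort_data("annotation references term(s) not in the %s graph: %s",
               dag$namespace, paste(head(unknown, 5L), collapse = ", "))
  }
  x <- distinct(x)
  structure(
    list(ann = x,
         namespace = dag$namespace,
         propagated = isTRUE(propagated),
         excluded = excluded %||% tibble(gene = character(),
                                         reason = character()),
         n_genes = dplyr::n_distinct(x$gene)),
    class = "go_annotations"
  )
}

#' @export
print.go_annotations <- function(x, ...) {
  cat(sprintf("<go_annotations> %s: %d genes, %d annotations (%s)%s\n",
              x$namespace, x$n_genes, nrow(x$ann),
              if (x$propagated) "propagated" else "direct",
              if (nrow(x$excluded)) sprintf(", %d genes excluded",
                                            nrow(x$excluded)) else ""))
  invisible(x)
}

#' Tidy annotations into a gene/term tibble
#'
#' @param x A [go_annotations()] object.
#' @param ... Unused.
#' @return A tibble with columns `gene` and `term`.
#' @export
tidy.go_annotations <- function(x, ...) x$ann

#' Read gene annotations from GAF or two-column TSV
#'
#' Accepts GAF 2.1/2.2 (17-column tab-separated, `!` comment lines) or a
#' simple two-column TSV (`gene<TAB>term1,term2,...`). Rows carrying a `NOT`
#' qualifier or an excluded evidence code are dropped; annotations to terms
#' absent from `dag` (other namespaces, unknown ids) are dropped with a
#' logged count; genes left with no usable term are recorded in the
#' exclusion list rather than erroring.
#'
#' @param path Path to the annotation file (or a character vector of lines).
#' @param dag A [go_dag()] giving the working namespace.
#' @param format `"auto"` (default), `"gaf"` or `"tsv"`.
#' @param evidence_exclude Character vector of GAF evidence codes to drop
#'   (e.g. `"IEA"`); `NULL` keeps everything.
#' @param gene_column For GAF input, `"symbol"` (column 3, default) or
#'   `"id"` (column 2).
#' @return An unpropagated [go_annotations()] object.
#' @export
read_annotations <- function(path, dag, format = c("auto", "gaf", "tsv"),
                             evidence_exclude = NULL,
                             gene_column = c("symbol", "id")) {
  format <- match.arg(format)
  gene_column <- match.arg(gene_column)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  body_idx <- which(!startsWith(lines, "!") & nzchar(trimws(lines)))

  if (format == "auto") {
    probe <- strsplit(lines[body_idx[1L]], "\t", fixed = TRUE)[[1L]]
    format <- if (length(probe) >= 15L) "gaf" else "tsv"
  }

  rows <- vector("list", length(body_idx))
  for (j in seq_along(body_idx)) {
    i <- body_idx[[j]]
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (format == "gaf") {
      if (length(fields) < 15L) {
        abort_data("malformed GAF line %d: %d fields (need >= 15)", i,
                   length(fields))
      }
      qualifier <- fields[[4L]]
      if (grepl("(^|\\|)NOT($|\\|)", qualifier)) next
      if (!is.null(evidence_exclude) && fields[[7L]] %in% evidence_exclude) next
      gene <- if (gene_column == "symbol") fields[[3L]] else fields[[2L]]
      rows[[j]] <- tibble(gene = gene, term = fields[[5L]])
    } else {
      if (length(fields) != 2L) {
        abort_data("malformed TSV line %d: %d fields (need 2)", i,
                   length(fields))
      }
      terms <- trimws(strsplit(fields[[2L]], ",", fixed = TRUE)[[1L]])
      rows[[j]] <- tibble(gene = fields[[1L]], term = terms[nzchar(terms)])
    }
  }
  ann <- distinct(bind_rows(rows))
  if (!nrow(ann)) abort_data("no annotations parsed from input")

  # resolve alt ids, then restrict to the working namespace
  alt <- dag$alt_ids
  if (length(alt)) {
    hit <- ann$term %in% names(alt)
    ann$term[hit] <- unname(alt[ann$term[hit]])
  }
  known <- ann$term %in% dag$terms$id
  n_dropped <- sum(!known)
  if (n_dropped) {
    inform(sprintf(
      "read_annotations: dropped %d annotation(s) to terms outside the %s graph",
      n_dropped, dag$namespace))
  }
  kept <- ann[known, , drop = FALSE]
  lost_genes <- setdiff(unique(ann$gene), unique(kept$gene))
  excluded <- tibble(gene = lost_genes,
                     reason = rep("no terms in namespace", length(lost_genes)))
  if (!nrow(kept)) abort_data("no annotations remain in namespace %s",
                              dag$namespace)
  go_annotations(kept, dag, propagated = FALSE, excluded = excluded)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Closes every gene's term set under the ancestor relation over `is_a` and
#' `part_of` edges: a gene annotated to a term is annotated to all of that
#' term's ancestors. Input must be unpropagated; propagating twice is an
#' error rather than a silent no-op.
#'
#' @param ann An unpropagated [go_annotations()] object.
#' @param dag The companion [go_dag()].
#' @return A propagated [go_annotations()] object.
#' @export
propagate_annotations <- function(ann, dag) {
  if (ann$propagated) abort_data("annotations are already propagated")
  clos <- all_closures(dag)
  per_gene <- split(ann$ann$term, ann$ann$gene)
  out <- purrr::imap(per_gene, function(terms, gene) {
    tibble(gene = gene, term = unique(unlist(clos[terms], use.names = FALSE)))
  })
  res <- go_annotations(bind_rows(out), dag, propagated = TRUE,
                        excluded = ann$excluded)
  res
}

#' Write annotations as a two-column TSV
#'
#' One row per gene: `gene<TAB>term1,term2,...` — the dialect
#' [read_annotations()] consumes.
#'
#' @param ann A [go_annotations()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(ann, path) {
  per_gene <- split(ann$ann$term, ann$ann$gene)
  genes <- names(per_gene)
  lines <- vapply(genes, function(g) {
    paste0(g, "\t", paste(sort(per_gene[[g]]), collapse = ","))
  }, "")
  writeLines(lines[order(genes)], path)
  invisible(path)
}
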