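#' Gene-by-gene functional similarity matrix
#'
#' Builds the square symmetric matrix of aggregated semantic similarities
#' over a labelled gene list. Genes without any usable annotation in the
#' working namespace (or, for IC-based measures, without any term of
#' defined IC) are dropped and reported in the exclusion list; row order
#' follows the input order of the retained genes.
#'
#' @param genes A data frame whose first column holds gene ids, with an
#'   optional `label` column (e.g. disease of origin); or a character
#'   vector of gene ids. Duplicated ids are collapsed with a warning.
#' @param dag A [go_dag()].
#' @param ann A [go_annotations()] object holding direct annotations.
#' @param measure,aggregator Similarity measure and aggregation function
#'   (defaults `"rel"` + `"max"`).
#' @param ic Optional precomputed IC table; computed from `ann` when
#'   needed.
#' @param wang_weights Relation weights for the Wang measure.
#' @param use_propagated Aggregate over propagated closures instead of
#'   direct term sets (default `FALSE`: direct).
#' @return A `gene_sim` object: the matrix plus gene labels, the exclusion
#'   list and run metadata.
#' @export
gene_similarity <- function(genes, dag, ann, measure = "rel",
                            aggregator = "max", ic = NULL,
                            wang_weights = wang_default_weights,
                            use_propagated = FALSE) {
  measure <- match_enum(tolower(measure), SIM_MEASURES, "measure")
  aggregator <- match_enum(tolower(aggregator), AGGREGATORS, "aggregator")

  if (is.character(genes)) genes <- tibble(gene = genes)
  genes <- as_tibble(genes)
  names(genes)[[1L]] <- "gene"
  genes$gene <- as.character(genes$gene)
  if (anyDuplicated(genes$gene)) {
    warn(sprintf("gene_similarity: %d duplicated gene id(s) collapsed",
                 sum(duplicated(genes$gene))))
    genes <- genes[!duplicated(genes$gene), , drop = FALSE]
  }

  if (is.null(ic) && measure != "wang") {
    ic <- compute_ic(if (ann$propagated) ann else
                       propagate_annotations(ann, dag), dag)
  }
  work_ann <- if (use_propagated && !ann$propagated) {
    propagate_annotations(ann, dag)
  } else {
    ann
  }

  sets <- gene_term_sets(work_ann, genes$gene, measure, ic)
  excluded <- bind_rows(
    ann$excluded[ann$excluded$gene %in% genes$gene, , drop = FALSE],
    tibble(gene = setdiff(sets$dropped_genes, ann$excluded$gene),
           reason = sets$reasons[!sets$dropped_genes %in% ann$excluded$gene])
  )
  retained <- genes[genes$gene %in% names(sets$sets), , drop = FALSE]
  if (nrow(retained) < 2L) {
    abort_data("fewer than 2 genes retained (%d); cannot build a similarity matrix",
               nrow(retained))
  }

  dag <- cache_closures(dag)
  uterms <- unique(unlist(sets$sets, use.names = FALSE))
  tsm <- term_set_similarity(dag, uterms, measure, ic, wang_weights)

  n <- nrow(retained)
  S <- matrix(0, n, n, dimnames = list(retained$gene, retained$gene))
  tsets <- sets$sets[retained$gene]
  for (i in seq_len(n)) {
    ti <- tsets[[i]]
    for (j in i:n) {
      S[i, j] <- S[j, i] <- aggregate_scores(
        tsm[ti, tsets[[j]], drop = FALSE], aggregator)
    }
  }

  structure(
    list(matrix = S,
         genes = retained,
         excluded = excluded,
         measure = measure,
         aggregator = aggregator,
         namespace = dag$namespace,
         metadata = list(use_propagated = use_propagated,
                         wang_weights = as.list(wang_weights),
                         n_input_genes = nrow(genes))),
    class = "gene_sim"
  )
}

#' @export
print.gene_sim <- function(x, ...) {
  cat(sprintf("<gene_sim> %d x %d genes (%s + %s, %s); %d excluded\n",
              nrow(x$matrix), ncol(x$matrix), x$measure, x$aggregator,
              x$namespace, nrow(x$excluded)))
  invisible(x)
}

#' @export
as.matrix.gene_sim <- function(x, ...) x$matrix

#' Tidy a gene similarity matrix into long pair form
#'
#' @param x A `gene_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `gene1`, `gene2`, `similarity`
#'   (upper-triangle pairs, including the diagonal).
#' @export
tidy.gene_sim <- function(x, ...) {
  m <- x$matrix
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  tibble(gene1 = rownames(m)[idx[, 1L]],
         gene2 = colnames(m)[idx[, 2L]],
         similarity = m[idx])
}

#' One-row summary of a gene similarity matrix
#'
#' @param x A `gene_sim` object.
#' @param ... Unused.
#' @return A one-row tibble (gene counts, measure, aggregator, score range).
#' @export
glance.gene_sim <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  tibble(n_genes = nrow(x$matrix), n_excluded = nrow(x$excluded),
         measure = x$measure, aggregator = x$aggregator,
         namespace = x$namespace,
         min_similarity = min(off), mean_similarity = mean(off),
         max_similarity = max(off))
}

#' Heatmap of a gene similarity matrix
#'
#' @param object A `gene_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_sim <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(gene1 = rownames(m), gene2 = colnames(m))
  df$similarity <- as.vector(t(m))
  df$gene1 <- factor(df$gene1, levels = rev(rownames(m)))
  df$gene2 <- factor(df$gene2, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$gene2, .data$gene1,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Functional similarity (%s + %s)",
                                  object$measure, object$aggregator)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Write / read a gene similarity matrix as TSV + JSON sidecar
#'
#' The TSV holds the gene id column, an optional `label` column, then the
#' square similarity block; the sidecar (`<path>.json`) records measure,
#' aggregator, namespace and the exclusion list so a run can be resumed
#' from the matrix alone.
#'
#' @param x A `gene_sim` object.
#' @param path Output TSV path.
#' @return `path` invisibly (`write_gene_sim`); a `gene_sim` object
#'   (`read_gene_sim`).
#' @export
write_gene_sim <- function(x, path) {
  df <- tibble(gene = x$genes$gene)
  if ("label" %in% names(x$genes)) df$label <- x$genes$label
  # doubles serialised with %.17g so the matrix round-trips bit-exactly
  df <- dplyr::bind_cols(df, as_tibble(apply(x$matrix, 2L, num17)))
  readr::write_tsv(df, path)
  meta <- list(measure = x$measure, aggregator = x$aggregator,
               namespace = x$namespace, metadata = x$metadata,
               excluded = x$excluded)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gene_sim
#' @export
read_gene_sim <- function(path) {
  # base parser: correctly rounded doubles, so %.17g output round-trips
  df <- as_tibble(utils::read.delim(path, check.names = FALSE))
  has_label <- names(df)[[2L]] == "label"
  first_sim <- if (has_label) 3L else 2L
  m <- as.matrix(df[, first_sim:ncol(df)])
  rownames(m) <- df$gene
  if (!identical(colnames(m), df$gene)) {
    abort_data("similarity TSV is not square (header/id mismatch)")
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  genes <- tibble(gene = df$gene)
  if (has_label) genes$label <- df$label
  excluded <- if (!is.null(meta$excluded) && length(meta$excluded)) {
    bind_rows(lapply(meta$excluded, as_tibble))
  } else {
    tibble(gene = character(), reason = character())
  }
  structure(
    list(matrix = m, genes = genes, excluded = excluded,
         measure = meta$measure %||% NA_character_,
         aggregator = meta$aggregator %||% NA_character_,
         namespace = meta$namespace %||% NA_character_,
         metadata = meta$metadata %||% list()),
    class = "gene_sim"
  )
}
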