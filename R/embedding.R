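#' Convert a similarity matrix to a distance matrix
#'
#' Elementwise `d = 1 - s` with the diagonal forced to zero. Entries must
#' already lie in `[0, 1]` and the matrix must be symmetric.
#'
#' @param sim A `gene_sim` object or a square symmetric numeric matrix with
#'   entries in `[0, 1]`.
#' @return A `gene_dist` object wrapping the distance matrix.
#' @export
sim_to_dist <- function(sim) {
  m <- if (inherits(sim, "gene_sim")) sim$matrix else as.matrix(sim)
  if (!is_square_symmetric(m)) abort_data("similarity matrix must be square and symmetric")
  if (min(m) < -1e-12 || max(m) > 1 + 1e-12) {
    abort_data("similarity entries must lie in [0, 1] (range %.4f..%.4f)",
               min(m), max(m))
  }
  d <- 1 - m
  diag(d) <- 0
  gene_dist(d)
}

#' Distance matrix container
#'
#' @param m Square symmetric non-negative matrix with zero diagonal; row
#'   names identify the genes.
#' @return A `gene_dist` object.
#' @export
gene_dist <- function(m) {
  m <- as.matrix(m)
  if (!is_square_symmetric(m)) abort_data("distance matrix must be square and symmetric")
  if (min(m) < -1e-12) abort_data("distances must be non-negative")
  if (max(abs(diag(m))) > 1e-12) abort_data("distance diagonal must be zero")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("g", seq_len(nrow(m)))
  }
  structure(list(matrix = m), class = "gene_dist")
}

#' @export
print.gene_dist <- function(x, ...) {
  cat(sprintf("<gene_dist> %d genes\n", nrow(x$matrix)))
  invisible(x)
}

#' @export
as.matrix.gene_dist <- function(x, ...) x$matrix

#' @export
as.dist.gene_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$matrix, diag = diag, upper = upper)
}

subset_dist <- function(d, keep) gene_dist(d$matrix[keep, keep, drop = FALSE])

#' Low-dimensional embeddings of the gene similarity structure
#'
#' Projects genes into a low-dimensional space for clustering and
#' visualisation. `"pca"` treats each gene's row of the similarity matrix
#' as its feature vector; `"pcoa"` performs classical metric scaling of the
#' `1 - s` distance matrix; `"tsne"` and `"umap"` are stochastic 2-D layouts
#' run with a fixed seed (deterministic for identical input and
#' parameters).
#'
#' @param x A `gene_sim`, `gene_dist`, or numeric matrix (genes in rows).
#'   PCA accepts feature matrices or `gene_sim`; PCoA accepts distances or
#'   anything convertible via [sim_to_dist()]; t-SNE/UMAP accept either.
#' @param method One of `"pca"`, `"pcoa"`, `"tsne"`, `"umap"`.
#' @param n_components Number of output dimensions (stochastic methods are
#'   fixed at 2).
#' @param seed Integer seed for the stochastic methods.
#' @param perplexity,n_neighbors,min_dist Hyper-parameters of t-SNE / UMAP.
#' @return A `gene_embedding` object: coordinate matrix (rows = genes),
#'   per-dimension explained-variance fractions (PCA/PCoA), method tag,
#'   seed and parameters.
#' @export
embed_genes <- function(x, method = c("pca", "pcoa", "tsne", "umap"),
                        n_components = 2, seed = 1L, perplexity = 30,
                        n_neighbors = 15, min_dist = 0.1) {
  method <- match_enum(method[[1L]], c("pca", "pcoa", "tsne", "umap"),
                       "embedding method")
  switch(method,
    pca = embed_pca(x, n_components),
    pcoa = embed_pcoa(x, n_components),
    embed_stochastic(x, method, seed = seed, perplexity = perplexity,
                     n_neighbors = n_neighbors, min_dist = min_dist)
  )
}

as_feature_matrix <- function(x) {
  if (inherits(x, "gene_sim")) return(x$matrix)
  if (inherits(x, "gene_embedding")) return(x$coords)
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  m
}

as_distance <- function(x) {
  if (inherits(x, "gene_dist")) return(x)
  if (inherits(x, "gene_sim")) return(sim_to_dist(x))
  if (inherits(x, "gene_embedding")) {
    return(gene_dist(as.matrix(dist(x$coords))))
  }
  m <- as.matrix(x)
  if (is_square_symmetric(m) && max(abs(diag(m))) < 1e-12) return(gene_dist(m))
  gene_dist(as.matrix(dist(m)))
}

new_embedding <- function(coords, method, evr = NULL, seed = NULL,
                          params = list()) {
  colnames(coords) <- paste0("dim_", seq_len(ncol(coords)))
  structure(list(coords = coords, method = method,
                 explained_variance = evr, seed = seed, params = params),
            class = "gene_embedding")
}

# fix sign: the largest-magnitude element of each column made positive
fix_signs <- function(scores, loadings = NULL) {
  ref <- if (is.null(loadings)) scores else loadings
  flip <- vapply(seq_len(ncol(ref)), function(j) {
    v <- ref[, j]
    sign(v[which.max(abs(v))]) < 0
  }, TRUE)
  scores[, flip] <- -scores[, flip, drop = FALSE]
  scores
}

embed_pca <- function(x, n_components) {
  X <- as_feature_matrix(x)
  n <- nrow(X)
  if (n_components > min(n - 1L, ncol(X))) {
    abort_config("n_components (%d) exceeds min(n - 1, p) = %d",
                 n_components, min(n - 1L, ncol(X)))
  }
  total_var <- sum(apply(X, 2L, stats::var))
  if (total_var < 1e-14) abort_numeric("feature matrix has zero variance")
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  evr_all <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- fix_signs(fit$x[, seq_len(n_components), drop = FALSE],
                      fit$rotation[, seq_len(n_components), drop = FALSE])
  rownames(scores) <- rownames(X)
  new_embedding(scores, "pca", evr = evr_all[seq_len(n_components)],
                params = list(evr_full = evr_all))
}

embed_pcoa <- function(x, n_components) {
  d <- as_distance(x)
  n <- nrow(d$matrix)
  if (n < 3L) abort_data("PCoA needs at least 3 points")
  # cmdscale warns when fewer than k positive eigenvalues exist; the
  # spectrum is handled explicitly below
  fit <- suppressWarnings(
    cmdscale(stats::as.dist(d$matrix), k = min(n_components, n - 1L),
             eig = TRUE))
  eig <- fit$eig
  pos <- eig[eig > 1e-10]
  if (!length(pos)) abort_numeric("no positive eigenvalues in classical scaling")
  n_neg <- sum(eig < -1e-10)
  if (n_neg) {
    inform(sprintf("embed_pcoa: dropped %d negative eigenvalue(s)", n_neg))
  }
  k <- min(n_components, length(pos), ncol(fit$points))
  coords <- fix_signs(fit$points[, seq_len(k), drop = FALSE])
  rownames(coords) <- rownames(d$matrix)
  new_embedding(coords, "pcoa", evr = pos[seq_len(k)] / sum(pos),
                params = list(n_negative_eigenvalues = n_neg))
}

embed_stochastic <- function(x, method, seed, perplexity = 30,
                             n_neighbors = 15, min_dist = 0.1) {
  if (is.null(seed)) abort_config("stochastic embeddings require a seed")
  if (method == "tsne") {
    if (!requireNamespace("Rtsne", quietly = TRUE)) {
      abort_config("t-SNE requires the Rtsne package")
    }
    is_dist <- inherits(x, "gene_dist")
    X <- if (is_dist) x$matrix else as_feature_matrix(x)
    n <- nrow(X)
    if (3 * perplexity >= n - 1) {
      abort_config("perplexity %g too large for n = %d (need 3*perplexity < n - 1)",
                   perplexity, n)
    }
    set.seed(seed)
    fit <- Rtsne::Rtsne(X, dims = 2L, perplexity = perplexity,
                        is_distance = is_dist, pca = !is_dist,
                        check_duplicates = FALSE, num_threads = 1L)
    coords <- fit$Y
    rownames(coords) <- rownames(X)
    return(new_embedding(coords, "tsne", seed = seed,
                         params = list(perplexity = perplexity)))
  }
  if (!requireNamespace("uwot", quietly = TRUE)) {
    abort_config("UMAP requires the uwot package")
  }
  X <- if (inherits(x, "gene_dist")) x$matrix else as_feature_matrix(x)
  n <- nrow(X)
  if (n_neighbors >= n) {
    abort_config("n_neighbors %d must be smaller than n = %d", n_neighbors, n)
  }
  set.seed(seed)
  input <- if (inherits(x, "gene_dist")) stats::as.dist(X) else X
  coords <- uwot::umap(input, n_neighbors = n_neighbors, min_dist = min_dist,
                       n_threads = 1L, n_sgd_threads = 1L)
  rownames(coords) <- rownames(X)
  new_embedding(coords, "umap", seed = seed,
                params = list(n_neighbors = n_neighbors, min_dist = min_dist))
}

#' Choose the number of retained components
#'
#' `"elbow"` returns the smallest `k` for which the drop
#' `evr[k] - evr[k+1]` falls below `drop_frac` times the first drop
#' `evr[1] - evr[2]` (i.e. the curve has flattened relative to its initial
#' slope); `"threshold"` simply returns the user-fixed `k`.
#'
#' @param evr Non-increasing explained-variance fractions.
#' @param strategy `"elbow"` or `"threshold"`.
#' @param k Component count for the threshold strategy.
#' @param drop_frac Flatness ratio for the elbow rule (default 0.1).
#' @return A list with the chosen `k` and the `curve` tibble.
#' @export
select_components <- function(evr, strategy = c("elbow", "threshold"),
                              k = NULL, drop_frac = 0.1) {
  strategy <- match.arg(strategy)
  if (any(diff(evr) > 1e-12)) {
    abort_data("explained-variance fractions must be non-increasing")
  }
  curve <- tibble(component = seq_along(evr), evr = as.numeric(evr))
  if (strategy == "threshold") {
    if (is.null(k)) abort_config("threshold strategy requires k")
    return(list(k = as.integer(k), curve = curve))
  }
  if (length(evr) < 3L) abort_data("elbow strategy needs at least 3 components")
  drops <- -diff(evr)
  ref <- drops[[1L]]
  if (ref <= 0) abort_numeric("flat variance curve; elbow undefined")
  hit <- which(drops < drop_frac * ref)
  list(k = if (length(hit)) as.integer(hit[[1L]]) else length(evr),
       curve = curve)
}

#' @export
print.gene_embedding <- function(x, ...) {
  cat(sprintf("<gene_embedding> %s: %d genes x %d dims\n",
              x$method, nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

#' Tidy an embedding into a coordinate tibble
#'
#' @param x A `gene_embedding` object.
#' @param ... Unused.
#' @return A tibble with `gene` and one `dim_*` column per dimension.
#' @export
tidy.gene_embedding <- function(x, ...) {
  dplyr::bind_cols(tibble(gene = rownames(x$coords)), as_tibble(x$coords))
}

#' Scatterplot of the first two embedding dimensions
#'
#' @param object A `gene_embedding` object.
#' @param labels Optional per-gene grouping (cluster or disease labels)
#'   used for colour, in row order.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_embedding <- function(object, labels = NULL, ...) {
  df <- tidy(object)
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$dim_1, .data$dim_2))
  } else {
    df$group <- factor(labels)
    ggplot2::ggplot(df, ggplot2::aes(.data$dim_1, .data$dim_2,
                                     colour = .data$group))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("%s embedding", toupper(object$method))) +
    ggplot2::theme_minimal()
}

#' Write / read an embedding as TSV + JSON sidecar
#'
#' @param x A `gene_embedding` object.
#' @param path Output TSV path.
#' @return `path` invisibly (`write_embedding`); a `gene_embedding`
#'   (`read_embedding`).
#' @export
write_embedding <- function(x, path) {
  df <- tidy(x)
  df[-1L] <- lapply(df[-1L], num17)
  readr::write_tsv(df, path)
  jsonlite::write_json(
    list(method = x$method, seed = x$seed, params = x$params,
         explained_variance = x$explained_variance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- as_tibble(utils::read.delim(path, check.names = FALSE))
  coords <- as.matrix(df[, -1L, drop = FALSE])
  rownames(coords) <- df[[1L]]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  new_embedding(coords, meta$method %||% "unknown",
                evr = unlist(meta$explained_variance),
                seed = meta$seed, params = meta$params %||% list())
}
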