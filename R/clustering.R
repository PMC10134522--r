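CLUSTER_METHODS <- c("kmeans", "pam", "ward", "fuzzy")

#' Cluster genes on an embedding or a distance matrix
#'
#' Four methods: k-means (k-means++ seeding, 10 restarts), PAM
#' (k-medoids, accepts distances natively), Ward hierarchical clustering
#' (Ward linkage on Euclidean coordinates, tree cut at `k`) and fuzzy
#' c-means (fuzzifier `m = 2`, hardened by maximum membership, ties to the
#' lowest cluster index). Coordinate-based methods given a distance matrix
#' auto-embed it with PCoA first (logged) unless `auto_embed = FALSE`.
#'
#' @param x A `gene_embedding`, `gene_dist`, `gene_sim` (converted to
#'   distances) or numeric coordinate matrix.
#' @param method One of `"kmeans"`, `"pam"`, `"ward"`, `"fuzzy"`.
#' @param k Number of clusters, `2 <= k <= n - 1`.
#' @param seed Integer seed (k-means restarts, fuzzy initialisation).
#' @param auto_embed Allow PCoA auto-embedding of distance input for
#'   coordinate-based methods.
#' @param nstart Restarts for k-means.
#' @param fuzzifier Fuzzy c-means exponent `m`.
#' @return A `cluster_solution`: per-gene labels `1..k`, the method, `k`,
#'   seed, optional membership matrix and the space clustered.
#' @export
cluster_genes <- function(x, method = c("kmeans", "pam", "ward", "fuzzy"),
                          k, seed = 1L, auto_embed = TRUE, nstart = 10L,
                          fuzzifier = 2) {
  method <- match_enum(method[[1L]], CLUSTER_METHODS, "clustering method")
  is_dist_input <- inherits(x, "gene_dist") || inherits(x, "gene_sim")
  n <- if (is_dist_input) nrow(as_distance(x)$matrix) else
    nrow(as_feature_matrix(x))
  if (k < 2L || k > n - 1L) {
    abort_config("k = %d outside the valid range 2..%d", k, n - 1L)
  }

  space <- if (is_dist_input) "distance" else "embedding"
  membership <- NULL

  if (method == "pam") {
    d <- as_distance(x)
    fit <- cluster::pam(stats::as.dist(d$matrix), k = k, diss = TRUE)
    labels <- setNames(as.integer(fit$clustering), rownames(d$matrix))
  } else {
    if (is_dist_input) {
      if (!auto_embed) {
        abort_config("method '%s' needs coordinates; set auto_embed = TRUE or embed first",
                     method)
      }
      inform(sprintf("cluster_genes: auto-embedding distances via PCoA for %s",
                     method))
      d <- as_distance(x)
      x <- embed_pcoa(d, n_components = min(n - 1L, 10L))
    }
    X <- as_feature_matrix(x)
    labels <- switch(method,
      kmeans = kmeanspp(X, k, seed = seed, nstart = nstart),
      ward = {
        hc <- hclust(dist(X), method = "ward.D2")
        setNames(as.integer(cutree(hc, k = k)), rownames(X))
      },
      fuzzy = {
        set.seed(seed)
        fit <- e1071::cmeans(X, centers = k, m = fuzzifier, iter.max = 200L)
        membership <- fit$membership
        rownames(membership) <- rownames(X)
        hard <- apply(membership, 1L, which.max)
        setNames(as.integer(hard), rownames(X))
      })
  }

  labels <- relabel_contiguous(labels)
  structure(
    list(labels = labels, method = method, k = max(labels), seed = seed,
         membership = membership, space = space),
    class = "cluster_solution"
  )
}

# k-means with k-means++ seeding and multiple restarts
kmeanspp <- function(X, k, seed, nstart = 10L) {
  set.seed(seed)
  n <- nrow(X)
  best <- NULL
  for (r in seq_len(nstart)) {
    centers_idx <- integer(k)
    centers_idx[1L] <- sample.int(n, 1L)
    d2 <- rowSums((X - matrix(X[centers_idx[1L], ], n, ncol(X),
                              byrow = TRUE))^2)
    for (j in seq_len(k - 1L)) {
      probs <- d2 / sum(d2)
      centers_idx[j + 1L] <- sample.int(n, 1L, prob = probs)
      d2_new <- rowSums((X - matrix(X[centers_idx[j + 1L], ], n, ncol(X),
                                    byrow = TRUE))^2)
      d2 <- pmin(d2, d2_new)
    }
    fit <- suppressWarnings(
      kmeans(X, centers = X[centers_idx, , drop = FALSE], iter.max = 100L))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  setNames(as.integer(best$cluster), rownames(X))
}

relabel_contiguous <- function(labels) {
  u <- sort(unique(labels))
  out <- match(labels, u)
  names(out) <- names(labels)
  out
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %s, k = %d, n = %d (%s space)\n",
              x$method, x$k, length(x$labels), x$space))
  invisible(x)
}

#' Tidy a cluster solution into a gene/cluster tibble
#'
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return A tibble with `gene` and `cluster` (plus memberships for fuzzy).
#' @export
tidy.cluster_solution <- function(x, ...) {
  out <- tibble(gene = names(x$labels), cluster = unname(x$labels))
  if (!is.null(x$membership)) {
    mem <- as_tibble(x$membership, .name_repair = ~ paste0("membership_",
                                                           seq_along(.x)))
    out <- dplyr::bind_cols(out, mem)
  }
  out
}

#' One-row summary of a cluster solution
#'
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble(method = x$method, k = x$k, n = length(x$labels), seed = x$seed,
         space = x$space)
}

#' Silhouette validation of a clustering
#'
#' For each gene, `a` is its mean distance to the other members of its own
#' cluster (cohesion) and `b` the smallest mean distance to the members of
#' any other cluster (separation from the nearest cluster); the silhouette
#' is `(b - a) / max(a, b)`, in `[-1, 1]`. Members of singleton clusters
#' get silhouette 0 by convention. Per-cluster values are the arithmetic
#' means of their members' silhouettes; the overall value is the mean over
#' all genes.
#'
#' @param d A `gene_dist` (or object convertible via [as_distance()]
#'   semantics: `gene_sim`, square matrix, coordinates).
#' @param labels Integer cluster labels (vector or `cluster_solution`).
#' @return A `silhouette_report` with per-gene, per-cluster and overall
#'   components.
#' @export
silhouette_report <- function(d, labels) {
  if (inherits(labels, "cluster_solution")) labels <- labels$labels
  D <- as_distance(d)$matrix
  n <- nrow(D)
  if (length(labels) != n) abort_data("labels length != number of genes")
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) abort_data("silhouette needs at least 2 clusters")

  sizes <- as.integer(table(factor(labels, levels = ks)))
  ind <- outer(labels, ks, "==") * 1            # n x k membership indicator
  sums <- D %*% ind                              # distance sums to each cluster
  own_col <- match(labels, ks)

  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    oc <- own_col[[i]]
    if (sizes[[oc]] == 1L) { a[i] <- 0; b[i] <- 0; s[i] <- 0; next }
    a[i] <- sums[i, oc] / (sizes[[oc]] - 1L)
    means_other <- sums[i, -oc] / sizes[-oc]
    b[i] <- min(means_other)
    s[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }

  genes <- tibble(gene = rownames(D), cluster = labels, a = a, b = b,
                  silhouette = s)
  clusters <- genes |>
    group_by(.data$cluster) |>
    summarise(n = dplyr::n(), silhouette = mean(.data$silhouette),
              .groups = "drop")
  structure(list(genes = genes, clusters = clusters, overall = mean(s)),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("<silhouette_report> %d genes, %d clusters, overall %.3f\n",
              nrow(x$genes), nrow(x$clusters), x$overall))
  invisible(x)
}

#' Tidy a silhouette report (per-gene rows)
#'
#' @param x A `silhouette_report`.
#' @param ... Unused.
#' @return The per-gene tibble (`gene`, `cluster`, `a`, `b`, `silhouette`).
#' @export
tidy.silhouette_report <- function(x, ...) x$genes

#' One-row summary of a silhouette report
#'
#' @param x A `silhouette_report`.
#' @param ... Unused.
#' @return A one-row tibble (cluster count, overall mean, outlier count).
#' @export
glance.silhouette_report <- function(x, ...) {
  tibble(n_genes = nrow(x$genes), k = nrow(x$clusters),
         overall_silhouette = x$overall,
         n_negative = sum(x$genes$silhouette < 0))
}

#' Per-cluster validation statistics
#'
#' For each cluster: size, diameter (largest within-cluster distance),
#' average within-cluster distance (over member pairs), average distance
#' from members to all non-members, separation (smallest member to
#' non-member distance) and mean silhouette, plus a `stable` flag marking
#' clusters whose mean silhouette reaches `stability_threshold` (an
#' interpretive aid, default 0.25).
#'
#' @param d Distances (as in [silhouette_report()]).
#' @param labels Integer cluster labels or a `cluster_solution`.
#' @param stability_threshold Mean-silhouette level flagged as stable.
#' @return A tibble with one row per cluster.
#' @export
cluster_stats <- function(d, labels, stability_threshold = 0.25) {
  if (inherits(labels, "cluster_solution")) labels <- labels$labels
  D <- as_distance(d)$matrix
  labels <- as.integer(labels)
  sil <- silhouette_report(gene_dist(D), labels)
  ks <- sort(unique(labels))
  rows <- purrr::map(ks, function(kk) {
    members <- labels == kk
    Din <- D[members, members, drop = FALSE]
    Dx <- D[members, !members, drop = FALSE]
    nk <- sum(members)
    within_pairs <- Din[upper.tri(Din)]
    tibble(
      cluster = kk,
      n = nk,
      diameter = if (nk > 1L) max(within_pairs) else 0,
      avg_within = if (nk > 1L) mean(within_pairs) else 0,
      avg_between = mean(Dx),
      separation = min(Dx),
      silhouette = sil$clusters$silhouette[sil$clusters$cluster == kk]
    )
  })
  out <- bind_rows(rows)
  out$stable <- out$silhouette >= stability_threshold
  out
}

#' Silhouette-guided selection of the number of clusters
#'
#' Clusters the data at every `k` in `k_range`, scores each solution by the
#' overall mean silhouette and returns the maximiser (ties to the smallest
#' `k`) together with the full silhouette-versus-k curve.
#'
#' @param x Data accepted by [cluster_genes()].
#' @param method Clustering method.
#' @param k_range Integer vector of candidate `k` (default
#'   `2..min(25, n - 1)`).
#' @param seed Integer seed.
#' @param validate_on Distances used for the silhouette scoring (a
#'   `gene_dist` or `gene_sim`). Defaults to distances derived from `x`
#'   itself; when clustering an embedding of a functional similarity
#'   matrix, pass the `1 - s` distances so the sweep is validated on the
#'   similarity structure rather than on embedding-space geometry.
#' @param ... Passed to [cluster_genes()].
#' @return A list with `k` (the optimum), `curve` (tibble `k`,
#'   `silhouette`) and `solutions` (per-k `cluster_solution`s).
#' @export
optimal_k <- function(x, method = "kmeans", k_range = NULL, seed = 1L,
                      validate_on = NULL, ...) {
  d <- if (is.null(validate_on)) as_distance(x) else as_distance(validate_on)
  if (!identical(rownames(d$matrix), gene_ids_of(x))) {
    abort_data("validate_on distances do not match the clustered genes")
  }
  n <- nrow(d$matrix)
  if (is.null(k_range)) k_range <- 2:min(25L, n - 1L)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) abort_config("empty k range")
  if (min(k_range) < 2L || max(k_range) > n - 1L) {
    abort_config("k range %d..%d outside 2..%d", min(k_range), max(k_range),
                 n - 1L)
  }
  solutions <- lapply(k_range, function(k) {
    cluster_genes(x, method = method, k = k, seed = seed, ...)
  })
  sils <- vapply(solutions, function(sol) {
    silhouette_report(d, sol)$overall
  }, 0)
  best <- which.max(sils)   # first maximum = smallest k on ties
  list(k = k_range[[best]],
       curve = tibble(k = k_range, silhouette = sils),
       solutions = setNames(solutions, paste0("k", k_range)))
}

#' Outlier-refinement loop
#'
#' Round 1 selects the optimal `k` by silhouette sweep, clusters, and flags
#' every gene with a negative silhouette as an outlier. Outliers are
#' removed and round 2 repeats the sweep and clustering on the reduced
#' set. Exactly one refinement pass is run by default; `iterate = TRUE`
#' repeats until no outlier remains.
#'
#' @inheritParams optimal_k
#' @param iterate Repeat the removal until a fixed point.
#' @return A `refinement` object: `round1` and `round2` (each with `k`,
#'   `solution`, `silhouette`, `curve`), and the `outliers` character
#'   vector.
#' @export
refine_outliers <- function(x, method = "kmeans", k_range = NULL, seed = 1L,
                            validate_on = NULL, iterate = FALSE, ...) {
  vd <- if (is.null(validate_on)) NULL else as_distance(validate_on)
  run_round <- function(data, vdist) {
    opt <- optimal_k(data, method = method, k_range = k_range, seed = seed,
                     validate_on = vdist, ...)
    sol <- opt$solutions[[paste0("k", opt$k)]]
    sil <- silhouette_report(if (is.null(vdist)) as_distance(data) else vdist,
                             sol)
    list(k = opt$k, curve = opt$curve, solution = sol, silhouette = sil)
  }

  round1 <- run_round(x, vd)
  outliers <- round1$silhouette$genes$gene[round1$silhouette$genes$silhouette < 0]

  current <- x
  all_out <- outliers
  repeat {
    if (!length(all_out)) {
      inform("refine_outliers: no outliers found; round 2 equals round 1")
      round2 <- round1
      break
    }
    keep <- setdiff(gene_ids_of(current), all_out)
    if (length(keep) < 3L) abort_data("outlier removal left fewer than 3 genes")
    current <- subset_genes(current, keep)
    round2 <- run_round(current,
                        if (is.null(vd)) NULL else subset_dist(vd, keep))
    new_out <- round2$silhouette$genes$gene[round2$silhouette$genes$silhouette < 0]
    if (!iterate || !length(new_out)) break
    all_out <- c(all_out, new_out)
  }

  structure(list(round1 = round1, round2 = round2, outliers = all_out),
            class = "refinement")
}

gene_ids_of <- function(x) {
  if (inherits(x, "gene_dist")) return(rownames(x$matrix))
  if (inherits(x, "gene_sim")) return(x$genes$gene)
  rownames(as_feature_matrix(x))
}

subset_genes <- function(x, keep) {
  if (inherits(x, "gene_dist")) return(subset_dist(x, keep))
  if (inherits(x, "gene_sim")) {
    x$matrix <- x$matrix[keep, keep, drop = FALSE]
    x$genes <- x$genes[x$genes$gene %in% keep, , drop = FALSE]
    return(x)
  }
  if (inherits(x, "gene_embedding")) {
    x$coords <- x$coords[keep, , drop = FALSE]
    return(x)
  }
  as_feature_matrix(x)[keep, , drop = FALSE]
}

#' @export
print.refinement <- function(x, ...) {
  cat(sprintf(
    "<refinement> round 1: k = %d (%d outliers) -> round 2: k = %d, n = %d\n",
    x$round1$k, length(x$outliers), x$round2$k,
    nrow(x$round2$silhouette$genes)))
  invisible(x)
}

#' Tidy a refinement into a per-gene table
#'
#' @param x A `refinement` object.
#' @param ... Unused.
#' @return Tibble with `round`, `gene`, `cluster`, `silhouette`, `outlier`.
#' @export
tidy.refinement <- function(x, ...) {
  bind_rows(
    mutate(x$round1$silhouette$genes, round = 1L,
           outlier = .data$gene %in% x$outliers),
    mutate(x$round2$silhouette$genes, round = 2L, outlier = FALSE)
  ) |>
    select("round", "gene", "cluster", "silhouette", "outlier")
}

#' Silhouette plot with per-cluster bars and overall mean line
#'
#' @param report A `silhouette_report`.
#' @return A ggplot object.
#' @export
plot_silhouette <- function(report) {
  df <- report$genes |>
    arrange(.data$cluster, dplyr::desc(.data$silhouette)) |>
    mutate(rank = dplyr::row_number(), cluster = factor(.data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$silhouette,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = report$overall, colour = "red") +
    ggplot2::labs(x = NULL, y = "silhouette") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Silhouette-versus-k curve plot
#'
#' @param curve Tibble with columns `k` and `silhouette` (from
#'   [optimal_k()]).
#' @return A ggplot object.
#' @export
plot_silhouette_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$k, .data$silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette") +
    ggplot2::theme_minimal()
}
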