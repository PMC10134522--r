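# Independent brute-force oracles. These deliberately avoid the package's
# memoised/vectorised code paths: closures by breadth-first search over the
# raw edge table, Wang S-values by exhaustive path-product enumeration,
# silhouettes by the textbook per-point formula.

oracle_closure <- function(dag, term) {
  edges <- dag$edges
  seen <- term
  frontier <- term
  while (length(frontier)) {
    parents <- edges$parent[edges$child %in% frontier]
    frontier <- setdiff(parents, seen)
    seen <- union(seen, frontier)
  }
  seen
}

oracle_ic <- function(dag, direct) {
  # direct: tibble(gene, term); counts genes per term after closure
  per_gene <- split(direct$term, direct$gene)
  prop <- lapply(per_gene, function(ts) {
    unique(unlist(lapply(ts, oracle_closure, dag = dag)))
  })
  n_root <- sum(vapply(prop, function(ts) dag$root %in% ts, TRUE))
  counts <- table(unlist(prop))
  p <- setNames(rep(0, nrow(dag$terms)), dag$terms$id)
  p[names(counts)] <- as.numeric(counts) / n_root
  ic <- ifelse(p > 0, -log(p), NA_real_)
  list(p = p, ic = ic, ic_max = max(ic, na.rm = TRUE))
}

oracle_mica_ic <- function(dag, icv, t1, t2) {
  common <- intersect(oracle_closure(dag, t1), oracle_closure(dag, t2))
  vals <- icv[common]
  vals <- vals[!is.na(vals)]
  best <- max(vals)
  list(term = sort(names(vals)[vals == best])[[1L]], ic = best)
}

oracle_ic_measure <- function(dag, orc, t1, t2, measure) {
  m <- oracle_mica_ic(dag, orc$ic, t1, t2)
  ic1 <- orc$ic[[t1]]; ic2 <- orc$ic[[t2]]
  switch(measure,
    resnik = m$ic / orc$ic_max,
    lin = if (ic1 + ic2 == 0) 0 else 2 * m$ic / (ic1 + ic2),
    rel = if (ic1 + ic2 == 0) 0 else
      2 * m$ic * (1 - orc$p[[m$term]]) / (ic1 + ic2),
    jiang = 1 - min(1, ic1 + ic2 - 2 * m$ic))
}

# Wang S-values by enumerating every directed path term -> ancestor and
# taking the best product of edge weights along a path.
oracle_wang_s <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  s <- setNames(numeric(0), character(0))
  walk <- function(node, prod) {
    cur <- if (node %in% names(s)) s[[node]] else -Inf
    if (prod <= cur) return(invisible())
    s[node] <<- prod
    edges <- dag$edges[dag$edges$child == node, , drop = FALSE]
    for (i in seq_len(nrow(edges))) {
      walk(edges$parent[[i]], prod * weights[[edges$relation[[i]]]])
    }
  }
  walk(term, 1)
  s
}

oracle_wang_sim <- function(dag, t1, t2, weights = c(is_a = 0.8, part_of = 0.6)) {
  s1 <- oracle_wang_s(dag, t1, weights)
  s2 <- oracle_wang_s(dag, t2, weights)
  shared <- intersect(names(s1), names(s2))
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

oracle_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- a <- b <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a[i] <- mean(D[i, own])
    b[i] <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, 0))
    s[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  s
}

# Random rooted DAG: term 1 is the root; each later term picks 1-2 earlier
# parents, so the graph is acyclic by construction.
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  children <- list()
  for (i in 2:n_terms) {
    n_par <- sample(1:min(2L, i - 1L), 1L)
    parents <- sample(ids[seq_len(i - 1L)], n_par)
    children[[i]] <- tibble::tibble(
      child = ids[[i]], parent = parents,
      relation = sample(c("is_a", "part_of"), n_par, replace = TRUE,
                        prob = c(0.8, 0.2)))
  }
  go_dag(tibble::tibble(id = ids, name = ids, namespace = "BP"),
         dplyr::bind_rows(children))
}

random_corpus <- function(dag, n_genes, seed) {
  set.seed(seed)
  non_root <- setdiff(dag$terms$id, dag$root)
  rows <- lapply(seq_len(n_genes), function(g) {
    tibble::tibble(gene = sprintf("g%03d", g),
                   term = sample(non_root, sample(1:3, 1L)))
  })
  go_annotations(dplyr::bind_rows(rows), dag)
}

# exhaustive minimiser of within-cluster sum of squares over 2-partitions
oracle_best_2partition <- function(x) {
  n <- length(x)
  best <- NULL; best_ss <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    ss <- sum((x[grp] - mean(x[grp]))^2) + sum((x[!grp] - mean(x[!grp]))^2)
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- grp }
  }
  best
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

t1_direct <- function() {
  tibble::tibble(gene = c("g1", "g2", "g3"), term = c("GO:C", "GO:D", "GO:B"))
}
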