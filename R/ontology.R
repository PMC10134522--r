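#' Gene Ontology DAG objects
#'
#' A `go_dag` holds one namespace of the Gene Ontology as a rooted directed
#' acyclic graph: a term table plus child-to-parent edges typed `is_a` or
#' `part_of`. It is the substrate for annotation propagation (true-path
#' rule), information-content calculations and the Wang similarity measure.
#'
#' @param terms A data frame with columns `id`, `name`, `namespace`
#'   (namespace values are one of `"BP"`, `"MF"`, `"CC"`).
#' @param edges A data frame with columns `child`, `parent`, `relation`
#'   (`relation` in `is_a`/`part_of`); all child/parent ids must appear in
#'   `terms$id`.
#' @param alt_ids Optional named character vector mapping alternate term ids
#'   to their canonical id.
#'
#' @return A `go_dag` object.
#' @export
#' @examples
#' dag <- go_dag(
#'   terms = data.frame(id = c("R", "A", "B"), name = c("root", "a", "b"),
#'                      namespace = "BP"),
#'   edges = data.frame(child = c("A", "B"), parent = "R", relation = "is_a")
#' )
#' term_ancestors(dag, "A")
go_dag <- function(terms, edges, alt_ids = character()) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  ns <- unique(terms$namespace)
  if (length(ns) != 1L) {
    abort_data("a go_dag holds exactly one namespace, got: %s",
               paste(ns, collapse = ", "))
  }
  match_enum(ns, c("BP", "MF", "CC"), "namespace")
  if (anyDuplicated(terms$id)) {
    abort_data("duplicated term ids: %s",
               paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel)) {
    abort_data("unknown edge relation(s): %s", paste(bad_rel, collapse = ", "))
  }
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing)) {
    abort_data("edge references term(s) absent from the term table: %s",
               paste(head(missing, 5L), collapse = ", "))
  }

  check_acyclic(terms$id, edges)

  parentless <- setdiff(terms$id, edges$child)
  if (length(parentless) != 1L) {
    abort_data("expected exactly one root (parentless term), found %d: %s",
               length(parentless), paste(head(parentless, 5L), collapse = ", "))
  }

  parents <- split(edges$parent, factor(edges$child, levels = terms$id))
  relations <- split(edges$relation, factor(edges$child, levels = terms$id))

  structure(
    list(terms = terms, edges = edges,
         parents = parents, relations = relations,
         root = parentless, namespace = ns,
         alt_ids = alt_ids),
    class = "go_dag"
  )
}

check_acyclic <- function(ids, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = ids)
  )
  if (!igraph::is_dag(g)) {
    ord <- suppressWarnings(igraph::topo_sort(g))
    cyclic <- setdiff(ids, names(ord))
    abort_data("ontology graph contains a cycle involving term '%s'",
               if (length(cyclic)) cyclic[[1L]] else ids[[1L]])
  }
  invisible(TRUE)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %s: %d terms, %d edges, root %s\n",
              x$namespace, nrow(x$terms), nrow(x$edges), x$root))
  invisible(x)
}

#' @export
format.go_dag <- function(x, ...) {
  sprintf("<go_dag %s/%d terms>", x$namespace, nrow(x$terms))
}

#' Tidy a GO DAG into its edge list
#'
#' @param x A [go_dag()].
#' @param ... Unused.
#' @return A tibble with one row per child-parent edge.
#' @export
tidy.go_dag <- function(x, ...) x$edges

obo_namespace_map <- c(
  biological_process = "BP",
  molecular_function = "MF",
  cellular_component = "CC"
)

#' Read one namespace of an OBO ontology file
#'
#' Parses OBO 1.2/1.4 text, keeps non-obsolete terms of the requested
#' namespace, retains only `is_a` and `part_of` relationships, resolves
#' `alt_id` entries to their canonical term, and drops the few edges whose
#' parent lives in a different namespace. Cycles and references to terms
#' absent from the file are hard errors.
#'
#' @param path Path to an OBO file (or a character vector of its lines).
#' @param namespace One of `"BP"`, `"MF"`, `"CC"`.
#' @return A [go_dag()] restricted to the requested namespace.
#' @export
read_obo <- function(path, namespace = c("BP", "MF", "CC")) {
  namespace <- match_enum(namespace[[1L]], c("BP", "MF", "CC"), "namespace")
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path

  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) abort_data("no stanzas found in OBO input")
  bounds <- c(stanza_starts, length(lines) + 1L)

  records <- list()
  for (i in seq_along(stanza_starts)) {
    if (lines[[stanza_starts[i]]] != "[Term]") next
    body <- lines[seq(stanza_starts[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    keys <- sub(":.*$", "", body)
    vals <- trimws(sub("^[^:]+:", "", body))
    vals <- trimws(sub("!.*$", "", vals))  # strip trailing term-label comments
    rec <- list(
      id = vals[keys == "id"][1L],
      name = if (any(keys == "name")) vals[keys == "name"][1L] else NA_character_,
      namespace = if (any(keys == "namespace")) vals[keys == "namespace"][1L] else NA_character_,
      obsolete = any(keys == "is_obsolete" & vals == "true"),
      alt_id = vals[keys == "alt_id"],
      is_a = vals[keys == "is_a"],
      relationship = vals[keys == "relationship"]
    )
    if (is.na(rec$id)) abort_data("OBO [Term] stanza without an id")
    records[[length(records) + 1L]] <- rec
  }
  if (!length(records)) abort_data("OBO input contains no [Term] stanzas")

  ids_all <- vapply(records, `[[`, "", "id")
  obsolete <- vapply(records, `[[`, TRUE, "obsolete")
  ns_all <- unname(obo_namespace_map[vapply(records, `[[`, "", "namespace")])

  alt_pairs <- purrr::map(records, function(r) {
    if (length(r$alt_id)) setNames(rep(r$id, length(r$alt_id)), r$alt_id) else NULL
  })
  alt_ids <- unlist(alt_pairs) %||% character()

  canon <- function(x) ifelse(x %in% names(alt_ids), unname(alt_ids[x]), x)

  keep <- !obsolete & !is.na(ns_all) & ns_all == namespace
  kept_ids <- ids_all[keep]
  known_ids <- ids_all[!obsolete]

  edge_rows <- purrr::map(records[keep], function(r) {
    parents <- character(); rels <- character()
    if (length(r$is_a)) {
      parents <- c(parents, r$is_a)
      rels <- c(rels, rep("is_a", length(r$is_a)))
    }
    for (rel in r$relationship) {
      parts <- strsplit(trimws(rel), "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of") {
        parents <- c(parents, parts[[2L]])
        rels <- c(rels, "part_of")
      }
    }
    if (!length(parents)) return(NULL)
    tibble(child = r$id, parent = canon(parents), relation = rels)
  })
  edges <- bind_rows(edge_rows)
  if (!nrow(edges)) {
    edges <- tibble(child = character(), parent = character(),
                    relation = character())
  }

  if (nrow(edges)) {
    unknown_parent <- setdiff(edges$parent, c(known_ids, kept_ids))
    if (length(unknown_parent)) {
      abort_data("term(s) reference parent(s) missing from the file: %s",
                 paste(head(unknown_parent, 5L), collapse = ", "))
    }
    cross <- !(edges$parent %in% kept_ids)
    if (any(cross)) {
      inform(sprintf("read_obo: dropped %d cross-namespace edge(s)", sum(cross)))
      edges <- edges[!cross, , drop = FALSE]
    }
  }

  terms <- tibble(
    id = kept_ids,
    name = vapply(records[keep], `[[`, "", "name"),
    namespace = namespace
  )
  go_dag(terms, edges, alt_ids = alt_ids)
}

#' Ancestor closure of a term
#'
#' Returns the term itself together with every ancestor reachable through
#' `is_a` / `part_of` edges. Under the true-path rule this is the implicit
#' annotation set of a gene annotated to `term`, and it is the term set over
#' which the Wang semantic value is accumulated.
#'
#' @param dag A [go_dag()].
#' @param term A term id present in `dag`.
#' @return Character vector of term ids (unordered), always containing `term`.
#' @export
term_ancestors <- function(dag, term) {
  if (!term %in% dag$terms$id) abort_data("unknown term '%s'", term)
  all_closures(dag)[[term]]
}

# Closures for every term, memoised on the dag environment keyed by identity.
all_closures <- function(dag) {
  cache <- attr(dag, "closure_cache", exact = TRUE)
  if (!is.null(cache)) return(cache)
  parents <- dag$parents
  memo <- new.env(parent = emptyenv())
  closure <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- parents[[id]]
    res <- if (length(ps)) unique(c(id, unlist(lapply(ps, closure)))) else id
    memo[[id]] <- res
    res
  }
  out <- lapply(dag$terms$id, closure)
  names(out) <- dag$terms$id
  out
}

# Attach the closure cache; returns the dag (call once before heavy use).
cache_closures <- function(dag) {
  attr(dag, "closure_cache") <- all_closures(dag)
  dag
}

#' Write a go_dag back to OBO text
#'
#' Emits the minimal OBO subset [read_obo()] consumes, so synthetic
#' ontologies round-trip through the file interface.
#'
#' @param dag A [go_dag()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  ns_long <- names(obo_namespace_map)[match(dag$namespace, obo_namespace_map)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[[i]]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", dag$terms$name[[i]]),
             paste0("namespace: ", ns_long))
    ps <- dag$parents[[id]]
    rl <- dag$relations[[id]]
    for (j in seq_along(ps)) {
      out <- c(out, if (rl[[j]] == "is_a") paste0("is_a: ", ps[[j]])
                    else paste0("relationship: part_of ", ps[[j]]))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
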