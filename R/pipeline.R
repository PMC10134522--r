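#' Assemble and validate a pipeline run configuration
#'
#' Merges package defaults, an optional YAML config file and direct
#' arguments (strongest last), then validates every enumerated field
#' before any computation. The merged config is echoed verbatim into the
#' run directory by [run_pipeline()].
#'
#' @param yaml Optional path to a YAML config file.
#' @param ... Individual fields overriding the file: `obo`, `annotations`,
#'   `genes`, `out_dir`, `namespace`, `measure`, `aggregator`,
#'   `evidence_exclude`, `embed_method`, `n_components`, `cluster_method`,
#'   `k`, `k_min`, `k_max`, `refine`, `stability_threshold`, `seed`,
#'   `perplexity`, `n_neighbors`, `min_dist`, `use_propagated`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(yaml = NULL, ...) {
  defaults <- list(
    obo = NULL, annotations = NULL, genes = NULL, out_dir = NULL,
    namespace = "BP", measure = "rel", aggregator = "max",
    evidence_exclude = NULL,
    embed_method = "pca", n_components = 6L,
    cluster_method = "kmeans", k = NULL, k_min = 2L, k_max = 25L,
    refine = TRUE, stability_threshold = 0.25, seed = 1L,
    perplexity = 30, n_neighbors = 15, min_dist = 0.1,
    use_propagated = FALSE
  )
  from_file <- if (!is.null(yaml)) {
    if (!file.exists(yaml)) abort_config("config file not found: %s", yaml)
    yaml::read_yaml(yaml)
  } else {
    list()
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, TRUE)]
  cfg <- modifyList(modifyList(defaults, from_file), overrides)

  match_enum(cfg$namespace, c("BP", "MF", "CC"), "namespace")
  cfg$measure <- match_enum(tolower(cfg$measure), SIM_MEASURES, "measure")
  cfg$aggregator <- match_enum(tolower(cfg$aggregator), AGGREGATORS,
                               "aggregator")
  match_enum(cfg$embed_method, c("pca", "pcoa", "tsne", "umap"),
             "embed_method")
  match_enum(cfg$cluster_method, CLUSTER_METHODS, "cluster_method")
  for (field in c("obo", "annotations", "genes", "out_dir")) {
    if (is.null(cfg[[field]])) abort_config("config field '%s' is required",
                                            field)
  }
  for (field in c("obo", "annotations", "genes")) {
    if (!file.exists(cfg[[field]])) {
      abort_config("input file for '%s' not found: %s", field, cfg[[field]])
    }
  }
  if (!is.null(cfg$k) && cfg$k < 2L) abort_config("k must be >= 2")
  if (cfg$k_min < 2L || cfg$k_max < cfg$k_min) {
    abort_config("invalid k range %s..%s", cfg$k_min, cfg$k_max)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full similarity - embedding - clustering pipeline
#'
#' Executes the three stages on the configured inputs and writes every
#' intermediate and final artifact into the run directory: the similarity
#' matrix (TSV + JSON sidecar), exclusion list, embedding, cluster
#' assignments with silhouettes and outlier flags, per-cluster statistics,
#' the silhouette-versus-k curve, static plots and a metadata record with
#' input checksums. A stage failure leaves partial outputs plus a `FAILED`
#' marker naming the stage.
#'
#' @param config A [run_config()].
#' @param resume Reuse `similarity.tsv` / `embedding.tsv` already present
#'   in the run directory instead of recomputing them.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  cfg_plain <- unclass(config)
  yaml::write_yaml(cfg_plain[!vapply(cfg_plain, is.null, TRUE)],
                   out("config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)),
                 out("FAILED"))
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = class(e)[[1L]], parent = e)
    })
  }

  # stage 1: similarity
  sim_path <- out("similarity.tsv")
  sim <- if (resume && file.exists(sim_path)) {
    inform("run_pipeline: resuming from existing similarity.tsv")
    read_gene_sim(sim_path)
  } else {
    stage("similarity", {
      dag <- read_obo(config$obo, config$namespace)
      ann <- read_annotations(config$annotations, dag,
                              evidence_exclude = config$evidence_exclude)
      genes <- readr::read_tsv(config$genes, show_col_types = FALSE)
      names(genes)[[1L]] <- "gene"
      s <- gene_similarity(genes, dag, ann, measure = config$measure,
                           aggregator = config$aggregator,
                           use_propagated = config$use_propagated)
      write_gene_sim(s, sim_path)
      readr::write_tsv(s$excluded, out("excluded_genes.tsv"))
      s
    })
  }

  # stage 2: embedding
  emb_path <- out("embedding.tsv")
  emb <- if (resume && file.exists(emb_path)) {
    inform("run_pipeline: resuming from existing embedding.tsv")
    read_embedding(emb_path)
  } else {
    stage("embedding", {
      n <- nrow(sim$matrix)
      ncomp <- min(config$n_components, n - 1L)
      e <- embed_genes(if (config$embed_method == "pca") sim else
                         sim_to_dist(sim),
                       method = config$embed_method, n_components = ncomp,
                       seed = config$seed, perplexity = config$perplexity,
                       n_neighbors = config$n_neighbors,
                       min_dist = config$min_dist)
      write_embedding(e, emb_path)
      e
    })
  }

  # stage 3: clustering + validation
  stage("clustering", {
    d <- sim_to_dist(sim)      # validation on the functional distances
    n <- nrow(d$matrix)
    k_range <- seq(config$k_min, min(config$k_max, n - 1L))
    if (!is.null(config$k)) {
      sol <- cluster_genes(emb, method = config$cluster_method, k = config$k,
                           seed = config$seed)
      sil <- silhouette_report(d, sol)
      curve <- tibble(k = config$k, silhouette = sil$overall)
      assignment <- mutate(sil$genes, outlier = .data$silhouette < 0)
    } else if (config$refine) {
      ref <- refine_outliers(emb, method = config$cluster_method,
                             k_range = k_range, seed = config$seed,
                             validate_on = d)
      sol <- ref$round2$solution
      sil <- ref$round2$silhouette
      curve <- ref$round2$curve
      readr::write_tsv(ref$round1$curve, out("silhouette_curve_round1.tsv"))
      assignment <- tidy(ref) |>
        filter(.data$round == 2L | .data$outlier) |>
        select(-"round")
      d <- subset_dist(sim_to_dist(sim), sil$genes$gene)
    } else {
      opt <- optimal_k(emb, method = config$cluster_method,
                       k_range = k_range, seed = config$seed,
                       validate_on = d)
      sol <- opt$solutions[[paste0("k", opt$k)]]
      sil <- silhouette_report(d, sol)
      curve <- opt$curve
      assignment <- mutate(sil$genes, outlier = .data$silhouette < 0)
    }

    readr::write_tsv(assignment, out("clusters.tsv"))
    readr::write_tsv(curve, out("silhouette_curve.tsv"))
    stats_tab <- cluster_stats(d, sol,
                               stability_threshold = config$stability_threshold)
    readr::write_tsv(stats_tab, out("cluster_stats.tsv"))

    save_plot_quietly(plot_silhouette(sil), out("silhouette.pdf"))
    save_plot_quietly(autoplot(emb, labels = sol$labels[rownames(d$matrix)]),
                      out("embedding.pdf"))

    meta <- list(
      package = as.character(utils::packageVersion("gostrat")),
      seed = config$seed,
      parameters = cfg_plain[!vapply(cfg_plain, is.null, TRUE)],
      inputs = lapply(c(obo = config$obo, annotations = config$annotations,
                        genes = config$genes),
                      function(p) unname(tools::md5sum(p))),
      n_genes = nrow(sim$matrix),
      n_excluded = nrow(sim$excluded),
      k = sol$k,
      overall_silhouette = sil$overall
    )
    jsonlite::write_json(meta, out("metadata.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })

  invisible(config$out_dir)
}

save_plot_quietly <- function(p, path) {
  tryCatch({
    grDevices::pdf(path, width = 7, height = 5)
    print(p)
    grDevices::dev.off()
  }, error = function(e) {
    inform(sprintf("plot export skipped (%s): %s", basename(path),
                   conditionMessage(e)))
  })
  invisible(path)
}
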