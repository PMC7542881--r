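# End-to-end pipeline orchestration: load -> merge -> filter -> harmonize ->
# distances -> optimal-k -> cluster -> highlight -> ORA -> plots -> exports,
# driven by a config that round-trips through YAML. Each stage logs counts to
# stderr and any failure is reported with the stage's name.

#' Build a pipeline configuration
#'
#' @param inputs list of input specs, each a list with `path`, `dialect`
#'   (`"gmt"`, `"ipa"`, `"great"`, `"generic"`), `experiment`, and optional
#'   `species` / `categories`.
#' @param mapping optional list with `path`, `namespace` and optional
#'   `unmapped_policy` (`"keep"`/`"drop"`) enabling harmonization.
#' @param metric `"rr"`, `"jaccard"` or `"kappa"`.
#' @param cap optional similarity cap for the heatmap colour scale.
#' @param cluster list with `method` (`"kmeans"`/`"hierarchical"`) and either
#'   a fixed `k` or `optimal = list(method=, k_min=, k_max=, gap_B=)`.
#' @param seed integer seed driving every stochastic step.
#' @param highlight optional path to a one-gene-per-line subset file.
#' @param annotations optional path to an annotation GMT for per-cluster ORA.
#' @param network_threshold edge threshold for the similarity network.
#' @param min_size,max_size optional gene-set size filter.
#' @param out_dir output directory.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(inputs, out_dir, mapping = NULL, metric = "rr",
                            cap = NULL, cluster = list(method = "kmeans", k = 3),
                            seed = 1L, highlight = NULL, annotations = NULL,
                            network_threshold = 0, min_size = NULL,
                            max_size = NULL) {
  structure(list(
    inputs = inputs, out_dir = out_dir, mapping = mapping,
    metric = tolower(metric), cap = cap, cluster = cluster,
    seed = as.integer(seed), highlight = highlight,
    annotations = annotations, network_threshold = network_threshold,
    min_size = min_size, max_size = max_size
  ), class = "PipelineConfig")
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_pipeline_config
#' @param config a `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                   path)
  invisible(path)
}

stage_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

load_one_input <- function(spec) {
  dialect <- tolower(spec$dialect)
  species <- if (is.null(spec$species)) "" else spec$species
  res <- switch(dialect,
    gmt = read_gmt(spec$path, spec$experiment, species = species),
    ipa = read_ipa(spec$path, spec$experiment, species = species),
    great = read_great(spec$path, spec$experiment,
                       categories = spec$categories, species = species),
    generic = read_generic(spec$path, spec$experiment, species = species),
    stop("unknown dialect: ", spec$dialect))
  stage_msg("load", spec$path, ": ", res$report$sets_created, " sets (",
            res$report$rows_skipped, " rows skipped)")
  res$collection
}

#' Run the full pipeline
#'
#' Executes every configured stage in order and writes all artifacts plus a
#' `manifest.tsv` describing them. Re-running with the same config and seed
#' reproduces the tabular artifacts byte for byte.
#'
#' @param config a `PipelineConfig` or path to a YAML config.
#' @return invisibly, a list with `collection`, `similarity`, `clustering`,
#'   `curve` (if optimal-k was requested), `ora` (if annotations given), and
#'   `manifest` (data.frame of artifact paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  colls <- run_stage("load", lapply(config$inputs, load_one_input))

  coll <- run_stage("merge", {
    if (length(colls) > 1) merge_collections(colls) else colls[[1]]
  })
  stage_msg("merge", n_sets(coll), " sets, universe ",
            length(gene_universe(coll)))

  if (!is.null(config$min_size) || !is.null(config$max_size)) {
    coll <- run_stage("manage", manage_gene_sets(
      coll,
      min_size = if (is.null(config$min_size)) 1L else config$min_size,
      max_size = if (is.null(config$max_size)) Inf else config$max_size))
    stage_msg("manage", n_sets(coll), " sets after size filter")
  }

  if (!is.null(config$mapping)) {
    coll <- run_stage("harmonize", {
      tab <- read_mapping_table(config$mapping$path)
      policy <- if (is.null(config$mapping$unmapped_policy)) "keep" else
        config$mapping$unmapped_policy
      harmonize(coll, tab, config$mapping$namespace, policy)$collection
    })
    stage_msg("harmonize", "universe now ", length(gene_universe(coll)))
  }

  sim <- run_stage("distances", build_similarity_matrix(
    coll, metric = toupper(config$metric)))
  stage_msg("distances", sim$metric, " matrix, ", sim$infinite_replaced,
            " infinities replaced")

  curve <- NULL
  k <- config$cluster$k
  if (!is.null(config$cluster$optimal)) {
    curve <- run_stage("optimal-k", {
      o <- config$cluster$optimal
      optimal_k(sim, method = o$method, k_range = o$k_min:o$k_max,
                seed = config$seed,
                gap_B = if (is.null(o$gap_B)) 50L else o$gap_B)
    })
    k <- curve$recommended_k
    stage_msg("optimal-k", curve$method, " recommends k = ", k)
  }
  if (is.null(k)) stop("pipeline stage 'cluster' failed: no k configured")

  clustering <- run_stage("cluster", cluster_gene_sets(
    sim, k = k, method = config$cluster$method, seed = config$seed))
  stage_msg("cluster", clustering$method, " k = ", k)

  if (!is.null(config$highlight)) {
    clustering <- run_stage("highlight", {
      subset <- readLines(config$highlight, warn = FALSE)
      highlight_score(coll, clustering, subset)
    })
    stage_msg("highlight", "scores in [",
              round(min(clustering$highlight_scores), 3), ", ",
              round(max(clustering$highlight_scores), 3), "]")
  }

  ora <- NULL
  if (!is.null(config$annotations)) {
    ora <- run_stage("ora", {
      ann <- read_gmt(config$annotations, experiment = "annotation")$collection
      ora_per_cluster(coll, clustering, ann)
    })
    stage_msg("ora", nrow(ora), " cluster-term tests")
  }

  out <- config$out_dir
  artifact <- function(kind, path) data.frame(kind = kind, path = path,
                                              stringsAsFactors = FALSE)
  manifest <- list()

  paths <- run_stage("export", write_outputs(coll, sim, clustering, out))
  for (i in seq_along(paths)) {
    manifest[[length(manifest) + 1]] <- artifact(names(paths)[i], paths[[i]])
  }

  net <- run_stage("network", build_network(sim, clustering,
                                            config$network_threshold))
  edge_path <- file.path(out, "network_edges.tsv")
  run_stage("network", write_edge_list(net, edge_path,
                                       file.path(out, "network.graphml")))
  manifest[[length(manifest) + 1]] <- artifact("edges", edge_path)
  manifest[[length(manifest) + 1]] <- artifact("graphml",
                                               file.path(out, "network.graphml"))

  run_stage("plot", {
    render_heatmap(sim, clustering, cap = config$cap,
                   out_path = file.path(out, "heatmap.png"))
    render_dendrogram(sim, out_path = file.path(out, "dendrogram.png"),
                      newick_path = file.path(out, "dendrogram.nwk"))
  })
  manifest[[length(manifest) + 1]] <- artifact("heatmap", file.path(out, "heatmap.png"))
  manifest[[length(manifest) + 1]] <- artifact("dendrogram", file.path(out, "dendrogram.png"))
  manifest[[length(manifest) + 1]] <- artifact("newick", file.path(out, "dendrogram.nwk"))

  if (!is.null(ora)) {
    ora_path <- file.path(out, "ora_per_cluster.tsv")
    write_tsv(ora, ora_path)
    manifest[[length(manifest) + 1]] <- artifact("ora", ora_path)
  }
  if (!is.null(curve)) {
    curve_path <- file.path(out, "k_selection.tsv")
    write_tsv(data.frame(k = curve$k_values, criterion = curve$criterion_values),
              curve_path)
    manifest[[length(manifest) + 1]] <- artifact("k_selection", curve_path)
  }

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  stage_msg("done", nrow(manifest), " artifacts in ", out)

  invisible(list(collection = coll, similarity = sim, clustering = clustering,
                 curve = curve, ora = ora, manifest = manifest))
}
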