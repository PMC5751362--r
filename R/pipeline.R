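#' Pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end procedure.
#' Defaults reproduce the study constants: association screen p < 0.01, HWE
#' p >= 5e-7, missingness <= 5\%, MAF >= 5\%, 5 kb mapping flank, hub degree
#' > 17.  `mcode_scope` selects whether molecular-complex detection runs on
#' the hub-induced subgraph (`"hubs"`, the default) or the full risk-gene
#' network (`"network"`).
#'
#' @param ped,map,bed,edges paths to the genotype PED/MAP, gene BED and edge
#'   list files.
#' @param gmt optional path to a GMT annotation file (enrichment is skipped
#'   when `NULL`).
#' @param thresholds a [qc_thresholds()] object.
#' @param flank_bp SNP-to-gene flanking window in bp.
#' @param min_score minimum interaction confidence score.
#' @param hub_degree exclusive hub degree threshold.
#' @param mcode an [mcode_params()] object.
#' @param mcode_scope `"hubs"` or `"network"`.
#' @param alpha,top_k enrichment raw-p cutoff and table length.
#' @param seed integer seed echoed into the run report.
#' @param out_dir output directory for the stage tables; `NULL` disables
#'   writing.
#' @return list with class `pipeline_config`.
#' @export
pipeline_config <- function(ped, map, bed, edges, gmt = NULL,
                            thresholds = qc_thresholds(), flank_bp = 5000,
                            min_score = 0, hub_degree = 17,
                            mcode = mcode_params(),
                            mcode_scope = c("hubs", "network"),
                            alpha = 0.01, top_k = 10, seed = 1L,
                            out_dir = NULL) {
  mcode_scope <- match.arg(mcode_scope)
  structure(list(ped = ped, map = map, bed = bed, edges = edges, gmt = gmt,
                 thresholds = thresholds, flank_bp = flank_bp,
                 min_score = min_score, hub_degree = hub_degree,
                 mcode = mcode, mcode_scope = mcode_scope,
                 alpha = alpha, top_k = top_k, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror [pipeline_config()] arguments; QC threshold keys
#' (`hwe_p_min`, `miss_max`, `maf_min`, `quality_min`, `assoc_p_max`) and
#' MCODE keys (`node_score_cutoff`, `k_core`, `haircut`, ...) may be given
#' at the top level.  Referenced input files are checked for existence
#' before any computation (fail fast).
#'
#' @param path path to a YAML configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  for (key in c("ped", "map", "bed", "edges")) {
    if (is.null(y[[key]])) stop("config is missing required key: ", key)
  }
  thr_keys <- c("hwe_p_min", "miss_max", "maf_min", "quality_min",
                "assoc_p_max")
  thr <- do.call(qc_thresholds, y[intersect(thr_keys, names(y))])
  mc_keys <- c("degree_cutoff", "node_score_cutoff", "k_core", "haircut",
               "fluff", "fluff_density_cutoff", "max_depth")
  mc <- do.call(mcode_params, y[intersect(mc_keys, names(y))])
  cfg <- pipeline_config(
    ped = y$ped, map = y$map, bed = y$bed, edges = y$edges, gmt = y$gmt,
    thresholds = thr, flank_bp = y$flank_bp %||% 5000,
    min_score = y$min_score %||% 0, hub_degree = y$hub_degree %||% 17,
    mcode = mc, mcode_scope = y$mcode_scope %||% "hubs",
    alpha = y$alpha %||% 0.01, top_k = y$top_k %||% 10,
    seed = y$seed %||% 1L, out_dir = y$out_dir
  )
  paths <- c(cfg$ped, cfg$map, cfg$bed, cfg$edges, cfg$gmt)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("config references missing file(s): ", paste(missing, collapse = ", "))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full core-hub discovery pipeline
#'
#' Executes, in order: per-SNP QC and allelic association, risk-SNP
#' screening, SNP-to-gene mapping, risk-gene interaction subgraph
#' construction, topology metrics, hub selection, MCODE-style module
#' detection with core-hub designation, and (when a GMT file is configured)
#' gene-set enrichment of the risk genes.  All intermediate tables are
#' written to `config$out_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: list with stage `counts` (snps_in, snps_qc,
#'   snps_risk, genes, network_nodes, network_edges, hubs, clusters,
#'   core_hubs), the echoed `thresholds` and `seed`, and the stage outputs
#'   (`assoc`, `risk_snps`, `mappings`, `risk_genes`, `graph`,
#'   `network_summary`, `hubs`, `clusters`, `enrichment`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- read_ped_map(config$ped, config$map)
  annotation <- read_gene_bed(config$bed)
  edge_table <- read_edge_list(config$edges, min_score = config$min_score)
  collection <- if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL

  assoc <- snp_association(dataset, config$thresholds)
  risk <- screen_risk_snps(assoc, config$thresholds$assoc_p_max)
  mappings <- map_snps(risk, annotation, config$flank_bp)
  gene_set <- collapse_genes(mappings)
  graph <- build_graph(edge_table, gene_set$gene_ids)
  net_sum <- network_summary(graph)
  metrics <- data.frame(
    gene_id = graph$nodes,
    degree = unname(graph_degree(graph)),
    clustering_coefficient = unname(clustering_coefficient(graph)),
    betweenness = unname(betweenness_centrality(graph)),
    topological_coefficient = unname(topological_coefficient(graph)),
    stringsAsFactors = FALSE
  )
  hubs <- select_hubs(graph, config$hub_degree)
  mcode_graph <- if (config$mcode_scope == "hubs") {
    .induced(graph, hubs$gene_id)
  } else {
    graph
  }
  clusters <- find_complexes(mcode_graph, config$mcode)
  core_hubs <- vapply(clusters, function(x)
    if (is.na(x$core_hub)) NA_character_ else x$core_hub, "")
  enrichment <- NULL
  if (!is.null(collection)) {
    enrichment <- enrich(gene_set$gene_ids, collection,
                         alpha = config$alpha, top_k = config$top_k)
  }
  counts <- list(
    snps_in = nrow(dataset$snps),
    snps_qc = sum(assoc$qc_pass),
    snps_risk = nrow(risk),
    genes = length(gene_set$gene_ids),
    network_nodes = net_sum$n_nodes,
    network_edges = net_sum$n_edges,
    hubs = nrow(hubs),
    clusters = length(clusters),
    core_hubs = sum(!is.na(core_hubs))
  )
  report <- structure(list(
    counts = counts,
    thresholds = config$thresholds,
    flank_bp = config$flank_bp, min_score = config$min_score,
    hub_degree = config$hub_degree, mcode_scope = config$mcode_scope,
    seed = config$seed,
    assoc = assoc, risk_snps = risk, mappings = mappings,
    risk_genes = gene_set, graph = graph, network_summary = net_sum,
    node_metrics = metrics, hubs = hubs, clusters = clusters,
    core_hubs = core_hubs[!is.na(core_hubs)],
    enrichment = enrichment
  ), class = "run_report")
  if (!is.null(config$out_dir)) {
    write_tables(list(
      assoc = assoc, snp_gene = mappings, genes = gene_set$gene_ids,
      node_metrics = metrics, hubs = hubs, clusters = clusters,
      enrichment = enrichment,
      summary = c(counts, list(
        hwe_p_min = config$thresholds$hwe_p_min,
        miss_max = config$thresholds$miss_max,
        maf_min = config$thresholds$maf_min,
        assoc_p_max = config$thresholds$assoc_p_max,
        flank_bp = config$flank_bp, min_score = config$min_score,
        hub_degree = config$hub_degree, mcode_scope = config$mcode_scope,
        mean_degree = net_sum$mean_degree,
        network_clustering_coefficient =
          net_sum$network_clustering_coefficient,
        characteristic_path_length = net_sum$characteristic_path_length,
        seed = config$seed))
    ), config$out_dir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Core-hub discovery run\n")
  cat(sprintf("  SNPs: %d in, %d after QC, %d risk (p < %g)\n",
              x$counts$snps_in, x$counts$snps_qc, x$counts$snps_risk,
              x$thresholds$assoc_p_max))
  cat(sprintf("  Risk genes: %d; network: %d nodes / %d edges\n",
              x$counts$genes, x$counts$network_nodes,
              x$counts$network_edges))
  cat(sprintf("  Hubs (degree > %g): %d; clusters: %d; core hubs: %d\n",
              x$hub_degree, x$counts$hubs, x$counts$clusters,
              x$counts$core_hubs))
  if (length(x$core_hubs)) {
    cat("  Core hub genes:", paste(x$core_hubs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.run_report <- function(object, ...) {
  print(object)
  ns <- object$network_summary
  cat(sprintf("  Mean degree %.3f, clustering coefficient %.3f, path length %.3f\n",
              ns$mean_degree, ns$network_clustering_coefficient,
              ns$characteristic_path_length))
  if (length(object$clusters)) {
    cat("  Clusters (score, nodes, edges, core hub):\n")
    for (i in seq_along(object$clusters)) {
      cl <- object$clusters[[i]]
      cat(sprintf("    %d: %.3f, %d, %d, %s\n", i, cl$score, cl$n_nodes,
                  cl$n_edges,
                  if (is.na(cl$core_hub)) "(none: tie)" else cl$core_hub))
    }
  }
  invisible(object)
}
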