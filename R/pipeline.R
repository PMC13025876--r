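# End-to-end pipeline: target lists -> PPI network -> centrality screen
# -> MCODE -> MCC -> consensus hubs, with optional ORA and DEG/GSEA arms.
# Every stage writes TSV/JSON artefacts and a single summary JSON.

#' Build a validated pipeline configuration
#'
#' Collects all file paths and tunable parameters of the pipeline in one
#' declarative object. Every parameter that the underlying workflow
#' leaves unstated is surfaced here with its documented default rather
#' than hard-coded.
#'
#' @param compound_lists Character vector of compound-target list files.
#' @param disease_lists Character vector of disease gene list files.
#' @param edges STRING-dialect edge list file.
#' @param min_score Confidence cutoff, 0-1000 scale (default 900).
#' @param rounds Median-screening rounds (default 2).
#' @param mcode_node_score_cutoff,mcode_degree_cutoff,mcode_haircut,mcode_fluff
#'   MCODE parameters (defaults 0.2, 2, TRUE, FALSE).
#' @param mcc_k MCC top-k size (default 10).
#' @param consensus_module Which MCODE-derived list enters the consensus:
#'   `"top_cluster"` (default) or `"all_seeds"`.
#' @param ora_gmt Optional GMT file for over-representation of the
#'   overlap targets.
#' @param ora_universe `"collection"` (default) or `"network"`.
#' @param expression,groups Optional expression matrix and two-column
#'   annotation files enabling the DEG/GSEA arm.
#' @param deg_alpha DEG significance threshold — required when
#'   `expression` is supplied; see [deg_alpha_presets].
#' @param deg_lfc Absolute log2FC threshold (default 1).
#' @param gsea_gmt Optional GMT for GSEA (defaults to `ora_gmt`).
#' @param gsea_weight,gsea_nperm GSEA parameters (defaults 1, 1000).
#' @param seed Master seed for all stochastic steps.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(compound_lists, disease_lists, edges,
                            min_score = 900L, rounds = 2L,
                            mcode_node_score_cutoff = 0.2,
                            mcode_degree_cutoff = 2L,
                            mcode_haircut = TRUE, mcode_fluff = FALSE,
                            mcc_k = 10L,
                            consensus_module = c("top_cluster",
                                                 "all_seeds"),
                            ora_gmt = NULL,
                            ora_universe = c("collection", "network"),
                            expression = NULL, groups = NULL,
                            deg_alpha = NULL, deg_lfc = 1,
                            gsea_gmt = NULL, gsea_weight = 1,
                            gsea_nperm = 1000L, seed = 1L) {
  consensus_module <- match.arg(consensus_module)
  ora_universe <- match.arg(ora_universe)
  stopifnot(min_score >= 0, min_score <= 1000, rounds >= 1,
            mcc_k >= 1, gsea_nperm >= 10)
  if (!is.null(expression) && is.null(deg_alpha))
    stop("deg_alpha is required when an expression matrix is supplied; ",
         "choose one of deg_alpha_presets or an explicit value")
  structure(list(
    compound_lists = compound_lists, disease_lists = disease_lists,
    edges = edges, min_score = min_score, rounds = rounds,
    mcode_node_score_cutoff = mcode_node_score_cutoff,
    mcode_degree_cutoff = mcode_degree_cutoff,
    mcode_haircut = mcode_haircut, mcode_fluff = mcode_fluff,
    mcc_k = mcc_k, consensus_module = consensus_module,
    ora_gmt = ora_gmt, ora_universe = ora_universe,
    expression = expression, groups = groups,
    deg_alpha = deg_alpha, deg_lfc = deg_lfc,
    gsea_gmt = gsea_gmt %||% ora_gmt, gsea_weight = gsea_weight,
    gsea_nperm = gsea_nperm, seed = seed), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes target assembly, network construction, median centrality
#' screening, MCODE clustering, MCC ranking and the hub consensus, plus
#' the ORA and DEG/GSEA arms when their inputs are configured. Per-stage
#' tables are written as TSV and the machine-readable summary as
#' `summary.json` under `out_dir`; output is byte-identical across runs
#' with the same configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage objects and the `summary`
#'   list mirrored in `summary.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- target lists ---------------------------------------------------
  targets <- stage("target_sets", {
    compound <- gs_union(lapply(config$compound_lists, read_gene_list),
                         label = "compound targets")
    disease <- gs_union(lapply(config$disease_lists, read_gene_list),
                        label = "disease targets")
    if (length(compound) == 0L) stop("compound target list is empty")
    if (length(disease) == 0L) stop("disease gene list is empty")
    overlap <- gs_intersect(compound, disease, label = "overlap targets")
    if (length(overlap) == 0L)
      stop("compound and disease lists do not overlap")
    list(compound = compound, disease = disease, overlap = overlap)
  })
  write_gene_set(targets$overlap, file.path(out_dir, "overlap_targets.tsv"))
  jsonlite::write_json(
    as.list(attr(targets$overlap, "venn")),
    file.path(out_dir, "venn_counts.json"), auto_unbox = TRUE)

  # -- network --------------------------------------------------------
  network <- stage("ppi_network", {
    net <- read_string_edges(config$edges, min_score = config$min_score)
    mapped <- induced_subgraph(net, targets$overlap)
    connected <- drop_isolated(mapped)
    list(full = net, mapped = mapped, connected = connected)
  })
  write_string_edges(network$connected,
                     file.path(out_dir, "network_edges.tsv"))

  # -- centrality screening ------------------------------------------
  trace <- stage("centrality_screen",
                 median_screen(network$connected, rounds = config$rounds))
  for (r in seq_along(trace$tables))
    write_tsv(trace$tables[[r]],
              file.path(out_dir, sprintf("centrality_round%d.tsv", r)))
  write_screening_trace(trace, file.path(out_dir, "screening_trace.json"))

  # -- MCODE ----------------------------------------------------------
  clusters <- stage("mcode_clusters", mcode_find_complexes(
    network$connected,
    node_score_cutoff = config$mcode_node_score_cutoff,
    degree_cutoff = config$mcode_degree_cutoff,
    haircut = config$mcode_haircut, fluff = config$mcode_fluff))
  write_tsv(mcode_summary(clusters), file.path(out_dir, "mcode_clusters.tsv"))
  module_set <- stage("mcode_clusters", {
    if (!length(clusters)) gene_set(character(), label = "module")
    else if (config$consensus_module == "top_cluster")
      clusters[[1L]]$members
    else gene_set(vapply(clusters, `[[`, character(1), "seed"),
                  label = "cluster seeds")
  })

  # -- MCC ------------------------------------------------------------
  mcc <- stage("mcc_ranking", {
    tab <- mcc_scores(network$connected)
    list(table = tab, top = mcc_top(tab, k = config$mcc_k))
  })
  write_tsv(mcc$table[, c("node", "MCC", "MCC_exact", "clique_count")],
            file.path(out_dir, "mcc_scores.tsv"))

  # -- consensus ------------------------------------------------------
  consensus <- stage("hub_consensus", consensus_hubs(
    trace$final, module_set, mcc$top,
    centrality = trace$tables[[length(trace$tables)]]))
  write_gene_set(consensus$hubs, file.path(out_dir, "consensus_hubs.tsv"))

  # -- optional ORA ---------------------------------------------------
  ora_res <- NULL
  if (!is.null(config$ora_gmt)) {
    ora_res <- stage("enrichment_ora", {
      coll <- read_gmt(config$ora_gmt)
      uni <- if (config$ora_universe == "network")
        gene_set(network$connected$nodes) else NULL
      ora(targets$overlap, coll, universe = uni)
    })
    write_tsv(ora_res, file.path(out_dir, "ora_overlap.tsv"))
  }

  # -- optional DEG / GSEA --------------------------------------------
  deg_res <- NULL
  gsea_res <- NULL
  if (!is.null(config$expression)) {
    deg_res <- stage("deg_screen", {
      mat <- read_expression(config$expression)
      grp <- read_groups(config$groups)
      differential_expression(mat, grp, alpha = config$deg_alpha,
                              lfc = config$deg_lfc)
    })
    write_tsv(deg_res, file.path(out_dir, "deg_table.tsv"))
    if (!is.null(config$gsea_gmt)) {
      gsea_res <- stage("gsea", {
        ranked <- rank_genes(deg_res)
        gsea_preranked(ranked, read_gmt(config$gsea_gmt),
                       n_perm = config$gsea_nperm, seed = config$seed,
                       weight = config$gsea_weight)
      })
      write_tsv(gsea_res, file.path(out_dir, "gsea_results.tsv"))
    }
  }

  # -- summary --------------------------------------------------------
  summary <- list(
    seed = config$seed,
    counts = list(
      compound_targets = length(targets$compound),
      disease_targets = length(targets$disease),
      overlap_targets = length(targets$overlap),
      network_nodes_mapped = length(network$mapped$nodes),
      network_nodes_connected = length(network$connected$nodes),
      network_edges = n_edges(network$connected),
      screening = vapply(trace$rounds, function(r)
        length(r$survivors), integer(1)),
      mcode_clusters = length(clusters),
      module_list = length(module_set),
      mcc_top = length(mcc$top),
      consensus_hubs = length(consensus$hubs)),
    hubs = consensus$hubs$symbols,
    top_ora = if (!is.null(ora_res))
      utils::head(ora_res[, c("term", "k", "K", "p", "q")], 10L) else NULL,
    deg = if (!is.null(deg_res))
      list(up = sum(deg_res$flag == "up"),
           down = sum(deg_res$flag == "down")) else NULL,
    top_gsea = if (!is.null(gsea_res))
      utils::head(gsea_res[, c("term", "size", "ES", "NES", "p", "q")],
                  10L) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(list(targets = targets, network = network, trace = trace,
                 clusters = clusters, module_set = module_set, mcc = mcc,
                 consensus = consensus, ora = ora_res, deg = deg_res,
                 gsea = gsea_res, summary = summary))
}
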