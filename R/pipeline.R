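#' @title End-to-end pipeline orchestration
#'
#' @description
#' Runs the stages in their published order — compound drug-likeness
#' gate, target-prediction filter, disease-gene selection, the two Venn
#' intersections, network assembly, PPI confidence filter, hub
#' selection, MCODE clustering, over-representation analysis and the
#' compound-target-pathway network — from one flat configuration list,
#' writing diff-able TSV/SIF/GraphML/JSON stage outputs and a run
#' report containing every funnel count.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' All thresholds at their published values: >= 2 of 5 drug-likeness
#' rules, bioavailability score >= 0.30, prediction probability >= 0.1,
#' disease relevance score >= 10, top-decile (10%) expression
#' selection, PPI confidence > 0.7, top 20 hubs, MCODE node score
#' cutoff 0.2 / k-core 2 / degree cutoff 2, FDR gate 0.01.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    min_rules_passed = 2,
    min_bas = 0.30,
    p_min = 0.1,
    score_min = 10,
    de_fraction = 0.10,
    ppi_threshold = 0.7,
    top_k = 20,
    node_score_cutoff = 0.2,
    k_core = 2,
    degree_cutoff = 2,
    haircut = TRUE,
    fluff = FALSE,
    fdr_gate = 0.01,
    enrich_method = "hypergeometric"
  )
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented range before any stage
#' runs; unknown keys are rejected.
#'
#' @param config named list (missing keys fall back to
#'   [default_config()]).
#' @return the completed configuration, invisibly usable.
#' @export
validate_config <- function(config = list()) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config <- utils::modifyList(base, config)
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(config$min_rules_passed >= 0 && config$min_rules_passed <= 5,
      "min_rules_passed must lie in [0, 5]")
  chk(config$min_bas >= 0 && config$min_bas <= 1,
      "min_bas must lie in [0, 1]")
  chk(config$p_min >= 0 && config$p_min <= 1,
      "p_min must lie in [0, 1]")
  chk(config$score_min >= 0, "score_min must be non-negative")
  chk(config$de_fraction > 0 && config$de_fraction <= 0.5,
      "de_fraction must lie in (0, 0.5]")
  chk(config$ppi_threshold >= 0 && config$ppi_threshold <= 1,
      "ppi_threshold must lie in [0, 1]")
  chk(config$top_k >= 1, "top_k must be >= 1")
  chk(config$node_score_cutoff >= 0 && config$node_score_cutoff < 1,
      "node_score_cutoff must lie in [0, 1)")
  chk(config$k_core >= 0, "k_core must be >= 0")
  chk(config$degree_cutoff >= 0, "degree_cutoff must be >= 0")
  chk(config$fdr_gate > 0 && config$fdr_gate <= 1,
      "fdr_gate must lie in (0, 1]")
  chk(config$enrich_method %in% c("hypergeometric", "ease"),
      "enrich_method must be 'hypergeometric' or 'ease'")
  config
}

#' Run the full network-pharmacology pipeline
#'
#' @param data list with the six inputs: `descriptors`, `predictions`,
#'   `disease`, `expression` (list with `expr` and `labels`),
#'   `ppi_edges`, `annotations` (as produced by [gen_all()] or read
#'   from files with the io helpers).
#' @param config configuration list; see [default_config()].
#' @param outdir when non-NULL, all stage outputs and the JSON report
#'   are written there (two runs on identical inputs and config produce
#'   byte-identical files).
#' @return the run report: a named list of funnel counts, network
#'   shapes, hub list, cluster table, enrichment summary and the
#'   applied configuration.
#' @export
run_pipeline <- function(data, config = list(), outdir = NULL) {
  config <- validate_config(config)
  need <- c("descriptors", "predictions", "disease", "expression",
            "ppi_edges", "annotations")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    stop("missing pipeline input(s): ", paste(missing, collapse = ", "))
  }

  # 1. compound drug-likeness gate
  verdicts <- select_candidates(data$descriptors,
                                min_rules_passed = config$min_rules_passed,
                                min_bas = config$min_bas)
  selected <- verdicts$compound_id[verdicts$selected]

  # 2. target-prediction filter and targetless-compound drop
  fp <- filter_predictions(data$predictions, p_min = config$p_min)
  retained <- drop_targetless_compounds(selected, fp$per_compound)
  mapping <- fp$per_compound[retained]
  target_union <- sort(unique(unlist(mapping, use.names = FALSE)))

  # 3. compound-target network over the full screened compound layer
  bipartite <- build_bipartite(mapping, compounds = selected)

  # 4. disease genes and first Venn intersection
  disease_genes <- filter_disease_genes(data$disease,
                                        score_min = config$score_min)
  candidates <- intersect_gene_sets(target_union, disease_genes)

  # 5. expression validation and second Venn intersection
  de <- select_top_decile_de(data$expression$expr, data$expression$labels,
                             fraction = config$de_fraction)
  de_union <- sort(union(de$over, de$under))
  validated <- intersect_gene_sets(candidates, de_union)

  # 6. PPI filter, hubs, clusters
  ppi <- filter_ppi(data$ppi_edges, threshold = config$ppi_threshold)
  hubs <- top_k_by_degree(ppi, k = config$top_k)
  hub_means <- if (length(hubs) > 0) mean_metrics(ppi, hubs) else
    c(mean_degree = NA_real_, mean_betweenness = NA_real_,
      mean_closeness = NA_real_)
  clusters <- mcode(ppi,
                    node_score_cutoff = config$node_score_cutoff,
                    k_core = config$k_core,
                    degree_cutoff = config$degree_cutoff,
                    haircut = config$haircut, fluff = config$fluff)
  cl_table <- cluster_table(clusters)

  # 7. over-representation of the validated targets
  enrichment <- enrich(validated, data$annotations,
                       method = config$enrich_method,
                       fdr_gate = config$fdr_gate)

  # 8. compound-target-pathway network restricted to hubs and
  #    significant pathway terms
  hub_mapping <- lapply(mapping, intersect, hubs)
  hub_mapping <- hub_mapping[lengths(hub_mapping) > 0L]
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  pw_membership <- lapply(
    stats::setNames(sig$term_id, sig$term_id),
    function(id) {
      m <- data$annotations$members[[match(id, data$annotations$term_id)]]
      intersect(m, hubs)
    }
  )
  pw_membership <- pw_membership[lengths(pw_membership) > 0L]
  tripartite <- if (length(hub_mapping) > 0L) {
    build_tripartite(hub_mapping, pw_membership)
  } else NULL

  report <- list(
    config = config,
    funnel = list(
      compounds_total = nrow(data$descriptors),
      compounds_druglike = length(selected),
      compounds_with_targets = length(retained),
      predicted_targets = length(target_union),
      disease_genes = length(disease_genes),
      candidate_targets = length(candidates),
      tcga_de_genes = length(de_union),
      validated_targets = length(validated)
    ),
    bipartite = list(nodes = igraph::vcount(bipartite),
                     edges = igraph::ecount(bipartite)),
    ppi = list(nodes = igraph::vcount(ppi), edges = igraph::ecount(ppi)),
    hubs = hubs,
    hub_mean_metrics = as.list(signif(hub_means, 4)),
    clusters = cl_table,
    enrichment = list(
      terms_tested = nrow(enrichment),
      significant = sum(enrichment$significant),
      top_term = if (nrow(enrichment) > 0) enrichment$term_id[1] else NA_character_
    ),
    tripartite = if (is.null(tripartite)) NULL else list(
      nodes = igraph::vcount(tripartite),
      edges = igraph::ecount(tripartite),
      classes = as.list(table(igraph::V(tripartite)$class))
    )
  )

  if (!is.null(outdir)) {
    ok <- FALSE
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    on.exit(if (!ok) unlink(outdir, recursive = TRUE), add = TRUE)
    write_tsv(verdicts, file.path(outdir, "verdicts.tsv"))
    write_gene_list(selected, file.path(outdir, "compounds_selected.txt"))
    write_gene_list(retained, file.path(outdir, "compounds_with_targets.txt"))
    write_gene_list(target_union, file.path(outdir, "targets_predicted.txt"))
    write_gene_list(disease_genes, file.path(outdir, "disease_genes.txt"))
    write_gene_list(candidates, file.path(outdir, "targets_candidate.txt"))
    write_gene_list(validated, file.path(outdir, "targets_validated.txt"))
    write_sif(bipartite, file.path(outdir, "bipartite.sif"))
    write_graphml(bipartite, file.path(outdir, "bipartite.graphml"))
    write_sif(ppi, file.path(outdir, "ppi.sif"))
    write_graphml(ppi, file.path(outdir, "ppi.graphml"))
    write_tsv(node_metrics(ppi), file.path(outdir, "ppi_metrics.tsv"))
    write_tsv(cl_table, file.path(outdir, "clusters.tsv"))
    write_tsv(enrichment, file.path(outdir, "enrichment.tsv"))
    write_tsv(bubble_table(enrichment), file.path(outdir, "bubble.tsv"))
    if (!is.null(tripartite)) {
      write_sif(tripartite, file.path(outdir, "tripartite.sif"))
      write_graphml(tripartite, file.path(outdir, "tripartite.graphml"))
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ok <- TRUE
  }
  report
}
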