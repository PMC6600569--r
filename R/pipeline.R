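#' Configure an end-to-end pipeline run
#'
#' Either `counts` (a path or count table, with optional `annotation`) or
#' `simulation` (a [simulation_config()], with optional simulated
#' annotation settings) must be supplied.
#'
#' @param out_dir Output directory (created if needed).
#' @param counts Count table path or tibble (`gene_id`, `length`, samples).
#' @param annotation Annotation path or tibble (`gene_id`, `term`).
#' @param simulation A [simulation_config()] for synthetic input.
#' @param sim_annotation List with `n_terms`, `background_rate`,
#'   `enriched_rate` to also simulate an annotation map (simulation runs
#'   only).
#' @param library_sizes Mapped reads per sample for file input.
#' @param thresholds DEG [threshold_set()] (default `(2, 0.05, 2)`).
#' @param gcn_thresholds Threshold set selecting network genes (default the
#'   looser `(0, 0.05, 1.5)` preset).
#' @param hrr_cutoff Maximum HRR score for a network edge (default 30).
#' @param mcl [mcl_params()] for module detection.
#' @param enrichment_background `"universe"` (annotation universe) or
#'   `"network"` (network genes) — an explicit choice, no silent default
#'   beyond the documented one.
#' @param min_mapped,alpha Enrichment settings (see
#'   [hypergeom_enrichment()]).
#' @param flat_threshold,pseudocount Trend / ratio settings (see
#'   [classify_profile()], [log2_ratio()]).
#' @param n_permutations Trend-significance permutations.
#' @param seed Master seed; all stage seeds derive from it.
#' @param verbose Log stage progress with [message()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            counts = NULL,
                            annotation = NULL,
                            simulation = NULL,
                            sim_annotation = NULL,
                            library_sizes = NULL,
                            thresholds = threshold_set(),
                            gcn_thresholds = threshold_set(preset = "gcn"),
                            hrr_cutoff = 30,
                            mcl = mcl_params(),
                            enrichment_background = c("universe", "network"),
                            min_mapped = 2,
                            alpha = 0.05,
                            flat_threshold = 1,
                            pseudocount = 1,
                            n_permutations = 1000,
                            seed = 1L) {
  if (is.null(counts) && is.null(simulation)) {
    abort("pipeline needs either `counts` or a `simulation` config.")
  }
  if (!is.null(simulation) && !inherits(simulation, "simulation_config")) {
    abort("`simulation` must come from simulation_config().")
  }
  if (is.character(counts) && !file.exists(counts)) {
    abort(sprintf("counts file not found: %s", counts))
  }
  if (is.character(annotation) && !file.exists(annotation)) {
    abort(sprintf("annotation file not found: %s", annotation))
  }
  structure(
    list(out_dir = out_dir, counts = counts, annotation = annotation,
         simulation = simulation, sim_annotation = sim_annotation,
         library_sizes = library_sizes, thresholds = thresholds,
         gcn_thresholds = gcn_thresholds, hrr_cutoff = hrr_cutoff,
         mcl = mcl,
         enrichment_background = match.arg(enrichment_background),
         min_mapped = min_mapped, alpha = alpha,
         flat_threshold = flat_threshold, pseudocount = pseudocount,
         n_permutations = n_permutations, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Run the full analysis chain from one configuration
#'
#' Stage order: input (simulate or read) -> RPKM -> DEG calling -> Venn ->
#' trend profiles -> HRR network -> topology statistics -> MCL modules ->
#' module composition -> enrichment (when an annotation is available).
#' Every stage's output is written under `out_dir` as TSV/JSON, and
#' `manifest.json` records package version, all effective parameters, the
#' seed, and per-stage row counts. Reruns with an identical config and seed
#' reproduce byte-identical outputs. A failing stage aborts with the stage
#' named; earlier outputs are left in place.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(
    package = "coexpipe",
    version = as.character(packageVersion("coexpipe")),
    seed = config$seed,
    parameters = list(
      thresholds = unclass(config$thresholds),
      gcn_thresholds = unclass(config$gcn_thresholds),
      hrr_cutoff = config$hrr_cutoff,
      mcl = unclass(config$mcl),
      enrichment_background = config$enrichment_background,
      min_mapped = config$min_mapped, alpha = config$alpha,
      flat_threshold = config$flat_threshold,
      pseudocount = config$pseudocount,
      n_permutations = config$n_permutations),
    stages = list())
  res <- list()

  say("stage input")
  res$truth <- NULL
  counts <- stage("input", {
    if (!is.null(config$simulation)) {
      sim <- simulate_counts(config$simulation)
      res$truth <- sim$truth
      write_json_out(list(
        module_membership = sim$truth$module_membership,
        de_calls = sim$truth$de_calls), out("truth.json"))
      sim$counts
    } else if (is.character(config$counts)) {
      read_count_matrix(config$counts, config$library_sizes)
    } else {
      config$counts
    }
  })
  write_count_matrix(counts, out("counts.tsv"))
  manifest$stages$counts <- list(file = "counts.tsv", rows = nrow(counts))

  annotation <- stage("annotation", {
    if (!is.null(config$sim_annotation) && !is.null(res$truth)) {
      sa <- config$sim_annotation
      ann <- simulate_annotation(res$truth, n_terms = sa$n_terms,
                                 background_rate = sa$background_rate,
                                 enriched_rate = sa$enriched_rate,
                                 seed = child_seed(config$seed, 2))
      res$truth$enriched_terms <- ann$enriched_terms
      ann
    } else if (is.character(config$annotation)) {
      read_annotation(config$annotation)
    } else {
      config$annotation
    }
  })
  if (!is.null(annotation)) {
    write_annotation(annotation, out("annotation.tsv"))
    n_ann <- if (inherits(annotation, "sim_annotation"))
      nrow(annotation$annotation) else nrow(annotation)
    manifest$stages$annotation <- list(file = "annotation.tsv", rows = n_ann)
  }

  say("stage rpkm")
  expr <- stage("rpkm", compute_rpkm(counts, config$library_sizes))
  readr::write_tsv(expr, out("rpkm.tsv"))
  manifest$stages$rpkm <- list(file = "rpkm.tsv", rows = nrow(expr))

  say("stage diffexp")
  degs <- stage("diffexp", call_degs(counts, config$thresholds,
                                     config$library_sizes,
                                     pseudocount = config$pseudocount))
  readr::write_tsv(degs, out("deg_table.tsv"))
  sets <- deg_sets(degs)
  deg_union <- unique(unlist(sets))
  manifest$stages$diffexp <- list(file = "deg_table.tsv", rows = nrow(degs),
                                  n_deg_union = length(deg_union))

  if (length(sets) == 3L) {
    say("stage venn")
    venn <- stage("venn", venn_partition(sets))
    write_json_out(list(regions = venn,
                        totals = as.list(attr(venn, "totals")),
                        union_size = attr(venn, "union_size")),
                   out("venn.json"))
    manifest$stages$venn <- list(file = "venn.json",
                                 union_size = attr(venn, "union_size"))
    res$venn <- venn
  }

  say("stage trends")
  trends <- NULL
  if (length(deg_union) > 0 && ncol(wide_to_matrix(expr)) == 3L) {
    deg_expr <- expr[expr$gene_id %in% deg_union, ]
    trends <- stage("trends", classify_profile(
      deg_expr, flat_threshold = config$flat_threshold,
      pseudocount = config$pseudocount))
    readr::write_tsv(trends, out("trends.tsv"))
    tsig <- stage("trends", profile_significance(
      deg_expr, flat_threshold = config$flat_threshold,
      pseudocount = config$pseudocount,
      n_permutations = config$n_permutations,
      seed = child_seed(config$seed, 3)))
    write_json_out(tsig, out("trend_summary.json"))
    manifest$stages$trends <- list(file = "trends.tsv", rows = nrow(trends))
  }

  say("stage network")
  gcn_degs <- stage("network", call_degs(counts, config$gcn_thresholds,
                                         config$library_sizes,
                                         pseudocount = config$pseudocount))
  gcn_genes <- unique(gcn_degs$gene_id[gcn_degs$passes_filters])
  net <- NULL
  partition <- NULL
  if (length(gcn_genes) >= 3) {
    net <- stage("network", suppressWarnings(
      hrr_network(expr, genes = gcn_genes, cutoff = config$hrr_cutoff)))
    write_edge_list(net, out("edges.tsv"))
    write_sif(net, out("network.sif"))
    nstats <- stage("network", network_stats(net))
    write_json_out(nstats, out("network_stats.json"))
    manifest$stages$network <- list(
      file = "edges.tsv", nodes = nrow(net$nodes), edges = nrow(net$edges))

    say("stage mcl")
    partition <- stage("mcl", mcl_cluster(net, config$mcl))
    readr::write_tsv(partition, out("modules.tsv"))
    n_modules <- length(unique(partition$cluster[partition$is_module]))
    module_sizes <- sort(unique(partition$cluster_size[partition$is_module]))
    write_json_out(list(
      n_clusters = length(unique(partition$cluster)),
      n_modules = n_modules,
      module_size_range = if (length(module_sizes))
        c(min(module_sizes), max(module_sizes)) else NULL,
      genes_in_modules = sum(partition$is_module),
      converged = attr(partition, "converged")), out("module_summary.json"))
    manifest$stages$mcl <- list(file = "modules.tsv",
                                rows = nrow(partition),
                                n_modules = n_modules)
    comp <- stage("mcl", module_composition(partition, degs))
    readr::write_tsv(comp, out("module_composition.tsv"))
    res$composition <- comp
  }

  if (!is.null(annotation) && !is.null(partition)) {
    say("stage enrich")
    bg <- if (config$enrichment_background == "network")
      net$nodes$gene_id else NULL
    enr <- stage("enrich", hypergeom_enrichment(
      partition, annotation, background = bg,
      min_mapped = config$min_mapped, alpha = config$alpha))
    readr::write_tsv(enr, out("enrichment.tsv"))
    manifest$stages$enrich <- list(
      file = "enrichment.tsv", rows = nrow(enr),
      n_significant = sum(enr$significant))
    res$enrichment <- enr
  }

  write_json_out(manifest, out("manifest.json"))
  say("pipeline complete: %s", config$out_dir)
  res$counts <- counts
  res$expr <- expr
  res$degs <- degs
  res$trends <- trends
  res$network <- net
  res$partition <- partition
  res$annotation <- annotation
  res$manifest <- manifest
  invisible(res)
}
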