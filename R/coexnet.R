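#' Pearson correlation matrix of gene expression profiles
#'
#' Computes the gene-by-gene Pearson correlation of expression profiles,
#' by default on `log2(value + 1)` (variance stabilisation for RPKM).
#' Genes with zero variance have undefined correlation; their off-diagonal
#' entries are set to 0, the diagonal stays 1, and the affected genes are
#' recorded in `attr(, "zero_variance")` with a warning. A warning is also
#' issued when fewer than 4 samples are available, where Pearson r is
#' near-degenerate (most |r| mass near 1).
#'
#' @param expr Wide expression table (`gene_id` + sample columns).
#' @param genes Optional character vector restricting to a gene subset.
#' @param log_transform Apply `log2(x + 1)` first (default `TRUE`).
#' @return Symmetric correlation matrix with unit diagonal, gene ids as
#'   dimnames.
#' @export
pearson_matrix <- function(expr, genes = NULL, log_transform = TRUE) {
  m <- wide_to_matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      abort(sprintf("genes not in `expr`: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 2) abort("need at least two samples for correlation.")
  if (ncol(m) < 4) {
    warn(sprintf(
      "Pearson correlation on %d samples is near-degenerate (|r| mass near 1).",
      ncol(m)))
  }
  if (log_transform) m <- log2(m + 1)
  v <- apply(m, 1, sd)
  cc <- suppressWarnings(cor(t(m)))
  zv <- rownames(m)[v == 0]
  if (length(zv)) {
    warn(sprintf("%d gene(s) with zero variance; correlations set to 0: %s",
                 length(zv), paste(head(zv, 5), collapse = ", ")))
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  attr(cc, "zero_variance") <- zv
  cc
}

#' Highest-reciprocal-rank matrix from a correlation matrix
#'
#' For each gene, the other genes are ranked by descending correlation
#' (best neighbour = rank 1; negative correlations rank last), ties broken
#' deterministically by ascending gene order. The HRR of a pair is the worse
#' of the two mutual ranks: `HRR(A, B) = max(rank_A(B), rank_B(A))` —
#' symmetric by construction, low values meaning robust reciprocal
#' co-expression.
#'
#' @param corr Square symmetric correlation matrix (>= 3 genes).
#' @return Symmetric integer matrix of HRR scores (`NA` on the diagonal).
#' @export
hrr_matrix <- function(corr) {
  n <- nrow(corr)
  if (is.null(n) || n != ncol(corr)) abort("`corr` must be square.")
  if (n < 3) abort("HRR needs at least 3 genes (ranks degenerate below that).")
  if (max(abs(corr - t(corr))) > 1e-8) abort("`corr` must be symmetric.")
  ranks <- matrix(NA_integer_, n, n, dimnames = dimnames(corr))
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    o <- cand[order(-corr[i, cand], cand)]
    ranks[i, o] <- seq_len(n - 1L)
  }
  hrr <- pmax(ranks, t(ranks))
  storage.mode(hrr) <- "integer"
  hrr
}

#' Build an HRR co-expression network
#'
#' Keeps an edge for every gene pair whose HRR score is at most `cutoff`
#' (inclusive) and weights it `1 / HRR`; genes with no surviving edge remain
#' as isolated nodes.
#'
#' @param hrr Symmetric integer HRR matrix from [hrr_matrix()].
#' @param corr Optional matching correlation matrix; stored as the edge
#'   attribute `r`.
#' @param cutoff Maximum HRR score for an edge (default 30).
#' @return A list of class `coexpression_network`: `nodes` (tibble
#'   `gene_id`), `edges` (tibble `from`, `to`, `r`, `hrr`, `weight`),
#'   `cutoff`.
#' @export
build_network <- function(hrr, corr = NULL, cutoff = 30) {
  if (cutoff < 1) abort("`cutoff` must be at least 1.")
  genes <- rownames(hrr) %||% sprintf("g%d", seq_len(nrow(hrr)))
  keep <- which(upper.tri(hrr) & !is.na(hrr) & hrr <= cutoff, arr.ind = TRUE)
  hrr_kept <- as.integer(hrr[keep])
  edges <- tibble(
    from = genes[keep[, 1]],
    to = genes[keep[, 2]],
    r = if (is.null(corr)) NA_real_ else corr[keep],
    hrr = hrr_kept,
    weight = 1 / as.numeric(hrr_kept))
  structure(list(nodes = tibble(gene_id = genes),
                 edges = edges,
                 cutoff = cutoff),
            class = "coexpression_network")
}

#' One-call HRR network from an expression table
#'
#' Convenience chain [pearson_matrix()] -> [hrr_matrix()] ->
#' [build_network()].
#'
#' @inheritParams pearson_matrix
#' @inheritParams build_network
#' @return A `coexpression_network`.
#' @export
hrr_network <- function(expr, genes = NULL, cutoff = 30, log_transform = TRUE) {
  cc <- pearson_matrix(expr, genes = genes, log_transform = log_transform)
  build_network(hrr_matrix(cc), corr = cc, cutoff = cutoff)
}

# igraph view of a coexpression_network (or bare edge table + nodes).
as_igraph <- function(net) {
  if (inherits(net, "coexpression_network")) {
    igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                  vertices = net$nodes$gene_id)
  } else if (inherits(net, "igraph")) {
    net
  } else {
    abort("cannot convert to igraph.")
  }
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("HRR co-expression network: %d nodes, %d edges (HRR <= %s)\n",
              nrow(x$nodes), nrow(x$edges), format(x$cutoff)))
  invisible(x)
}

#' NetworkAnalyzer-style topology statistics
#'
#' Simple-graph summary statistics as reported by graph-viewer network
#' analysers: mean local clustering coefficient over nodes of degree >= 2,
#' average neighbour count (mean degree), density
#' (`mean degree / (n - 1)`), degree heterogeneity (coefficient of
#' variation of degree), degree centralization
#' (`n/(n-2) * (max_degree/(n-1) - density)`), connected components,
#' isolated nodes, diameter and radius (max/min node eccentricity within
#' connected components, over non-isolated nodes), number and percentage of
#' ordered connected node pairs ("shortest paths"), and characteristic path
#' length (mean distance over those pairs).
#'
#' @param net A `coexpression_network` (or igraph graph).
#' @return One-row tibble of class `network_stats`.
#' @export
network_stats <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) abort("empty graph.")
  deg <- igraph::degree(g)
  avg_neighbors <- mean(deg)
  density <- if (n > 1) avg_neighbors / (n - 1) else NA_real_
  local_cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc_nodes <- deg >= 2
  clustering <- if (any(cc_nodes)) mean(local_cc[cc_nodes]) else NA_real_
  comps <- igraph::components(g)
  isolated <- sum(deg == 0)
  # unweighted hop distances over all nodes; Inf marks disconnected pairs
  d <- igraph::distances(g, weights = NA)
  diag(d) <- Inf
  finite <- is.finite(d)
  n_paths <- sum(finite)
  non_iso <- deg > 0
  ecc <- if (any(non_iso)) {
    apply(d[non_iso, , drop = FALSE], 1, function(r) max(r[is.finite(r)]))
  } else numeric(0)
  mdeg <- mean(deg)
  het <- if (mdeg > 0) sqrt(mean(deg^2) - mdeg^2) / mdeg else NA_real_
  centralization <- if (n > 2) (n / (n - 2)) * (max(deg) / (n - 1) - density)
                    else NA_real_
  out <- tibble(
    n_nodes = n,
    clustering_coefficient = clustering,
    avg_neighbors = avg_neighbors,
    connected_components = comps$no,
    diameter = if (length(ecc)) max(ecc) else NA_real_,
    radius = if (length(ecc)) min(ecc) else NA_real_,
    density = density,
    heterogeneity = het,
    centralization = centralization,
    isolated_nodes = isolated,
    shortest_paths = n_paths,
    shortest_paths_percent = if (n > 1) 100 * n_paths / (n * (n - 1))
                             else NA_real_,
    characteristic_path_length = if (n_paths > 0) mean(d[finite]) else NA_real_,
    self_loops = 0L,
    multi_edge_pairs = 0L)
  class(out) <- c("network_stats", class(out))
  out
}
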