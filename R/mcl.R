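#' Markov cluster algorithm parameters
#'
#' @param inflation Elementwise power applied after each expansion; > 1,
#'   larger values give finer clusters (default 1.6).
#' @param expansion Matrix power of the expansion step (integer >= 2).
#' @param prune_threshold Entries below this are dropped after each
#'   inflation, keeping the flow matrix sparse.
#' @param convergence_tol Iteration stops when the largest elementwise
#'   change falls below this.
#' @param max_iterations Hard iteration cap; non-convergence is flagged,
#'   never silent.
#' @param min_module_size Clusters at or above this size are flagged as
#'   modules (default 15).
#' @return A list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 1.6, expansion = 2L,
                       prune_threshold = 1e-5, convergence_tol = 1e-6,
                       max_iterations = 100L, min_module_size = 15L) {
  if (inflation <= 1) abort("`inflation` must be > 1.")
  check_scalar(expansion, "expansion", integerish = TRUE)
  if (expansion < 2) abort("`expansion` must be >= 2.")
  check_scalar(prune_threshold, "prune_threshold")
  check_scalar(convergence_tol, "convergence_tol")
  check_scalar(max_iterations, "max_iterations", integerish = TRUE)
  check_scalar(min_module_size, "min_module_size", integerish = TRUE)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 min_module_size = as.integer(min_module_size)),
            class = "mcl_params")
}

# Column-stochastic normalisation of a sparse non-negative matrix.
mcl_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

# Inflation: elementwise power, prune small entries, renormalise columns.
mcl_inflate <- function(M, inflation, prune_threshold) {
  M <- as(M, "CsparseMatrix")
  M@x <- M@x^inflation
  M@x[M@x < prune_threshold] <- 0
  M <- Matrix::drop0(M)
  mcl_normalize(M)
}

#' Markov clustering of a co-expression network
#'
#' From-scratch MCL: the weighted adjacency matrix (weight = 1/HRR for HRR
#' networks) gets a self-loop per node equal to its maximum incident edge
#' weight (damps odd-cycle periodicity; 1 for isolated nodes), is made
#' column-stochastic, and is then iterated with alternating expansion
#' (matrix power) and inflation (elementwise power, pruning, column
#' renormalisation) until the largest elementwise change drops below
#' `convergence_tol` or `max_iterations` is hit (flagged, never silent).
#' Clusters are read off the attractor structure of the limit matrix:
#' attractors (nodes with positive return flow) sharing flow form attractor
#' systems, and each node joins the cluster of the system(s) it flows to; a
#' node reached by several systems is assigned to the largest cluster, ties
#' to the smallest cluster index. The algorithm is fully deterministic.
#'
#' Cluster ids are renumbered 1, 2, ... by decreasing size (ties by first
#' member in node order).
#'
#' @param net A `coexpression_network` from [build_network()], or a data
#'   frame with columns `from`, `to`, `weight`.
#' @param params An [mcl_params()].
#' @return Tibble of class `module_partition`: `gene_id`, `cluster`,
#'   `cluster_size`, `is_module` (size >= `min_module_size`). Attributes:
#'   `converged`, `iterations`, `params`.
#' @export
mcl_cluster <- function(net, params = mcl_params()) {
  if (!inherits(params, "mcl_params")) abort("`params` must come from mcl_params().")
  if (is.data.frame(net)) {
    nodes <- unique(c(net$from, net$to))
    net <- list(nodes = tibble(gene_id = nodes), edges = net)
  }
  genes <- net$nodes$gene_id
  n <- length(genes)
  if (n == 0) abort("empty graph.")
  e <- net$edges
  if (nrow(e) > 0 && any(e$weight <= 0)) abort("edge weights must be positive.")
  i <- match(e$from, genes); j <- match(e$to, genes)
  if (any(i == j)) abort("self-loops are not allowed in the input graph.")
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(e$weight, 2), dims = c(n, n))
  # self-loop = max incident weight (1 for isolated nodes)
  max_inc <- apply_max_incident(A)
  A <- A + Matrix::Diagonal(n, x = max_inc)
  M <- mcl_normalize(A)

  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    M_new <- M
    for (k in seq_len(params$expansion - 1L)) M_new <- M_new %*% M
    M_new <- mcl_inflate(M_new, params$inflation, params$prune_threshold)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("MCL did not converge within %d iterations; returning the current clustering.",
                 params$max_iterations))
  }

  cluster <- mcl_read_clusters(M, params$prune_threshold)
  sizes <- table(cluster)
  # renumber by decreasing size, ties by first member in node order
  first_member <- vapply(names(sizes), function(cl) min(which(cluster == cl)),
                         numeric(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  cluster <- unname(relabel[as.character(cluster)])
  size_of <- as.integer(table(cluster)[as.character(cluster)])
  out <- tibble(gene_id = genes, cluster = as.integer(cluster),
                cluster_size = size_of,
                is_module = size_of >= params$min_module_size)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "params") <- params
  class(out) <- c("module_partition", class(out))
  out
}

# Max incident off-diagonal weight per node of a symmetric sparse matrix.
apply_max_incident <- function(A) {
  n <- nrow(A)
  out <- rep(1, n)
  At <- as(A, "TsparseMatrix")
  if (length(At@x)) {
    agg <- tapply(At@x, At@i, max)
    out[as.integer(names(agg)) + 1L] <- pmax(unname(agg), 0)
    out[out == 0] <- 1
  }
  out
}

# Read the partition off the limit matrix: attractor systems and their
# basins, with deterministic resolution of (rare) overlapping basins.
mcl_read_clusters <- function(M, eps) {
  n <- nrow(M)
  M <- as(M, "CsparseMatrix")
  d <- Matrix::diag(M)
  attractors <- which(d > eps)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  # attractor systems: components of the flow graph restricted to attractors
  sub <- as(M[attractors, attractors, drop = FALSE], "TsparseMatrix")
  ii <- sub@i + 1L; jj <- sub@j + 1L
  off <- ii != jj & sub@x > 0
  g <- igraph::graph_from_edgelist(cbind(ii[off], jj[off]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(attractors) - igraph::vcount(g)))
  sys_of <- igraph::components(g)$membership
  n_sys <- max(sys_of)
  # basin of a system: every node receiving flow from one of its attractors
  basins <- vector("list", n_sys)
  Mt <- as(M, "TsparseMatrix")
  row_sys <- rep(NA_integer_, n)
  row_sys[attractors] <- sys_of
  for (s in seq_len(n_sys)) basins[[s]] <- integer(0)
  keep <- !is.na(row_sys[Mt@i + 1L]) & Mt@x > 0
  for (idx in which(keep)) {
    s <- row_sys[Mt@i[idx] + 1L]
    basins[[s]] <- c(basins[[s]], Mt@j[idx] + 1L)
  }
  basins <- lapply(seq_len(n_sys), function(s)
    unique(c(basins[[s]], attractors[sys_of == s])))
  sizes <- lengths(basins)
  cluster <- rep(NA_integer_, n)
  # larger cluster wins a contested node; ties -> smallest cluster index
  ord <- order(-sizes, seq_len(n_sys))
  for (s in rev(ord)) cluster[basins[[s]]] <- s
  # safety: unassigned nodes (transient, only possible pre-convergence)
  # follow their strongest outgoing flow; failing that, become singletons
  un <- which(is.na(cluster))
  for (u in un) {
    col <- M[, u]
    tgt <- which(col == max(col))[1]
    cluster[u] <- if (!is.na(cluster[tgt])) cluster[tgt] else {
      max(cluster, 0L, na.rm = TRUE) + 1L
    }
  }
  cluster
}

#' Up/down expression composition of each cluster
#'
#' For every cluster of a partition, the fraction of its members called up
#' (resp. down) in a designated comparison of a DEG table. Clusters with no
#' member present in that comparison's calls get `NA` fractions (undefined,
#' not zero).
#'
#' @param partition A `module_partition` from [mcl_cluster()].
#' @param deg_table A `deg_table` from [call_degs()].
#' @param comparison Which comparison to use; defaults to the last one in
#'   the table (the widest time contrast in a time course).
#' @return Tibble `cluster`, `cluster_size`, `is_module`, `n_called`,
#'   `frac_up`, `frac_down`.
#' @export
module_composition <- function(partition, deg_table, comparison = NULL) {
  comps <- unique(deg_table$comparison)
  comparison <- comparison %||% comps[length(comps)]
  if (!comparison %in% comps) {
    abort(sprintf("comparison '%s' not present in `deg_table`.", comparison))
  }
  calls <- deg_table[deg_table$comparison == comparison, c("gene_id", "direction")]
  partition |>
    dplyr::left_join(calls, by = "gene_id") |>
    dplyr::group_by(.data$cluster, .data$cluster_size, .data$is_module) |>
    dplyr::summarise(
      n_called = sum(!is.na(.data$direction)),
      frac_up = ifelse(n_called > 0,
                       sum(.data$direction == "up", na.rm = TRUE) /
                         pmax(n_called, 1L), NA_real_),
      frac_down = ifelse(n_called > 0,
                         sum(.data$direction == "down", na.rm = TRUE) /
                           pmax(n_called, 1L), NA_real_),
      .groups = "drop") |>
    dplyr::arrange(.data$cluster)
}
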