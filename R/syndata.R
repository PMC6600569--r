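#' Specify a simulation of a no-replicate RNA-seq time course
#'
#' Builds the configuration consumed by [simulate_counts()]. The defaults
#' emulate a three-point (0 h / 2 h / 4 h) hormone-treatment design with one
#' sequencing library per time point and negative-binomial count noise.
#'
#' @param n_genes Number of genes to simulate.
#' @param library_sizes Integer vector of expected mapped reads per sample,
#'   one per time point.
#' @param n_timepoints Number of time points (defaults to
#'   `length(library_sizes)`).
#' @param gene_length_range Length-2 vector: gene lengths (bp) are drawn
#'   uniformly on this range.
#' @param nb_dispersion Negative-binomial `size` parameter as used by
#'   [stats::rnbinom()]: counts have variance `mu + mu^2 / nb_dispersion`, so
#'   larger values mean less overdispersion. The default 1000 (extra CV of
#'   about 3 percent on top of Poisson) models the technical noise of a
#'   single sequencing library per time point, the no-replicate design this
#'   generator emulates; biological signal enters through the latent module
#'   and DE offsets, not through count dispersion. Use smaller values (e.g.
#'   10-50) to emulate biological-replicate-scale variance instead.
#' @param baseline_log2_mean,baseline_log2_sd Mean and standard deviation of
#'   the per-gene baseline log2 abundance (a log-normal abundance model on the
#'   log2 scale).
#' @param modules List of [module_spec()] objects: planted co-expression
#'   modules. Module genes occupy the first gene indices, in list order.
#' @param de_genes List of [de_spec()] objects: planted differentially
#'   expressed genes. May not collide with module gene indices.
#' @param n_replicates Columns per time point (1 = the no-replicate design).
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return A list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 100, library_sizes = c(1e5, 1e5, 1e5),
#'                          modules = list(module_spec(20, c(0, 2, 2))),
#'                          seed = 1)
simulation_config <- function(n_genes,
                              library_sizes,
                              n_timepoints = length(library_sizes),
                              gene_length_range = c(200L, 3000L),
                              nb_dispersion = 1000,
                              baseline_log2_mean = 5,
                              baseline_log2_sd = 2,
                              modules = list(),
                              de_genes = list(),
                              n_replicates = 1L,
                              seed = 1L) {
  check_scalar(n_genes, "n_genes", integerish = TRUE)
  check_scalar(n_timepoints, "n_timepoints", integerish = TRUE)
  if (n_timepoints < 2) abort("`n_timepoints` must be at least 2.")
  if (length(library_sizes) != n_timepoints) {
    abort("`library_sizes` must have one entry per time point.")
  }
  if (any(library_sizes <= 0)) abort("`library_sizes` must be positive.")
  if (length(gene_length_range) != 2L || any(gene_length_range < 1)) {
    abort("`gene_length_range` must be two lengths >= 1 bp.")
  }
  check_scalar(nb_dispersion, "nb_dispersion")
  check_scalar(n_replicates, "n_replicates", integerish = TRUE)
  for (m in modules) {
    if (!inherits(m, "module_spec")) abort("`modules` must be module_spec objects.")
    if (length(m$profile) != n_timepoints) {
      abort("module profile length must equal `n_timepoints`.")
    }
  }
  module_sizes <- vapply(modules, `[[`, numeric(1), "size")
  if (sum(module_sizes) > n_genes) abort("module sizes exceed `n_genes`.")
  module_genes <- sum(module_sizes)
  de_idx <- vapply(de_genes, `[[`, numeric(1), "gene_index")
  for (d in de_genes) {
    if (!inherits(d, "de_spec")) abort("`de_genes` must be de_spec objects.")
    if (d$gene_index > n_genes) abort("DE `gene_index` out of range.")
    if (any(d$comparison > n_timepoints)) abort("DE comparison index out of range.")
  }
  if (any(de_idx <= module_genes)) {
    abort(sprintf(
      "DE gene indices %s collide with planted module genes (indices 1..%d).",
      paste(de_idx[de_idx <= module_genes], collapse = ", "), module_genes))
  }
  if (anyDuplicated(de_idx)) abort("duplicated DE gene indices.")
  structure(
    list(n_genes = as.integer(n_genes),
         n_timepoints = as.integer(n_timepoints),
         library_sizes = as.numeric(library_sizes),
         gene_length_range = as.integer(round(gene_length_range)),
         nb_dispersion = nb_dispersion,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         modules = modules,
         de_genes = de_genes,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Planted co-expression module specification
#'
#' @param size Number of member genes.
#' @param profile Numeric vector of latent log2-expression offsets, one per
#'   time point; all members share it.
#' @param within_noise_sd Per-gene, per-time-point Gaussian noise (log2 units)
#'   around the shared profile.
#' @return A list of class `module_spec`.
#' @export
module_spec <- function(size, profile, within_noise_sd = 0.25) {
  check_scalar(size, "size", integerish = TRUE)
  if (!is.numeric(profile) || length(profile) < 2) {
    abort("`profile` must be a numeric vector over the time points.")
  }
  if (within_noise_sd < 0) abort("`within_noise_sd` must be non-negative.")
  structure(list(size = as.integer(size), profile = as.numeric(profile),
                 within_noise_sd = within_noise_sd),
            class = "module_spec")
}

#' Planted differentially expressed gene specification
#'
#' @param gene_index Index of the affected gene.
#' @param comparison Ordered pair of time-point indices `(earlier, later)`.
#' @param log2_fc Expected log2 fold change of the later over the earlier
#'   time point.
#' @return A list of class `de_spec`.
#' @export
de_spec <- function(gene_index, comparison = c(1L, 2L), log2_fc) {
  check_scalar(gene_index, "gene_index", integerish = TRUE)
  if (length(comparison) != 2L || comparison[1] == comparison[2]) {
    abort("`comparison` must be two distinct time-point indices.")
  }
  check_scalar(abs(log2_fc) + 1, "log2_fc", positive = TRUE)
  structure(list(gene_index = as.integer(gene_index),
                 comparison = as.integer(comparison),
                 log2_fc = as.numeric(log2_fc)),
            class = "de_spec")
}

# Sample labels: hours for the canonical 3-point design, generic otherwise.
timepoint_labels <- function(n) {
  if (n == 3L) c("0h", "2h", "4h") else paste0("t", seq_len(n) - 1L)
}

#' Simulate a read-count matrix with planted structure
#'
#' Draws negative-binomial counts from a log-linear latent model: each gene
#' has a baseline log2 abundance, module members add a shared time profile
#' (plus within-module noise), planted DE genes add their log2 fold change at
#' the later time point of their comparison. The expected count of gene *g*
#' in sample *s* is `library_size[s]` times the relative abundance implied by
#' its latent log2 expression (abundance weighted by gene length, so RPKM
#' reflects the latent expression).
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_result` with elements:
#'   * `counts`: tibble `gene_id`, `length`, one count column per sample,
#'     with the configured library sizes in `attr(, "library_sizes")`;
#'   * `truth`: ground truth (`gene_ids`, `module_membership`,
#'     `de_calls`, `sample_labels`).
#' @export
#' @examples
#' sim <- simulate_counts(simulation_config(50, c(1e5, 1e5, 1e5), seed = 7))
#' sim$counts
simulate_counts <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from simulation_config().")
  }
  withr::local_seed(config$seed)
  n <- config$n_genes
  nt <- config$n_timepoints
  gene_ids <- sprintf("gene_%05d", seq_len(n))
  lengths <- as.integer(round(runif(
    n, config$gene_length_range[1], config$gene_length_range[2])))

  base <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  latent <- matrix(base, nrow = n, ncol = nt)

  membership <- integer(0)
  member_gene <- character(0)
  at <- 0L
  for (mi in seq_along(config$modules)) {
    m <- config$modules[[mi]]
    idx <- at + seq_len(m$size)
    noise <- matrix(rnorm(m$size * nt, 0, m$within_noise_sd), nrow = m$size)
    latent[idx, ] <- latent[idx, ] +
      matrix(m$profile, nrow = m$size, ncol = nt, byrow = TRUE) + noise
    membership <- c(membership, rep.int(mi, m$size))
    member_gene <- c(member_gene, gene_ids[idx])
    at <- at + m$size
  }

  labels <- timepoint_labels(nt)
  de_rows <- lapply(config$de_genes, function(d) {
    i <- d$gene_index
    latent[i, d$comparison[2]] <<- latent[i, d$comparison[1]] + d$log2_fc
    tibble(gene_id = gene_ids[i],
           comparison = paste0(labels[d$comparison[2]], "_vs_",
                               labels[d$comparison[1]]),
           direction = if (d$log2_fc > 0) "up" else "down",
           log2_fc = d$log2_fc)
  })

  # Relative abundance: transcript concentration 2^latent, read mass
  # proportional to concentration x length.
  mass <- 2^latent * lengths
  prob <- sweep(mass, 2, colSums(mass), "/")
  nrep <- config$n_replicates
  counts <- matrix(0L, nrow = n, ncol = nt * nrep)
  col_labels <- character(nt * nrep)
  lib_sizes <- numeric(nt * nrep)
  k <- 0L
  for (t in seq_len(nt)) {
    for (r in seq_len(nrep)) {
      k <- k + 1L
      mu <- config$library_sizes[t] * prob[, t]
      counts[, k] <- rnbinom(n, mu = mu, size = config$nb_dispersion)
      col_labels[k] <- if (nrep == 1L) labels[t] else
        paste0(labels[t], "_r", r)
      lib_sizes[k] <- config$library_sizes[t]
    }
  }
  colnames(counts) <- col_labels

  counts_tbl <- dplyr::bind_cols(
    tibble(gene_id = gene_ids, length = lengths),
    as_tibble(counts))
  attr(counts_tbl, "library_sizes") <- setNames(lib_sizes, col_labels)

  truth <- list(
    gene_ids = gene_ids,
    sample_labels = labels,
    module_membership = tibble(gene_id = member_gene, module = membership),
    de_calls = if (length(de_rows)) dplyr::bind_rows(de_rows) else
      tibble(gene_id = character(), comparison = character(),
             direction = character(), log2_fc = numeric()),
    enriched_terms = NULL)

  structure(list(counts = counts_tbl, truth = truth), class = "sim_result")
}

#' Simulate a gene-to-term annotation map with planted enrichment
#'
#' Each planted module receives one dedicated term; module members carry that
#' term with probability `enriched_rate`, every other gene with probability
#' `background_rate`. The remaining terms annotate all genes at the
#' background rate.
#'
#' @param truth Ground truth from [simulate_counts()] (`$truth`).
#' @param n_terms Total number of annotation terms (must be at least the
#'   number of planted modules).
#' @param background_rate,enriched_rate Annotation probabilities with
#'   `0 <= background_rate < enriched_rate <= 1`.
#' @param seed Integer seed.
#' @return A list of class `sim_annotation`: `annotation` (tibble
#'   `gene_id`, `term`, one row per association) and `enriched_terms`
#'   (tibble `module`, `term`, the planted truth).
#' @export
simulate_annotation <- function(truth, n_terms, background_rate,
                                enriched_rate, seed = 1L) {
  if (is.null(truth$gene_ids)) abort("`truth` must carry `gene_ids`.")
  if (background_rate < 0 || enriched_rate > 1 ||
      background_rate >= enriched_rate) {
    abort("need 0 <= background_rate < enriched_rate <= 1.")
  }
  modules <- sort(unique(truth$module_membership$module))
  if (n_terms < length(modules)) {
    abort("`n_terms` must be at least the number of planted modules.")
  }
  withr::local_seed(seed)
  genes <- truth$gene_ids
  terms <- sprintf("TERM:%04d", seq_len(n_terms))
  planted <- tibble(module = modules,
                    term = terms[seq_along(modules)])
  rows <- vector("list", n_terms)
  for (ti in seq_len(n_terms)) {
    p <- rep(background_rate, length(genes))
    if (ti <= length(modules)) {
      members <- truth$module_membership$gene_id[
        truth$module_membership$module == modules[ti]]
      p[genes %in% members] <- enriched_rate
    }
    hit <- runif(length(genes)) < p
    rows[[ti]] <- tibble(gene_id = genes[hit], term = terms[ti])
  }
  structure(list(annotation = dplyr::bind_rows(rows),
                 enriched_terms = planted,
                 universe = genes),
            class = "sim_annotation")
}
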