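#' Hypergeometric term enrichment of network modules
#'
#' For each module and annotation term: with `N` background genes, `K` of
#' them carrying the term, a module of `n` background genes containing `k`
#' term carriers, the enrichment p-value is the upper hypergeometric tail
#' `P(X >= k)`. Terms with fewer than `min_mapped` mapped entries in the
#' module are excluded before testing; p-values are adjusted within each
#' module (Benjamini-Hochberg by default, plain Hochberg step-up via
#' `method = "hochberg"`); a term is significant iff `q < alpha`.
#'
#' The background defaults to the annotation universe (all genes the map
#' knows about); pass `background` explicitly to restrict it, e.g. to the
#' network genes.
#'
#' @param partition Data frame with `gene_id` and `cluster` (or `module`)
#'   columns, e.g. a `module_partition`; by default only clusters flagged
#'   `is_module` are tested when that column is present.
#' @param annotation Two-column data frame `gene_id`, `term` (one row per
#'   association), or a `sim_annotation` from [simulate_annotation()].
#' @param background Character vector of background genes. Defaults to the
#'   annotation universe (`$universe` for a `sim_annotation`, otherwise all
#'   annotated genes).
#' @param min_mapped Minimum mapped entries per (module, term) to test
#'   (default 2).
#' @param alpha Significance threshold on the adjusted q (default 0.05).
#' @param method Multiple-testing adjustment, `"BH"` or `"hochberg"`.
#' @param modules_only Test only clusters flagged `is_module` (default
#'   `TRUE`; ignored if the column is absent).
#' @return Tibble of class `enrichment_result`: `module`, `term`, `k`, `n`,
#'   `K`, `N`, `p`, `q`, `significant`.
#' @export
hypergeom_enrichment <- function(partition, annotation, background = NULL,
                                 min_mapped = 2, alpha = 0.05,
                                 method = c("BH", "hochberg"),
                                 modules_only = TRUE) {
  method <- match.arg(method)
  if (inherits(annotation, "sim_annotation")) {
    background <- background %||% annotation$universe
    annotation <- annotation$annotation
  }
  if (!all(c("gene_id", "term") %in% names(annotation))) {
    abort("`annotation` needs `gene_id` and `term` columns.")
  }
  if (nrow(annotation) == 0) abort("empty annotation map.")
  if ("module" %in% names(partition) && !"cluster" %in% names(partition)) {
    partition$cluster <- partition$module
  }
  if (!all(c("gene_id", "cluster") %in% names(partition))) {
    abort("`partition` needs `gene_id` and `cluster` columns.")
  }
  if (modules_only && "is_module" %in% names(partition)) {
    partition <- partition[partition$is_module, ]
  }
  if (nrow(partition) == 0) abort("no modules to test.")
  background <- unique(background %||% unique(annotation$gene_id))
  annotation <- annotation[annotation$gene_id %in% background, ]
  N <- length(background)
  K_by_term <- table(annotation$term[!duplicated(annotation[c("gene_id", "term")])])

  res <- lapply(split(partition$gene_id, partition$cluster), function(members) {
    members <- intersect(unique(members), background)
    n <- length(members)
    if (n == 0) return(NULL)
    ann_m <- annotation[annotation$gene_id %in% members, ]
    k_by_term <- table(unique(ann_m[c("gene_id", "term")])$term)
    k_by_term <- k_by_term[k_by_term >= min_mapped]
    if (length(k_by_term) == 0) return(NULL)
    terms <- names(k_by_term)
    k <- as.integer(k_by_term)
    K <- as.integer(K_by_term[terms])
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = terms, k = k, n = n, K = K, N = N, p = p,
           q = p.adjust(p, method = method))
  })
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) {
    out <- tibble(module = integer(), term = character(), k = integer(),
                  n = integer(), K = integer(), N = integer(),
                  p = numeric(), q = numeric(), significant = logical())
  } else {
    out <- dplyr::bind_rows(res[keep], .id = "module") |>
      dplyr::mutate(module = utils::type.convert(.data$module, as.is = TRUE),
                    significant = .data$q < alpha) |>
      dplyr::arrange(.data$module, .data$p)
  }
  class(out) <- c("enrichment_result", class(out))
  out
}
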