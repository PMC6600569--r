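#' Audic-Claverie exact test for two counts without replicates
#'
#' Probability model for observing count `y` in a library of size `N2` given
#' count `x` in a library of size `N1` under equal underlying abundance:
#' `P(y | x) = choose(x + y, y) * q^y * (1 - q)^(x + 1)` with
#' `q = N2 / (N1 + N2)`. The upper tail sums `P(y' | x)` over `y' >= y`, the
#' lower over `y' <= y`, and the two-sided p-value is
#' `min(1, 2 * min(tails))`. All summation is done in log space with
#' streaming log-sum-exp; the upper tail is truncated when the next term
#' falls below `1e-16` of the running sum.
#'
#' @param x,y Non-negative integer counts (vectorised, recycled).
#' @param N1,N2 Library sizes (total mapped reads) of the two libraries.
#' @return Two-sided p-values in `(0, 1]`.
#' @export
#' @examples
#' ac_pvalue(0, 5, 1e6, 1e6)  # 2 * 2^-5 = 0.0625
ac_pvalue <- function(x, y, N1, N2) {
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  N1 <- rep_len(as.numeric(N1), n); N2 <- rep_len(as.numeric(N2), n)
  if (any(x < 0 | y < 0)) abort("counts must be non-negative.")
  if (any(N1 < 1 | N2 < 1)) abort("library sizes must be >= 1.")
  vapply(seq_len(n), function(i) {
    ac_pvalue_one(x[i], y[i], N1[i], N2[i])
  }, numeric(1))
}

ac_pvalue_one <- function(x, y, N1, N2) {
  q <- N2 / (N1 + N2)
  lower <- ac_log_tail(x, q, 0, y)
  upper <- ac_log_tail(x, q, y, Inf)
  # clamp at the smallest positive double so extreme contrasts stay in (0, 1]
  max(min(1, 2 * exp(min(lower, upper))), .Machine$double.xmin)
}

# log P(from <= Y <= to | x) under the conditioned count model.
ac_log_tail <- function(x, q, from, to) {
  lmass <- function(yy) lchoose(x + yy, yy) + yy * log(q) + (x + 1) * log1p(-q)
  if (is.finite(to)) {
    return(logsumexp(lmass(from:to)))
  }
  # Open upper tail: accumulate in blocks until the remainder is negligible.
  block <- 256L
  lo <- from
  acc <- -Inf
  repeat {
    terms <- lmass(lo + 0:(block - 1L))
    acc <- logsumexp(c(acc, terms))
    # Past the mode the terms decrease; stop once the last term cannot move
    # the sum at relative tolerance 1e-16.
    last <- terms[block]
    if (lo + block - 1 > x * q / (1 - q) && last < acc + log(1e-16)) break
    lo <- lo + block
    if (lo > from + 1e7) abort("Audic-Claverie tail failed to converge.")
  }
  min(acc, 0)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment via [stats::p.adjust()], with input validation on the
#' `(0, 1]` domain. Use `method = "hochberg"` for the plain Hochberg step-up
#' (family-wise) procedure instead.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @param method `"BH"` (default) or `"hochberg"`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues, method = c("BH", "hochberg")) {
  method <- match.arg(method)
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(pvalues, method = method)
}

#' Differential-expression threshold set
#'
#' The three filters applied jointly by [call_degs()]: minimum expression
#' (RPKM, max over the two compared samples), maximum FDR q, and minimum
#' absolute log2 ratio. All comparisons are inclusive. The default
#' `(2, 0.05, 2)` is the strict DEG set; `preset = "unfiltered"` drops the
#' expression filter `(0, 0.05, 2)`; `preset = "gcn"` is the looser set used
#' to pick network genes `(0, 0.05, 1.5)`.
#'
#' @param min_rpkm,max_fdr,min_abs_log2 Filter values.
#' @param preset Optional name overriding the three values.
#' @return A list of class `threshold_set`.
#' @export
threshold_set <- function(min_rpkm = 2, max_fdr = 0.05, min_abs_log2 = 2,
                          preset = NULL) {
  if (!is.null(preset)) {
    v <- switch(match.arg(preset, c("default", "unfiltered", "gcn")),
                default = c(2, 0.05, 2),
                unfiltered = c(0, 0.05, 2),
                gcn = c(0, 0.05, 1.5))
    min_rpkm <- v[1]; max_fdr <- v[2]; min_abs_log2 <- v[3]
  }
  if (min_rpkm < 0 || min_abs_log2 < 0 || max_fdr <= 0 || max_fdr > 1) {
    abort("invalid threshold values.")
  }
  structure(list(min_rpkm = min_rpkm, max_fdr = max_fdr,
                 min_abs_log2 = min_abs_log2),
            class = "threshold_set")
}

#' Call differentially expressed genes across all pairwise comparisons
#'
#' For every ordered pair of samples (later vs earlier, in column order) each
#' gene gets an Audic-Claverie two-sided p-value from its raw counts, a
#' Benjamini-Hochberg q within the comparison, and a log2 ratio of
#' pseudocounted RPKM (or raw counts with `ratio_on = "counts"`). A gene
#' passes iff `q <= max_fdr`, `|log2_ratio| >= min_abs_log2` and
#' `max(RPKM) >= min_rpkm` over the two samples — all boundaries inclusive.
#'
#' @param counts Wide count table (`gene_id`, `length`, sample columns).
#' @param thresholds A [threshold_set()].
#' @param library_sizes Mapped reads per sample; defaults as in
#'   [compute_rpkm()].
#' @param pseudocount Pseudocount in RPKM units (or count units) for the
#'   ratio.
#' @param ratio_on Compute the log2 ratio on `"rpkm"` (default) or raw
#'   `"counts"`.
#' @return Tibble of class `deg_table`: `gene_id`, `comparison`, `x`, `y`,
#'   `N1`, `N2`, `log2_ratio`, `p`, `q`, `direction` (`up`/`down`/`none`),
#'   `passes_filters`.
#' @export
call_degs <- function(counts, thresholds = threshold_set(),
                      library_sizes = NULL, pseudocount = 1,
                      ratio_on = c("rpkm", "counts")) {
  ratio_on <- match.arg(ratio_on)
  if (!inherits(thresholds, "threshold_set")) {
    abort("`thresholds` must come from threshold_set().")
  }
  if (nrow(counts) == 0L) {
    abort("`counts` must contain at least one gene and two samples.")
  }
  cm <- wide_to_matrix(counts)
  if (ncol(cm) < 2L) {
    abort("`counts` must contain at least one gene and two samples.")
  }
  expr <- compute_rpkm(counts, library_sizes)
  em <- wide_to_matrix(expr)
  libs <- attr(expr, "library_sizes")
  ratio_m <- if (ratio_on == "rpkm") em else cm
  comps <- pairwise_comparisons(colnames(cm))

  res <- purrr::pmap(comps, function(comparison, earlier, later) {
    x <- cm[, earlier]; y <- cm[, later]
    lr <- log2((ratio_m[, later] + pseudocount) /
               (ratio_m[, earlier] + pseudocount))
    p <- ac_pvalue(x, y, libs[earlier], libs[later])
    q <- bh_fdr(p)
    max_rpkm <- pmax(em[, earlier], em[, later])
    passes <- q <= thresholds$max_fdr &
      abs(lr) >= thresholds$min_abs_log2 &
      max_rpkm >= thresholds$min_rpkm
    tibble(gene_id = rownames(cm), comparison = comparison,
           x = as.integer(x), y = as.integer(y),
           N1 = unname(libs[earlier]), N2 = unname(libs[later]),
           log2_ratio = lr, p = p, q = q,
           direction = dplyr::case_when(
             passes & lr > 0 ~ "up",
             passes & lr < 0 ~ "down",
             .default = "none"),
           passes_filters = passes)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("deg_table", class(out))
  attr(out, "thresholds") <- thresholds
  out
}

#' Extract per-comparison DEG gene sets from a DEG table
#'
#' @param deg_table Result of [call_degs()].
#' @return Named list of character vectors (genes passing filters), one per
#'   comparison.
#' @export
deg_sets <- function(deg_table) {
  split(deg_table$gene_id[deg_table$passes_filters],
        deg_table$comparison[deg_table$passes_filters])
}

#' Three-way Venn partition of DEG sets
#'
#' Splits the union of three gene sets into the seven disjoint regions
#' (three exclusive, three pairwise-only, one triple) and reports each
#' region's share of the union, rounded to one decimal.
#'
#' @param sets Named list of exactly three character vectors.
#' @return Tibble of class `venn_partition`: `region`, `count`,
#'   `percentage`; per-set totals in `attr(, "totals")`, union size in
#'   `attr(, "union_size")`.
#' @export
venn_partition <- function(sets) {
  if (length(sets) != 3L) abort("`sets` must be a list of three gene sets.")
  nm <- names(sets) %||% c("A", "B", "C")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  inC <- universe %in% sets[[3]]
  code <- inA + 2L * inB + 4L * inC
  region_names <- c(paste0(nm, "_only"),
                    paste0(nm[1], "&", nm[2]),
                    paste0(nm[1], "&", nm[3]),
                    paste0(nm[2], "&", nm[3]),
                    paste0(nm, collapse = "&"))
  codes <- c(1L, 2L, 4L, 3L, 5L, 6L, 7L)
  counts <- vapply(codes, function(cc) sum(code == cc), integer(1))
  total <- length(universe)
  out <- tibble(region = region_names,
                count = counts,
                percentage = if (total > 0) round(100 * counts / total, 1)
                             else rep(NA_real_, 7))
  attr(out, "totals") <- setNames(lengths(sets), nm)
  attr(out, "union_size") <- total
  class(out) <- c("venn_partition", class(out))
  out
}

#' Region percentages (and triple-intersection recovery) from printed counts
#'
#' Reporting helper for a three-set Venn diagram when only the six
#' single/pairwise region counts and the union total are known: the triple
#' intersection is recovered as `total - sum(counts)` and every region's
#' percentage of the union is rounded to one decimal.
#'
#' @param region_counts Numeric vector of 6 (triple recovered) or 7 region
#'   counts, ordered as in [venn_partition()].
#' @param total Size of the union of the three sets.
#' @return Tibble `count`, `percentage`, with the recovered (or given)
#'   triple-intersection count last.
#' @export
#' @examples
#' venn_percentages(c(414, 586, 174, 714, 213, 44), total = 2148)
venn_percentages <- function(region_counts, total) {
  if (!length(region_counts) %in% c(6L, 7L)) {
    abort("`region_counts` must have 6 or 7 entries.")
  }
  if (length(region_counts) == 6L) {
    triple <- total - sum(region_counts)
    if (triple < 0) abort("region counts exceed the stated total.")
    region_counts <- c(region_counts, triple)
  } else if (sum(region_counts) != total) {
    abort("region counts must sum to the union total.")
  }
  tibble(count = as.numeric(region_counts),
         percentage = round(100 * region_counts / total, 1))
}
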