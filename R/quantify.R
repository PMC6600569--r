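#' RPKM normalisation of a read-count table
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm = 1e9 * count / (library_size * length)`.
#'
#' @param counts Wide count table: `gene_id`, `length` (bp), one integer
#'   column per sample (as produced by [simulate_counts()] or
#'   [read_count_matrix()]).
#' @param library_sizes Named or positional numeric vector of mapped reads
#'   per sample. Defaults to the `library_sizes` attribute of `counts` if
#'   present, otherwise to the column sums.
#' @return Tibble `gene_id` plus one RPKM column per sample.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", length = 1000L, s1 = 10L)
#' compute_rpkm(counts, library_sizes = 1e6)  # RPKM 10
compute_rpkm <- function(counts, library_sizes = NULL) {
  m <- wide_to_matrix(counts)
  if (!"length" %in% names(counts)) abort("`counts` must have a `length` column.")
  len <- counts$length
  if (any(len <= 0)) {
    abort(sprintf("non-positive gene length for: %s",
                  paste(counts$gene_id[len <= 0], collapse = ", ")))
  }
  if (any(m < 0)) abort("counts must be non-negative.")
  libs <- library_sizes %||% attr(counts, "library_sizes") %||% colSums(m)
  if (!is.null(names(libs)) && all(colnames(m) %in% names(libs))) {
    libs <- libs[colnames(m)]
  }
  if (length(libs) != ncol(m)) {
    abort("`library_sizes` must have one entry per sample column.")
  }
  if (any(libs <= 0)) {
    abort(sprintf("non-positive library size for sample: %s",
                  paste(colnames(m)[libs <= 0], collapse = ", ")))
  }
  rpkm <- 1e9 * sweep(m / len, 2, libs, "/")
  out <- dplyr::bind_cols(tibble(gene_id = counts$gene_id), as_tibble(rpkm))
  attr(out, "library_sizes") <- setNames(as.numeric(libs), colnames(m))
  out
}

#' Per-gene log2 expression ratio between two samples
#'
#' `log2((later + pseudocount) / (earlier + pseudocount))`, computed on the
#' values in `expr` (RPKM by convention; raw counts work identically).
#'
#' @param expr Wide expression table (`gene_id` + sample columns), e.g. from
#'   [compute_rpkm()].
#' @param comparison Character or integer pair `(earlier, later)` naming two
#'   sample columns; the ratio is later over earlier.
#' @param pseudocount Value added to both sides before the ratio (same units
#'   as `expr`); keeps genes expressed in only one sample finite.
#' @return Tibble `gene_id`, `log2_ratio`.
#' @export
#' @examples
#' expr <- tibble::tibble(gene_id = "g", a = 1, b = 4)
#' log2_ratio(expr, c("a", "b"), pseudocount = 0)  # 2
log2_ratio <- function(expr, comparison, pseudocount = 1) {
  if (length(comparison) != 2L) abort("`comparison` must name two samples.")
  m <- wide_to_matrix(expr)
  cols <- if (is.numeric(comparison)) colnames(m)[comparison] else comparison
  missing <- setdiff(cols, colnames(m))
  if (length(missing)) {
    abort(sprintf("sample(s) not in `expr`: %s", paste(missing, collapse = ", ")))
  }
  if (pseudocount < 0) abort("`pseudocount` must be non-negative.")
  tibble(gene_id = expr$gene_id,
         log2_ratio = unname(log2((m[, cols[2]] + pseudocount) /
                                  (m[, cols[1]] + pseudocount))))
}

#' All ordered pairwise comparisons of a sample series
#'
#' For the canonical 0/2/4 h design this returns
#' `2h_vs_0h`, `4h_vs_0h`, `4h_vs_2h` — each later library over each
#' earlier one.
#'
#' @param sample_labels Character vector of sample labels in time order.
#' @return Tibble `comparison`, `earlier`, `later`.
#' @export
pairwise_comparisons <- function(sample_labels) {
  if (length(sample_labels) < 2) abort("need at least two samples.")
  pairs <- utils::combn(sample_labels, 2)
  tibble(comparison = paste0(pairs[2, ], "_vs_", pairs[1, ]),
         earlier = pairs[1, ], later = pairs[2, ])
}
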