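# Small reporting arithmetic shared by the summary tables: rounded
# percentages and mean sequence lengths, as printed in assembly/annotation
# summaries.

#' Rounded percentage of a count over a total
#'
#' @param n Count (numerator).
#' @param total Total (denominator, > 0).
#' @param digits Decimal places (default 2).
#' @return `100 * n / total`, rounded.
#' @export
#' @examples
#' percent_of(48927, 124041)  # 39.44
percent_of <- function(n, total, digits = 2) {
  if (any(total <= 0)) abort("`total` must be positive.")
  round(100 * n / total, digits)
}

#' Mean sequence length from a total length and a sequence count
#'
#' @param total_bp Summed sequence length (bp).
#' @param n_seq Number of sequences (> 0).
#' @param digits Decimal places (default 2).
#' @return Mean length in bp, rounded.
#' @export
#' @examples
#' mean_length(74396629, 124041)  # 599.77
mean_length <- function(total_bp, n_seq, digits = 2) {
  if (any(n_seq <= 0)) abort("`n_seq` must be positive.")
  round(total_bp / n_seq, digits)
}
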