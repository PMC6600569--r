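#' Classify three-point expression series into eight trend profiles
#'
#' Each of the two consecutive transitions (t0 to t1, t1 to t2) is scored
#' `up` if the log2 change of pseudocounted expression is at least
#' `flat_threshold`, `down` if at most `-flat_threshold`, else `flat`.
#' Coding down = 0, flat = 1, up = 2, the pair `(first, second)` maps to
#' `3 * first + second`, the all-flat cell is excluded, and indices above it
#' shift down by one — giving the fixed bijection:
#' down-down 0, down-flat 1, down-up 2, flat-down 3, flat-up 4, up-down 5,
#' up-flat 6, up-up 7. Genes flat in both transitions get profile `NA`.
#'
#' @param expr Wide expression table (`gene_id` + exactly three sample
#'   columns in time order), non-negative values (RPKM by convention).
#' @param flat_threshold Minimum absolute log2 change to leave `flat`
#'   (log2 units, default 1).
#' @param pseudocount Pseudocount applied before the log ratio.
#' @return Tibble of class `trend_profiles`: `gene_id`, `state1`, `state2`
#'   (`down`/`flat`/`up`), `profile` (0-7 or `NA`).
#' @export
#' @examples
#' expr <- tibble::tibble(gene_id = "g", t0 = 1, t1 = 10, t2 = 10)
#' classify_profile(expr)  # up then flat: profile 6
classify_profile <- function(expr, flat_threshold = 1, pseudocount = 1) {
  m <- wide_to_matrix(expr)
  if (ncol(m) != 3L) abort("`expr` must have exactly three sample columns.")
  if (any(m < 0)) abort("expression values must be non-negative.")
  if (flat_threshold < 0) abort("`flat_threshold` must be non-negative.")
  d1 <- log2((m[, 2] + pseudocount) / (m[, 1] + pseudocount))
  d2 <- log2((m[, 3] + pseudocount) / (m[, 2] + pseudocount))
  state <- function(d) ifelse(d >= flat_threshold, 2L,
                       ifelse(d <= -flat_threshold, 0L, 1L))
  s1 <- state(d1); s2 <- state(d2)
  out <- tibble(gene_id = expr$gene_id,
                state1 = c("down", "flat", "up")[s1 + 1L],
                state2 = c("down", "flat", "up")[s2 + 1L],
                profile = profile_index(s1, s2))
  attr(out, "flat_threshold") <- flat_threshold
  class(out) <- c("trend_profiles", class(out))
  out
}

# (state1, state2) coded down=0/flat=1/up=2 -> profile index 0..7, NA for
# flat-flat (raw cell 4 excluded, higher cells shift down by one).
profile_index <- function(s1, s2) {
  raw <- 3L * s1 + s2
  ifelse(raw == 4L, NA_integer_, ifelse(raw > 4L, raw - 1L, raw))
}

#' Permutation significance of trend-profile counts
#'
#' Shuffles the time-point labels independently for each gene
#' `n_permutations` times, reclassifies, and reports for every profile the
#' fraction of permutations whose profile count reaches the observed count
#' (a one-sided over-representation p-value, STEM-style).
#'
#' @inheritParams classify_profile
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Integer seed; results are deterministic given it.
#' @return Tibble `profile` (0-7), `count` (observed), `p`.
#' @export
profile_significance <- function(expr, flat_threshold = 1, pseudocount = 1,
                                 n_permutations = 1000, seed = 1L) {
  m <- wide_to_matrix(expr)
  if (ncol(m) != 3L) abort("`expr` must have exactly three sample columns.")
  if (nrow(m) == 0L) abort("no genes to assess.")
  if (n_permutations < 100) abort("`n_permutations` must be >= 100.")
  withr::local_seed(seed)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  # Profile of every gene under each of the 6 orderings, computed once.
  prof_by_perm <- sapply(seq_len(6), function(k) {
    cp <- classify_profile(
      dplyr::bind_cols(tibble(gene_id = rownames(m)),
                       as_tibble(m[, perms[k, ], drop = FALSE],
                                 .name_repair = "minimal")),
      flat_threshold = flat_threshold, pseudocount = pseudocount)
    cp$profile
  })
  count8 <- function(prof) tabulate(prof[!is.na(prof)] + 1L, nbins = 8L)
  observed <- count8(prof_by_perm[, 1])
  n <- nrow(m)
  exceed <- integer(8)
  for (b in seq_len(n_permutations)) {
    pick <- sample.int(6L, n, replace = TRUE)
    exceed <- exceed + (count8(prof_by_perm[cbind(seq_len(n), pick)]) >= observed)
  }
  tibble(profile = 0:7, count = observed, p = exceed / n_permutations)
}
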