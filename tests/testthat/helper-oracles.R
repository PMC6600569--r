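# Independent oracles used across the suite. Each reimplements the target
# quantity by direct/brute-force computation, never by calling the package
# path it checks.

# Audic-Claverie two-sided p by direct summation of the point-mass series
# in plain arithmetic (small-count instances only).
ac_brute <- function(x, y, N1, N2, rel_tol = 1e-16) {
  q <- N2 / (N1 + N2)
  mass <- function(yy) exp(lchoose(x + yy, yy)) * q^yy * (1 - q)^(x + 1)
  lower <- sum(mass(0:y))
  upper <- 0
  yy <- y
  repeat {
    term <- mass(yy)
    upper <- upper + term
    if (yy > x * q / (1 - q) && term < rel_tol * upper) break
    yy <- yy + 1
    if (yy > y + 1e6) stop("oracle failed to converge")
  }
  min(1, 2 * min(lower, upper))
}

# Negative-binomial closed form for the same tails.
ac_nb <- function(x, y, N1, N2) {
  p0 <- N1 / (N1 + N2)
  upper <- stats::pnbinom(y - 1, size = x + 1, prob = p0, lower.tail = FALSE)
  lower <- stats::pnbinom(y, size = x + 1, prob = p0)
  min(1, 2 * min(lower, upper))
}

# Upper-tail hypergeometric p by exhaustive combinatorial summation.
hyper_brute <- function(k, K, n, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j) / choose(N, n))
}

# HRR matrix by explicit double-loop rank tables.
hrr_brute <- function(corr) {
  n <- nrow(corr)
  rank_of <- function(i, j) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-corr[i, others], others)]
    which(ord == j)
  }
  out <- matrix(NA_integer_, n, n, dimnames = dimnames(corr))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) out[i, j] <- max(rank_of(i, j), rank_of(j, i))
  }
  out
}

# Adjusted Rand index by direct pair counting.
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  pairs <- utils::combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 1 else num / den
}

# Venn region counts by brute-force membership enumeration.
venn_brute <- function(sets) {
  u <- unique(unlist(sets))
  member <- sapply(sets, function(s) u %in% s)
  counts <- c(
    sum(member[, 1] & !member[, 2] & !member[, 3]),
    sum(!member[, 1] & member[, 2] & !member[, 3]),
    sum(!member[, 1] & !member[, 2] & member[, 3]),
    sum(member[, 1] & member[, 2] & !member[, 3]),
    sum(member[, 1] & !member[, 2] & member[, 3]),
    sum(!member[, 1] & member[, 2] & member[, 3]),
    sum(member[, 1] & member[, 2] & member[, 3]))
  counts
}

# Small standard simulation shared by several tests.
quick_sim <- function(seed = 1, n_genes = 120, modules = list(),
                      de_genes = list(), lib = 1e5, dispersion = 10) {
  simulate_counts(simulation_config(
    n_genes = n_genes, library_sizes = rep(lib, 3), modules = modules,
    de_genes = de_genes, nb_dispersion = dispersion, seed = seed))
}
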