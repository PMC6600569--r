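# Internal numeric and validation helpers.

# Stable log(sum(exp(x))) for a numeric vector; -Inf-safe.
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Assert a single positive, finite number.
check_scalar <- function(x, name, positive = TRUE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  invisible(x)
}

# Extract the gene x sample numeric matrix from a wide expression/count table
# (gene_id column, optional length column, remaining columns = samples).
wide_to_matrix <- function(df, value_cols = NULL) {
  if (!"gene_id" %in% names(df)) abort("table must have a `gene_id` column.")
  drop <- intersect(c("gene_id", "length"), names(df))
  cols <- value_cols %||% setdiff(names(df), drop)
  m <- as.matrix(df[cols])
  if (!is.numeric(m)) abort("sample columns must be numeric.")
  rownames(m) <- df$gene_id
  m
}

# Deterministic child seed derived from a base seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 8191) %% 2147483647
}
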