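# Readers and writers for the plain-text interchange formats:
# counts TSV (gene_id, length, samples...), annotation TSV (gene_id, term),
# edge-list TSV, SIF, and JSON summaries.

#' Read a count matrix TSV
#'
#' Expected header: `gene_id`, `length`, then one column per sample.
#'
#' @param path File path.
#' @param library_sizes Optional mapped-read totals per sample; stored as an
#'   attribute (defaulted to column sums downstream if absent).
#' @return Count tibble as produced by [simulate_counts()].
#' @export
read_count_matrix <- function(path, library_sizes = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "length") %in% names(x))) {
    abort("count TSV must have `gene_id` and `length` columns.")
  }
  if (anyDuplicated(x$gene_id)) abort("duplicated gene ids in count TSV.")
  if (!is.null(library_sizes)) attr(x, "library_sizes") <- library_sizes
  x
}

#' Write a count matrix TSV
#' @param counts Count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a two-column gene-to-term annotation TSV
#'
#' One `gene_id<TAB>term` association per row; a header is auto-detected.
#'
#' @param path File path.
#' @return Tibble `gene_id`, `term`.
#' @export
read_annotation <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("^gene_id\t", first)
  x <- readr::read_tsv(path, col_names = if (has_header) TRUE else
                         c("gene_id", "term"),
                       skip = 0, show_col_types = FALSE)
  if (ncol(x) < 2) abort("annotation TSV must have two columns.")
  names(x)[1:2] <- c("gene_id", "term")
  x[1:2]
}

#' Write an annotation map TSV
#' @param annotation Tibble `gene_id`, `term` (or `sim_annotation`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  if (inherits(annotation, "sim_annotation")) annotation <- annotation$annotation
  readr::write_tsv(annotation, path, col_names = FALSE)
  invisible(path)
}

#' Write a network edge list TSV (`from to r hrr weight`)
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' Write a network in SIF format (`geneA hrr geneB`)
#'
#' Simple interaction format for graph viewers; isolated nodes are written
#' as bare node lines.
#'
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  e <- net$edges
  lines <- sprintf("%s\t%d\t%s", e$from, e$hrr, e$to)
  isolated <- setdiff(net$nodes$gene_id, c(e$from, e$to))
  readr::write_lines(c(lines, isolated), path)
  invisible(path)
}

# Deterministic JSON writer used for all summary artifacts.
write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
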