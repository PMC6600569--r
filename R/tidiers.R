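# broom-style tidy()/glance() methods for the result classes.

#' @describeIn build_network tidy(): the edge table.
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @method tidy coexpression_network
#' @export
tidy.coexpression_network <- function(x, ...) as_tibble(x$edges)

#' @describeIn build_network glance(): one-row topology summary
#'   ([network_stats()]).
#' @method glance coexpression_network
#' @export
glance.coexpression_network <- function(x, ...) {
  out <- network_stats(x)
  class(out) <- class(out)[-1]
  out
}

#' @describeIn mcl_cluster tidy(): the assignment table as a plain tibble.
#' @param x A `module_partition`.
#' @param ... Unused.
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "module_partition")
  as_tibble(out)
}

#' @describeIn mcl_cluster glance(): one-row clustering summary (cluster and
#'   module counts, module size range, convergence flag).
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  msz <- x$cluster_size[x$is_module]
  tibble(n_clusters = length(unique(x$cluster)),
         n_modules = length(unique(x$cluster[x$is_module])),
         min_module_size = if (length(msz)) min(msz) else NA_integer_,
         max_module_size = if (length(msz)) max(msz) else NA_integer_,
         genes_in_modules = sum(x$is_module),
         n_genes = nrow(x),
         converged = isTRUE(attr(x, "converged")),
         iterations = attr(x, "iterations") %||% NA_integer_)
}

#' @describeIn call_degs tidy(): the DEG table as a plain tibble.
#' @param x A `deg_table`.
#' @param ... Unused.
#' @method tidy deg_table
#' @export
tidy.deg_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "deg_table")
  as_tibble(out)
}

#' @describeIn call_degs glance(): one row per comparison with gene counts
#'   and up/down DEG tallies.
#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  x |>
    dplyr::group_by(comparison = .data$comparison) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     n_deg = sum(.data$passes_filters),
                     n_up = sum(.data$direction == "up"),
                     n_down = sum(.data$direction == "down"),
                     .groups = "drop")
}

#' @describeIn venn_partition glance(): one-row summary with the union size
#'   and per-set totals.
#' @param x A `venn_partition`.
#' @param ... Unused.
#' @method glance venn_partition
#' @export
glance.venn_partition <- function(x, ...) {
  totals <- attr(x, "totals")
  dplyr::bind_cols(
    tibble(union_size = attr(x, "union_size")),
    as_tibble(as.list(setNames(as.integer(totals),
                               paste0("total_", names(totals))))))
}
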