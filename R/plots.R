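# ggplot2 views of the result classes.

#' Volcano plot of a DEG table
#'
#' One panel per comparison; points coloured by direction call.
#'
#' @param object A `deg_table` from [call_degs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2_ratio,
                               y = -log10(.data$p),
                               colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", none = "grey70")) +
    ggplot2::labs(x = "log2 ratio (later / earlier)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of trend-profile membership
#'
#' @param object A `trend_profiles` from [classify_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_profiles
#' @export
autoplot.trend_profiles <- function(object, ...) {
  counts <- object |>
    dplyr::filter(!is.na(.data$profile)) |>
    dplyr::count(profile = factor(.data$profile, levels = 0:7))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$profile, y = .data$n)) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::labs(x = "trend profile", y = "genes") +
    ggplot2::theme_minimal()
}

#' Cluster-size bar chart of a module partition
#'
#' @param object A `module_partition` from [mcl_cluster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot module_partition
#' @export
autoplot.module_partition <- function(object, ...) {
  sizes <- object |>
    dplyr::distinct(.data$cluster, .data$cluster_size, .data$is_module)
  ggplot2::ggplot(sizes,
                  ggplot2::aes(x = factor(.data$cluster),
                               y = .data$cluster_size,
                               fill = .data$is_module)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#27ae60",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "cluster", y = "size", fill = "module") +
    ggplot2::theme_minimal()
}

#' Degree distribution of a co-expression network
#'
#' @param object A `coexpression_network` from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coexpression_network
#' @export
autoplot.coexpression_network <- function(object, ...) {
  deg <- igraph::degree(as_igraph(object))
  ggplot2::ggplot(tibble(degree = deg), ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "#8e44ad") +
    ggplot2::labs(x = "node degree", y = "nodes") +
    ggplot2::theme_minimal()
}

#' Hormone-ratio time series plot
#'
#' @param ratios Output of [hormone_ratio()], or several such tables bound
#'   with a `label` column.
#' @return A ggplot object.
#' @export
plot_hormone_ratio <- function(ratios) {
  aes <- if ("label" %in% names(ratios)) {
    ggplot2::aes(x = .data$time, y = .data$ratio, colour = .data$label)
  } else {
    ggplot2::aes(x = .data$time, y = .data$ratio)
  }
  ggplot2::ggplot(ratios, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "content ratio") +
    ggplot2::theme_minimal()
}
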