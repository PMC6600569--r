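#' Relative qPCR quantification by the Livak 2^-ddCt method
#'
#' Replicate Ct values are averaged on the Ct scale per (gene, condition);
#' `dCt = Ct_target - mean(Ct_references)` per condition (multiple reference
#' genes are combined by the arithmetic mean of their Ct, i.e. the geometric
#' mean of their linear quantities); `ddCt = dCt_condition -
#' dCt_calibrator`; relative expression is `2^-ddCt` (exactly 1 for the
#' calibrator itself).
#'
#' @param ct Long Ct table: columns `gene`, `condition`, `replicate`, `ct`
#'   (cycles, > 0).
#' @param references Character vector of reference (housekeeping) gene
#'   names; each must be measured in every condition.
#' @param calibrator The baseline condition (e.g. `"0h"`).
#' @param targets Genes to quantify; defaults to all non-reference genes.
#' @return Tibble `gene`, `condition`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expr`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   gene = rep(c("tgt", "ref"), each = 2),
#'   condition = rep(c("0h", "2h"), 2),
#'   replicate = 1L,
#'   ct = c(26, 24, 20, 20))
#' ddct(ct, references = "ref", calibrator = "0h")  # 2h: ddCt -2 -> 4
ddct <- function(ct, references, calibrator, targets = NULL) {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    abort(sprintf("`ct` needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(ct$ct <= 0)) abort("Ct values must be positive.")
  if (!calibrator %in% ct$condition) {
    abort(sprintf("calibrator condition '%s' not present.", calibrator))
  }
  mean_ct <- ct |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  conditions <- unique(ct$condition)
  for (cond in conditions) {
    present <- mean_ct$gene[mean_ct$condition == cond]
    miss <- setdiff(references, present)
    if (length(miss)) {
      abort(sprintf("reference gene(s) %s missing in condition '%s'.",
                    paste(miss, collapse = ", "), cond))
    }
  }
  ref_ct <- mean_ct |>
    dplyr::filter(.data$gene %in% references) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(ref_ct = mean(.data$ct), .groups = "drop")
  targets <- targets %||% setdiff(unique(ct$gene), references)
  out <- mean_ct |>
    dplyr::filter(.data$gene %in% targets) |>
    dplyr::left_join(ref_ct, by = "condition") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(delta_delta_ct = .data$delta_ct -
                    .data$delta_ct[.data$condition == calibrator]) |>
    dplyr::ungroup() |>
    dplyr::mutate(rel_expr = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("gene", "condition", "delta_ct", "delta_delta_ct",
                  "rel_expr")
  missing_cal <- setdiff(targets, out$gene[out$condition == calibrator])
  if (length(missing_cal)) {
    abort(sprintf("target(s) %s not measured in calibrator condition '%s'.",
                  paste(missing_cal, collapse = ", "), calibrator))
  }
  out
}

#' Hormone-content ratio time series
#'
#' Elementwise ratio of two hormone content series (e.g. ABA over GA3) on a
#' shared time grid, preserving time order.
#'
#' @param hormones Long table: columns `hormone`, `time`, `content`
#'   (e.g. ng per g fresh weight, >= 0).
#' @param numerator,denominator Hormone names.
#' @return Tibble `time`, `numerator`, `denominator`, `ratio`.
#' @export
#' @examples
#' h <- tibble::tibble(hormone = rep(c("ABA", "GA3"), each = 2),
#'                     time = rep(c(0, 4), 2), content = c(80, 80, 10, 20))
#' hormone_ratio(h, "ABA", "GA3")  # ratios 8, 4
hormone_ratio <- function(hormones, numerator, denominator) {
  need <- c("hormone", "time", "content")
  if (!all(need %in% names(hormones))) {
    abort(sprintf("`hormones` needs columns: %s.", paste(need, collapse = ", ")))
  }
  num <- hormones[hormones$hormone == numerator, ]
  den <- hormones[hormones$hormone == denominator, ]
  if (nrow(num) == 0) abort(sprintf("hormone '%s' not present.", numerator))
  if (nrow(den) == 0) abort(sprintf("hormone '%s' not present.", denominator))
  num <- num[order(num$time), ]
  den <- den[order(den$time), ]
  if (!identical(num$time, den$time)) {
    abort("numerator and denominator must share the same time grid.")
  }
  zero <- den$time[den$content == 0]
  if (length(zero)) {
    abort(sprintf("zero denominator content at time point(s): %s",
                  paste(zero, collapse = ", ")))
  }
  tibble(time = num$time,
         numerator = num$content,
         denominator = den$content,
         ratio = num$content / den$content)
}
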