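#' Relative expression by the 2^-ddCT method
#'
#' For each sample, `delta_ct = target CT - reference-gene CT`;
#' `delta_delta_ct = delta_ct - mean(delta_ct of the calibrator group)`
#' (per gene); `fold_change = 2^-delta_delta_ct`. Amplification efficiency
#' is taken as 2 (perfect doubling). By construction the geometric mean of
#' the calibrator group's fold changes is 1.
#'
#' @param ct_table Tibble with columns `sample_id`, `group`, `gene`, `ct`
#'   (target CT, cycles) and `reference_ct` (housekeeping-gene CT, cycles).
#' @param calibrator_group Label of the calibrator (reference condition)
#'   group; must be present with at least one sample per gene.
#' @return A `vasc_ddct` tibble: input columns plus `delta_ct`,
#'   `delta_delta_ct`, `fold_change`. Samples missing either CT are dropped
#'   with a message. Attribute `calibrator` records the calibrator label.
#' @export
delta_delta_ct <- function(ct_table, calibrator_group) {
  need <- c("sample_id", "group", "gene", "ct", "reference_ct")
  if (!is.data.frame(ct_table) || !all(need %in% names(ct_table))) {
    abort(paste0("`ct_table` must have columns ", paste(need, collapse = ", "), "."))
  }
  if (!calibrator_group %in% ct_table$group) {
    abort(sprintf("calibrator group '%s' not present.", calibrator_group))
  }
  miss <- !is.finite(ct_table$ct) | !is.finite(ct_table$reference_ct)
  if (any(miss)) {
    inform(sprintf("delta_delta_ct: dropping %d sample row(s) with missing CT values.",
                   sum(miss)))
    ct_table <- dplyr::filter(ct_table, !miss)
  }
  out <- ct_table |>
    dplyr::mutate(delta_ct = .data$ct - .data$reference_ct) |>
    dplyr::group_by(.data$gene)
  cal_n <- out |>
    dplyr::summarise(n = sum(.data$group == calibrator_group))
  if (any(cal_n$n == 0)) {
    abort(sprintf("empty calibrator group for gene(s): %s",
                  paste(cal_n$gene[cal_n$n == 0], collapse = ", ")))
  }
  out <- out |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct -
        mean(.data$delta_ct[.data$group == calibrator_group]),
      fold_change = 2^(-.data$delta_delta_ct)
    ) |>
    dplyr::ungroup()
  out <- new_vasc_tbl(out, "vasc_ddct")
  attr(out, "calibrator") <- calibrator_group
  out
}

#' Per-group fold-change summaries
#'
#' Fold changes are multiplicative, so groups are summarized by the
#' geometric mean with log2-scale dispersion.
#'
#' @param result A `vasc_ddct` tibble from [delta_delta_ct()].
#' @return A tibble with one row per gene and group: `n`,
#'   `geo_mean_fold_change`, `log2_sd` (sd of log2 fold changes).
#' @export
fold_change_summary <- function(result) {
  if (!all(c("gene", "group", "fold_change") %in% names(result))) {
    abort("`result` must come from delta_delta_ct().")
  }
  result |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      geo_mean_fold_change = 2^mean(log2(.data$fold_change)),
      log2_sd = sd(log2(.data$fold_change)),
      .groups = "drop"
    )
}
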