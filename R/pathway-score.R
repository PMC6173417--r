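#' Pathway score of one gene set
#'
#' The pathway activity score: the mean log2 fold change of the set's genes
#' present in the DE table, divided by the standard deviation of those fold
#' changes. Genes absent from the DE table are ignored and counted in
#' `n_dropped`. A set whose usable LFCs are all identical (sd = 0) gets a
#' flagged row with `score = NA` rather than an infinite score.
#'
#' @param de A DE table (tibble with `gene_id` and `log2_fold_change`).
#' @param genes Character vector of gene symbols (one gene set).
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return One-row tibble: `n_genes_used`, `n_dropped`, `mean_lfc`,
#'   `sd_lfc`, `score`, `flagged`.
#' @export
compute_score <- function(de, genes, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!all(c("gene_id", "log2_fold_change") %in% names(de))) {
    abort("`de` must have columns gene_id and log2_fold_change.")
  }
  lfc <- de$log2_fold_change[match(genes, de$gene_id)]
  dropped <- sum(is.na(lfc))
  lfc <- lfc[!is.na(lfc)]
  n <- length(lfc)
  if (n < 2) {
    return(tibble(n_genes_used = n, n_dropped = dropped,
                  mean_lfc = NA_real_, sd_lfc = NA_real_, score = NA_real_,
                  flagged = TRUE))
  }
  m <- mean(lfc)
  s <- if (sd_type == "sample") sd(lfc) else sqrt(mean((lfc - m)^2))
  tibble(n_genes_used = n, n_dropped = dropped, mean_lfc = m, sd_lfc = s,
         score = if (s > 0) m / s else NA_real_, flagged = s == 0)
}

#' Score every pathway of a catalog against a DE table
#'
#' Applies [compute_score()] to each set. Sets with fewer than two usable
#' genes are skipped (reported via a message); degenerate sd-zero sets are
#' kept but flagged and excluded from ranking downstream.
#'
#' @inheritParams compute_score
#' @param catalog A gene set catalog tibble ([parse_gmt()]).
#' @param min_genes Minimum usable genes per set (>= 2).
#' @return A `vasc_scores` tibble: `pathway`, `n_genes_used`, `n_dropped`,
#'   `mean_lfc`, `sd_lfc`, `score`, `flagged`.
#' @export
score_pathways <- function(de, catalog, sd_type = c("sample", "population"),
                           min_genes = 2) {
  assert_catalog(catalog)
  sd_type <- match.arg(sd_type)
  if (min_genes < 2) abort("min_genes must be >= 2 (the sd needs two points).")
  rows <- purrr::map(catalog$genes, ~ compute_score(de, .x, sd_type = sd_type))
  out <- dplyr::bind_cols(tibble(pathway = catalog$set_name),
                          dplyr::bind_rows(rows))
  skipped <- out$n_genes_used < min_genes
  if (any(skipped)) {
    inform(sprintf("score_pathways: skipped %d set(s) with < %d usable genes: %s",
                   sum(skipped), min_genes,
                   paste(head(out$pathway[skipped], 5), collapse = ", ")))
    out <- dplyr::filter(out, !skipped)
  }
  new_vasc_tbl(out, "vasc_scores")
}

#' Rank pathways and call top/bottom deciles
#'
#' Sorts pathways by score (highest first), then labels the top
#' `floor(fraction * N)` as `"up"` and the bottom `floor(fraction * N)` as
#' `"down"`; everything else is `"none"`. N counts only finitely-scored
#' pathways; flagged / non-finite rows are dropped with a message before
#' ranking. Ties (in score) are broken by pathway name so the ordering is
#' deterministic.
#'
#' @param scores A `vasc_scores` tibble from [score_pathways()].
#' @param fraction Decile fraction in (0, 0.5); default 0.10.
#' @return The scored tibble sorted by descending score with added `rank`
#'   (1 = highest score) and `call` columns.
#' @export
rank_and_call <- function(scores, fraction = 0.10) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 0.5) {
    abort("fraction must lie in (0, 0.5).")
  }
  if (!all(c("pathway", "score") %in% names(scores))) {
    abort("`scores` must have columns pathway and score.")
  }
  bad <- !is.finite(scores$score)
  if (any(bad)) {
    inform(sprintf("rank_and_call: dropping %d flagged/non-finite score row(s).",
                   sum(bad)))
    scores <- dplyr::filter(scores, !bad)
  }
  n <- nrow(scores)
  if (n == 0L) {
    return(new_vasc_tbl(dplyr::mutate(scores, rank = integer(), call = character()),
                        "vasc_scores"))
  }
  out <- dplyr::arrange(scores, dplyr::desc(.data$score), .data$pathway)
  k <- floor(fraction * n)
  if (k == 0L) warn("rank_and_call: floor(fraction * N) is 0; all calls are 'none'.")
  call <- rep("none", n)
  if (k > 0L) {
    call[seq_len(k)] <- "up"
    call[seq(n - k + 1L, n)] <- "down"
  }
  out$rank <- seq_len(n)
  out$call <- call
  new_vasc_tbl(out, "vasc_scores")
}

#' Assemble a pathways-by-timepoints heatmap matrix
#'
#' Rows are the union of pathway names across timepoints (in order of first
#' appearance), columns the timepoints in the supplied order; cells hold the
#' chosen value, `NA` where a pathway was not scored at a timepoint.
#'
#' @param scored_by_timepoint Named list mapping timepoint label to a scored
#'   pathway tibble (from [score_pathways()] / [rank_and_call()]).
#' @param value Which column to place in the cells: `"score"` or
#'   `"mean_lfc"`.
#' @return A tibble with a `pathway` column plus one column per timepoint.
#' @export
build_heatmap_matrix <- function(scored_by_timepoint,
                                 value = c("score", "mean_lfc")) {
  value <- match.arg(value)
  if (!is.list(scored_by_timepoint) || length(scored_by_timepoint) < 1L ||
      is.null(names(scored_by_timepoint)) ||
      any(!nzchar(names(scored_by_timepoint)))) {
    abort("`scored_by_timepoint` must be a non-empty named list of scored tables.")
  }
  tps <- names(scored_by_timepoint)
  if (anyDuplicated(tps)) abort("duplicate timepoint labels.")
  long <- purrr::imap(scored_by_timepoint, function(tbl, tp) {
    tibble(pathway = tbl$pathway, timepoint = tp, value = tbl[[value]])
  })
  long <- dplyr::bind_rows(long)
  wide <- tidyr::pivot_wider(long, names_from = "timepoint",
                             values_from = "value")
  # keep supplied column order and first-appearance row order
  wide[, c("pathway", tps)]
}
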