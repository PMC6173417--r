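# broom-style tidiers for the package's result objects. tidy() returns the
# per-unit table as a plain tibble; glance() a one-row summary.

#' @exportS3Method generics::tidy
tidy.vasc_de <- function(x, ...) as_tibble(unclass_vasc(x))

#' @exportS3Method generics::glance
glance.vasc_de <- function(x, alpha = 0.05, ...) {
  tibble(
    n_genes = nrow(x),
    n_tested = sum(!x$all_zero),
    n_sig = sum(x$adj_p <= alpha & !x$all_zero),
    median_dispersion = median(x$dispersion[!x$all_zero])
  )
}

#' @exportS3Method generics::tidy
tidy.vasc_scores <- function(x, ...) as_tibble(unclass_vasc(x))

#' @exportS3Method generics::glance
glance.vasc_scores <- function(x, ...) {
  tibble(
    n_pathways = nrow(x),
    n_up = if ("call" %in% names(x)) sum(x$call == "up") else NA_integer_,
    n_down = if ("call" %in% names(x)) sum(x$call == "down") else NA_integer_,
    n_flagged = sum(x$flagged)
  )
}

#' @exportS3Method generics::tidy
tidy.vasc_gsea <- function(x, ...) as_tibble(unclass_vasc(x))

#' @exportS3Method generics::glance
glance.vasc_gsea <- function(x, q_max = 0.05, ...) {
  tibble(
    n_sets = nrow(x),
    n_significant = sum(x$fdr_q <= q_max, na.rm = TRUE),
    min_fdr_q = if (nrow(x) > 0) min(x$fdr_q, na.rm = TRUE) else NA_real_
  )
}

#' @exportS3Method generics::tidy
tidy.vasc_ddct <- function(x, ...) as_tibble(unclass_vasc(x))

#' @exportS3Method generics::glance
glance.vasc_ddct <- function(x, ...) {
  grp <- fold_change_summary(x)
  cal <- attr(x, "calibrator")
  treated <- grp[grp$group != cal, , drop = FALSE]
  tibble(
    n_samples = nrow(x),
    n_genes = length(unique(x$gene)),
    calibrator = cal,
    geo_mean_fold_change = 2^mean(log2(treated$geo_mean_fold_change))
  )
}

unclass_vasc <- function(x) {
  class(x) <- setdiff(class(x), c("vasc_de", "vasc_scores", "vasc_gsea",
                                  "vasc_ddct", "vasc_ranking", "vasc_catalog"))
  attr(x, "contrast") <- NULL
  attr(x, "calibrator") <- NULL
  attr(x, "dropped_symbols") <- NULL
  x
}
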