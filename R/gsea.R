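#' Signed -log10(p) gene ranking
#'
#' Builds the preranked-GSEA input metric from a DE table:
#' `sign(LFC) * -log10(max(p, p_floor))`. An LFC of exactly zero gives a
#' metric of zero. Genes with a missing p-value or LFC are excluded (with a
#' message). The result is sorted by descending metric, ties broken by
#' gene id.
#'
#' @param de A DE table with `gene_id`, `log2_fold_change`, `p_value`.
#' @param p_floor Lower bound on p before taking the log, keeping the metric
#'   finite. Default 1e-300.
#' @return A `vasc_ranking` tibble with columns `gene_id`, `metric`.
#' @export
rank_metric <- function(de, p_floor = 1e-300) {
  if (!all(c("gene_id", "log2_fold_change", "p_value") %in% names(de))) {
    abort("`de` must have columns gene_id, log2_fold_change, p_value.")
  }
  if (!is.numeric(p_floor) || p_floor <= 0 || p_floor >= 1) {
    abort("p_floor must lie in (0, 1).")
  }
  if (nrow(de) == 0L) abort("`de` is empty.")
  bad <- !is.finite(de$log2_fold_change) | !is.finite(de$p_value)
  if (any(bad)) {
    inform(sprintf("rank_metric: excluding %d gene(s) with missing p or LFC.",
                   sum(bad)))
    de <- dplyr::filter(de, !bad)
  }
  out <- tibble(
    gene_id = de$gene_id,
    metric = sign(de$log2_fold_change) * -log10(pmax(de$p_value, p_floor))
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$metric), .data$gene_id)
  new_vasc_tbl(out, "vasc_ranking")
}

# Enrichment score from sorted hit positions; O(n_hits) per evaluation.
# The running sum changes slope only at hits, so its extrema lie at the
# values just after each hit and just before each hit; candidates are scanned
# in walk order and the first value of maximal |.| wins, matching a full
# prefix evaluation exactly.
es_from_hits <- function(pos, w_all, n_total, weight_exponent) {
  s <- length(pos)
  w <- w_all[pos]
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else rep(1 / s, s)
  miss <- 1 / (n_total - s)
  cs <- cumsum(inc)
  shift <- (pos - seq_len(s)) * miss
  after <- cs - shift                 # value at position pos_i
  before <- c(0, cs[-s]) - shift      # value at position pos_i - 1
  val <- c(rbind(before, after))      # walk order: before_1, after_1, before_2, ...
  keep <- rep(TRUE, 2L * s)
  if (pos[1] == 1L) keep[1] <- FALSE  # position 0 is not part of the walk
  val <- val[keep]
  val[which.max(abs(val))]
}

#' Weighted running-sum enrichment score
#'
#' The weighted Kolmogorov–Smirnov-style statistic of preranked gene set
#' enrichment: walking down the ranking, each set member ("hit") adds
#' `|metric|^weight_exponent` (normalized so the hits sum to one) and each
#' non-member subtracts `1/(N - N_hits)`; the enrichment score is the
#' running-sum value of maximal absolute deviation from zero, keeping its
#' sign. `weight_exponent = 0` gives the classic unweighted KS statistic.
#' If every hit metric is zero (possible only with a positive exponent),
#' hits contribute equal increments.
#'
#' @param ranking A `vasc_ranking` tibble ([rank_metric()]); re-sorted
#'   defensively with the same tie rule.
#' @param genes Character vector of set members; at least one must be in the
#'   ranking and at least one ranked gene must be outside the set.
#' @param weight_exponent Non-negative weight on `|metric|`; default 1.
#' @return A list with `es` (scalar) and `running_sum` (length-N numeric,
#'   the full walk).
#' @export
enrichment_score <- function(ranking, genes, weight_exponent = 1) {
  rk <- check_ranking(ranking)
  if (weight_exponent < 0) abort("weight_exponent must be >= 0.")
  hit <- rk$gene_id %in% genes
  n <- nrow(rk)
  n_hits <- sum(hit)
  if (n_hits == 0L) abort("set has no genes in the ranking.")
  if (n_hits == n) abort("set covers the whole ranking (miss denominator is zero).")
  w <- abs(rk$metric)^weight_exponent
  tot <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (tot > 0) w[hit] / tot else 1 / n_hits
  inc[!hit] <- -1 / (n - n_hits)
  running <- cumsum(inc)
  list(es = running[which.max(abs(running))], running_sum = running)
}

check_ranking <- function(ranking) {
  if (!all(c("gene_id", "metric") %in% names(ranking))) {
    abort("`ranking` must have columns gene_id and metric.")
  }
  if (anyDuplicated(ranking$gene_id)) abort("ranking gene ids must be unique.")
  if (any(!is.finite(ranking$metric))) abort("ranking metrics must be finite.")
  dplyr::arrange(as_tibble(ranking), dplyr::desc(.data$metric), .data$gene_id)
}

#' Preranked gene set enrichment analysis
#'
#' From-scratch preranked GSEA: for every catalog set, the weighted
#' running-sum enrichment score ([enrichment_score()]); a permutation null
#' from `n_perm` random same-size gene draws out of the ranking (shared
#' across sets of equal size, seeded and deterministic); the normalized
#' enrichment score `NES = ES / mean(|null ES| of matching sign)`; a nominal
#' permutation p with `+1` continuity; and an FDR q per the canonical
#' NES-pooled-null procedure (or Benjamini–Hochberg on the nominal p with
#' `fdr_method = "bh"`). Sets with no gene in the ranking, or covering it
#' entirely, are skipped with a message and absent from the result.
#'
#' @inheritParams enrichment_score
#' @param catalog A gene set catalog tibble.
#' @param n_perm Number of permutations (>= 100); default 1000.
#' @param seed Integer seed; results are deterministic given it.
#' @param fdr_method `"pooled"` (canonical) or `"bh"`.
#' @return A `vasc_gsea` tibble: `set_name`, `n_genes_used`, `es`, `nes`,
#'   `nominal_p`, `fdr_q`.
#' @export
gsea_preranked <- function(ranking, catalog, n_perm = 1000,
                           weight_exponent = 1, seed = 1,
                           fdr_method = c("pooled", "bh")) {
  fdr_method <- match.arg(fdr_method)
  rk <- check_ranking(ranking)
  assert_catalog(catalog)
  if (nrow(catalog) == 0L) abort("catalog is empty.")
  if (n_perm < 100) abort("n_perm must be >= 100.")
  n <- nrow(rk)
  w_all <- abs(rk$metric)^weight_exponent

  hits <- lapply(catalog$genes, function(g) which(rk$gene_id %in% g))
  n_used <- lengths(hits)
  skip <- n_used == 0L | n_used == n
  if (any(skip)) {
    inform(paste0("gsea_preranked: skipping set(s) with no hits or covering the ranking: ",
                  paste(catalog$set_name[skip], collapse = ", ")))
  }
  keep <- which(!skip)
  if (length(keep) == 0L) {
    return(new_vasc_tbl(tibble(set_name = character(), n_genes_used = integer(),
                               es = numeric(), nes = numeric(),
                               nominal_p = numeric(), fdr_q = numeric()),
                        "vasc_gsea"))
  }

  es_obs <- vapply(keep, function(i)
    es_from_hits(hits[[i]], w_all, n, weight_exponent), numeric(1))
  sizes <- n_used[keep]

  # permutation null per distinct set size, one seeded stream per size
  null_by_size <- lapply(sort(unique(sizes)), function(s) {
    withr::with_seed(sub_seed(seed, paste0("gsea-perm-", s)), {
      vapply(seq_len(n_perm), function(p)
        es_from_hits(sort(sample.int(n, s)), w_all, n, weight_exponent),
        numeric(1))
    })
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))

  res <- purrr::map2_dfr(es_obs, sizes, function(es, s) {
    null <- null_by_size[[as.character(s)]]
    pos <- null[null >= 0]; neg <- null[null < 0]
    if (es >= 0) {
      mean_abs <- if (length(pos) > 0) mean(pos) else NA_real_
      p <- (1 + sum(pos >= es)) / (1 + length(pos))
    } else {
      mean_abs <- if (length(neg) > 0) mean(abs(neg)) else NA_real_
      p <- (1 + sum(abs(neg) >= abs(es))) / (1 + length(neg))
    }
    tibble(es = es, nes = if (is.na(mean_abs) || mean_abs == 0) NA_real_
           else es / mean_abs, nominal_p = p)
  })

  fdr_q <- if (fdr_method == "bh") {
    adjust_bh(res$nominal_p)
  } else {
    # pooled null NES: each set's null ES normalized by its size's
    # matching-sign mean, pooled over all retained sets
    null_nes <- unlist(lapply(sizes, function(s) {
      null <- null_by_size[[as.character(s)]]
      pos <- null[null >= 0]; neg <- null[null < 0]
      mp <- if (length(pos) > 0) mean(pos) else NA_real_
      mn <- if (length(neg) > 0) mean(abs(neg)) else NA_real_
      c(if (!is.na(mp) && mp > 0) pos / mp, if (!is.na(mn) && mn > 0) neg / mn)
    }), use.names = FALSE)
    obs_nes <- res$nes
    vapply(obs_nes, function(x) {
      if (is.na(x)) return(NA_real_)
      if (x >= 0) {
        num_pool <- sum(null_nes >= 0)
        num <- if (num_pool > 0) sum(null_nes >= x) / num_pool else 0
        den_pool <- sum(obs_nes >= 0, na.rm = TRUE)
        den <- if (den_pool > 0) sum(obs_nes >= x, na.rm = TRUE) / den_pool else 1
      } else {
        num_pool <- sum(null_nes < 0)
        num <- if (num_pool > 0) sum(null_nes <= x) / num_pool else 0
        den_pool <- sum(obs_nes < 0, na.rm = TRUE)
        den <- if (den_pool > 0) sum(obs_nes <= x, na.rm = TRUE) / den_pool else 1
      }
      min(1, num / max(den, .Machine$double.eps))
    }, numeric(1))
  }

  out <- dplyr::bind_cols(
    tibble(set_name = catalog$set_name[keep], n_genes_used = sizes),
    res, tibble(fdr_q = fdr_q))
  new_vasc_tbl(out, "vasc_gsea")
}

#' Filter enrichment results at an FDR threshold
#'
#' With per-timepoint results (a `timepoint` column present, e.g. several
#' [gsea_preranked()] outputs bound together), a set is retained if its FDR q
#' is at or below `q_max` at ANY timepoint, and all of its rows (every
#' timepoint) are returned — the display convention for time-course
#' enrichment panels. Without a `timepoint` column this is a plain row
#' filter.
#'
#' @param results A `vasc_gsea` tibble, optionally with a `timepoint` column.
#' @param q_max FDR threshold; default 0.05.
#' @return The filtered tibble.
#' @export
filter_significant <- function(results, q_max = 0.05) {
  if (!all(c("set_name", "fdr_q") %in% names(results))) {
    abort("`results` must have columns set_name and fdr_q.")
  }
  if (nrow(results) == 0L) return(results)
  if ("timepoint" %in% names(results)) {
    keep_sets <- unique(results$set_name[!is.na(results$fdr_q) &
                                           results$fdr_q <= q_max])
    dplyr::filter(results, .data$set_name %in% keep_sets)
  } else {
    dplyr::filter(results, !is.na(.data$fdr_q) & .data$fdr_q <= q_max)
  }
}
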