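#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed the canonical way: for each
#' sample, the median over usable genes of the ratio of its count to the
#' gene's geometric mean across samples. Usable genes have nonzero counts in
#' every sample. Factors are not rescaled afterwards.
#'
#' @param counts Count tibble: `gene_id` column plus one integer column per
#'   sample.
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  mat <- counts_matrix(counts)
  usable <- rowSums(mat > 0) == ncol(mat)
  if (!any(usable)) {
    abort("normalization error: no gene has nonzero counts in every sample.")
  }
  lg <- log(mat[usable, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, median))
  tibble(sample_id = colnames(mat), size_factor = unname(sf))
}

#' Two-group negative binomial Wald test
#'
#' A minimal differential-expression stage: normalized group means give the
#' log2 fold change (with a pseudocount keeping zero groups finite); a
#' per-gene method-of-moments dispersion pooled across the two groups feeds a
#' delta-method standard error for the LFC; the Wald statistic is referred to
#' a t distribution whose Welch–Satterthwaite effective degrees of freedom
#' reflect how much of the variance is the estimated overdispersion component
#' (it reduces to the normal reference when that component vanishes).
#' Benjamini–Hochberg adjustment is applied across the tested genes.
#'
#' This stage deliberately omits dispersion shrinkage across genes, LFC
#' priors and outlier handling; it targets calibrated (LFC, p) pairs, not
#' bit-compatibility with any particular DE package.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param samples Sample annotation tibble with `sample_id` and `condition`.
#' @param reference,treated Condition labels to contrast; the LFC is
#'   treated vs reference.
#' @param size_factors Optional tibble from [estimate_size_factors()]
#'   (typically estimated on the full matrix); when `NULL`, estimated from
#'   the two groups' samples.
#' @param pseudocount Pseudocount (normalized-count units) added inside the
#'   LFC ratio. Default 0.5.
#' @param dispersion_floor Lower bound for the moment dispersion estimate.
#' @return A `vasc_de` tibble with columns `gene_id`, `base_mean`,
#'   `log2_fold_change`, `stat`, `p_value`, `adj_p`, `dispersion`,
#'   `all_zero`. Genes with zero counts in both groups keep their rows with
#'   `log2_fold_change = 0`, `p_value = adj_p = 1` and `all_zero = TRUE`.
#' @export
test_two_group <- function(counts, samples, reference, treated,
                           size_factors = NULL, pseudocount = 0.5,
                           dispersion_floor = 1e-8) {
  mat <- counts_matrix(counts)
  cond <- sample_conditions(mat, samples)
  for (lab in c(reference, treated)) {
    if (!lab %in% cond) abort(sprintf("unknown condition label '%s'.", lab))
    if (sum(cond == lab) < 2) abort(sprintf("condition '%s' has < 2 replicates.", lab))
  }
  keep <- cond %in% c(reference, treated)
  mat <- mat[, keep, drop = FALSE]
  cond <- cond[keep]

  if (is.null(size_factors)) {
    size_factors <- estimate_size_factors(
      dplyr::bind_cols(tibble(gene_id = rownames(mat)),
                       as_tibble(mat, .name_repair = "minimal")))
  }
  sf <- size_factors$size_factor[match(colnames(mat), size_factors$sample_id)]
  if (anyNA(sf)) abort("size_factors missing entries for some samples.")
  if (any(!is.finite(sf)) || any(sf <= 0)) abort("size factors must be positive and finite.")

  q <- sweep(mat, 2, sf, "/")
  is_ref <- cond == reference
  n_r <- sum(is_ref); n_t <- sum(!is_ref)
  qr <- q[, is_ref, drop = FALSE]; qt <- q[, !is_ref, drop = FALSE]
  m_r <- rowMeans(qr); m_t <- rowMeans(qt)
  all_zero <- m_r == 0 & m_t == 0

  # pooled within-group variance of normalized counts
  v_r <- rowSums((qr - m_r)^2) / (n_r - 1)
  v_t <- rowSums((qt - m_t)^2) / (n_t - 1)
  df_pool <- n_r + n_t - 2
  s2 <- ((n_r - 1) * v_r + (n_t - 1) * v_t) / df_pool

  # moment dispersion: E[var(q)] ~ mu * mean(1/sf) + alpha * mu^2 per group
  phi_r <- mean(1 / sf[is_ref]); phi_t <- mean(1 / sf[!is_ref])
  pois_pooled <- ((n_r - 1) * m_r * phi_r + (n_t - 1) * m_t * phi_t) / df_pool
  denom <- ((n_r - 1) * m_r^2 + (n_t - 1) * m_t^2) / df_pool
  alpha <- ifelse(denom > 0, pmax((s2 - pois_pooled) / denom, dispersion_floor),
                  dispersion_floor)

  lfc <- log2((m_t + pseudocount) / (m_r + pseudocount))

  # delta-method variance of log2 group means, split into the known Poisson
  # part and the estimated overdispersion part (for the effective df)
  pois_var_mean_r <- m_r * sum(1 / sf[is_ref]) / n_r^2
  pois_var_mean_t <- m_t * sum(1 / sf[!is_ref]) / n_t^2
  disp_var_mean_r <- alpha * m_r^2 / n_r
  disp_var_mean_t <- alpha * m_t^2 / n_t
  ln2sq <- log(2)^2
  ratio_sq <- function(num, m) ifelse(m + pseudocount > 0,
                                      num / (m + pseudocount)^2, 0)
  a_known <- (ratio_sq(pois_var_mean_r, m_r) +
                ratio_sq(pois_var_mean_t, m_t)) / ln2sq
  b_est <- (ratio_sq(disp_var_mean_r, m_r) +
              ratio_sq(disp_var_mean_t, m_t)) / ln2sq
  se <- sqrt(a_known + b_est)

  stat <- ifelse(se > 0, lfc / se, 0)
  # Effective df of the t reference by Welch-Satterthwaite on the estimated
  # variance component b = C * (s2 - poisson part): its variance is that of
  # s2, whose relative variance exceeds the normal-theory chi-square because
  # NB counts carry excess kurtosis (~ 6*alpha + 1/(mu*(1+alpha*mu))).
  mu_hat <- (n_r * m_r + n_t * m_t) / (n_r + n_t)
  kappa <- 6 * alpha + 1 / pmax(mu_hat * (1 + alpha * mu_hat), 1e-8)
  w_k <- ((n_r - 1)^2 / n_r + (n_t - 1)^2 / n_t) / df_pool^2
  rel_var_s2 <- 2 / df_pool + w_k * kappa
  c_coef <- ifelse(denom > 0,
                   (ratio_sq(m_r^2 / n_r, m_r) +
                      ratio_sq(m_t^2 / n_t, m_t)) / denom / ln2sq, 0)
  var_b <- rel_var_s2 * (s2 * c_coef)^2
  df_eff <- ifelse(var_b > 0, 2 * (a_known + b_est)^2 / var_b, Inf)
  p <- 2 * pt(-abs(stat), df = df_eff)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  lfc[all_zero] <- 0
  p[all_zero] <- 1
  stat[all_zero] <- 0

  adj <- rep(1, length(p))
  adj[!all_zero] <- adjust_bh(p[!all_zero])

  out <- tibble(
    gene_id = rownames(mat),
    base_mean = unname(rowMeans(q)),
    log2_fold_change = unname(lfc),
    stat = unname(stat),
    p_value = unname(p),
    adj_p = unname(adj),
    dispersion = unname(alpha),
    all_zero = unname(all_zero)
  )
  out <- new_vasc_tbl(out, "vasc_de")
  attr(out, "contrast") <- c(reference = reference, treated = treated)
  out
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1), computed via [stats::p.adjust()]
#' after validating that all inputs lie in (0, 1].
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted values, same order as the input.
#' @export
adjust_bh <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}
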