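# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities by the most direct route possible
# (full prefix scans, direct formulas) so they share no code with the
# implementation they check.

# Brute-force enrichment score: evaluate the running sum at every prefix.
oracle_es <- function(metrics, hit, weight_exponent = 1) {
  stopifnot(any(hit), any(!hit))
  n <- length(metrics)
  w <- abs(metrics)^weight_exponent
  tot <- sum(w[hit])
  run <- numeric(n)
  cur <- 0
  for (k in seq_len(n)) {
    cur <- cur + if (hit[k]) {
      if (tot > 0) w[k] / tot else 1 / sum(hit)
    } else {
      -1 / (n - sum(hit))
    }
    run[k] <- cur
  }
  run[which.max(abs(run))]
}

# Classic unweighted KS running-sum statistic (equal hit increments).
oracle_es_unweighted <- function(hit) {
  n <- length(hit)
  run <- cumsum(ifelse(hit, 1 / sum(hit), -1 / (n - sum(hit))))
  run[which.max(abs(run))]
}

# Direct mean / sample-sd pathway score.
oracle_score <- function(de, genes) {
  lfc <- de$log2_fold_change[de$gene_id %in% genes]
  list(mean = mean(lfc), sd = sd(lfc), score = mean(lfc) / sd(lfc),
       n = length(lfc))
}

# Random DE table fixture.
random_de <- function(n_genes, seed) {
  withr::with_seed(seed, tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    base_mean = stats::rlnorm(n_genes, 4, 1),
    log2_fold_change = stats::rnorm(n_genes, 0, 1.2),
    p_value = stats::runif(n_genes)
  ))
}

# Random catalog over a gene universe.
random_catalog <- function(universe, n_sets, size_range, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      set_name = sprintf("set%03d", seq_len(n_sets)),
      description = "random",
      collection = "test",
      genes = lapply(seq_len(n_sets), function(i) {
        choices <- seq.int(size_range[1], size_range[2])
        sample(universe, choices[sample.int(length(choices), 1)])
      })
    )
  })
}

# Small null simulation + DE, shared by several tests.
null_de <- function(n_genes, seed, n_replicates = 6, dispersion = 0.1) {
  cfg <- sim_config(n_genes = n_genes, timepoints = c("baseline", "t1"),
                    n_replicates = n_replicates, dispersion = dispersion,
                    n_sets = 2, set_size_range = c(5, 10),
                    planted_signals = list(), seed = seed)
  sim <- simulate_counts(cfg)
  test_two_group(sim$counts, sim$samples, "baseline", "t1")
}
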