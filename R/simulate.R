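#' Configure a synthetic vascular-injury time course
#'
#' Builds the configuration for [simulate_counts()]. Defaults emulate the
#' injury time-course design the package targets: a baseline vessel plus
#' post-surgery timepoints, six biological replicates per group, negative
#' binomial counts (variance = mu + dispersion * mu^2), and two planted
#' signals — a transient inflammatory induction peaking at 6 h and a
#' persistent suppression of a VSMC differentiation set sustained across all
#' timepoints.
#'
#' @param n_genes Number of genes.
#' @param timepoints Ordered condition labels; the first is the baseline /
#'   reference condition.
#' @param n_replicates Samples per condition (>= 2).
#' @param baseline_meanlog,baseline_sdlog Log-normal location/scale of the
#'   per-gene baseline mean expression.
#' @param dispersion NB dispersion alpha >= 0; `0` gives Poisson counts.
#' @param n_sets Total number of gene sets in the generated catalog
#'   (planted + null).
#' @param set_size_range Inclusive `(min, max)` set size.
#' @param planted_signals List of planted signals; each element is a list with
#'   `set_name`, `profile` (`"persistent"` or `"transient"`), `delta` (log2
#'   fold change magnitude) and, for transient profiles, `peak` (the timepoint
#'   at which the effect is present). Transient signals are nonzero only at
#'   their peak timepoint; persistent signals at every non-baseline timepoint.
#' @param lib_size_range Per-sample library-size multipliers are drawn
#'   uniformly from this interval so normalization is exercised.
#' @param delta_jitter_sd Optional per-gene Gaussian jitter (sd, log2 units)
#'   around a planted delta; `0` (default) keeps planted sets coherent.
#' @param seed Integer seed; all draws are deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       timepoints = c("baseline", "1h", "6h", "24h"),
                       n_replicates = 6,
                       baseline_meanlog = 4,
                       baseline_sdlog = 1.5,
                       dispersion = 0.1,
                       n_sets = 100,
                       set_size_range = c(20, 80),
                       planted_signals = list(
                         list(set_name = "inflammatory_response",
                              profile = "transient", peak = "6h", delta = 2),
                         list(set_name = "vsmc_differentiation",
                              profile = "persistent", delta = -1)
                       ),
                       lib_size_range = c(0.7, 1.3),
                       delta_jitter_sd = 0,
                       seed = 1) {
  if (n_replicates < 2) abort("n_replicates must be >= 2.")
  if (length(timepoints) < 2 || anyDuplicated(timepoints)) {
    abort("timepoints must be >= 2 unique labels (first one is the baseline).")
  }
  if (dispersion < 0) abort("dispersion must be >= 0.")
  if (length(set_size_range) != 2 || set_size_range[1] < 2 ||
      set_size_range[1] > set_size_range[2] || set_size_range[2] > n_genes) {
    abort("set_size_range must satisfy 2 <= min <= max <= n_genes.")
  }
  for (sig in planted_signals) {
    if (!all(c("set_name", "profile", "delta") %in% names(sig))) {
      abort("each planted signal needs set_name, profile and delta.")
    }
    if (!sig$profile %in% c("persistent", "transient")) {
      abort("planted profile must be 'persistent' or 'transient'.")
    }
    if (!is.finite(sig$delta)) abort("planted delta must be finite.")
    if (sig$profile == "transient") {
      if (is.null(sig$peak) || !sig$peak %in% timepoints[-1]) {
        abort("transient signals need a `peak` among the non-baseline timepoints.")
      }
    }
  }
  if (length(planted_signals) > n_sets) abort("more planted signals than n_sets.")
  structure(list(
    n_genes = as.integer(n_genes), timepoints = as.character(timepoints),
    n_replicates = as.integer(n_replicates),
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion, n_sets = as.integer(n_sets),
    set_size_range = as.integer(set_size_range),
    planted_signals = planted_signals, lib_size_range = lib_size_range,
    delta_jitter_sd = delta_jitter_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a count matrix with planted pathway signals
#'
#' Draws NB(mu, dispersion) counts per gene and sample, with per-gene
#' baseline means log-normal, per-sample library-size multipliers, and
#' planted log2 fold changes applied coherently to all genes of each planted
#' set. Planted sets use disjoint genes; null sets are drawn from the
#' remaining genes. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `vasc_sim` with elements:
#'   `counts` (tibble, `gene_id` + one column per sample),
#'   `samples` (tibble `sample_id`, `condition`),
#'   `catalog` (gene set catalog tibble),
#'   `truth_genes` (tibble `gene_id`, `timepoint`, `true_lfc`),
#'   `truth_sets` (tibble `set_name`, `label` in null/transient/persistent),
#'   and `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tps <- cfg$timepoints
  non_base <- tps[-1]
  n_planted <- length(cfg$planted_signals)

  # --- set membership -------------------------------------------------------
  size_choices <- seq.int(cfg$set_size_range[1], cfg$set_size_range[2])
  sizes <- withr::with_seed(sub_seed(cfg$seed, "set-sizes"), {
    size_choices[sample.int(length(size_choices), cfg$n_sets, replace = TRUE)]
  })
  planted_total <- sum(sizes[seq_len(n_planted)])
  if (planted_total >= cfg$n_genes) {
    abort("set_size_range infeasible: planted sets would exhaust the genes.")
  }
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  membership <- withr::with_seed(sub_seed(cfg$seed, "set-members"), {
    planted_pool <- sample(cfg$n_genes, planted_total)
    null_pool <- setdiff(seq_len(cfg$n_genes), planted_pool)
    if (max(sizes) > length(null_pool)) {
      abort("set_size_range infeasible: not enough non-planted genes for null sets.")
    }
    offs <- c(0L, cumsum(sizes[seq_len(n_planted)]))
    members <- vector("list", cfg$n_sets)
    for (i in seq_len(cfg$n_sets)) {
      members[[i]] <- if (i <= n_planted) {
        planted_pool[(offs[i] + 1L):offs[i + 1L]]
      } else {
        sample(null_pool, sizes[i])
      }
    }
    members
  })
  set_names <- c(vapply(cfg$planted_signals, `[[`, character(1), "set_name"),
                 sprintf("null_set_%03d", seq_len(cfg$n_sets - n_planted)))
  catalog <- new_vasc_tbl(tibble(
    set_name = set_names,
    description = c(vapply(cfg$planted_signals, `[[`, character(1), "profile"),
                    rep("null", cfg$n_sets - n_planted)),
    collection = "simulated",
    genes = lapply(membership, function(ix) gene_ids[ix])
  ), "vasc_catalog")

  # --- true LFC per gene and timepoint -------------------------------------
  lfc <- matrix(0, nrow = cfg$n_genes, ncol = length(non_base),
                dimnames = list(gene_ids, non_base))
  for (i in seq_len(n_planted)) {
    sig <- cfg$planted_signals[[i]]
    active <- if (sig$profile == "persistent") non_base else sig$peak
    delta <- rep(sig$delta, length(membership[[i]]))
    if (cfg$delta_jitter_sd > 0) {
      delta <- delta + withr::with_seed(
        sub_seed(cfg$seed, paste0("jitter-", i)),
        rnorm(length(delta), 0, cfg$delta_jitter_sd))
    }
    lfc[membership[[i]], active] <- delta
  }

  # --- sample frame and expected means -------------------------------------
  samples <- tibble(
    sample_id = paste0(rep(tps, each = cfg$n_replicates), "_rep",
                       rep(seq_len(cfg$n_replicates), length(tps))),
    condition = rep(tps, each = cfg$n_replicates)
  )
  mu0 <- withr::with_seed(sub_seed(cfg$seed, "means"),
                          rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog))
  lib <- withr::with_seed(sub_seed(cfg$seed, "libsize"),
                          runif(nrow(samples), cfg$lib_size_range[1], cfg$lib_size_range[2]))
  fold <- cbind(matrix(1, cfg$n_genes, 1), 2^lfc)[, match(samples$condition, tps)]
  mu <- sweep(mu0 * fold, 2, lib, "*")

  # --- NB draws -------------------------------------------------------------
  mat <- withr::with_seed(sub_seed(cfg$seed, "counts"), {
    n <- length(mu)
    if (cfg$dispersion == 0) {
      matrix(rpois(n, lambda = as.vector(mu)), nrow = cfg$n_genes)
    } else {
      matrix(rnbinom(n, mu = as.vector(mu), size = 1 / cfg$dispersion),
             nrow = cfg$n_genes)
    }
  })
  dimnames(mat) <- list(gene_ids, samples$sample_id)
  counts <- dplyr::bind_cols(tibble(gene_id = gene_ids),
                             as_tibble(mat, .name_repair = "minimal"))

  truth_genes <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(gene_id = gene_ids),
                     as_tibble(lfc, .name_repair = "minimal")),
    -"gene_id", names_to = "timepoint", values_to = "true_lfc")
  truth_sets <- tibble(
    set_name = set_names,
    label = c(vapply(cfg$planted_signals, `[[`, character(1), "profile"),
              rep("null", cfg$n_sets - n_planted))
  )
  structure(list(counts = counts, samples = samples, catalog = catalog,
                 truth_genes = truth_genes, truth_sets = truth_sets,
                 config = cfg),
            class = "vasc_sim")
}

#' Simulate a qPCR CT table with known fold change
#'
#' Generates calibrator and treated groups for one target gene against a
#' reference (housekeeping) gene. Treated-group target CTs are offset from
#' the calibrator by `-log2(true_fold_change)` plus Gaussian noise;
#' reference-gene CTs share the same per-sample structure.
#'
#' @param n_samples Samples per group (>= 2).
#' @param true_fold_change True expression ratio treated / calibrator (> 0).
#' @param ct_noise_sd Gaussian noise sd (cycles) added to each measured CT.
#' @param seed Integer seed.
#' @param target_gene,reference_gene Gene labels carried into the table.
#' @param groups Labels for the calibrator and treated groups.
#' @return A CT table tibble: `sample_id`, `group`, `gene`, `ct`,
#'   `reference_ct`.
#' @export
simulate_ct_table <- function(n_samples, true_fold_change, ct_noise_sd, seed = 1,
                              target_gene = "Acta2", reference_gene = "B2m",
                              groups = c("calibrator", "treated")) {
  if (n_samples < 2) abort("need >= 2 samples per group.")
  if (!is.finite(true_fold_change) || true_fold_change <= 0) {
    abort("true_fold_change must be > 0.")
  }
  if (ct_noise_sd < 0) abort("ct_noise_sd must be >= 0.")
  withr::with_seed(sub_seed(seed, "ct-table"), {
    n <- 2L * n_samples
    grp <- rep(groups, each = n_samples)
    ref_ct <- 20 + rnorm(n, 0, ct_noise_sd)
    delta_ct_true <- 5 - ifelse(grp == groups[2], log2(true_fold_change), 0)
    target_ct <- ref_ct + delta_ct_true + rnorm(n, 0, ct_noise_sd)
    tibble(
      sample_id = paste0(grp, "_", rep(seq_len(n_samples), 2)),
      group = grp,
      gene = target_gene,
      ct = target_ct,
      reference_ct = ref_ct,
      reference_gene = reference_gene
    )
  })
}
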