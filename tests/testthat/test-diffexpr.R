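make_counts <- function(mat, gene_ids = sprintf("g%02d", seq_len(nrow(mat)))) {
  colnames(mat) <- colnames(mat) %||% sprintf("s%d", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(mat, .name_repair = "minimal"))
}

test_that("median-of-ratios size factors match direct computation", {
  # identical samples -> all factors 1
  m <- matrix(c(3, 7, 11), 3, 4)
  colnames(m) <- paste0("s", 1:4)
  expect_equal(estimate_size_factors(make_counts(m))$size_factor, rep(1, 4))

  # doubling every count doubles the factor
  m2 <- cbind(A = c(10, 20, 40), B = c(20, 40, 80))
  sf <- estimate_size_factors(make_counts(m2))
  expect_equal(sf$size_factor[2] / sf$size_factor[1], 2)

  # 3-gene x 2-sample toy: hand-computed geometric means and medians
  # counts A = (1, 2, 4), B = (2, 8, 8); geo means (sqrt(2), 4, sqrt(32));
  # ratios A = (1/sqrt2, 1/2, 1/sqrt2) -> median 1/sqrt2; B mirror sqrt2
  m3 <- cbind(A = c(1, 2, 4), B = c(2, 8, 8))
  sf3 <- estimate_size_factors(make_counts(m3))
  expect_equal(sf3$size_factor, c(1 / sqrt(2), sqrt(2)))

  expect_error(estimate_size_factors(make_counts(cbind(A = c(0, 1), B = c(1, 0)))),
               "no gene")
})

test_that("scaling one sample rescales its factor by c and keeps LFCs", {
  sim <- simulate_counts(sim_config(n_genes = 200, timepoints = c("baseline", "t1"),
                                    n_replicates = 3, n_sets = 2,
                                    set_size_range = c(5, 10),
                                    planted_signals = list(), seed = 8))
  counts <- sim$counts
  sf0 <- estimate_size_factors(counts)
  de0 <- test_two_group(counts, sim$samples, "baseline", "t1",
                        pseudocount = 0)

  scaled <- counts
  scaled[[2]] <- scaled[[2]] * 3
  sf1 <- estimate_size_factors(scaled)
  # the scaled sample's factor grows by exactly c relative to the others
  # (the geometric-mean reference itself shifts by c^(1/n), a common factor)
  expect_equal(sf1$size_factor[1] / sf1$size_factor[2],
               3 * sf0$size_factor[1] / sf0$size_factor[2])
  expect_equal(sf1$size_factor[-1] / sf0$size_factor[-1],
               rep((1 / 3)^(1 / 6), 5))
  # normalized means shift by a common factor, so every LFC is unchanged
  de1 <- test_two_group(scaled, sim$samples, "baseline", "t1",
                        pseudocount = 0)
  expect_equal(de1$log2_fold_change, de0$log2_fold_change, tolerance = 1e-12)
})

test_that("swapping reference and treated negates LFCs, keeps p-values", {
  sim <- simulate_counts(sim_config(n_genes = 150, timepoints = c("baseline", "t1"),
                                    n_replicates = 4, n_sets = 2,
                                    set_size_range = c(5, 10),
                                    planted_signals = list(
                                      list(set_name = "up", profile = "persistent",
                                           delta = 1)),
                                    seed = 21))
  fwd <- test_two_group(sim$counts, sim$samples, "baseline", "t1")
  rev <- test_two_group(sim$counts, sim$samples, "t1", "baseline")
  expect_equal(rev$log2_fold_change, -fwd$log2_fold_change)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("degenerate genes get sentinel rows, equal groups get LFC zero", {
  m <- rbind(c(5, 5, 6, 5, 5, 6), c(0, 0, 0, 0, 0, 0), c(9, 9, 9, 9, 9, 9))
  colnames(m) <- paste0("s", 1:6)
  counts <- make_counts(m)
  samples <- tibble::tibble(sample_id = paste0("s", 1:6),
                            condition = rep(c("ref", "trt"), each = 3))
  sf <- tibble::tibble(sample_id = paste0("s", 1:6), size_factor = rep(1, 6))
  de <- test_two_group(counts, samples, "ref", "trt", size_factors = sf)
  expect_equal(nrow(de), 3L) # row alignment preserved
  expect_equal(de$log2_fold_change[c(1, 3)], c(0, 0))
  expect_true(de$all_zero[2])
  expect_equal(de$p_value[2], 1)
  expect_equal(de$adj_p[2], 1)
  expect_error(test_two_group(counts, samples, "ref", "nope"), "unknown condition")
  samples2 <- samples; samples2$condition <- c("ref", rep("trt", 5))
  expect_error(test_two_group(counts, samples2, "ref", "trt"), "< 2 replicates")
})

test_that("planted signals are detected with high power", {
  # 200 planted genes at delta = 2, alpha = 0.05, 6 vs 6
  cfg <- sim_config(n_genes = 2000, timepoints = c("baseline", "t1"),
                    n_replicates = 6, dispersion = 0.05, n_sets = 4,
                    set_size_range = c(50, 50),
                    planted_signals = list(
                      list(set_name = paste0("p", 1:4)[1], profile = "persistent", delta = 2),
                      list(set_name = "p2", profile = "persistent", delta = 2),
                      list(set_name = "p3", profile = "persistent", delta = 2),
                      list(set_name = "p4", profile = "persistent", delta = 2)),
                    seed = 77)
  sim <- simulate_counts(cfg)
  de <- test_two_group(sim$counts, sim$samples, "baseline", "t1")
  planted <- sim$counts$gene_id %in% unlist(sim$catalog$genes[1:4])
  expect_equal(sum(planted), 200L)
  expect_gte(mean(de$adj_p[planted] < 0.05), 0.9)
})

test_that("fold changes agree with an independent NB DE implementation", {
  cfg <- sim_config(n_genes = 400, timepoints = c("baseline", "t1"),
                    n_replicates = 6, dispersion = 0.1, n_sets = 2,
                    set_size_range = c(20, 20),
                    planted_signals = list(
                      list(set_name = "up", profile = "persistent", delta = 1.5),
                      list(set_name = "dn", profile = "persistent", delta = -1.5)),
                    seed = 12)
  sim <- simulate_counts(cfg)
  de <- test_two_group(sim$counts, sim$samples, "baseline", "t1")

  mat <- as.matrix(sim$counts[, -1])
  rownames(mat) <- sim$counts$gene_id
  cold <- data.frame(condition = factor(sim$samples$condition,
                                        levels = c("baseline", "t1")))
  dds <- DESeq2::DESeqDataSetFromMatrix(mat, cold, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)

  keep <- de$base_mean > 5 & !de$all_zero
  expect_gt(cor(de$log2_fold_change[keep], res$log2FoldChange[keep]), 0.98)
  # strongly significant genes agree in direction
  strong <- which(!is.na(res$padj) & res$padj < 1e-4)
  expect_true(all(sign(de$log2_fold_change[strong]) ==
                    sign(res$log2FoldChange[strong])))
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(rep(0.02, 5)), rep(0.02, 5))
  # p * m / rank then cumulative minimum from the largest p down
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_error(adjust_bh(c(0.1, 0)), "p-values")
  expect_error(adjust_bh(c(0.1, 1.2)), "p-values")

  # permutation invariance and elementwise dominance
  p <- withr::with_seed(4, runif(50))
  perm <- withr::with_seed(5, sample(50))
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  expect_true(all(adjust_bh(p) >= p))
})
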