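ranking_from <- function(metrics, ids = sprintf("g%02d", seq_along(metrics))) {
  rank_metric(tibble::tibble(gene_id = ids, log2_fold_change = metrics,
                             p_value = 10^(-abs(metrics))))
}

test_that("rank metric is signed -log10(p), sorted with lexicographic ties", {
  de <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       log2_fold_change = c(3, -3, 0.5, 0),
                       p_value = c(0.01, 0.01, 1, 0.2))
  rk <- rank_metric(de)
  expect_equal(rk$metric[rk$gene_id == "a"], 2)
  expect_equal(rk$metric[rk$gene_id == "b"], -2)
  expect_equal(rk$metric[rk$gene_id == "c"], 0)
  expect_equal(rk$metric[rk$gene_id == "d"], 0) # zero LFC -> metric 0
  expect_equal(rk$gene_id, c("a", "c", "d", "b")) # desc metric, ties by id
  expect_equal(rk$metric, sort(rk$metric, decreasing = TRUE))

  # the floor keeps extreme p finite
  tiny <- rank_metric(tibble::tibble(gene_id = "x", log2_fold_change = 1,
                                     p_value = 1e-320), p_floor = 1e-300)
  expect_equal(tiny$metric, 300)

  de$p_value[1] <- NA
  expect_message(rk2 <- rank_metric(de), "excluding 1")
  expect_false("a" %in% rk2$gene_id)
})

test_that("enrichment score handles the textbook extremes", {
  rk <- ranking_from(c(3, 2, 1, -1, -2))
  expect_equal(enrichment_score(rk, rk$gene_id[1])$es, 1)

  bottom <- enrichment_score(rk, rk$gene_id[5])
  expect_lt(bottom$es, 0)

  expect_error(enrichment_score(rk, "nope"), "no genes")
  expect_error(enrichment_score(rk, rk$gene_id), "covers")

  run <- enrichment_score(rk, rk$gene_id[c(1, 2)])$running_sum
  expect_length(run, 5)
  expect_true(all(abs(run) <= 1 + 1e-12))
})

test_that("enrichment score equals the exhaustive prefix oracle", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(4:12, 1))
    metrics <- withr::with_seed(seed + 1000, round(rnorm(n, 0, 2), 3))
    rk <- ranking_from(metrics, ids = sprintf("z%02d", seq_len(n)))
    k <- withr::with_seed(seed + 2000, sample(seq_len(n - 1), 1))
    genes <- withr::with_seed(seed + 3000, sample(rk$gene_id, k))
    hit <- rk$gene_id %in% genes
    for (w in c(0, 1, 2)) {
      expect_equal(enrichment_score(rk, genes, weight_exponent = w)$es,
                   oracle_es(rk$metric, hit, w), tolerance = 1e-12)
    }
    # weight 0 reduces to the classic unweighted KS statistic
    expect_equal(enrichment_score(rk, genes, weight_exponent = 0)$es,
                 oracle_es_unweighted(hit), tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  for (seed in 1:20) {
    n <- 60
    metrics <- withr::with_seed(seed, rnorm(n, 0, 2))
    rk <- ranking_from(metrics, ids = sprintf("q%03d", seq_len(n)))
    genes <- withr::with_seed(seed + 10, sample(rk$gene_id, 8))
    ours <- enrichment_score(rk, genes, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(rk$metric, rk$gene_id),
                               selectedStats = which(rk$gene_id %in% genes),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("negating metrics and reversing the ranking negates the score", {
  for (seed in 1:10) {
    metrics <- withr::with_seed(seed, rnorm(15, 0, 2))
    rk <- ranking_from(metrics, ids = sprintf("r%02d", 1:15))
    genes <- withr::with_seed(seed + 30, sample(rk$gene_id, 4))
    neg <- tibble::tibble(gene_id = rk$gene_id, metric = -rk$metric)
    expect_equal(enrichment_score(neg, genes)$es,
                 -enrichment_score(rk, genes)$es, tolerance = 1e-12)
  }
})

test_that("preranked GSEA is deterministic and internally consistent", {
  de <- null_de(600, seed = 31)
  rk <- rank_metric(de)
  cat <- random_catalog(rk$gene_id, n_sets = 12, size_range = c(10, 30),
                        seed = 32)
  a <- gsea_preranked(rk, cat, n_perm = 200, seed = 99)
  b <- gsea_preranked(rk, cat, n_perm = 200, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$nominal_p,
                         gsea_preranked(rk, cat, n_perm = 200, seed = 100)$nominal_p))

  # the observed ES in the result equals the standalone scorer
  for (i in seq_len(nrow(cat))) {
    expect_equal(a$es[a$set_name == cat$set_name[i]],
                 enrichment_score(rk, cat$genes[[i]])$es, tolerance = 1e-12)
  }
  expect_true(all(abs(a$es) <= 1))
  expect_true(all(a$nominal_p > 0 & a$nominal_p <= 1))
  expect_true(all(a$fdr_q >= 0 & a$fdr_q <= 1))
})

test_that("an extreme top-of-ranking set is significantly enriched", {
  de <- null_de(500, seed = 41)
  rk <- rank_metric(de)
  stopifnot(rk$metric[5] > 0)
  cat <- tibble::tibble(set_name = "topk", description = "", collection = "t",
                        genes = list(rk$gene_id[1:5]))
  res <- gsea_preranked(rk, cat, n_perm = 1000, seed = 7)
  expect_gt(res$nes, 0)
  expect_lte(res$nominal_p, 0.05)
})

test_that("sets without usable genes are skipped with a message", {
  rk <- ranking_from(c(2, 1, -1, -2), ids = c("a", "b", "c", "d"))
  cat <- tibble::tibble(set_name = c("ok", "ghost"), description = "",
                        collection = "t",
                        genes = list(c("a", "c"), c("x", "y")))
  expect_message(res <- gsea_preranked(rk, cat, n_perm = 100, seed = 1),
                 "skipping")
  expect_equal(res$set_name, "ok")
})

test_that("the BH FDR alternative matches adjust_bh on nominal p", {
  de <- null_de(400, seed = 55)
  rk <- rank_metric(de)
  cat <- random_catalog(rk$gene_id, n_sets = 10, size_range = c(10, 20),
                        seed = 56)
  res <- gsea_preranked(rk, cat, n_perm = 200, seed = 5, fdr_method = "bh")
  expect_equal(res$fdr_q, adjust_bh(res$nominal_p))
})

test_that("the any-timepoint FDR filter keeps whole set trajectories", {
  res <- tibble::tibble(
    set_name = rep(c("A", "B", "C"), each = 2),
    timepoint = rep(c("t1", "t2"), 3),
    n_genes_used = 10L, es = 0.5, nes = 1.5,
    nominal_p = 0.01,
    fdr_q = c(0.04, 0.9, 0.06, 0.06, 0.001, 0.2))
  kept <- filter_significant(res, q_max = 0.05)
  expect_setequal(unique(kept$set_name), c("A", "C"))
  expect_equal(nrow(kept), 4L) # both timepoints retained for each kept set
  expect_equal(nrow(filter_significant(res[0, ], 0.05)), 0L)

  # without a timepoint column: plain row filter
  flat <- filter_significant(dplyr::select(res, -"timepoint"), 0.05)
  expect_equal(nrow(flat), 2L)
})
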