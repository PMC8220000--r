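test_that("hypergeometric upper tail matches exact enumeration", {
  expect_equal(hypergeometric_upper_tail(0, 4, 5, 10), 1)
  # C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(hypergeometric_upper_tail(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeometric_upper_tail(5, 5, 5, 5), 1)
  expect_error(hypergeometric_upper_tail(6, 4, 5, 10), "inconsistent")
  # oracle: stats::phyper over a parameter sweep
  set.seed(3)
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeometric_upper_tail(k, n, K, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("upper and lower hypergeometric tails are inclusive-consistent", {
  # P(X >= k) + P(X <= k) = 1 + P(X = k)
  for (k in 0:4) {
    up <- hypergeometric_upper_tail(k, 4, 5, 10)
    lo <- sum(vapply(0:k, function(i) dhyper(i, 5, 5, 4), 0))
    expect_equal(up + lo, 1 + dhyper(k, 5, 5, 4), tolerance = 1e-12)
  }
})

test_that("Benjamini-Hochberg step-up is exact and order-invariant", {
  expect_equal(benjamini_hochberg(c(0.01, 0.04, 0.03, 0.5)),
               c(0.04, 0.05333333333, 0.05333333333, 0.5),
               tolerance = 1e-9)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(0.7), 0.7)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
  expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"))  # oracle
})

test_that("over-representation combines the test and correction", {
  universe <- LETTERS[1:20]
  sets <- gene_set_collection(list(hit = LETTERS[1:5], miss = LETTERS[16:20]))
  res <- over_representation(LETTERS[1:5], universe, sets)
  expect_equal(res$k, c(5L, 0L))
  expect_equal(res$p_value[1], 1 / choose(20, 5))
  expect_equal(res$p_value[2], 1)
  expect_true(res$significant[1] && !res$significant[2])
})

test_that("GSEA enrichment score has the classic KS anchors", {
  ranked <- data.frame(gene = c("A", "B", "C", "D"), score = c(4, 3, 2, 1))
  sets <- gene_set_collection(list(top = "A", bottom = "D"))
  res <- gsea_preranked(ranked, sets, weight_exponent = 0, n_perm = 100,
                        seed = 1)
  expect_equal(res$es[res$set_name == "top"], 1)  # full mass at rank 1
  # reversing the ranking negates the ES at exponent 0
  rev_ranked <- data.frame(gene = c("D", "C", "B", "A"), score = c(4, 3, 2, 1))
  res_rev <- gsea_preranked(rev_ranked, sets, weight_exponent = 0,
                            n_perm = 100, seed = 1)
  expect_equal(res_rev$es[res_rev$set_name == "top"],
               -res$es[res$set_name == "top"])
  expect_equal(res_rev$es[res_rev$set_name == "bottom"],
               -res$es[res$set_name == "bottom"])
})

test_that("GSEA invariants hold on random instances", {
  set.seed(7)
  genes <- sprintf("G%03d", 1:150)
  for (i in 1:5) {
    scores <- setNames(rnorm(150), genes)
    sets <- gene_set_collection(list(s1 = sample(genes, 12),
                                     s2 = sample(genes, 30)))
    for (w in c(0, 1)) {
      res <- gsea_preranked(scores, sets, weight_exponent = w, n_perm = 50,
                            seed = i)
      expect_true(all(res$es >= -1 & res$es <= 1))
      expect_true(all(res$nominal_p >= 1 / 51 & res$nominal_p <= 1))
      expect_true(all(sign(res$nes)[res$es != 0] == sign(res$es)[res$es != 0]))
      # leading edge is a subset of the set intersected with the universe
      le <- strsplit(res$leading_edge, "/")
      expect_true(all(le[[1]] %in% sets$s1), info = sprintf("iter %d w %d", i, w))
      expect_true(all(le[[2]] %in% sets$s2))
    }
  }
  # disjoint set skipped with a warning, not an error
  expect_warning(
    res <- gsea_preranked(setNames(rnorm(50), sprintf("G%03d", 1:50)),
                          gene_set_collection(list(ok = "G001", no = "XX")),
                          n_perm = 20, seed = 1),
    "disjoint")
  expect_equal(res$set_name, "ok")
})

test_that("a planted set on a strong signal ranking is significant", {
  cs <- simulate_cohorts(cohort_sim_config(n_genes = 300,
                                           n_signature_genes = 40,
                                           n_prognostic_genes = 0,
                                           n_samples = 100, n_cohorts = 1,
                                           latent_factor_loading = 0.7,
                                           seed = 13))
  co <- cs$cohorts[[1]]
  score <- signature_score(co, cs$signature_genes)
  ranking <- rank_genes(co$expression, reference_score = score)
  sets <- simulate_gene_sets(rownames(co$expression), cs$signature_genes,
                             set_size = 20, n_decoys = 8, seed = 13)
  res <- gsea_preranked(ranking, sets, n_perm = 1000, seed = 13)
  expect_lt(res$fdr_q[res$set_name == "planted"], 0.25)
  expect_gt(res$es[res$set_name == "planted"], 0)
})

test_that("gene ranking modes match direct formulas", {
  expr <- matrix(c(1, 2, 3, 4, 5,
                   5, 4, 3, 2, 1,
                   2, 2, 2, 2, 2,
                   1, 3, 2, 5, 4,
                   0, 1, 0, 1, 0), 5, byrow = TRUE,
                 dimnames = list(c("up", "down", "flat", "noisy", "binary"),
                                 sprintf("S%d", 1:5)))
  ref <- c(1, 2, 3, 4, 5)
  expect_warning(rk <- rank_genes(expr, reference_score = ref),
                 "zero-variance")
  expect_equal(rk$gene[1], "up")       # r = 1 with itself
  expect_equal(rk$score[1], 1)
  expect_equal(rk$score[rk$gene == "down"], -1)
  expect_equal(rk$score[rk$gene == "flat"], 0)
  expect_equal(rk$score[rk$gene == "noisy"],
               unname(cor(expr["noisy", ], ref)))
  # fold-change mode: high minus low group means
  groups <- c("low", "low", "high", "high", "high")
  fc <- rank_genes(expr, groups = groups)
  expect_equal(fc$score[fc$gene == "up"], mean(c(3, 4, 5)) - mean(c(1, 2)))
  expect_equal(fc$score[fc$gene == "flat"], 0)
})
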