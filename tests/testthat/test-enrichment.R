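test_that("ranking is descending with lexicographic tie-break, NOTEST dropped", {
  d <- data.frame(gene_id = c("A", "B", "C", "D"),
                  test_stat = c(2, -1, 2, 99),
                  status = c("OK", "OK", "OK", "NOTEST"))
  r <- rank_by_statistic(d)
  expect_equal(r$gene_id, c("A", "C", "B"))
  expect_error(rank_by_statistic(d[d$status == "NOTEST" & FALSE, ]), "OK-status")
  # against an independent sort oracle
  set.seed(17)
  d2 <- data.frame(gene_id = sprintf("g%03d", sample(100)),
                   test_stat = rnorm(100), status = "OK")
  r2 <- rank_by_statistic(d2)
  expect_equal(r2$test_stat, sort(d2$test_stat, decreasing = TRUE))
})

test_that("Mann-Whitney set test matches the small worked example", {
  res <- mannwhitney_set_test(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$U, 4)
  expect_equal(res$p, 1 / 3)
  expect_equal(res$method, "exact")
})

test_that("exact mode equals exhaustive permutation for small n", {
  set.seed(23)
  for (n in 4:10) {
    for (m in c(1, floor(n / 2), n - 1)) {
      vals <- rnorm(n)
      memb <- seq_len(n) %in% sample(n, m)
      got <- mannwhitney_set_test(vals, memb, method = "exact")
      expect_equal(got$p, mw_perm_p(vals, memb), tolerance = 1e-12)
      # and with heavy ties
      vals_t <- sample(1:3, n, replace = TRUE)
      got_t <- mannwhitney_set_test(vals_t, memb, method = "exact")
      expect_equal(got_t$p, mw_perm_p(vals_t, memb), tolerance = 1e-12)
    }
  }
})

test_that("exact mode agrees with wilcox.test on untied data", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    m <- sample(2:(n - 2), 1)
    vals <- rnorm(n)
    memb <- seq_len(n) %in% sample(n, m)
    got <- mannwhitney_set_test(vals, memb, method = "exact")
    ref <- suppressWarnings(wilcox.test(vals[memb], vals[!memb], exact = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact and normal modes converge for large samples", {
  set.seed(6)
  vals <- rnorm(220)
  memb <- seq_len(220) %in% sample(220, 40) # 40 * 180 = 7200 <= 10000
  pe <- mannwhitney_set_test(vals, memb, method = "exact")$p
  pn <- mannwhitney_set_test(vals, memb, method = "normal")$p
  expect_lt(abs(pe - pn), 0.02)
})

test_that("degenerate and extremal behaviour of the set test", {
  expect_equal(mannwhitney_set_test(rep(3, 10), rep(c(TRUE, FALSE), 5))$p, 1)
  vals <- 1:20
  p_tail <- mannwhitney_set_test(vals, vals >= 16)$p
  p_mid <- mannwhitney_set_test(vals, vals %in% 8:12)$p
  expect_lt(p_tail, p_mid)
})

test_that("set-test p-values are uniform under the null", {
  set.seed(12)
  ps <- vapply(1:1000, function(i) {
    vals <- rnorm(40)
    memb <- seq_len(40) %in% sample(40, 20)
    mannwhitney_set_test(vals, memb)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH correction follows the step-up rule", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(0.37), 0.37)
  expect_equal(bh_correct(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_correct(p)
    expect_equal(q, bh_step_up(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("set z-score: worked example, zero case, affine invariance", {
  expect_equal(set_zscore(c(0, 0, 0, 0, 10, 10),
                          c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)), 2)
  v <- rnorm(30)
  memb <- seq_len(30) %in% 1:7
  base <- set_zscore(v, memb)
  expect_equal(set_zscore(3.7 * v + 11, memb), base, tolerance = 1e-12)
  expect_equal(set_zscore(c(rep(5, 4), 5, 5), memb[1:6] ), NA_real_)
  expect_equal(set_zscore(v, rep(FALSE, 29) |> c(TRUE)) * 0, 0) # |set| = 1 works
})

test_that("gsea recovers a planted top-decile set and is order-invariant", {
  set.seed(41)
  genes <- sprintf("g%03d", 1:200)
  stat <- sort(rnorm(200), decreasing = TRUE)
  d <- data.frame(gene_id = genes, test_stat = stat, status = "OK")
  coll <- list(planted = genes[1:20],
               random = sample(genes, 25),
               tiny = genes[1:3],
               dup_of_planted = genes[1:20])
  res <- gsea(d, coll, q_threshold = 0.001, min_set_size = 5)
  expect_true(res$significant[res$set == "planted"])
  expect_equal(res$direction[res$set == "planted"], 1)
  expect_equal(res$reason[res$set == "tiny"], "too_few_mapped_members")
  expect_true(is.na(res$q[res$set == "tiny"]))
  # duplicate set under two names: identical statistics
  expect_equal(res[res$set == "planted", c("U", "p", "z")],
               res[res$set == "dup_of_planted", c("U", "p", "z")],
               ignore_attr = TRUE)
  # invariance to collection order and to diff-table row order
  res_shuf <- gsea(d[sample(200), ], rev(coll))
  for (s in names(coll)) {
    expect_equal(res_shuf$p[res_shuf$set == s], res$p[res$set == s])
    expect_equal(res_shuf$q[res_shuf$set == s], res$q[res$set == s])
  }
  expect_error(gsea(d, list(nohit = c("zz1", "zz2"))), "min_set_size")
})

test_that("gba recovers a planted module and rejects degenerate focals", {
  members <- sprintf("gene%05d", 1:15)
  m <- gen_expression_compendium(
    n_genes = 120, n_samples = 100,
    planted = list(focal = "lincX", members = members, r = 0.9),
    noise_sd = 1, seed = 5)
  coll <- list(planted = members,
               decoy1 = sprintf("gene%05d", 20:40),
               decoy2 = sprintf("gene%05d", 50:90))
  res <- gba(m, "lincX", coll)
  e <- res$enrichment
  expect_true(e$significant[e$set == "planted"])
  expect_equal(e$set[which.min(e$p)], "planted")
  expect_true(all(res$profile$r >= -1 & res$profile$r <= 1))
  expect_false("lincX" %in% res$profile$gene_id)

  # an independent focal profile should find nothing at p < 1e-6
  m0 <- gen_expression_compendium(n_genes = 120, n_samples = 100, seed = 6)
  m0 <- rbind(m0, lincY = pmax(0, rnorm(100, 100, 20)))
  attr(m0, "biotype") <- c(attr(gen_expression_compendium(n_genes = 120,
                                                          n_samples = 100,
                                                          seed = 6), "biotype"),
                           lincY = "lincRNA")
  res0 <- gba(m0, "lincY", coll)
  expect_false(any(res0$enrichment$significant, na.rm = TRUE))

  mc <- m
  mc["lincX", ] <- 5
  expect_error(gba(mc, "lincX", coll), "zero-variance")
})
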