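test_that("annotation overlap excludes any-overlap, keeps half-open abutment", {
  cand <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                     start = c(100, 100), end = c(200, 200))
  ann <- data.frame(chrom = "chr1", start = c(150, 200), end = c(160, 300),
                    biotype = "coding")
  part <- filter_annotation_overlap(cand[1, ], ann[1, ])
  expect_equal(part$excluded$gene_id, "a")
  part2 <- filter_annotation_overlap(cand[2, ], ann[2, ])
  expect_equal(part2$kept$gene_id, "b") # [100,200) abuts [200,300): no overlap
  # lncRNA annotations never exclude
  lnc <- data.frame(chrom = "chr1", start = 100, end = 200, biotype = "lincRNA")
  expect_equal(nrow(filter_annotation_overlap(cand, lnc)$excluded), 0)
  expect_error(
    filter_annotation_overlap(
      data.frame(gene_id = "x", chrom = "chrZ", start = 0, end = 10), ann),
    "chrZ")
})

test_that("annotation overlap matches a brute-force all-pairs oracle", {
  set.seed(31)
  cand <- data.frame(gene_id = sprintf("c%02d", 1:50),
                     chrom = sample(c("chr1", "chr2"), 50, TRUE),
                     start = sample(0:5000, 50))
  cand$end <- cand$start + sample(50:500, 50, TRUE)
  ann <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                    start = sample(0:5000, 40), biotype = "coding")
  ann$end <- ann$start + sample(20:800, 40, TRUE)
  oracle_excluded <- vapply(seq_len(nrow(cand)), function(i) {
    any(vapply(seq_len(nrow(ann)), function(j) {
      cand$chrom[i] == ann$chrom[j] &&
        cand$start[i] < ann$end[j] && ann$start[j] < cand$end[i]
    }, logical(1)))
  }, logical(1))
  part <- filter_annotation_overlap(cand, ann,
                                    chrom_sizes = c(chr1 = 6000, chr2 = 6000))
  expect_setequal(part$excluded$gene_id, cand$gene_id[oracle_excluded])
  expect_setequal(part$kept$gene_id, cand$gene_id[!oracle_excluded])
})

test_that("CSF filter is strictly below the threshold", {
  cand <- make_candidates()
  part <- filter_csf(cand)
  expect_true(all(c("linc1", "linc2", "linc4", "linc6") %in% part$kept$gene_id))
  expect_true("linc3" %in% part$excluded$gene_id) # exactly -200: excluded
  expect_equal(part$excluded$reason[part$excluded$gene_id == "linc5"],
               "no_score")
})

test_that("mass-spec filter keeps <= 2 tags and rejects negative counts", {
  cand <- make_candidates()
  part <- filter_masspec(cand)
  expect_setequal(part$excluded$gene_id, "linc4") # 3 tags
  expect_true(all(part$kept$masspec_tags <= 2))
  cand$masspec_tags[1] <- -1
  expect_error(filter_masspec(cand), "negative")
})

test_that("selection cascade short-circuits traces but not membership", {
  cand <- make_candidates()
  ann <- data.frame(chrom = "chr1", start = 110, end = 130, biotype = "coding")
  res <- run_selection_pipeline(cand, ann,
                                config = list(chrom_sizes = c(chr1 = 1e6)))
  # linc1 overlaps the annotation: one trace entry, later filters unevaluated
  expect_equal(res$filter_trace[res$gene_id == "linc1"], "annotation:fail")
  expect_equal(res$fail_stage[res$gene_id == "linc1"], "annotation")
  # linc3 fails CSF at the boundary: trace stops there
  expect_equal(res$filter_trace[res$gene_id == "linc3"],
               "annotation:pass;csf:fail")
  # linc2 passes everything: full 5-entry trace
  expect_equal(res$filter_trace[res$gene_id == "linc2"],
               "annotation:pass;csf:pass;masspec:pass;rrs:pass;flags:pass")
  expect_true(res$kept[res$gene_id == "linc2"])
  expect_false(res$kept[res$gene_id == "linc6"]) # no human synteny

  # cascade membership equals the intersection of individual filters
  keep_ann <- filter_annotation_overlap(cand, ann,
                                        chrom_sizes = c(chr1 = 1e6))$kept$gene_id
  keep_csf <- filter_csf(cand)$kept$gene_id
  keep_ms <- filter_masspec(cand)$kept$gene_id
  keep_flags <- cand$gene_id[cand$has_human_synteny & cand$has_k4me3_k36me3]
  expect_setequal(res$gene_id[res$kept],
                  Reduce(intersect, list(keep_ann, keep_csf, keep_ms, keep_flags)))

  # attrition sums: kept + excluded per stage = stage input
  att <- attr(res, "attrition")
  expect_equal(att$n_kept + att$n_excluded, att$n_in)
  expect_equal(att$n_in[1], nrow(cand))
  expect_equal(att$n_in[-1], att$n_kept[-nrow(att)])
})

test_that("RRS screen flags coding-like candidates against a reference", {
  cand <- make_candidates()[2:3, ]
  cand$csf_score <- -300
  ann <- data.frame(chrom = "chr1", start = 0, end = 1, biotype = "coding")
  rrs <- data.frame(gene_id = c("linc2", "linc3"), max_rrs = c(0.8, 50))
  coding_ref <- c(5, 8, 10, 20, 30, 40) # 5th percentile ~ 5.75
  res <- run_selection_pipeline(cand, ann, rrs_results = rrs,
                                config = list(coding_rrs = coding_ref,
                                              chrom_sizes = c(chr1 = 1e6)))
  expect_true(res$kept[res$gene_id == "linc2"])
  expect_equal(res$fail_stage[res$gene_id == "linc3"], "rrs")
  expect_error(
    run_selection_pipeline(cand, ann,
                           rrs_results = data.frame(gene_id = "linc2",
                                                    max_rrs = 1)),
    "linc3")
})

test_that("temporal induction filter reproduces exhaustive evaluation", {
  tc <- data.frame(
    gene_id = rep(paste0("g", 1:6), each = 3),
    contrast = rep(c("adjacent", "adjacent", "vs_day0"), 6),
    q = c(0.005, 0.5, 0.004,   # g1: adjacent sig, induced
          0.005, 0.5, 0.004,   # g2: adjacent sig, repressed vs day0
          0.5, 0.5, 0.004,     # g3: not adjacent-significant
          0.009, 0.009, 0.5,   # g4: adjacent sig, day0 not significant
          0.5, 0.5, 0.5,       # g5: nothing
          0.001, 0.001, 0.001),# g6: everything, induced
    direction = c(1, 1, 1, 1, 1, -1, 1, 1, 1, 1, 1, 1, 1, 1, 1, -1, 1, 1))
  res <- temporal_induction_filter(tc)
  expect_setequal(res$de_any_adjacent, c("g1", "g2", "g4", "g6"))
  expect_setequal(res$induced_vs_day0, c("g1", "g6"))
  expect_true(all(res$induced_vs_day0 %in% res$de_any_adjacent))
  tc$contrast[1] <- "weird"
  expect_error(temporal_induction_filter(tc), "unlabelled")
})
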