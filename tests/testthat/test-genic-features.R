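# Gene-body masking, feature/class summaries, spinograms, ortholog matrices.

test_that("promoters are strand-aware around the TSS", {
  genes <- gene_models(c("p", "m"), "chr1", c("+", "-"), c(5000, 20000),
                       c(9000, 26000))
  pr <- promoter_intervals(genes)
  plus <- pr[pr$gene_id == "p", ]
  minus <- pr[pr$gene_id == "m", ]
  expect_equal(c(plus$start, plus$end), c(4000, 5100))
  expect_equal(c(minus$start, minus$end), c(25900, 27000))
})

test_that("gene-body means mask promoters and islands exactly", {
  # toy gene with 25 informative CpGs, 5 inside an island, promoter overlaps
  # the first 100 bp of the body
  genes <- gene_models("g1", "chr1", "+", 10000, 20000)
  pos <- seq(13000, 19650, by = 350)      # 20 CpGs clear of the island
  isl_pos <- seq(12000, 12400, by = 100)  # 5 CpGs inside it
  cgis <- genomic_intervals("chr1", 11990, 12410, "cpg_island")
  all_pos <- sort(c(pos, isl_pos))
  meth <- as.integer(all_pos %% 7 %in% 0:3)
  calls <- cpg_calls("chr1", all_pos, meth, 1)
  gbm <- gene_body_methylation(calls, genes, cgis = cgis, min_cpgs = 20)
  keep <- !(all_pos >= 11990 & all_pos < 12410)
  expect_equal(nrow(gbm), 1L)
  expect_equal(gbm$n_cpgs, 20L)
  expect_equal(gbm$meth, mean(meth[keep]))
  expect_equal(gbm$masked_bp, 420 + 100)  # island span + promoter overlap

  # a gene whose only CpGs sit in its promoter is omitted
  g2 <- gene_models("g2", "chr1", "+", 10000, 20000)
  calls2 <- cpg_calls("chr1", seq(10000, 10090, by = 10), 1, 2)
  gbm2 <- gene_body_methylation(calls2, g2, min_cpgs = 5)
  expect_equal(nrow(gbm2), 0L)
  expect_equal(attr(gbm2, "n_omitted"), 1L)

  # masking soundness: exhaustive check that no masked CpG contributes
  bund <- demo_small()
  gb <- gene_body_methylation(bund$methylome$calls, bund$genome$genes,
                              cgis = bund$genome$islands)
  calls <- bund$methylome$calls
  pr <- promoter_intervals(bund$genome$genes)
  set.seed(114)
  for (i in sample(nrow(gb), 10)) {
    g <- bund$genome$genes[bund$genome$genes$gene_id == gb$gene_id[i], ]
    p <- pr[pr$gene_id == g$gene_id, ]
    sel <- calls$chrom == g$chrom & calls$pos >= g$tx_start &
      calls$pos < g$tx_end & !is.na(calls$fraction)
    in_p <- calls$pos >= p$start & calls$pos < p$end
    in_i <- pmeth:::points_in_intervals(calls$chrom, calls$pos,
                                        bund$genome$islands)
    keep <- sel & !in_p & !in_i
    expect_equal(gb$meth[i], mean(calls$fraction[keep]))
    expect_equal(gb$n_cpgs[i], sum(keep))
  }
})

test_that("feature and class summaries match direct recomputation", {
  set.seed(111)
  pos <- sort(sample(1e5, 800))
  calls <- cpg_calls("chr1", pos, rbinom(800, 4, 0.6), 4)
  feats <- genomic_intervals("chr1",
                             c(0, 2e4, 4e4, 6e4, 9.9e4),
                             c(1e4, 3e4, 5e4, 7e4, 9.95e4),
                             c("repeat:LINE", "repeat:SINE", "repeat:LINE",
                               "cpg_island", "repeat:LTR"))
  fm <- feature_methylation(calls, feats, min_cpgs = 10)
  # per-feature: brute force each retained row
  for (i in seq_len(nrow(fm$per_feature))) {
    r <- fm$per_feature[i, ]
    sel <- calls$pos >= r$start & calls$pos < r$end
    expect_equal(r$meth, mean(calls$fraction[sel]))
  }
  # features under the CpG minimum are excluded
  expect_false(any(fm$per_feature$n_cpgs < 10))
  # class pools equal direct site pooling; complement covers the rest
  line_sel <- (calls$pos < 1e4) | (calls$pos >= 4e4 & calls$pos < 5e4)
  expect_equal(fm$per_class$meth[fm$per_class$label == "repeat:LINE"],
               mean(calls$fraction[line_sel]))
  rep_sel <- line_sel | (calls$pos >= 2e4 & calls$pos < 3e4) |
    (calls$pos >= 9.9e4 & calls$pos < 9.95e4)
  expect_equal(fm$per_class$meth[fm$per_class$label == "non-repetitive"],
               mean(calls$fraction[!rep_sel]))
  # permutation invariance in feature order (constructor restores sorting)
  shuf <- feats[sample(nrow(feats)), ]
  fm2 <- feature_methylation(calls, genomic_intervals(shuf$chrom, shuf$start,
                                                      shuf$end, shuf$label),
                             min_cpgs = 10)
  expect_equal(fm$per_feature, fm2$per_feature)
  expect_equal(fm$per_class[order(fm$per_class$label), ],
               fm2$per_class[order(fm2$per_class$label), ],
               ignore_attr = TRUE)
})

test_that("spinograms conserve counts and separate planted classes", {
  # complete separation: genic windows ~80%, intergenic ~20%
  set.seed(112)
  n <- 400
  genic <- rep(c(TRUE, FALSE), each = n / 2)
  means <- ifelse(genic, rnorm(n, 0.80, 0.01), rnorm(n, 0.20, 0.01))
  tr <- track_from_means(means, window_size = 5000)
  genes <- gene_models("g1", "chr1", "+", 0, (n / 2) * 5000)
  sp <- genic_spinogram(tr, genes)
  expect_equal(sum(sp$count), n)
  expect_equal(sum(sp$count * sp$p_genic, na.rm = TRUE), sum(genic))
  expect_equal(sp$p_genic[sp$bin_lo == 75], 1.0)
  expect_equal(sp$p_genic[sp$bin_lo == 20], 0.0)
  expect_equal(sum(sp$fraction), 1)
  # empty bins are reported with count 0 and undefined probability
  expect_true(any(sp$count == 0 & is.na(sp$p_genic)))
})

test_that("ortholog matrices equal an independent join", {
  set.seed(113)
  ids_a <- sprintf("hA%02d", 1:50)
  ids_b <- sprintf("mB%02d", 1:50)
  gbm_a <- structure(data.frame(gene_id = ids_a, meth = runif(50),
                                n_cpgs = 30L, masked_bp = 0),
                     class = c("gene_body_methylation", "data.frame"))
  keep_b <- sort(sample(50, 40))
  gbm_b <- structure(data.frame(gene_id = ids_b[keep_b],
                                meth = runif(40), n_cpgs = 25L,
                                masked_bp = 0),
                     class = c("gene_body_methylation", "data.frame"))
  ot <- data.frame(gene_id_a = ids_a, gene_id_b = ids_b)
  ot <- ot[sample(50), ]                      # shuffled id order
  mat <- build_ortholog_matrix(list(human = gbm_a, mouse = gbm_b),
                               list(mouse = ot))
  expect_equal(nrow(mat), 40L)                # rows need >= 2 species
  for (i in sample(40, 5)) {
    hid <- rownames(mat)[i]
    mid <- ot$gene_id_b[ot$gene_id_a == hid]
    expect_equal(mat[i, "human"], gbm_a$meth[gbm_a$gene_id == hid])
    expect_equal(mat[i, "mouse"], gbm_b$meth[gbm_b$gene_id == mid])
  }
  # duplicate orthologs resolve to the better-covered entry
  dup <- rbind(ot, data.frame(gene_id_a = ot$gene_id_a[1],
                              gene_id_b = gbm_b$gene_id[1]))
  gbm_b$n_cpgs[1] <- 999L
  expect_message(m2 <- build_ortholog_matrix(
    list(human = gbm_a, mouse = gbm_b), list(mouse = dup)), "duplicate")
  expect_equal(m2[ot$gene_id_a[1], "mouse"], gbm_b$meth[1])
})

test_that("identical methylomes through identity orthology give equal columns", {
  gbm <- structure(data.frame(gene_id = c("a", "b", "c"),
                              meth = c(0.2, 0.5, 0.8), n_cpgs = 30L,
                              masked_bp = 0),
                   class = c("gene_body_methylation", "data.frame"))
  ot <- data.frame(gene_id_a = c("a", "b", "c"),
                   gene_id_b = c("a", "b", "c"))
  mat <- build_ortholog_matrix(list(s1 = gbm, s2 = gbm), list(s2 = ot))
  expect_equal(mat[, 1], mat[, 2])
})
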