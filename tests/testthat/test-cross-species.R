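# Lifting, synteny cleaning, scaling, differential regions, break enrichment.

identity_chain <- function(len = 1000, chrom = "chrA") {
  structure(list(structure(list(
    id = "1", score = len, s_chrom = chrom, s_size = len, s_start = 0,
    s_end = len, t_chrom = chrom, t_size = len, strand = "+",
    t_start = 0, t_end = len,
    blocks = data.frame(s_start = 0, s_end = len, t_start = 0,
                        t_end = len)), class = "chain")),
    class = "chain_set")
}

test_that("identity chains map sites to themselves; gaps are unmapped", {
  calls <- cpg_calls("chrA", c(5, 50, 500), 1, 2)
  lt <- lift_cpgs(calls, identity_chain())
  expect_equal(lt$calls$pos, c(5, 50, 500))
  expect_equal(lt$n_mapped + lt$n_unmapped, lt$n_input)
  expect_equal(lt$n_unmapped, 0L)

  # a chain with an interior gap leaves in-gap sites unmapped
  tf <- tempfile()
  writeLines(c("chain 100 chrA 1000 + 0 500 chrB 1000 + 0 400 1",
               "200 100 0", "200", ""), tf)
  gaps <- read_chain(tf)
  calls <- cpg_calls("chrA", c(100, 250, 400), 1, 2)
  lt <- lift_cpgs(calls, gaps)
  expect_equal(lt$n_unmapped, 1L)           # pos 250 sits in the dt gap
  expect_equal(lt$calls$source_pos, c(100, 400))
  expect_equal(lt$calls$pos, c(100, 300))
})

test_that("target collisions resolve by chain score then source position", {
  ch <- identity_chain(1000)
  shifted <- structure(list(
    id = "2", score = 500, s_chrom = "chrA", s_size = 1000, s_start = 100,
    s_end = 200, t_chrom = "chrA", t_size = 1000, strand = "+",
    t_start = 0, t_end = 100,
    blocks = data.frame(s_start = 100, s_end = 200, t_start = 0,
                        t_end = 100)), class = "chain")
  both <- structure(c(ch, list(shifted)), class = "chain_set")
  # source 150 maps to 150 via the high-score chain, not 50 via the low one;
  # sources 50 and 150 would collide at 50 under the low-score chain only
  calls <- cpg_calls("chrA", c(50, 150), c(1, 2), c(2, 2))
  lt <- lift_cpgs(calls, both)
  expect_equal(lt$calls$pos, c(50, 150))
  expect_equal(lt$calls$meth_reads, c(1, 2))
})

test_that("synteny cleaning removes only small level-2 fills, monotonically", {
  calls <- cpg_calls("chr1", c(1e5, 6e5, 2e6, 5e6), 1, 2)
  lt <- lift_cpgs(calls, identity_chain(1e7, "chr1"))
  blocks <- synteny_blocks(rep("chr1", 3), c(0, 5e5, 1.5e6),
                           c(5e5, 1e6, 4.5e6), c(2L, 2L, 1L))
  # block 1: level 2, 0.5 Mb -> removed; block 2: level 2, 0.5 Mb -> removed;
  # block 3: level 1 (any size) -> retained
  cl <- clean_by_synteny(lt, blocks)
  expect_equal(cl$calls$pos, c(2e6, 5e6))
  expect_equal(cl$n_removed, 2L)
  expect_equal(cl$n_mapped + cl$n_removed + cl$n_unmapped, cl$n_input)
  # raising the threshold never removes fewer sites
  removed <- vapply(c(1e5, 5e5, 1e6, 5e6), function(thr)
    clean_by_synteny(lt, blocks, thr)$n_removed, numeric(1))
  expect_true(all(diff(removed) >= 0))
  expect_equal(clean_by_synteny(lt, blocks[0, ])$n_removed, 0L)
})

test_that("scale_track is an exact affine with the target moments", {
  x <- c(0.2, 0.5, 0.9, NA, 0.4)
  self <- scale_track(x, mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
  expect_equal(self, x)
  y <- scale_track(x, 0, 1)
  expect_equal(mean(y, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(y, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_error(scale_track(rep(0.5, 10), 0, 1), "SD")
})

test_that("differential regions: exact nulls and location invariance", {
  set.seed(81)
  a <- track_from_means(pmin(pmax(rnorm(200, 0.7, 0.03), 0), 1))
  expect_equal(nrow(differential_regions(a, a)), 0L)
  b <- a
  b$mean_meth <- pmin(a$mean_meth + 0.05, 1)
  expect_equal(nrow(differential_regions(a, b)), 0L)
  short <- track_from_means(rnorm(20, 0.7, 0.03))
  expect_error(differential_regions(short, short), "30")
})

test_that("a planted depression is recovered as one region of right sign", {
  set.seed(82)
  base <- rep(0.7, 500)
  a <- track_from_means(pmin(pmax(rnorm(500, base, 0.03), 0), 1))
  base[200:219] <- base[200:219] - 0.25          # 400 kb depression
  b <- track_from_means(pmin(pmax(rnorm(500, base, 0.03), 0), 1))
  regs <- differential_regions(a, b)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$direction, "higher-in-reference")
  planted <- c(199 * 20000, 220 * 20000)
  ov <- min(regs$end, planted[2]) - max(regs$start, planted[1])
  expect_gte(ov / (planted[2] - planted[1]), 0.8)
  expect_gte(ov / (regs$end - regs$start), 0.8)
})

test_that("synteny breaks derive from large-fill junctions only", {
  blocks <- synteny_blocks(rep("chr1", 4), c(0, 4e6, 5e6, 5.2e6),
                           c(4e6, 5e6, 5.2e6, 9e6), c(1L, 2L, 2L, 1L))
  # the 1 Mb level-2 block is not > 1 Mb, the 0.2 Mb one neither:
  # retained blocks are the two level-1 fills -> one junction at 4e6
  br <- synteny_breaks(blocks)
  expect_equal(br$pos, 4e6)
  blocks2 <- synteny_blocks(rep("chr1", 2), c(0, 4e6), c(4e6, 5.5e6),
                            c(1L, 2L))
  expect_equal(synteny_breaks(blocks2)$pos, 4e6)  # 1.5 Mb level-2 retained
})

test_that("break enrichment reports exact trivial fractions", {
  spans <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  breaks <- data.frame(chrom = "chr1", pos = c(1e5, 5e5, 9e5))
  all_regions <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  be <- break_enrichment(breaks, all_regions, spans, n_perm = 100, seed = 2)
  expect_equal(be$observed, 1)
  none <- all_regions[0, ]
  be0 <- break_enrichment(breaks, none, spans, n_perm = 100, seed = 2)
  expect_equal(be0$observed, 0)
  expect_equal(be0$p, 1)
  na <- break_enrichment(breaks[0, ], all_regions, spans, n_perm = 100,
                         seed = 2)
  expect_false(na$applicable)
})

test_that("lift conservation and inverse round trip hold on species pairs", {
  g <- simulate_genome(genome_spec(chrom_lengths = c(chr1 = 2e6),
                                   n_genes = 20, n_islands = 30), seed = 91)
  ms <- simulate_methylome(g, methylome_spec(), seed = 92)
  re <- data.frame(chrom = "chr1", start = c(5e5, 1.5e6),
                   end = c(7e5, 1.55e6), type = c("inversion", "deletion"))
  sp <- simulate_species_pair(g, ms, rearrangements = re, seed = 93)
  lt <- lift_cpgs(sp$calls2, sp$chain_rev)
  expect_equal(lt$n_mapped + lt$n_unmapped + lt$n_removed, lt$n_input)
  # forward then inverse returns every mapped site to its origin
  calls1 <- ms$calls
  fwd <- lift_cpgs(calls1, sp$chain_fwd)
  back <- lift_cpgs(fwd$calls, sp$chain_rev)
  expect_equal(back$n_unmapped, 0L)
  idx <- match(back$calls$source_pos, fwd$calls$pos)
  expect_false(anyNA(idx))
  expect_equal(back$calls$pos, fwd$calls$source_pos[idx])
})
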