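# The generators: determinism, rate/moment recovery, planted structure, and
# validity of the emitted formats.

test_that("generators are byte-identical under a fixed seed", {
  gs <- genome_spec(chrom_lengths = c(chr1 = 1e6), n_genes = 15,
                    n_islands = 20)
  g1 <- simulate_genome(gs, seed = 131)
  g2 <- simulate_genome(gs, seed = 131)
  expect_identical(g1, g2)
  m1 <- simulate_methylome(g1, methylome_spec(), seed = 132)
  m2 <- simulate_methylome(g2, methylome_spec(), seed = 132)
  expect_identical(m1, m2)
  s1 <- simulate_species_pair(g1, m1, seed = 133)
  s2 <- simulate_species_pair(g2, m2, seed = 133)
  expect_identical(s1, s2)
  # and a different seed changes the draw
  expect_false(identical(simulate_genome(gs, seed = 134)$cpgs, g1$cpgs))
})

test_that("island CpG enrichment recovers the requested rate ratio", {
  gs <- genome_spec(chrom_lengths = c(chr1 = 5e6), n_genes = 50,
                    n_islands = 200, island_enrichment = 10)
  g <- simulate_genome(gs, seed = 141)
  in_isl <- pmeth:::points_in_intervals(g$cpgs$chrom, g$cpgs$pos, g$islands)
  isl_bp <- sum(g$islands$end - g$islands$start)
  rate_in <- sum(in_isl) / isl_bp
  rate_out <- sum(!in_isl) / (5e6 - isl_bp)
  expect_equal(rate_in / rate_out, 10, tolerance = 0.2)
})

test_that("feature packing is validated and zero-gene genomes work", {
  expect_error(simulate_genome(genome_spec(chrom_lengths = c(chr1 = 1e5),
                                           n_genes = 50), seed = 1),
               "infeasible")
  g0 <- simulate_genome(genome_spec(chrom_lengths = c(chr1 = 2e6),
                                    n_genes = 0, n_islands = 10), seed = 142)
  expect_equal(nrow(g0$genes), 0L)
  ms <- simulate_methylome(g0, methylome_spec(), seed = 143)
  w5 <- window_methylation(ms$calls, 5000, 10,
                           chrom_lengths = g0$chrom_lengths)
  sp <- genic_spinogram(w5, g0$genes)
  expect_equal(attr(sp, "genic_fraction"), 0)
})

test_that("observed calls converge to true fractions at deep coverage", {
  g <- simulate_genome(genome_spec(chrom_lengths = c(chr1 = 1e6),
                                   n_genes = 10, n_islands = 10), seed = 151)
  ms <- simulate_methylome(g, methylome_spec(coverage_mean = 10000,
                                             coverage_dispersion = Inf),
                           seed = 152)
  rms <- sqrt(mean((ms$calls$fraction - ms$truth$true)^2))
  expect_lt(rms, 0.01)
})

test_that("per-domain site fractions recover the spec means", {
  # clean genome (no island/gene overlays): per-domain mean of the true
  # site fractions must match the truncated-Gaussian expectation to 3 SE
  g <- simulate_genome(genome_spec(chrom_lengths = c(chr1 = 4e6),
                                   n_genes = 0, n_islands = 0), seed = 181)
  ms <- simulate_methylome(g, methylome_spec(), seed = 182)
  trunc_mean <- function(mu, s) {
    a <- (0 - mu) / s; b <- (1 - mu) / s
    mu + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  d <- ms$domains
  k <- findInterval(ms$truth$pos, d$start)
  for (st in c("PMD", "HMD")) {
    sel <- d$state[k] == st
    mu0 <- if (st == "PMD") 0.40 else 0.80
    expected <- trunc_mean(mu0, ms$spec$site_noise_sd)
    se <- sd(ms$truth$true[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(ms$truth$true[sel]) - expected), 3 * se)
  }
})

test_that("emitted files are valid inputs to every reader", {
  g <- simulate_genome(genome_spec(chrom_lengths = c(chr1 = 1e6),
                                   n_genes = 15, n_islands = 20), seed = 161)
  ms <- simulate_methylome(g, methylome_spec(), seed = 162)
  sp <- simulate_species_pair(g, ms,
                              level2_blocks = data.frame(chrom = "chr1",
                                                         start = 4e5,
                                                         end = 6e5),
                              seed = 163)
  td <- withr::local_tempdir()
  f <- function(x) file.path(td, x)
  write_cpg_track(ms$calls, f("calls.tsv"))
  expect_equal(nrow(read_cpg_track(f("calls.tsv"))), nrow(ms$calls))
  write_genes(g$genes, f("genes.bed"))
  expect_equal(nrow(read_genes(f("genes.bed"))), nrow(g$genes))
  write_intervals(g$islands, f("cgi.bed"))
  expect_equal(read_intervals(f("cgi.bed"))$start, g$islands$start)
  write_expression(ms$expression, f("expr.tsv"))
  expect_equal(read_expression(f("expr.tsv"))$fpkm, ms$expression$fpkm)
  write_synteny(sp$synteny, f("synteny.tsv"))
  expect_equal(read_synteny(f("synteny.tsv"))$level, sp$synteny$level)
  write_chain(sp$chain_fwd, f("pair.chain"))
  ch <- read_chain(f("pair.chain"))
  # generated chains lift every site in unrearranged spans
  lt <- lift_cpgs(ms$calls, ch)
  expect_equal(lt$n_unmapped, 0L)
})

test_that("overlapping rearrangements are rejected", {
  g <- simulate_genome(genome_spec(chrom_lengths = c(chr1 = 1e6),
                                   n_genes = 5, n_islands = 5), seed = 171)
  ms <- simulate_methylome(g, methylome_spec(), seed = 172)
  re <- data.frame(chrom = "chr1", start = c(1e5, 1.5e5), end = c(2e5, 3e5),
                   type = c("inversion", "deletion"))
  expect_error(simulate_species_pair(g, ms, rearrangements = re, seed = 1),
               "overlapping")
})
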