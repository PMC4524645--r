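# synthetic_data: deterministic generators for genomes, methylomes, species
# pairs (chain maps, synteny tables, planted differential regions) and
# per-gene expression datasets. These carry the statistical structure the
# analysis modules assume — alternating PMD/HMD blocks, CpG-island
# hypomethylation, gene-body elevation in expressed genes, binomial read
# sampling at low coverage, and log-normal expression coupled to gene-body
# methylation — so the whole pipeline is testable without external data.

#' Genome specification for the synthetic generator
#'
#' Defaults describe the "demo" genome: 2 chromosomes x 10 Mb,
#' ~100,000 CpGs (background rate 1/200 bp, 10x enrichment inside islands),
#' 300 non-overlapping genes with log-normal lengths around 30 kb, 400 CpG
#' islands around 1 kb, and LINE/SINE/LTR repeats — sized so the full
#' pipeline runs in about a minute.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param cpg_rate Background CpG density per bp.
#' @param island_enrichment CpG density multiplier inside islands.
#' @param n_genes,gene_length_meanlog,gene_length_sdlog Gene count and
#'   log-normal length distribution.
#' @param n_islands,island_length_meanlog,island_length_sdlog Island count
#'   and log-normal length distribution.
#' @param repeat_density Named fraction of the genome covered per repeat
#'   class.
#' @param repeat_length Named element length per repeat class (bp).
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                        cpg_rate = 0.005, island_enrichment = 10,
                        n_genes = 300, gene_length_meanlog = log(3e4),
                        gene_length_sdlog = 0.5,
                        n_islands = 400, island_length_meanlog = log(1000),
                        island_length_sdlog = 0.3,
                        repeat_density = c(LINE = 0.10, SINE = 0.06,
                                           LTR = 0.04),
                        repeat_length = c(LINE = 3000, SINE = 300,
                                          LTR = 1500)) {
  stop_if_not(all(chrom_lengths > 0), "chromosome lengths must be > 0")
  stop_if_not(cpg_rate > 0 && island_enrichment >= 1,
              "densities must be positive")
  structure(list(chrom_lengths = chrom_lengths, cpg_rate = cpg_rate,
                 island_enrichment = island_enrichment, n_genes = n_genes,
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog,
                 n_islands = n_islands,
                 island_length_meanlog = island_length_meanlog,
                 island_length_sdlog = island_length_sdlog,
                 repeat_density = repeat_density,
                 repeat_length = repeat_length),
            class = "genome_spec")
}

# Place `n` non-overlapping intervals with the given lengths uniformly on
# [0, L): the free space is split by a uniform stick-breaking draw.
place_nonoverlapping <- function(n, lengths, L, margin = 0) {
  need <- sum(lengths) + 2 * margin * n
  if (n == 0L) return(numeric(0))
  if (need >= L)
    stop("infeasible packing: requested features exceed the chromosome",
         call. = FALSE)
  free <- L - need
  cuts <- sort(runif(n, 0, free))
  starts <- cuts + margin + c(0, cumsum(lengths[-n] + 2 * margin))
  floor(starts)
}

#' Simulate a genome annotation bundle
#'
#' Deterministic given `seed`. CpG positions are drawn from an inhomogeneous
#' Poisson process (background rate, enriched inside islands); genes are
#' non-overlapping by construction with strand-aware promoters derived as
#' 1000 bp upstream to 100 bp downstream of the TSS; repeats may overlap
#' other features, as they do in real genomes.
#'
#' @param spec A [genome_spec].
#' @param seed RNG seed.
#' @return A list of class `genome_bundle`: `chrom_lengths`, `cpgs`
#'   (data.frame `chrom`, `pos`), `genes` ([gene_models]), `promoters`,
#'   `islands`, `repeats` ([genomic_intervals]), `spec`, `seed`.
#' @export
simulate_genome <- function(spec = genome_spec(), seed) {
  with_seed(seed, {
    chroms <- names(spec$chrom_lengths)
    tot_len <- sum(spec$chrom_lengths)
    n_per <- function(n_total) {
      # apportion counts to chromosomes proportionally to length
      raw <- n_total * spec$chrom_lengths / tot_len
      k <- floor(raw)
      rem <- n_total - sum(k)
      if (rem > 0) k[order(raw - k, decreasing = TRUE)[seq_len(rem)]] <-
          k[order(raw - k, decreasing = TRUE)[seq_len(rem)]] + 1
      as.integer(k)
    }
    n_isl <- n_per(spec$n_islands)
    n_gen <- n_per(spec$n_genes)
    islands <- genes <- cpgs <- repeats <- list()
    for (ci in seq_along(chroms)) {
      cc <- chroms[ci]; L <- spec$chrom_lengths[[ci]]
      il <- pmax(round(rlnorm(n_isl[ci], spec$island_length_meanlog,
                              spec$island_length_sdlog)), 200)
      is_start <- place_nonoverlapping(n_isl[ci], il, L)
      islands[[cc]] <- data.frame(chrom = rep(cc, n_isl[ci]),
                                  start = is_start, end = is_start + il,
                                  stringsAsFactors = FALSE)
      gl <- pmax(round(rlnorm(n_gen[ci], spec$gene_length_meanlog,
                              spec$gene_length_sdlog)), 2000)
      gl <- pmin(gl, floor(L / 20))
      g_start <- place_nonoverlapping(n_gen[ci], gl, L, margin = 1200)
      genes[[cc]] <- data.frame(
        gene_id = sprintf("%s_g%04d", cc, seq_len(n_gen[ci])),
        chrom = rep(cc, n_gen[ci]),
        strand = sample(c("+", "-"), n_gen[ci], replace = TRUE),
        tx_start = g_start, tx_end = g_start + gl, stringsAsFactors = FALSE)
      # background CpGs + island surplus
      nbg <- rpois(1, spec$cpg_rate * L)
      pos <- floor(runif(nbg, 0, L))
      surplus <- spec$cpg_rate * (spec$island_enrichment - 1) * il
      extra <- unlist(lapply(seq_len(n_isl[ci]), function(k) {
        m <- rpois(1, surplus[k])
        floor(runif(m, is_start[k], is_start[k] + il[k]))
      }))
      pos <- sort(unique(c(pos, extra)))
      cpgs[[cc]] <- data.frame(chrom = cc, pos = pos,
                               stringsAsFactors = FALSE)
      reps <- lapply(names(spec$repeat_density), function(cl) {
        len <- spec$repeat_length[[cl]]
        m <- round(spec$repeat_density[[cl]] * L / len)
        st <- floor(runif(m, 0, L - len))
        data.frame(chrom = cc, start = st, end = st + len,
                   label = paste0("repeat:", cl), stringsAsFactors = FALSE)
      })
      repeats[[cc]] <- do.call(rbind, reps)
    }
    genes <- do.call(rbind, genes)
    g <- gene_models(genes$gene_id, genes$chrom, genes$strand,
                     genes$tx_start, genes$tx_end)
    isl <- do.call(rbind, islands)
    structure(list(
      chrom_lengths = spec$chrom_lengths,
      cpgs = do.call(rbind, cpgs),
      genes = g,
      promoters = promoter_intervals(g),
      islands = genomic_intervals(isl$chrom, isl$start, isl$end,
                                  "cpg_island"),
      repeats = {
        r <- do.call(rbind, repeats)
        genomic_intervals(r$chrom, r$start, r$end, r$label)
      },
      spec = spec, seed = seed), class = "genome_bundle")
  })
}

#' Methylome specification for the synthetic generator
#'
#' Defaults emulate a human-placenta-like methylome: alternating PMDs
#' (mean 0.40) and HMDs (mean 0.80) in log-normal blocks with median 180 kb
#' (multi-100-kb domain persistence, and short enough that windows much
#' wider than 50 kb mix adjacent domains and lose bimodality), hypomethylated
#' CpG islands (mean 0.10), a +0.10 gene-body elevation in expressed genes,
#' truncated-Gaussian site noise (SD 0.15, which averages to roughly 0.03
#' between-window SD at 20 kb given low-coverage binomial sampling),
#' negative-binomial coverage with mean depth 5, and log-normal expression
#' positively coupled to gene-body methylation (logistic coupling `kappa`).
#' `single_state = TRUE` produces a globally uniform methylome at
#' `flat_mean` (a mouse/cow-like track without PMD structure).
#'
#' @param pmd_mean,hmd_mean Domain baseline methylation fractions.
#' @param pmd_len,hmd_len Median domain block lengths in bp (alternating).
#' @param len_sdlog Log-normal sdlog of block lengths (0 = fixed-length
#'   blocks); drawn lengths are floored at 100 kb, the domain scale below
#'   which PMD/HMD structure is not called.
#' @param single_state,flat_mean Single-state alternative.
#' @param site_noise_sd Truncated-Gaussian per-CpG noise SD.
#' @param genebody_delta Methylation elevation in expressed gene bodies.
#' @param island_mean CpG-island methylation (overrides other structure).
#' @param coverage_mean,coverage_dispersion Negative-binomial read depth
#'   (mean and size); dispersion `Inf` gives Poisson.
#' @param coupling_kappa Logistic coupling of P(expressed) to gene-body
#'   methylation; 0 means independence.
#' @param expr_meanlog,expr_sdlog,silent_meanlog,silent_sdlog Log-normal
#'   FPKM parameters for expressed and silent genes.
#' @return A list of class `methylome_spec`.
#' @export
methylome_spec <- function(pmd_mean = 0.40, hmd_mean = 0.80,
                           pmd_len = 1.8e5, hmd_len = 1.8e5, len_sdlog = 0.5,
                           single_state = FALSE, flat_mean = 0.75,
                           site_noise_sd = 0.15, genebody_delta = 0.10,
                           island_mean = 0.10, coverage_mean = 5,
                           coverage_dispersion = 10, coupling_kappa = 3,
                           expr_meanlog = log(10), expr_sdlog = 1,
                           silent_meanlog = log(0.02), silent_sdlog = 1) {
  stop_if_not(all(c(pmd_mean, hmd_mean, island_mean, flat_mean) >= 0 &
                    c(pmd_mean, hmd_mean, island_mean, flat_mean) <= 1),
              "methylation means must lie in [0, 1]")
  stop_if_not(hmd_mean + genebody_delta <= 1 + 1e-9,
              "genebody_delta must keep elevated means <= 1")
  structure(as.list(environment()), class = "methylome_spec")
}

# True PMD/HMD block layout for a chromosome (alternating, PMD first).
domain_layout <- function(chrom, L, spec) {
  if (spec$single_state)
    return(data.frame(chrom = chrom, start = 0, end = L, state = "HMD",
                      stringsAsFactors = FALSE))
  starts <- ends <- numeric(0); states <- character(0)
  pos <- 0; s <- "PMD"
  while (pos < L) {
    len <- if (s == "PMD") spec$pmd_len else spec$hmd_len
    if (spec$len_sdlog > 0)
      len <- max(round(rlnorm(1, log(len), spec$len_sdlog)), 1e5)
    e <- min(pos + len, L)
    starts <- c(starts, pos); ends <- c(ends, e); states <- c(states, s)
    pos <- e
    s <- if (s == "PMD") "HMD" else "PMD"
  }
  data.frame(chrom = chrom, start = starts, end = ends, state = states,
             stringsAsFactors = FALSE)
}

#' Simulate a methylome over a genome bundle
#'
#' Builds the true per-CpG methylation fraction (domain baseline, gene-body
#' elevation for expressed genes, island override, truncated-Gaussian site
#' noise), then draws observed calls binomially at negative-binomial read
#' depth, and an expression table whose coupling to gene-body methylation is
#' controlled by `coupling_kappa`: P(expressed) =
#' logistic(kappa * (gene-body baseline methylation - gene average)), FPKM
#' log-normal for expressed genes and near zero for silent ones.
#'
#' @param bundle A `genome_bundle` from [simulate_genome()].
#' @param spec A [methylome_spec].
#' @param seed RNG seed.
#' @return A list of class `methylome_sim`: `calls` ([cpg_calls]), `truth`
#'   (data.frame `chrom`, `pos`, `base` noise-free fraction, `true` noisy
#'   fraction), `domains` (planted PMD/HMD layout), `expression`
#'   (`gene_id`, `fpkm`), `expressed` (logical per gene), `spec`, `seed`.
#' @export
simulate_methylome <- function(bundle, spec = methylome_spec(), seed) {
  with_seed(seed, {
    cp <- bundle$cpgs
    n <- nrow(cp)
    doms <- do.call(rbind, lapply(names(bundle$chrom_lengths), function(cc)
      domain_layout(cc, bundle$chrom_lengths[[cc]], spec)))
    base <- numeric(n)
    if (spec$single_state) {
      base[] <- spec$flat_mean
    } else {
      for (cc in unique(cp$chrom)) {
        sel <- cp$chrom == cc
        d <- doms[doms$chrom == cc, , drop = FALSE]
        k <- findInterval(cp$pos[sel], d$start)
        base[sel] <- ifelse(d$state[k] == "PMD", spec$pmd_mean,
                            spec$hmd_mean)
      }
    }
    # expression status from baseline gene-body methylation
    genes <- bundle$genes
    gr_sites <- pos_to_gr(cp$chrom, cp$pos)
    gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                       IRanges::IRanges(genes$tx_start + 1,
                                                        genes$tx_end))
    hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
    si <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
    gsum <- rowsum(base[si], group = gi)
    gn <- tabulate(gi, nrow(genes))
    gmean <- rep(mean(base), nrow(genes))
    gmean[as.integer(rownames(gsum))] <- gsum[, 1] /
      pmax(gn[as.integer(rownames(gsum))], 1)
    p_expr <- plogis(spec$coupling_kappa * (gmean - mean(gmean)))
    expressed <- runif(nrow(genes)) < p_expr
    # gene-body elevation for expressed genes
    if (any(expressed) && spec$genebody_delta != 0) {
      in_expr_gene <- unique(si[expressed[gi]])
      base[in_expr_gene] <- pmin(base[in_expr_gene] + spec$genebody_delta, 1)
    }
    # island override
    in_isl <- points_in_intervals(cp$chrom, cp$pos, bundle$islands)
    base[in_isl] <- spec$island_mean
    true_frac <- rtruncnorm(n, base, spec$site_noise_sd)
    depth <- if (is.finite(spec$coverage_dispersion))
      rnbinom(n, mu = spec$coverage_mean, size = spec$coverage_dispersion)
    else rpois(n, spec$coverage_mean)
    meth <- rbinom(n, depth, true_frac)
    calls <- cpg_calls(cp$chrom, cp$pos, meth, depth)
    fpkm <- ifelse(expressed,
                   rlnorm(nrow(genes), spec$expr_meanlog, spec$expr_sdlog),
                   rlnorm(nrow(genes), spec$silent_meanlog,
                          spec$silent_sdlog))
    structure(list(calls = calls,
                   truth = data.frame(chrom = cp$chrom, pos = cp$pos,
                                      base = base, true = true_frac,
                                      stringsAsFactors = FALSE),
                   domains = doms,
                   expression = data.frame(gene_id = genes$gene_id,
                                           fpkm = fpkm,
                                           stringsAsFactors = FALSE),
                   expressed = setNames(expressed, genes$gene_id),
                   spec = spec, seed = seed), class = "methylome_sim")
  })
}

#' Simulate a per-gene methylation/expression dataset
#'
#' A lightweight generator for the coupling analyses: gene-body methylation
#' from a two-component truncated-Gaussian mixture, expression status from
#' the logistic coupling model (`kappa = 0` gives exact independence), and
#' log-normal FPKM.
#'
#' @param n_genes Number of genes.
#' @param kappa Coupling strength (0 = independent).
#' @param seed RNG seed.
#' @param meth_modes,meth_sd,mix Mixture means, SD and low-mode weight.
#' @param expr_meanlog,expr_sdlog,silent_meanlog,silent_sdlog Log-normal
#'   FPKM parameters.
#' @return `data.frame` with `gene_id`, `meth`, `fpkm`, `expressed`.
#' @export
simulate_expression_dataset <- function(n_genes = 2000, kappa = 0, seed,
                                        meth_modes = c(0.45, 0.75),
                                        meth_sd = 0.08, mix = 0.5,
                                        expr_meanlog = log(10),
                                        expr_sdlog = 1,
                                        silent_meanlog = log(0.02),
                                        silent_sdlog = 1) {
  with_seed(seed, {
    lowmode <- runif(n_genes) < mix
    m <- rtruncnorm(n_genes, ifelse(lowmode, meth_modes[1], meth_modes[2]),
                    meth_sd)
    expressed <- runif(n_genes) < plogis(kappa * (m - mean(m)))
    fpkm <- ifelse(expressed, rlnorm(n_genes, expr_meanlog, expr_sdlog),
                   rlnorm(n_genes, silent_meanlog, silent_sdlog))
    data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)), meth = m,
               fpkm = fpkm, expressed = expressed, stringsAsFactors = FALSE)
  })
}

# Build the source->target alignment segments for one chromosome given
# non-overlapping rearrangement events sorted by start.
build_segments <- function(L, ev) {
  segs <- list(); cur_s <- 0; cur_t <- 0
  emit <- function(s0, s1, t0, strand)
    list(s_start = s0, s_end = s1, t_start = t0, t_end = t0 + (s1 - s0),
         strand = strand)
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$start > cur_s) {
      segs[[length(segs) + 1L]] <- emit(cur_s, e$start, cur_t, "+")
      cur_t <- cur_t + (e$start - cur_s)
    }
    if (e$type == "inversion") {
      segs[[length(segs) + 1L]] <- emit(e$start, e$end, cur_t, "-")
      cur_t <- cur_t + (e$end - e$start)
      cur_s <- e$end
    } else if (e$type == "deletion") {
      cur_s <- e$end
    } else if (e$type == "insertion") {
      cur_t <- cur_t + (e$end - e$start)   # novel target sequence
      cur_s <- max(cur_s, e$start)
    } else stop("unknown rearrangement type: ", e$type, call. = FALSE)
  }
  if (cur_s < L) {
    segs[[length(segs) + 1L]] <- emit(cur_s, L, cur_t, "+")
    cur_t <- cur_t + (L - cur_s)
  }
  list(segments = do.call(rbind, lapply(segs, as.data.frame)),
       target_len = cur_t)
}

#' Simulate a related second species
#'
#' Derives a second genome from a bundle through an explicit rearrangement
#' list (inversions, deletions, insertions of unaligned sequence), emits the
#' chain map exactly describing the constructed correspondence (and its
#' inverse), a simplified synteny table on the source genome (level-1 fills
#' for aligned spans plus any planted level-2 blocks), and a second
#' methylome: the first methylome's noise-free fractions carried through the
#' map, shifted by `diff_regions` offsets (source coordinates), re-noised
#' and re-sampled at fresh coverage. CpGs inside inserted (unaligned) target
#' sequence are novel and take the HMD baseline.
#'
#' @param bundle A `genome_bundle`.
#' @param methylome A `methylome_sim` simulated on `bundle`.
#' @param rearrangements `data.frame` with `chrom`, `start`, `end`, `type`
#'   (`inversion` | `deletion` | `insertion`), or `NULL`.
#' @param level2_blocks `data.frame` with `chrom`, `start`, `end` of planted
#'   second-level synteny fills (source coordinates), or `NULL`.
#' @param diff_regions `data.frame` with `chrom`, `start`, `end`, `offset`
#'   (methylation offset applied in the second species), or `NULL`.
#' @param seed RNG seed.
#' @return A list of class `species_pair`: `calls2`, `truth2` (target
#'   coordinates), `chain_fwd` (source -> target), `chain_rev`,
#'   `synteny` ([synteny_blocks]), `chrom_lengths2`, `map` (segment table),
#'   plus the planted `diff_regions`.
#' @export
simulate_species_pair <- function(bundle, methylome, rearrangements = NULL,
                                  level2_blocks = NULL, diff_regions = NULL,
                                  seed) {
  spec <- methylome$spec
  chroms <- names(bundle$chrom_lengths)
  if (!is.null(rearrangements)) {
    for (cc in unique(rearrangements$chrom)) {
      e <- rearrangements[rearrangements$chrom == cc, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
        stop("overlapping rearrangements on ", cc, call. = FALSE)
    }
  }
  maps <- list(); chains <- list(); target_len <- numeric(0)
  cid <- 0L
  for (cc in chroms) {
    L <- bundle$chrom_lengths[[cc]]
    ev <- if (is.null(rearrangements)) {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 type = character(0))
    } else rearrangements[rearrangements$chrom == cc, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    bs <- build_segments(L, ev)
    seg <- bs$segments
    seg$chrom <- cc
    maps[[cc]] <- seg
    target_len[[cc]] <- bs$target_len
    for (i in seq_len(nrow(seg))) {
      cid <- cid + 1L
      chains[[cid]] <- new_chain(
        id = as.character(cid), score = seg$s_end[i] - seg$s_start[i],
        s_chrom = cc, s_size = L, s_start = seg$s_start[i],
        s_end = seg$s_end[i], t_chrom = cc, t_size = bs$target_len,
        strand = seg$strand[i], t_start = seg$t_start[i],
        t_end = seg$t_end[i],
        blocks = data.frame(s_start = seg$s_start[i], s_end = seg$s_end[i],
                            t_start = seg$t_start[i], t_end = seg$t_end[i]))
    }
  }
  chain_fwd <- structure(chains, class = "chain_set")
  chain_rev <- invert_chain(chain_fwd)
  map <- do.call(rbind, maps)
  # carry CpGs and noise-free fractions through the map
  truth <- methylome$truth
  res <- with_seed(seed, {
    out <- list()
    for (cc in chroms) {
      seg <- maps[[cc]]
      sel <- which(truth$chrom == cc)
      pos <- truth$pos[sel]
      k <- findInterval(pos, seg$s_start)
      k[k < 1] <- NA
      inside <- !is.na(k) & pos < seg$s_end[pmax(k, 1)]
      k <- ifelse(inside, k, NA)
      off <- pos - seg$s_start[k]
      tpos <- ifelse(seg$strand[k] == "+", seg$t_start[k] + off,
                     seg$t_end[k] - 1 - off)
      keep <- inside & !is.na(tpos)
      base2 <- truth$base[sel][keep]
      src_pos <- pos[keep]
      # planted differential offsets (source coordinates)
      if (!is.null(diff_regions)) {
        dr <- diff_regions[diff_regions$chrom == cc, , drop = FALSE]
        for (i in seq_len(nrow(dr))) {
          hit <- src_pos >= dr$start[i] & src_pos < dr$end[i]
          base2[hit] <- pmin(pmax(base2[hit] + dr$offset[i], 0), 1)
        }
      }
      df <- data.frame(chrom = cc, pos = tpos[keep], base = base2,
                       source_pos = src_pos, stringsAsFactors = FALSE)
      # novel CpGs in inserted target spans
      ins_spans <- local({
        seg2 <- seg[order(seg$t_start), , drop = FALSE]
        gaps_lo <- c(0, seg2$t_end)
        gaps_hi <- c(seg2$t_start, target_len[[cc]])
        data.frame(lo = gaps_lo[gaps_hi > gaps_lo],
                   hi = gaps_hi[gaps_hi > gaps_lo])
      })
      if (nrow(ins_spans)) {
        novel <- unlist(lapply(seq_len(nrow(ins_spans)), function(i) {
          m <- rpois(1, bundle$spec$cpg_rate *
                       (ins_spans$hi[i] - ins_spans$lo[i]))
          floor(runif(m, ins_spans$lo[i], ins_spans$hi[i]))
        }))
        if (length(novel))
          df <- rbind(df, data.frame(chrom = cc, pos = novel,
                                     base = if (spec$single_state)
                                       spec$flat_mean else spec$hmd_mean,
                                     source_pos = NA_real_,
                                     stringsAsFactors = FALSE))
      }
      out[[cc]] <- df
    }
    df <- do.call(rbind, out)
    df <- df[order(df$chrom, df$pos, method = "radix"), , drop = FALSE]
    df <- df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
    n <- nrow(df)
    true2 <- rtruncnorm(n, df$base, spec$site_noise_sd)
    depth <- if (is.finite(spec$coverage_dispersion))
      rnbinom(n, mu = spec$coverage_mean, size = spec$coverage_dispersion)
    else rpois(n, spec$coverage_mean)
    meth <- rbinom(n, depth, true2)
    list(truth2 = data.frame(chrom = df$chrom, pos = df$pos,
                             base = df$base, true = true2,
                             source_pos = df$source_pos,
                             stringsAsFactors = FALSE),
         calls2 = cpg_calls(df$chrom, df$pos, meth, depth))
  })
  # synteny table on the source genome: aligned spans are level-1 fills
  lvl1 <- data.frame(chrom = map$chrom, start = map$s_start,
                     end = map$s_end, level = 1L)
  if (!is.null(level2_blocks))
    lvl1 <- rbind(lvl1, data.frame(chrom = level2_blocks$chrom,
                                   start = level2_blocks$start,
                                   end = level2_blocks$end, level = 2L))
  synteny <- synteny_blocks(lvl1$chrom, lvl1$start, lvl1$end, lvl1$level)
  structure(list(calls2 = res$calls2, truth2 = res$truth2,
                 chain_fwd = chain_fwd, chain_rev = chain_rev,
                 synteny = synteny, chrom_lengths2 = target_len,
                 map = map, diff_regions = diff_regions,
                 level2_blocks = level2_blocks, seed = seed),
            class = "species_pair")
}
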