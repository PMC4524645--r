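# cross_species: lift CpG calls between genomes through chain maps, clean by
# synteny fill level, scale tracks to a common location/spread, call
# differential regions and test syntenic-break enrichment.

#' Lift CpG calls through a chain map
#'
#' Each site maps through the highest-scoring chain block containing it
#' (positional lifting only — no sequence-conservation requirement, matching
#' the comparative-methylome convention of mapping CpGs regardless of whether
#' the dinucleotide is conserved). Sites falling in inter-block gaps are
#' unmapped. Negative-strand chains map by coordinate reflection. When two
#' source sites land on one target position, the site from the
#' higher-scoring chain wins, then the lower source coordinate.
#'
#' @param calls A [cpg_calls] table in source-genome coordinates.
#' @param chains A `chain_set` (see [read_chain()]).
#' @return A list of class `lifted_track`: `calls` (a `cpg_calls` table in
#'   target coordinates with `source_chrom`/`source_pos` provenance columns),
#'   `n_input`, `n_mapped`, `n_unmapped`, `n_removed` (0 until synteny
#'   cleaning), and `collided` (sites dropped in target-position ties,
#'   counted among unmapped).
#' @export
lift_cpgs <- function(calls, chains) {
  bt <- chain_block_table(chains)
  n_in <- nrow(calls)
  q <- pos_to_gr(calls$chrom, calls$pos)
  s <- GenomicRanges::GRanges(bt$s_chrom,
                              IRanges::IRanges(bt$s_start + 1, bt$s_end))
  hits <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    # per site keep the highest-scoring containing block (tie: first block)
    o <- order(qh, -bt$score[sh])
    qh <- qh[o]; sh <- sh[o]
    first <- !duplicated(qh)
    qh <- qh[first]; sh <- sh[first]
  }
  off <- calls$pos[qh] - bt$s_start[sh]
  tpos <- ifelse(bt$strand[sh] == "+", bt$t_start[sh] + off,
                 bt$t_end[sh] - 1 - off)
  lifted <- data.frame(chrom = bt$t_chrom[sh], pos = tpos,
                       meth_reads = calls$meth_reads[qh],
                       total_reads = calls$total_reads[qh],
                       fraction = calls$fraction[qh],
                       source_chrom = calls$chrom[qh],
                       source_pos = calls$pos[qh], stringsAsFactors = FALSE)
  # resolve target-position collisions: higher chain score, then lower
  # source coordinate
  n_collided <- 0L
  if (nrow(lifted)) {
    sc <- bt$score[sh]
    o <- order(lifted$chrom, lifted$pos, -sc, lifted$source_chrom,
               lifted$source_pos, method = "radix")
    lifted <- lifted[o, , drop = FALSE]
    dup <- duplicated(paste(lifted$chrom, lifted$pos))
    n_collided <- sum(dup)
    lifted <- lifted[!dup, , drop = FALSE]
  }
  rownames(lifted) <- NULL
  class(lifted) <- c("cpg_calls", "data.frame")
  structure(list(calls = lifted, n_input = n_in,
                 n_mapped = nrow(lifted),
                 n_unmapped = n_in - nrow(lifted),
                 n_removed = 0L, collided = n_collided),
            class = "lifted_track")
}

#' Remove lifted CpGs in small second-level synteny fills
#'
#' Drops sites inside level-2 net fills shorter than `min_level2_bp`
#' (default 1 Mb) — the small inter-/intrachromosomal translocations and
#' duplications that contaminate large-scale cross-species comparisons. All
#' other sites are retained; raising `min_level2_bp` never removes fewer
#' sites.
#'
#' @param lifted A `lifted_track` (see [lift_cpgs()]).
#' @param blocks A [synteny_blocks] table on the lift-target genome.
#' @param min_level2_bp Span threshold in bp (default 1e6).
#' @return The cleaned `lifted_track` with `n_removed` updated.
#' @export
clean_by_synteny <- function(lifted, blocks, min_level2_bp = 1e6) {
  calls <- lifted$calls
  if (is.null(blocks) || nrow(blocks) == 0L || nrow(calls) == 0L)
    return(lifted)
  bad <- blocks[blocks$level == 2L & blocks$span_bp < min_level2_bp, ,
                drop = FALSE]
  drop <- points_in_intervals(calls$chrom, calls$pos, bad)
  out <- lifted
  out$calls <- calls[!drop, , drop = FALSE]
  rownames(out$calls) <- NULL
  class(out$calls) <- c("cpg_calls", "data.frame")
  out$n_mapped <- nrow(out$calls)
  out$n_removed <- lifted$n_removed + sum(drop)
  out
}

#' Scale a series to a target mean and standard deviation
#'
#' Affine transform `(x - mean(x)) / sd(x) * target_sd + target_mean` over
#' the non-missing values, used to put two species' smoothed tracks on a
#' common location and spread before differencing.
#'
#' @param values Numeric series (may contain `NA`).
#' @param target_mean,target_sd Target moments.
#' @return The scaled series (missing values stay missing).
#' @export
scale_track <- function(values, target_mean, target_sd) {
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  stop_if_not(!is.na(s) && s > 0, "series SD must be > 0")
  (values - m) / s * target_sd + target_mean
}

#' Call differential-methylation regions between two species
#'
#' Both tracks (reference = the genome the comparison lives on, e.g. human;
#' other = the lifted species) are smoothed with a running median
#' (`width` windows), the other track is scaled to the reference's mean and
#' SD, and the smoothed difference is thresholded at `z_threshold` standard
#' deviations. The SD used for thresholding is the SD of the *unsmoothed*
#' scaled per-window difference series, so the threshold reflects the
#' window-to-window variability of the comparison rather than re-adapting to
#' the smoothed noise floor. Maximal runs of consecutive windows beyond the
#' threshold become regions; runs never span chromosomes or missing windows.
#'
#' @param reference,other `window_track` objects on the same grid.
#' @param width Running-median width in windows (default 15).
#' @param z_threshold Threshold in difference-SD units (default 1.5).
#' @return A `data.frame` of class `differential_regions` with `chrom`,
#'   `start`, `end`, `direction` (`higher-in-reference` /
#'   `lower-in-reference`), `max_abs_z`, `n_windows`; attributes `sd_diff`
#'   and `threshold`.
#' @export
differential_regions <- function(reference, other, width = 15,
                                 z_threshold = 1.5) {
  stop_if_not(nrow(reference) == nrow(other) &&
                all(reference$chrom == other$chrom) &&
                all(reference$start == other$start),
              "tracks must share the same window grid")
  shared <- !is.na(reference$mean_meth) & !is.na(other$mean_meth)
  if (sum(shared) < 30)
    stop("fewer than 30 shared windows; difference SD unstable",
         call. = FALSE)
  ref_m <- mean(reference$mean_meth[shared])
  ref_s <- sd(reference$mean_meth[shared])
  oth_m <- mean(other$mean_meth[shared])
  oth_s <- sd(other$mean_meth[shared])
  stop_if_not(oth_s > 0 && ref_s > 0, "track SD must be > 0")
  # put the other species on the reference's mean/SD; the affine is fitted
  # on the raw window series (the running median commutes with affine maps,
  # so scaling before or after smoothing differs only in which moments are
  # used, and the raw moments stay stable on structure-poor tracks)
  oth_scaled <- (other$mean_meth - oth_m) / oth_s * ref_s + ref_m
  raw_diff <- reference$mean_meth - oth_scaled
  sd_diff <- sd(raw_diff[shared])
  sm_ref <- rep(NA_real_, nrow(reference))
  sm_oth <- rep(NA_real_, nrow(other))
  for (cc in unique(reference$chrom)) {
    sel <- which(reference$chrom == cc)
    sm_ref[sel] <- running_median(reference$mean_meth[sel], width)
    sm_oth[sel] <- running_median(oth_scaled[sel], width)
  }
  diff_sm <- sm_ref - sm_oth
  thr <- z_threshold * sd_diff
  # windows within half a smoothing width of a chromosome end are almost
  # unsmoothed: their difference variance is that of the raw series, not
  # the smoothed one, so they are not eligible for region calls
  h <- (width - 1) / 2
  edge <- rep(TRUE, nrow(reference))
  for (cc in unique(reference$chrom)) {
    sel <- which(reference$chrom == cc)
    if (length(sel) > 2 * h)
      edge[sel[(h + 1):(length(sel) - h)]] <- FALSE
  }
  hit <- !is.na(diff_sm) & abs(diff_sm) > thr & shared & !edge
  regs <- list()
  if (any(hit)) {
    sign_d <- sign(diff_sm)
    grp_key <- paste(reference$chrom, sign_d)
    r <- rle(paste(hit, grp_key))
    stops <- cumsum(r$lengths); starts_i <- c(1L, head(stops, -1L) + 1L)
    run_hit <- hit[starts_i]
    for (k in which(run_hit)) {
      i0 <- starts_i[k]; i1 <- stops[k]
      z <- diff_sm[i0:i1] / sd_diff
      regs[[length(regs) + 1L]] <- data.frame(
        chrom = reference$chrom[i0], start = reference$start[i0],
        end = reference$end[i1],
        direction = if (diff_sm[i0] > 0) "higher-in-reference"
                    else "lower-in-reference",
        max_abs_z = max(abs(z)), n_windows = i1 - i0 + 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(regs)) do.call(rbind, regs)
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                  direction = character(0), max_abs_z = numeric(0),
                  n_windows = integer(0))
  rownames(out) <- NULL
  attr(out, "sd_diff") <- sd_diff
  attr(out, "threshold") <- thr
  class(out) <- c("differential_regions", "data.frame")
  out
}

#' Derive syntenic break positions from a synteny-block table
#'
#' Breaks are junctions between consecutive retained blocks on the same
#' chromosome, where retained blocks are the level-1 fills plus level-2
#' fills larger than `min_level2_bp` (the smaller level-2 regions having
#' been removed from the methylation data). Each junction contributes the
#' end coordinate of the upstream block.
#'
#' @param blocks A [synteny_blocks] table.
#' @param min_level2_bp Level-2 span threshold (default 1e6).
#' @return `data.frame` with `chrom`, `pos`.
#' @export
synteny_breaks <- function(blocks, min_level2_bp = 1e6) {
  keep <- blocks$level == 1L |
    (blocks$level == 2L & blocks$span_bp > min_level2_bp)
  b <- blocks[keep, , drop = FALSE]
  res <- lapply(split(b, b$chrom), function(s) {
    if (nrow(s) < 2) return(NULL)
    data.frame(chrom = s$chrom[1], pos = s$end[-nrow(s)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(chrom = character(0), pos = numeric(0))
  rownames(out) <- NULL
  out
}

#' Test enrichment of syntenic breaks in differential regions
#'
#' Observed statistic: the fraction of breaks falling inside a differential
#' region. The null re-places each break uniformly within its chromosome's
#' analyzable span (per-chromosome break counts preserved); the empirical
#' p-value is two-sided (doubled smaller tail, capped at 1).
#'
#' @param breaks `data.frame` with `chrom`, `pos` (see [synteny_breaks()]).
#' @param regions A `differential_regions` table (or any chrom/start/end
#'   data.frame).
#' @param spans `data.frame` of analyzable spans (`chrom`, `start`, `end`).
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @return A list of class `break_enrichment`: `observed` (fraction),
#'   `null` (vector), `p`, `n_breaks`, `applicable`.
#' @export
break_enrichment <- function(breaks, regions, spans, n_perm = 999, seed) {
  stop_if_not(n_perm >= 100, "n_perm must be >= 100")
  if (nrow(breaks) == 0L)
    return(structure(list(observed = NA_real_, null = numeric(0),
                          p = NA_real_, n_breaks = 0L, applicable = FALSE),
                     class = "break_enrichment"))
  # flatten regions to disjoint sorted intervals per chromosome for fast
  # findInterval membership inside the permutation loop
  reg_flat <- if (nrow(regions) == 0L) list() else {
    red <- GenomicRanges::reduce(iv_to_gr(regions))
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                     start = GenomicRanges::start(red) - 1,
                     end = GenomicRanges::end(red))
    split(df[, c("start", "end")], df$chrom)
  }
  in_regions <- function(chrom_list) {
    # chrom_list: named list of position vectors per chromosome
    hits <- 0L
    for (cc in names(chrom_list)) {
      rg <- reg_flat[[cc]]
      if (is.null(rg)) next
      pos <- chrom_list[[cc]]
      k <- findInterval(pos, rg$start)
      hits <- hits + sum(k >= 1 & pos < rg$end[pmax(k, 1L)])
    }
    hits
  }
  per_chrom <- split(breaks$pos, breaks$chrom)
  n_breaks <- nrow(breaks)
  observed <- in_regions(per_chrom) / n_breaks
  span_by_chrom <- split(spans, spans$chrom)
  stop_if_not(all(names(per_chrom) %in% names(span_by_chrom)),
              "every break chromosome needs an analyzable span")
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sim <- lapply(names(per_chrom), function(cc) {
      sp <- span_by_chrom[[cc]]
      len <- sp$end - sp$start
      u <- runif(length(per_chrom[[cc]]), 0, sum(len))
      k <- findInterval(u, cumsum(c(0, len)), rightmost.closed = TRUE)
      k <- pmin(pmax(k, 1L), nrow(sp))
      sp$start[k] + (u - cumsum(c(0, len))[k])
    })
    names(sim) <- names(per_chrom)
    in_regions(sim) / n_breaks
  }, numeric(1)))
  p_le <- (1 + sum(null <= observed)) / (1 + n_perm)
  p_ge <- (1 + sum(null >= observed)) / (1 + n_perm)
  p <- if (nrow(regions) == 0L) 1 else min(1, 2 * min(p_le, p_ge))
  structure(list(observed = observed, null = null, p = p,
                 n_breaks = nrow(breaks), applicable = TRUE),
            class = "break_enrichment")
}
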