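# genic_features: gene-body and annotation-class methylation with
# promoter/CpG-island masking, spinograms (genic-location prediction from
# methylation), and cross-species ortholog matrices.

#' Strand-aware promoter intervals
#'
#' Promoters are defined as `upstream` bp upstream to `downstream` bp
#' downstream of the transcription start site: for a `+` gene
#' `[tx_start - upstream, tx_start + downstream)`, for a `-` gene
#' `[tx_end - downstream, tx_end + upstream)`. Coordinates are clipped at 0.
#'
#' @param genes A [gene_models] table.
#' @param upstream,downstream Extent in bp (defaults 1000 and 100).
#' @return A [genomic_intervals] table labeled `promoter`, with a `gene_id`
#'   column.
#' @export
promoter_intervals <- function(genes, upstream = 1000, downstream = 100) {
  plus <- genes$strand == "+"
  start <- pmax(ifelse(plus, genes$tx_start - upstream,
                       genes$tx_end - downstream), 0)
  end <- ifelse(plus, genes$tx_start + downstream, genes$tx_end + upstream)
  out <- data.frame(chrom = genes$chrom, start = start, end = end,
                    label = rep("promoter", nrow(genes)),
                    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Gene-body methylation with promoter and CpG-island masking
#'
#' For each gene, the unweighted mean of CpG methylation fractions within
#' `[tx_start, tx_end)`, excluding any position inside the gene's own
#' promoter or inside any CpG island. Genes with fewer than `min_cpgs`
#' retained informative CpGs are omitted (and counted).
#'
#' @param calls A [cpg_calls] table.
#' @param genes A [gene_models] table.
#' @param promoters Optional promoter [genomic_intervals] with a `gene_id`
#'   column; derived from `genes` via [promoter_intervals()] when `NULL`.
#' @param cgis CpG-island [genomic_intervals] (may be `NULL`).
#' @param min_cpgs Minimum retained CpGs per gene (default 20).
#' @return A `data.frame` of class `gene_body_methylation` with `gene_id`,
#'   `meth`, `n_cpgs`, `masked_bp`; attribute `n_omitted` counts genes
#'   failing the filter.
#' @export
gene_body_methylation <- function(calls, genes, promoters = NULL,
                                  cgis = NULL, min_cpgs = 20) {
  if (is.null(promoters)) promoters <- promoter_intervals(genes)
  stop_if_not(!is.null(promoters$gene_id),
              "promoters need a gene_id column to be matched to genes")
  covered <- !is.na(calls$fraction)
  sub <- calls[covered, , drop = FALSE]
  in_island <- points_in_intervals(sub$chrom, sub$pos, cgis)
  gr_sites <- pos_to_gr(sub$chrom, sub$pos)
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$tx_start + 1,
                                                      genes$tx_end))
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  si <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  # mask sites inside the owning gene's promoter
  prom_idx <- match(genes$gene_id[gi], promoters$gene_id)
  in_own_prom <- !is.na(prom_idx) &
    sub$pos[si] >= promoters$start[prom_idx] &
    sub$pos[si] < promoters$end[prom_idx] &
    sub$chrom[si] == promoters$chrom[prom_idx]
  keep <- !in_island[si] & !in_own_prom
  si <- si[keep]; gi <- gi[keep]
  n <- tabulate(gi, nbins = nrow(genes))
  s <- numeric(nrow(genes))
  if (length(gi)) {
    agg <- rowsum(sub$fraction[si], group = gi)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  masked <- vapply(seq_len(nrow(genes)), function(g) {
    pr <- promoters[which(promoters$gene_id == genes$gene_id[g])[1], ,
                    drop = FALSE]
    mask <- rbind(if (!is.null(cgis))
      cgis[, c("chrom", "start", "end")],
      pr[, c("chrom", "start", "end")])
    masked_bp_in(mask, genes$chrom[g], genes$tx_start[g], genes$tx_end[g])
  }, numeric(1))
  ok <- n >= min_cpgs
  out <- data.frame(gene_id = genes$gene_id[ok], meth = (s / n)[ok],
                    n_cpgs = n[ok], masked_bp = masked[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_omitted") <- sum(!ok)
  class(out) <- c("gene_body_methylation", "data.frame")
  out
}

#' Methylation over annotated features and feature classes
#'
#' Per-feature unweighted mean of covered CpG fractions (features with fewer
#' than `min_cpgs` informative sites are excluded from the per-feature
#' table), plus per-class pooled means over all covered sites in any feature
#' of the class, including a `non-repetitive` complement class (sites
#' outside every `repeat:*` feature).
#'
#' @param calls A [cpg_calls] table.
#' @param features A [genomic_intervals] table with class labels.
#' @param min_cpgs Per-feature minimum informative CpGs (default 10).
#' @return A list with `per_feature` (chrom, start, end, label, meth,
#'   n_cpgs) and `per_class` (label, meth, n_cpgs).
#' @export
feature_methylation <- function(calls, features, min_cpgs = 10) {
  sub <- calls[!is.na(calls$fraction), , drop = FALSE]
  gr_sites <- pos_to_gr(sub$chrom, sub$pos)
  hits <- GenomicRanges::findOverlaps(gr_sites, iv_to_gr(features))
  si <- S4Vectors::queryHits(hits); fi <- S4Vectors::subjectHits(hits)
  n <- tabulate(fi, nbins = nrow(features))
  s <- numeric(nrow(features))
  if (length(fi)) {
    agg <- rowsum(sub$fraction[si], group = fi)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  ok <- n >= min_cpgs
  per_feature <- data.frame(chrom = features$chrom[ok],
                            start = features$start[ok],
                            end = features$end[ok],
                            label = features$label[ok],
                            meth = (s / n)[ok], n_cpgs = n[ok],
                            stringsAsFactors = FALSE)
  # class pools: each covered site counted once per class it falls in
  cls <- unique(features$label)
  per_class <- do.call(rbind, lapply(cls, function(cl) {
    in_cl <- points_in_intervals(sub$chrom, sub$pos,
                                 features[features$label == cl, ,
                                          drop = FALSE])
    data.frame(label = cl, meth = mean(sub$fraction[in_cl]),
               n_cpgs = sum(in_cl), stringsAsFactors = FALSE)
  }))
  reps <- features[grepl("^repeat:", features$label), , drop = FALSE]
  in_rep <- points_in_intervals(sub$chrom, sub$pos, reps)
  per_class <- rbind(per_class,
                     data.frame(label = "non-repetitive",
                                meth = mean(sub$fraction[!in_rep]),
                                n_cpgs = sum(!in_rep),
                                stringsAsFactors = FALSE))
  rownames(per_class) <- NULL
  list(per_feature = per_feature, per_class = per_class)
}

#' Spinogram: probability a window is genic given its methylation
#'
#' Windows (typically 5 kb with at least 10 covered CpGs, enforced at track
#' construction) are classified genic when their midpoint lies inside any
#' gene body, binned by mean methylation on the percent scale, and the
#' conditional probability P(genic | bin) is reported per bin together with
#' its occupancy and an informativeness score `|P - 0.5|`.
#'
#' @param windows A `window_track`.
#' @param genes A [gene_models] table.
#' @param bin_width Bin width in percent (default 5, i.e. 20 bins).
#' @return A `data.frame` of class `spinogram` with `bin_lo`, `bin_hi`,
#'   `count`, `fraction`, `n_genic`, `p_genic`, `informativeness`; attribute
#'   `genic_fraction` is the overall genic fraction of covered windows.
#' @export
genic_spinogram <- function(windows, genes, bin_width = 5) {
  ok <- !is.na(windows$mean_meth)
  w <- windows[ok, , drop = FALSE]
  mid <- (w$start + w$end) / 2
  genic <- points_in_intervals(w$chrom, floor(mid),
                               data.frame(chrom = genes$chrom,
                                          start = genes$tx_start,
                                          end = genes$tx_end))
  edges <- seq(0, 100, by = bin_width)
  nb <- length(edges) - 1L
  bi <- pmin(pmax(findInterval(w$mean_meth * 100, edges,
                               rightmost.closed = TRUE), 1L), nb)
  count <- tabulate(bi, nb)
  n_genic <- tabulate(bi[genic], nb)
  p <- ifelse(count > 0, n_genic / count, NA_real_)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    count = count, fraction = count / sum(count),
                    n_genic = n_genic, p_genic = p,
                    informativeness = abs(p - 0.5))
  attr(out, "genic_fraction") <- mean(genic)
  class(out) <- c("spinogram", "data.frame")
  out
}

#' Build a cross-species ortholog gene-body methylation matrix
#'
#' One row per pivot-species gene, one column per species. Non-pivot species
#' are joined through pairwise ortholog tables mapping pivot gene ids to
#' that species' ids. Rows with fewer than two non-missing entries are
#' dropped. Duplicate orthologs for one pivot gene keep the entry with the
#' most informative CpGs (a message reports how many).
#'
#' @param gbm_list Named list of [gene_body_methylation] tables; the first
#'   element is the pivot species.
#' @param orthologs Named list (one element per non-pivot species, names
#'   matching `gbm_list`) of data.frames `gene_id_a` (pivot id),
#'   `gene_id_b` (species id).
#' @return A numeric matrix, rownames = pivot gene ids, colnames = species.
#' @export
build_ortholog_matrix <- function(gbm_list, orthologs) {
  stop_if_not(length(gbm_list) >= 2 && !is.null(names(gbm_list)),
              "gbm_list must be a named list of >= 2 species")
  pivot <- names(gbm_list)[1]
  others <- setdiff(names(gbm_list), pivot)
  stop_if_not(all(others %in% names(orthologs)),
              "orthologs must cover every non-pivot species")
  pivot_ids <- gbm_list[[pivot]]$gene_id
  mat <- matrix(NA_real_, nrow = length(pivot_ids), ncol = length(gbm_list),
                dimnames = list(pivot_ids, names(gbm_list)))
  mat[, pivot] <- gbm_list[[pivot]]$meth
  for (sp in others) {
    ot <- orthologs[[sp]]
    gbm <- gbm_list[[sp]]
    ot <- ot[ot$gene_id_a %in% pivot_ids & ot$gene_id_b %in% gbm$gene_id, ,
             drop = FALSE]
    if (anyDuplicated(ot$gene_id_a)) {
      # keep the ortholog with the highest n_cpgs
      nc <- gbm$n_cpgs[match(ot$gene_id_b, gbm$gene_id)]
      o <- order(ot$gene_id_a, -nc)
      ot <- ot[o, , drop = FALSE]
      ndup <- sum(duplicated(ot$gene_id_a))
      ot <- ot[!duplicated(ot$gene_id_a), , drop = FALSE]
      message(ndup, " duplicate ortholog(s) resolved by n_cpgs for ", sp)
    }
    mat[ot$gene_id_a, sp] <- gbm$meth[match(ot$gene_id_b, gbm$gene_id)]
  }
  mat[rowSums(!is.na(mat)) >= 2, , drop = FALSE]
}
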