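# expression_coupling: the binned co-independence test of gene-body
# methylation against expression, quadrant classification across two
# tissues, and gene-set overlaps.

# log(FPKM)+1 transform with a pseudo-count for zeros: log10(fpkm + eps) + 1.
transform_fpkm <- function(fpkm, eps = 0.01, log_base = 10) {
  log(fpkm + eps, base = log_base) + 1
}

# Equal-width or rank (equal-count) bin indices on [1, n_bins].
bin_index <- function(x, n_bins, binning = c("width", "rank")) {
  binning <- match.arg(binning)
  if (binning == "width") {
    edges <- seq(min(x), max(x), length.out = n_bins + 1)
  } else {
    edges <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                             names = FALSE))
  }
  pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
       length(edges) - 1L)
}

# Pool map: cells with expected < 1 are pooled into the nearest cell with
# expected >= 1 along the expression axis (same methylation row; ties to the
# lower bin). Rows with no eligible cell pool entirely into their
# largest-expected cell, which is kept only if the pooled expectation
# reaches 1. Returns an nb_m x nb_e matrix of pooled-cell ids (0 = dropped).
pool_map <- function(expected) {
  nr <- nrow(expected); nc <- ncol(expected)
  id <- matrix(0L, nr, nc)
  nxt <- 0L
  assign_id <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    elig <- which(expected[i, ] >= 1)
    if (length(elig)) {
      for (j in elig) { nxt <- nxt + 1L; assign_id[i, j] <- nxt }
      for (j in seq_len(nc)) {
        if (expected[i, j] >= 1) { id[i, j] <- assign_id[i, j]; next }
        tgt <- elig[which.min(abs(elig - j))]
        id[i, j] <- assign_id[i, tgt]
      }
    } else if (sum(expected[i, ]) >= 1) {
      nxt <- nxt + 1L
      id[i, ] <- nxt
    } # else: whole row dropped (id 0)
  }
  id
}

#' Binned co-independence test of methylation and expression
#'
#' Divides the methylation axis and the transformed-expression axis
#' (`log10(fpkm + 0.01) + 1`) into `n_bins` equally spaced bins over each
#' axis's observed range, counts genes per cell, and compares the observed
#' joint counts to the product of the marginals. The test statistic is the
#' chi-square sum over cells after pooling small-expectation cells along the
#' expression axis; its reference distribution is, by default, the
#' permutation null obtained by shuffling expression across genes (exact
#' under exchangeability), with a classical chi-square approximation
#' available as `mode = "chi2"`.
#'
#' @param meth `data.frame` with `gene_id` and `meth` (gene-body methylation
#'   fraction), or a named numeric vector.
#' @param expr `data.frame` with `gene_id` and `fpkm`, or a named numeric
#'   vector of FPKM.
#' @param n_bins Bins per axis (default 20).
#' @param mode `"permutation"` (default) or `"chi2"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutation null.
#' @param binning `"width"` (equal-spaced, default) or `"rank"`
#'   (equal-count) bins.
#' @param eps Pseudo-count for zero FPKM (default 0.01).
#' @return A list of class `quadrant_table`: `table` (long data.frame
#'   `bin_x` methylation bin, `bin_y` expression bin, `observed`,
#'   `expected`, `deviation`), `observed`/`expected` matrices
#'   (methylation x expression), `statistic`, `p_value`, `df` (chi2 mode),
#'   `n`, `mode`, `meth_breaks`, `expr_breaks`.
#' @export
coindependence_test <- function(meth, expr, n_bins = 20,
                                mode = c("permutation", "chi2"),
                                n_perm = 999, seed = 1,
                                binning = c("width", "rank"), eps = 0.01) {
  mode <- match.arg(mode)
  binning <- match.arg(binning)
  stop_if_not(n_bins >= 2, "n_bins must be >= 2")
  if (is.data.frame(meth)) meth <- setNames(meth$meth, meth$gene_id)
  if (is.data.frame(expr)) expr <- setNames(expr$fpkm, expr$gene_id)
  ids <- intersect(names(meth), names(expr))
  n <- length(ids)
  if (n < 200)
    warning("fewer than 200 matched genes; test underpowered")
  stop_if_not(n >= 3, "need at least 3 matched genes")
  m <- as.numeric(meth[ids])
  y <- transform_fpkm(as.numeric(expr[ids]), eps = eps)
  mi <- bin_index(m, n_bins, binning)
  ei <- bin_index(y, n_bins, binning)
  obs <- matrix(tabulate((ei - 1L) * n_bins + mi, n_bins * n_bins),
                n_bins, n_bins)
  row_tot <- rowSums(obs); col_tot <- colSums(obs)
  expected <- outer(row_tot, col_tot) / n
  pm <- pool_map(expected)
  npool <- max(pm)
  exp_pool <- as.numeric(rowsum(as.numeric(expected)[pm > 0],
                                group = pm[pm > 0]))
  cell_pool <- pm  # nb x nb matrix of pooled ids
  stat_of <- function(ei_vec) {
    cells <- (ei_vec - 1L) * n_bins + mi
    pooled_obs <- tabulate(cell_pool[cells], npool)
    sum((pooled_obs - exp_pool)^2 / exp_pool)
  }
  statistic <- stat_of(ei)
  if (mode == "permutation") {
    perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      stat_of(ei[sample.int(n)]), numeric(1)))
    p <- (1 + sum(perm_stats >= statistic)) / (1 + n_perm)
    dfree <- NA_real_
  } else {
    r <- sum(row_tot > 0); cc <- sum(col_tot > 0)
    dfree <- (r - 1) * (cc - 1)
    p <- pchisq(statistic, df = dfree, lower.tail = FALSE)
  }
  tab <- data.frame(bin_x = rep(seq_len(n_bins), n_bins),
                    bin_y = rep(seq_len(n_bins), each = n_bins),
                    observed = as.integer(obs),
                    expected = as.numeric(expected),
                    deviation = as.numeric(obs - expected))
  structure(list(table = tab, observed = obs, expected = expected,
                 statistic = statistic, p_value = p, df = dfree, n = n,
                 mode = mode, binning = binning,
                 meth_range = range(m), expr_range = range(y)),
            class = "quadrant_table")
}

#' Summed observed-minus-expected deviation in a grid sector
#'
#' Convenience accessor for the qualitative signature that genes with high
#' gene-body methylation are over-represented at intermediate expression:
#' sums the deviation over the sector of the quadrant grid selected by bin
#' ranges given as fractions of the axis.
#'
#' @param qt A `quadrant_table` from [coindependence_test()].
#' @param meth_frac,expr_frac Length-2 fractions of the bin range selecting
#'   the sector (defaults: top third of methylation, middle third of
#'   expression).
#' @return The summed deviation (observed - expected) over the sector.
#' @export
sector_deviation <- function(qt, meth_frac = c(2 / 3, 1),
                             expr_frac = c(1 / 3, 2 / 3)) {
  nb <- nrow(qt$observed)
  centers <- (seq_len(nb) - 0.5) / nb
  mi <- which(centers >= meth_frac[1] & centers <= meth_frac[2])
  ei <- which(centers >= expr_frac[1] & centers <= expr_frac[2])
  sum(qt$observed[mi, ei] - qt$expected[mi, ei])
}

#' Classify genes by high/low expression in two tissues
#'
#' Both tissues' FPKM are transformed as `log10(fpkm + 0.01) + 1` and genes
#' present in both are classified by whether each transformed value exceeds
#' the threshold (default 0.56).
#'
#' @param expr_a,expr_b `data.frame`s with `gene_id`, `fpkm` (or named FPKM
#'   vectors).
#' @param threshold Threshold on the transformed scale (default 0.56).
#' @param eps Pseudo-count for zero FPKM (default 0.01).
#' @return A list of class `expression_quadrants`: `classes` (data.frame
#'   `gene_id`, `class` in high-high/high-low/low-high/low-low), `counts`
#'   (named table), `n_excluded` (genes absent from one tissue),
#'   `threshold`.
#' @export
expression_quadrants <- function(expr_a, expr_b, threshold = 0.56,
                                 eps = 0.01) {
  if (is.data.frame(expr_a)) expr_a <- setNames(expr_a$fpkm, expr_a$gene_id)
  if (is.data.frame(expr_b)) expr_b <- setNames(expr_b$fpkm, expr_b$gene_id)
  ids <- intersect(names(expr_a), names(expr_b))
  n_excluded <- length(union(names(expr_a), names(expr_b))) - length(ids)
  a <- transform_fpkm(as.numeric(expr_a[ids]), eps = eps) > threshold
  b <- transform_fpkm(as.numeric(expr_b[ids]), eps = eps) > threshold
  cls <- paste0(ifelse(a, "high", "low"), "-", ifelse(b, "high", "low"))
  lv <- c("high-high", "high-low", "low-high", "low-low")
  counts <- table(factor(cls, levels = lv))
  structure(list(classes = data.frame(gene_id = ids, class = cls,
                                      stringsAsFactors = FALSE),
                 counts = counts, n_excluded = n_excluded,
                 threshold = threshold),
            class = "expression_quadrants")
}

#' Overlap cardinalities of gene sets
#'
#' All intersection sizes for every combination of two or more of the input
#' sets (plus the individual set sizes), e.g. genes with high gene-body
#' methylation in placenta, high methylation in oocytes, and high
#' expression.
#'
#' @param ... Named character vectors (gene-id sets), or a single named
#'   list of them.
#' @return `data.frame` with `sets` (names joined by `&`) and `size`.
#' @export
gene_set_overlap <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.character(sets[[1]]))
    sets <- sets[[1]]
  stop_if_not(length(sets) >= 2 && !is.null(names(sets)),
              "provide >= 2 named sets")
  sets <- lapply(sets, unique)
  nm <- names(sets)
  out <- list()
  for (k in seq(1, length(sets))) {
    combos <- utils::combn(nm, k, simplify = FALSE)
    for (cmb in combos) {
      size <- length(Reduce(intersect, sets[cmb]))
      out[[length(out) + 1L]] <- data.frame(sets = paste(cmb, collapse = "&"),
                                            size = size,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
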