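# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Normalize chromosome names
#'
#' Adds or strips the `"chr"` prefix so tracks from different sources join on
#' the same chromosome labels.
#'
#' @param x Character vector of chromosome names.
#' @param style `"chr"` (UCSC style, `chr1`) or `"plain"` (Ensembl style, `1`).
#' @return Character vector of normalized names.
#' @export
normalize_chroms <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", as.character(x))
  if (style == "chr") paste0("chr", bare) else bare
}

# Convert a 0-based half-open interval data.frame to GRanges (1-based closed).
iv_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# Point positions (0-based) to width-1 GRanges.
pos_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1, width = 1L))
}

# Logical: is each (chrom, pos) 0-based point inside any interval of `ivs`
# (0-based half-open data.frame with chrom/start/end)?
points_in_intervals <- function(chrom, pos, ivs) {
  if (length(pos) == 0L) return(logical(0))
  if (is.null(ivs) || nrow(ivs) == 0L) return(rep(FALSE, length(pos)))
  GenomicRanges::countOverlaps(pos_to_gr(chrom, pos), iv_to_gr(ivs)) > 0L
}

# Total bp of the union of `ivs` clipped to one interval (chrom, start, end).
masked_bp_in <- function(ivs, chrom, start, end) {
  if (is.null(ivs) || nrow(ivs) == 0L) return(0L)
  keep <- ivs$chrom == chrom & ivs$end > start & ivs$start < end
  if (!any(keep)) return(0L)
  clip <- ivs[keep, , drop = FALSE]
  clip$start <- pmax(clip$start, start)
  clip$end <- pmin(clip$end, end)
  red <- GenomicRanges::reduce(iv_to_gr(clip))
  sum(as.integer(IRanges::width(red)))
}

# Distance from each point to the nearest value in a sorted numeric vector.
dist_to_nearest_point <- function(pos, points) {
  if (length(points) == 0L) return(rep(NA_real_, length(pos)))
  points <- sort(points)
  idx <- findInterval(pos, points)
  lo <- ifelse(idx >= 1L, points[pmax(idx, 1L)], Inf)
  hi <- ifelse(idx < length(points), points[pmin(idx + 1L, length(points))], Inf)
  pmin(abs(pos - lo), abs(hi - pos))
}

# Draw n values from a Gaussian truncated to [lo, hi] (inverse-CDF method).
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (all(sd == 0)) return(pmin(pmax(mean, lo), hi))
  a <- pnorm(lo, mean, sd)
  b <- pnorm(hi, mean, sd)
  u <- runif(n, a, b)
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
}

stop_if_not <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
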