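# window_analysis: fixed-window methylation tracks, smoothing, density
# summaries and track correlation.

#' Average methylation in non-overlapping fixed windows
#'
#' Tiles each chromosome into abutting `window_size`-bp windows and computes
#' the unweighted mean of per-site methylation fractions of the covered CpGs
#' in each window. Windows with fewer than `min_cpgs` covered sites are kept
#' in the grid but have missing (`NA`) methylation, mirroring the discard
#' rule used for 20 kb windows with fewer than 20 informative CpGs.
#'
#' @param calls A [cpg_calls] table. Sites with no methylation information
#'   (zero coverage and no fraction) do not count as covered.
#' @param window_size Window width in bp (default 20000).
#' @param min_cpgs Minimum covered CpG sites for a window mean (default 20).
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   given, the tiling extends to the chromosome end (a trailing partial
#'   window is kept if it meets `min_cpgs`), otherwise to the last covered
#'   CpG.
#' @return A `data.frame` of class `window_track` with columns `chrom`,
#'   `start`, `end`, `mean_meth`, `n_cpgs`; attribute `window_size`.
#' @export
window_methylation <- function(calls, window_size = 20000, min_cpgs = 20,
                               chrom_lengths = NULL) {
  stop_if_not(window_size > 0, "window_size must be > 0")
  stop_if_not(min_cpgs >= 1, "min_cpgs must be >= 1")
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths)
            else sort(unique(calls$chrom))
  res <- lapply(chroms, function(cc) {
    sub <- calls[calls$chrom == cc, , drop = FALSE]
    covered <- !is.na(sub$fraction)
    nw <- if (!is.null(chrom_lengths)) {
      as.integer(ceiling(chrom_lengths[[cc]] / window_size))
    } else if (any(covered)) {
      as.integer(max(sub$pos[covered]) %/% window_size) + 1L
    } else 0L
    if (nw == 0L) return(NULL)
    n <- integer(nw); s <- numeric(nw)
    if (any(covered)) {
      idx <- as.integer(sub$pos[covered] %/% window_size) + 1L
      keep <- idx <= nw
      idx <- idx[keep]
      fr <- sub$fraction[covered][keep]
      n <- tabulate(idx, nbins = nw)
      agg <- rowsum(fr, group = idx)
      s[as.integer(rownames(agg))] <- agg[, 1]
    }
    mean_meth <- ifelse(n >= min_cpgs, s / n, NA_real_)
    starts <- (seq_len(nw) - 1) * window_size
    ends <- pmin(starts + window_size,
                 if (!is.null(chrom_lengths)) chrom_lengths[[cc]] else
                   starts + window_size)
    data.frame(chrom = cc, start = starts, end = ends,
               mean_meth = mean_meth, n_cpgs = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_meth = numeric(0),
                      n_cpgs = integer(0))
  rownames(out) <- NULL
  attr(out, "window_size") <- window_size
  attr(out, "min_cpgs") <- min_cpgs
  class(out) <- c("window_track", "data.frame")
  out
}

#' Global (read-weighted) methylation level
#'
#' The average methylation of all CpG sites in all aligned reads:
#' `sum(meth_reads) / sum(total_reads)`. For fraction-dialect tracks without
#' read counts it falls back to the unweighted mean of site fractions, with a
#' warning.
#'
#' @param calls A [cpg_calls] table.
#' @return A single fraction in `[0, 1]`.
#' @export
global_methylation <- function(calls) {
  if (all(!is.na(calls$total_reads))) {
    tot <- sum(calls$total_reads)
    stop_if_not(tot > 0, "no aligned reads")
    sum(calls$meth_reads) / tot
  } else {
    warning("read counts unknown; using unweighted mean of site fractions")
    mean(calls$fraction, na.rm = TRUE)
  }
}

#' Running median over an ordered series
#'
#' Centered running median with odd width, ignoring missing values. At the
#' series ends the neighborhood shrinks symmetrically (half-width
#' `min(h, i - 1, n - i)`), so the window stays centered and odd; this keeps
#' the smoother an exact identity — hence idempotent — on monotone series.
#' An all-missing neighborhood yields `NA`.
#'
#' @param values Numeric series (may contain `NA`).
#' @param width Odd window width in elements (default 15).
#' @return Smoothed numeric series of the same length.
#' @export
running_median <- function(values, width = 15) {
  stop_if_not(width >= 1 && width %% 2 == 1, "width must be odd and >= 1")
  n <- length(values)
  if (n == 0L) return(numeric(0))
  h <- (width - 1L) / 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    w <- values[(i - hi):(i + hi)]
    w <- w[!is.na(w)]
    if (!length(w)) NA_real_ else median(w)
  }, numeric(1))
}

#' Gaussian kernel smoothing of a window track
#'
#' Nadaraya-Watson estimate with a Gaussian kernel over window centers,
#' evaluated at every window center. Missing windows contribute to neither
#' numerator nor denominator, and no value is produced where no covered
#' window lies within one bandwidth of the evaluation point (smoothing never
#' invents signal inside long missing-data gaps, which would otherwise
#' produce the spurious excursions seen when sparse lifted data are smoothed
#' naively).
#'
#' @param track A `window_track` (see [window_methylation()]).
#' @param bandwidth Kernel standard deviation in bp; default three window
#'   widths.
#' @return `track` with an added `smooth` column.
#' @export
kernel_smooth <- function(track, bandwidth = NULL) {
  ws <- attr(track, "window_size")
  if (is.null(bandwidth)) bandwidth <- 3 * ws
  stop_if_not(bandwidth > 0, "bandwidth must be > 0")
  out <- track
  out$smooth <- NA_real_
  for (cc in unique(track$chrom)) {
    sel <- which(track$chrom == cc)
    centers <- (track$start[sel] + track$end[sel]) / 2
    y <- track$mean_meth[sel]
    ok <- which(!is.na(y))
    if (!length(ok)) next
    xo <- centers[ok]; yo <- y[ok]
    sm <- vapply(centers, function(x0) {
      d <- xo - x0
      if (min(abs(d)) > bandwidth) return(NA_real_)
      w <- dnorm(d, sd = bandwidth)
      sum(w * yo) / sum(w)
    }, numeric(1))
    out$smooth[sel] <- sm
  }
  out
}

#' Density summary of window methylation
#'
#' Gaussian kernel density (Silverman's rule bandwidth) of window methylation
#' on the percent scale `[0, 100]`, with median, interquartile range, and an
#' operational bimodality flag: the flag is true when the density has at
#' least two local maxima separated by a trough lower than
#' `(1 - trough_depth)` times the smaller of the two peaks. Peaks smaller
#' than `peak_floor` times the global maximum are ignored as numerical
#' ripple.
#'
#' @param track A `window_track` with at least 2 covered windows.
#' @param grid_step Evaluation grid step in percent (default 0.5).
#' @param trough_depth Required relative trough depth (default 0.15).
#' @param peak_floor Minimum peak height relative to the density maximum
#'   (default 0.05).
#' @return A list of class `methylation_density`: `density` (data.frame
#'   `x`, `y`), `median`, `iqr` (named length-2), `bimodal`, `n_peaks`, `n`,
#'   `bw`. Degenerate all-equal input yields a point-mass summary with
#'   `density = NULL`.
#' @export
methylation_density <- function(track, grid_step = 0.5, trough_depth = 0.15,
                                peak_floor = 0.05) {
  x <- track$mean_meth[!is.na(track$mean_meth)] * 100
  stop_if_not(length(x) >= 2, "need at least 2 covered windows")
  med <- median(x)
  iqr <- quantile(x, c(0.25, 0.75), names = FALSE)
  if (diff(range(x)) < 1e-9) {
    return(structure(list(density = NULL, median = med,
                          iqr = c(lower = iqr[1], upper = iqr[2]),
                          bimodal = FALSE, n_peaks = 1L, n = length(x),
                          bw = NA_real_),
                     class = "methylation_density"))
  }
  ngrid <- as.integer(round(100 / grid_step)) + 1L
  d <- density(x, bw = "nrd0", from = 0, to = 100, n = ngrid)
  # renormalize over [0, 100] (trapezoid) so the truncated density integrates
  # to one
  area <- sum((d$y[-1] + d$y[-ngrid]) / 2) * diff(d$x[1:2])
  y <- d$y / area
  is_peak <- c(FALSE, y[2:(ngrid - 1)] > y[1:(ngrid - 2)] &
                 y[2:(ngrid - 1)] >= y[3:ngrid], FALSE)
  is_peak[1] <- y[1] > y[2]
  is_peak[ngrid] <- y[ngrid] > y[ngrid - 1]
  peaks <- which(is_peak & y >= peak_floor * max(y))
  bimodal <- FALSE
  if (length(peaks) >= 2) {
    for (i in seq_len(length(peaks) - 1)) {
      for (j in (i + 1):length(peaks)) {
        trough <- min(y[peaks[i]:peaks[j]])
        lower_peak <- min(y[peaks[i]], y[peaks[j]])
        if (trough < (1 - trough_depth) * lower_peak) bimodal <- TRUE
      }
    }
  }
  structure(list(density = data.frame(x = d$x, y = y), median = med,
                 iqr = c(lower = iqr[1], upper = iqr[2]), bimodal = bimodal,
                 n_peaks = length(peaks), n = length(x), bw = d$bw),
            class = "methylation_density")
}

#' Pearson correlation of two window tracks
#'
#' Tracks must be on the same window grid; only windows covered in both are
#' used.
#'
#' @param a,b `window_track` objects on identical grids.
#' @return A list with `r` (Pearson correlation) and `n` (shared windows).
#' @export
correlate_tracks <- function(a, b) {
  stop_if_not(nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
                all(a$start == b$start),
              "tracks must share the same window grid")
  ok <- !is.na(a$mean_meth) & !is.na(b$mean_meth)
  n <- sum(ok)
  if (n < 3) stop("fewer than 3 shared covered windows", call. = FALSE)
  list(r = cor(a$mean_meth[ok], b$mean_meth[ok]), n = n)
}

#' Export a window track as bedGraph
#' @param track A `window_track`.
#' @param path Output path.
#' @param column Which column to write (`"mean_meth"` or `"smooth"`).
#' @return `path`, invisibly.
#' @export
write_window_track <- function(track, path, column = "mean_meth") {
  ok <- !is.na(track[[column]])
  lines <- sprintf("%s\t%d\t%d\t%.6f", track$chrom[ok],
                   as.integer(track$start[ok]), as.integer(track$end[ok]),
                   track[[column]][ok])
  writeLines(lines, path)
  invisible(path)
}
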