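# Shared fixtures, built in code. Generators are deterministic under seed,
# so repeated calls with the same arguments return identical objects.

# Random count-dialect call table on one chromosome.
random_calls <- function(n, seed, chrom = "chr1", span = 1e5,
                         max_depth = 20) {
  set.seed(seed)
  pos <- sort(sample(span, n))
  depth <- sample(0:max_depth, n, replace = TRUE)
  meth <- rbinom(n, depth, runif(n))
  cpg_calls(chrom, pos, meth, depth)
}

# Brute-force window means: direct subsetting per window, mean of fractions.
brute_window_means <- function(calls, window_size, min_cpgs) {
  covered <- calls[!is.na(calls$fraction), , drop = FALSE]
  out <- list()
  for (cc in sort(unique(calls$chrom))) {
    sub <- covered[covered$chrom == cc, , drop = FALSE]
    if (!nrow(sub)) next
    nw <- max(sub$pos) %/% window_size + 1
    for (w in seq_len(nw)) {
      lo <- (w - 1) * window_size; hi <- lo + window_size
      f <- sub$fraction[sub$pos >= lo & sub$pos < hi]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start = lo, n = length(f),
        mean = if (length(f) >= min_cpgs) mean(f) else NA_real_)
    }
  }
  do.call(rbind, out)
}

# Naive O(n*w) running median, symmetric shrinking end windows, NA-dropping.
brute_running_median <- function(x, width) {
  h <- (width - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- h
    while (i - hi < 1 || i + hi > n) hi <- hi - 1
    w <- x[(i - hi):(i + hi)]
    w <- w[!is.na(w)]
    out[i] <- if (!length(w)) NA_real_ else median(w)
  }
  out
}

# A small domain-structured genome + methylome shared by several tests.
demo_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- simulate_genome(genome_spec(chrom_lengths = c(chr1 = 4e6),
                                       n_genes = 60, n_islands = 80),
                           seed = 301)
      ms <- simulate_methylome(g, methylome_spec(), seed = 302)
      cache <<- list(genome = g, methylome = ms)
    }
    cache
  }
})

# A window track built directly from given per-window means (20 kb grid).
track_from_means <- function(means, chrom = "chr1", window_size = 20000) {
  n <- length(means)
  out <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * window_size,
                    end = seq_len(n) * window_size, mean_meth = means,
                    n_cpgs = ifelse(is.na(means), 0L, 50L))
  attr(out, "window_size") <- window_size
  class(out) <- c("window_track", "data.frame")
  out
}
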