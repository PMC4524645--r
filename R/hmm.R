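# domain_segmentation: two-state Gaussian-emission HMM over window
# methylation (PMD = lower-mean state, HMD = higher-mean state), plus a
# permutation test of boundary proximity to genomic features.

# Split a window track into observation segments: per chromosome, runs of
# windows separated by more than gap_max consecutive missing windows. Missing
# windows inside a segment are simply skipped (the chain is not restarted).
track_segments <- function(track, gap_max = 5) {
  segs <- list()
  for (cc in unique(track$chrom)) {
    sel <- which(track$chrom == cc)
    ok <- sel[!is.na(track$mean_meth[sel])]
    if (!length(ok)) next
    # window index within chromosome, used to measure gaps
    widx <- match(ok, sel)
    brk <- c(0L, which(diff(widx) > gap_max + 1L), length(ok))
    for (i in seq_len(length(brk) - 1L)) {
      rows <- ok[(brk[i] + 1L):brk[i + 1L]]
      segs[[length(segs) + 1L]] <-
        list(chrom = cc, rows = rows, obs = track$mean_meth[rows])
    }
  }
  segs
}

# Scaled forward-backward for one observation vector. Returns log-likelihood
# and posterior quantities needed by Baum-Welch.
fb_pass <- function(obs, mu, sigma, A, pi0) {
  Tn <- length(obs); K <- length(mu)
  B <- matrix(0, Tn, K)
  for (k in seq_len(K))
    B[, k] <- pmax(dnorm(obs, mu[k], sigma[k]), 1e-300)
  alpha <- matrix(0, Tn, K); cvec <- numeric(Tn)
  a <- pi0 * B[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  if (Tn >= 2) for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  if (Tn >= 2) for (t in (Tn - 1):1)
    beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  for (t in seq_len(Tn - 1)) {
    x <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A
    xi_sum <- xi_sum + x / sum(x)
  }
  list(loglik = sum(log(cvec)), gamma = gamma, xi_sum = xi_sum)
}

viterbi_path <- function(obs, mu, sigma, A, pi0) {
  Tn <- length(obs); K <- length(mu)
  logB <- matrix(0, Tn, K)
  for (k in seq_len(K))
    logB[, k] <- dnorm(obs, mu[k], sigma[k], log = TRUE)
  logA <- log(A)
  delta <- matrix(-Inf, Tn, K); psi <- matrix(0L, Tn, K)
  delta[1, ] <- log(pi0) + logB[1, ]
  if (Tn >= 2) for (t in 2:Tn) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn >= 2) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

# Merge sub-threshold domains within one segment's run-length encoding.
merge_short_runs <- function(runs, min_domain_bp) {
  repeat {
    if (nrow(runs) <= 1L) break
    len <- runs$end - runs$start
    small <- which(len < min_domain_bp)
    if (!length(small)) break
    i <- small[which.min(len[small])]
    nb <- c(if (i > 1L) i - 1L, if (i < nrow(runs)) i + 1L)
    j <- nb[which.max((runs$end - runs$start)[nb])]
    runs$state[i] <- runs$state[j]
    # collapse adjacent equal states
    keep <- c(TRUE, runs$state[-1] != runs$state[-nrow(runs)])
    grp <- cumsum(keep)
    runs <- data.frame(state = runs$state[keep],
                       start = as.numeric(tapply(runs$start, grp, min)),
                       end = as.numeric(tapply(runs$end, grp, max)))
  }
  runs
}

#' Segment a window track into PMDs and HMDs
#'
#' Fits a two-state Gaussian-emission hidden Markov model to the covered
#' window means by Baum-Welch (emissions shared genome-wide; the chain is
#' decoded per chromosome and restarted across missing-data gaps longer than
#' `gap_max` windows), Viterbi-decodes the state path, merges adjacent
#' same-state windows into domains, and labels the lower-emission-mean state
#' PMD. Domains shorter than `min_domain_bp` are absorbed into their longer
#' neighbor. When the fitted state means are closer than `min_separation`
#' the track is declared to have no PMD structure and a single HMD spans each
#' chromosome's analyzable windows.
#'
#' @param track A `window_track` with at least 50 covered windows.
#' @param max_iter,tol Baum-Welch iteration cap (default 100) and relative
#'   log-likelihood convergence tolerance (default 1e-8).
#' @param seed RNG seed (the fit itself is deterministic — quartile-based
#'   initialization — but the seed is part of the interface for
#'   reproducibility of any downstream stochastic use).
#' @param min_domain_bp Minimum domain length in bp (default 1e5).
#' @param gap_max Maximum run of missing windows bridged within one chain
#'   (default 5).
#' @param min_separation Minimum distance between fitted state means for a
#'   PMD/HMD call (default 0.10).
#' @return A list of class `domain_segmentation`: `domains` (data.frame
#'   `chrom`, `start`, `end`, `state`, `mean_meth`, `n_windows`), `emission`
#'   (per-state mean/sd), `loglik` (per-iteration vector), `converged`,
#'   `no_structure`, `window_size`.
#' @export
fit_domain_hmm <- function(track, max_iter = 100, tol = 1e-8, seed = 1,
                           min_domain_bp = 1e5, gap_max = 5,
                           min_separation = 0.10) {
  obs_all <- track$mean_meth[!is.na(track$mean_meth)]
  stop_if_not(length(obs_all) >= 50, "need at least 50 covered windows")
  stop_if_not(all(obs_all >= -1e-9 & obs_all <= 1 + 1e-9),
              "window methylation must lie in [0, 1]")
  segs <- track_segments(track, gap_max = gap_max)
  ws <- attr(track, "window_size")

  degenerate <- sd(obs_all) < 1e-8
  mu <- sigma <- c(NA_real_, NA_real_); ll_trace <- numeric(0)
  converged <- TRUE
  if (!degenerate) {
    mu <- unname(quantile(obs_all, c(0.25, 0.75)))
    sigma <- rep(max((mu[2] - mu[1]) / 2, 1e-3), 2)
    A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
    pi0 <- c(0.5, 0.5)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      ll <- 0
      g_sum <- numeric(2); g1 <- numeric(2); xi <- matrix(0, 2, 2)
      m_sum <- numeric(2); v_sum <- numeric(2)
      passes <- vector("list", length(segs))
      for (s in seq_along(segs)) {
        p <- fb_pass(segs[[s]]$obs, mu, sigma, A, pi0)
        passes[[s]] <- p
        ll <- ll + p$loglik
        g1 <- g1 + p$gamma[1, ]
        g_sum <- g_sum + colSums(p$gamma)
        xi <- xi + p$xi_sum
        m_sum <- m_sum + colSums(p$gamma * segs[[s]]$obs)
      }
      ll_trace <- c(ll_trace, ll)
      if (iter > 1 &&
          abs(ll - ll_trace[iter - 1]) < tol * (abs(ll_trace[iter - 1]) + 1)) {
        converged <- TRUE
        break
      }
      pi0 <- g1 / sum(g1)
      pi0 <- pmax(pi0, 1e-6); pi0 <- pi0 / sum(pi0)
      A <- xi / rowSums(xi)
      A <- pmax(A, 1e-6); A <- A / rowSums(A)
      mu_new <- m_sum / g_sum
      for (s in seq_along(segs))
        v_sum <- v_sum + colSums(passes[[s]]$gamma *
                                   outer(segs[[s]]$obs, mu_new, "-")^2)
      mu <- mu_new
      sigma <- pmax(sqrt(v_sum / g_sum), 1e-4)
    }
    # canonical state order: state 1 = PMD (lower mean)
    if (mu[1] > mu[2]) {
      mu <- rev(mu); sigma <- rev(sigma)
      A <- A[2:1, 2:1]; pi0 <- rev(pi0)
    }
  }

  no_structure <- degenerate || (mu[2] - mu[1]) < min_separation
  if (no_structure) {
    doms <- do.call(rbind, lapply(split(seq_along(segs), vapply(
      segs, function(s) s$chrom, character(1))), function(ii) {
        rows <- unlist(lapply(segs[ii], `[[`, "rows"))
        data.frame(chrom = segs[[ii[1]]]$chrom,
                   start = min(track$start[rows]),
                   end = max(track$end[rows]), state = "HMD",
                   mean_meth = mean(track$mean_meth[rows]),
                   n_windows = length(rows), stringsAsFactors = FALSE)
      }))
    emission <- data.frame(state = c("PMD", "HMD"), mean = c(NA, mean(obs_all)),
                           sd = c(NA, sd(obs_all)))
  } else {
    dom_list <- lapply(segs, function(sg) {
      path <- viterbi_path(sg$obs, mu, sigma, A, pi0)
      r <- rle(path)
      stops <- cumsum(r$lengths)
      starts_i <- c(1L, head(stops, -1L) + 1L)
      runs <- data.frame(state = r$values,
                         start = as.numeric(track$start[sg$rows[starts_i]]),
                         end = as.numeric(track$end[sg$rows[stops]]))
      runs <- merge_short_runs(runs, min_domain_bp)
      # per-domain summaries over the segment's covered windows
      w_start <- track$start[sg$rows]
      dom_of <- findInterval(w_start, runs$start)
      data.frame(chrom = sg$chrom, start = runs$start, end = runs$end,
                 state = c("PMD", "HMD")[runs$state],
                 mean_meth = as.numeric(tapply(sg$obs, dom_of, mean)),
                 n_windows = as.integer(tabulate(dom_of, nrow(runs))),
                 stringsAsFactors = FALSE)
    })
    doms <- do.call(rbind, dom_list)
    emission <- data.frame(state = c("PMD", "HMD"), mean = mu, sd = sigma)
  }
  doms <- doms[order(doms$chrom, doms$start, method = "radix"), , drop = FALSE]
  rownames(doms) <- NULL
  structure(list(domains = doms, emission = emission, loglik = ll_trace,
                 converged = converged, no_structure = no_structure,
                 window_size = ws),
            class = "domain_segmentation")
}

#' Extract PMD/HMD boundaries from a segmentation
#'
#' Internal change-points only: junctions where two domains abut on the same
#' chromosome (domains separated by missing-data gaps do not form an
#' observable boundary).
#'
#' @param seg A `domain_segmentation`.
#' @return `data.frame` with `chrom`, `pos`.
#' @export
domain_boundaries <- function(seg) {
  d <- seg$domains
  res <- list()
  for (cc in unique(d$chrom)) {
    s <- d[d$chrom == cc, , drop = FALSE]
    if (nrow(s) < 2) next
    abut <- s$end[-nrow(s)] == s$start[-1]
    pos <- s$end[-nrow(s)][abut]
    if (length(pos))
      res[[cc]] <- data.frame(chrom = cc, pos = pos, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(chrom = character(0), pos = numeric(0))
  rownames(out) <- NULL
  out
}

#' Test PMD boundary proximity to genomic features
#'
#' Observed statistic: the median, over all domain boundaries, of the
#' distance to the nearest feature point (interval starts and ends, i.e. gene
#' ends or CpG-island edges). The null re-places each boundary uniformly at
#' random within its chromosome's analyzable span (missing-data gaps carry no
#' observable boundary and are excluded), preserving the per-chromosome
#' boundary count, and the one-sided empirical p-value asks whether
#' boundaries are closer to features than expected by chance.
#'
#' @param seg A `domain_segmentation`, or a list with elements `boundaries`
#'   (data.frame `chrom`, `pos`) and `spans` (data.frame `chrom`, `start`,
#'   `end` of analyzable spans).
#' @param features A [genomic_intervals] table. Chromosomes without features
#'   are excluded from the statistic.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed (required; the null is stochastic).
#' @return A list of class `boundary_proximity`: `observed` (median
#'   distance, bp), `null` (vector of permuted medians), `p` (one-sided,
#'   `(1 + #\{null <= observed\}) / (1 + n_perm)`), `n_boundaries`,
#'   `applicable`.
#' @export
boundary_proximity <- function(seg, features, n_perm = 999, seed) {
  stop_if_not(n_perm >= 100, "n_perm must be >= 100")
  if (inherits(seg, "domain_segmentation")) {
    bounds <- domain_boundaries(seg)
    spans <- seg$domains
    spans <- data.frame(chrom = spans$chrom, start = spans$start,
                        end = spans$end)
  } else {
    bounds <- seg$boundaries
    spans <- seg$spans
  }
  feat_chroms <- unique(features$chrom)
  bounds <- bounds[bounds$chrom %in% feat_chroms, , drop = FALSE]
  if (nrow(bounds) == 0L)
    return(structure(list(observed = NA_real_, null = numeric(0),
                          p = NA_real_, n_boundaries = 0L,
                          applicable = FALSE),
                     class = "boundary_proximity"))
  pts <- split(c(features$start, features$end),
               c(features$chrom, features$chrom))
  per_chrom <- split(bounds$pos, bounds$chrom)
  observed <- median(unlist(Map(function(cc, pos)
    dist_to_nearest_point(pos, pts[[cc]]), names(per_chrom), per_chrom)))
  spans <- spans[spans$chrom %in% names(per_chrom), , drop = FALSE]
  span_by_chrom <- split(spans, spans$chrom)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    d <- unlist(lapply(names(per_chrom), function(cc) {
      sp <- span_by_chrom[[cc]]
      len <- sp$end - sp$start
      u <- runif(length(per_chrom[[cc]]), 0, sum(len))
      # map uniform draws on total span length into the span union
      k <- findInterval(u, cumsum(c(0, len)), rightmost.closed = TRUE)
      k <- pmin(pmax(k, 1L), nrow(sp))
      pos <- sp$start[k] + (u - cumsum(c(0, len))[k])
      dist_to_nearest_point(pos, pts[[cc]])
    }))
    median(d)
  }, numeric(1)))
  p <- (1 + sum(null <= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null, p = p,
                 n_boundaries = nrow(bounds), applicable = TRUE),
            class = "boundary_proximity")
}

#' Export domains as BED
#'
#' Name column is the PMD/HMD label, score is mean methylation x 1000.
#' @param seg A `domain_segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains <- function(seg, path) {
  d <- seg$domains
  write_intervals(data.frame(chrom = d$chrom, start = d$start, end = d$end,
                             label = d$state),
                  path, score = d$mean_meth * 1000)
}
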