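# UCSC chain files: parsing, writing, inversion. A chain maps the "source"
# genome (the file's tName side, the genome coordinates are lifted FROM) to
# the "target" genome (qName side). Internally every block stores
# forward-strand target coordinates; for strand "-" chains a source position
# p in block [s_start, s_end) maps to t_fwd_end - 1 - (p - s_start).

new_chain <- function(id, score, s_chrom, s_size, s_start, s_end,
                      t_chrom, t_size, strand, t_start, t_end, blocks) {
  structure(list(id = id, score = score,
                 s_chrom = s_chrom, s_size = s_size,
                 s_start = s_start, s_end = s_end,
                 t_chrom = t_chrom, t_size = t_size, strand = strand,
                 t_start = t_start, t_end = t_end,
                 blocks = blocks), class = "chain")
}

#' Read a UCSC chain file
#'
#' Parses the standard chain format: a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id` followed by `size dt dq` alignment triplets (last line `size`
#' only). Negative-strand query coordinates are normalized to forward-strand
#' intervals on read.
#'
#' @param path Chain file path.
#' @return A list of chains (class `chain_set`); each chain carries its
#'   score, source/target chromosome metadata and a block table with columns
#'   `s_start`, `s_end`, `t_start`, `t_end` (target coordinates always
#'   forward-strand; `strand` is stored at the chain level).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  hdr_idx <- grep("^chain\\b", lines)
  stop_if_not(length(hdr_idx) > 0, "no chain records found")
  bounds <- c(hdr_idx, length(lines) + 1L)
  chains <- vector("list", length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    h <- strsplit(trimws(lines[hdr_idx[k]]), "\\s+")[[1]]
    stop_if_not(length(h) >= 12, "chain header must have 12 fields")
    score <- as.numeric(h[2])
    s_chrom <- h[3]; s_size <- as.numeric(h[4])
    stop_if_not(h[5] == "+", "tStrand must be '+' in chain format")
    s_start <- as.numeric(h[6]); s_end <- as.numeric(h[7])
    t_chrom <- h[8]; t_size <- as.numeric(h[9]); strand <- h[10]
    q_start <- as.numeric(h[11]); q_end <- as.numeric(h[12])
    id <- if (length(h) >= 13) h[13] else as.character(k)
    body <- lines[(hdr_idx[k] + 1L):(bounds[k + 1L] - 1L)]
    body <- trimws(body)
    body <- body[nzchar(body)]
    trip <- lapply(strsplit(body, "\\s+"), as.numeric)
    nb <- length(trip)
    stop_if_not(nb >= 1, "chain has no alignment lines")
    s0 <- s_start; q0 <- q_start
    bl <- matrix(NA_real_, nrow = nb, ncol = 4)
    for (i in seq_len(nb)) {
      size <- trip[[i]][1]
      bl[i, 1] <- s0; bl[i, 2] <- s0 + size
      bl[i, 3] <- q0; bl[i, 4] <- q0 + size       # q-strand coords for now
      if (i < nb) {
        stop_if_not(length(trip[[i]]) == 3,
                    "non-final alignment line must be 'size dt dq'")
        s0 <- s0 + size + trip[[i]][2]
        q0 <- q0 + size + trip[[i]][3]
      } else {
        s0 <- s0 + size; q0 <- q0 + size
      }
    }
    if (abs(s0 - s_end) > 0 || abs(q0 - q_end) > 0)
      stop("format error: block arithmetic does not sum to declared chain ",
           "span (chain ", id, ")", call. = FALSE)
    blocks <- data.frame(s_start = bl[, 1], s_end = bl[, 2])
    if (strand == "+") {
      blocks$t_start <- bl[, 3]; blocks$t_end <- bl[, 4]
      t_start <- q_start; t_end <- q_end
    } else if (strand == "-") {
      blocks$t_start <- t_size - bl[, 4]
      blocks$t_end <- t_size - bl[, 3]
      t_start <- t_size - q_end; t_end <- t_size - q_start
    } else stop("qStrand must be '+' or '-'", call. = FALSE)
    chains[[k]] <- new_chain(id, score, s_chrom, s_size, s_start, s_end,
                             t_chrom, t_size, strand, t_start, t_end, blocks)
  }
  structure(chains, class = "chain_set")
}

#' Write a chain set as a UCSC chain file
#'
#' @param chains A `chain_set` (see [read_chain()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  out <- character(0)
  for (ch in chains) {
    bl <- ch$blocks
    if (ch$strand == "+") {
      q_s <- bl$t_start; q_e <- bl$t_end
      q_start <- ch$t_start; q_end <- ch$t_end
    } else {
      # back to q-strand coordinates; ascending s <=> descending forward t
      q_s <- ch$t_size - bl$t_end; q_e <- ch$t_size - bl$t_start
      q_start <- ch$t_size - ch$t_end; q_end <- ch$t_size - ch$t_start
    }
    hdr <- sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                   format(ch$score, scientific = FALSE, trim = TRUE),
                   ch$s_chrom, as.integer(ch$s_size),
                   as.integer(ch$s_start), as.integer(ch$s_end),
                   ch$t_chrom, as.integer(ch$t_size), ch$strand,
                   as.integer(q_start), as.integer(q_end), ch$id)
    nb <- nrow(bl)
    body <- character(nb)
    for (i in seq_len(nb)) {
      size <- bl$s_end[i] - bl$s_start[i]
      if (i < nb) {
        dt <- bl$s_start[i + 1] - bl$s_end[i]
        dq <- q_s[i + 1] - q_e[i]
        body[i] <- sprintf("%d %d %d", as.integer(size), as.integer(dt),
                           as.integer(dq))
      } else body[i] <- sprintf("%d", as.integer(size))
    }
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

# Flatten a chain_set to one block-level data.frame used by lift_cpgs.
chain_block_table <- function(chains) {
  do.call(rbind, lapply(chains, function(ch) {
    data.frame(chain_id = ch$id, score = ch$score, strand = ch$strand,
               s_chrom = ch$s_chrom, s_start = ch$blocks$s_start,
               s_end = ch$blocks$s_end, t_chrom = ch$t_chrom,
               t_size = ch$t_size, t_start = ch$blocks$t_start,
               t_end = ch$blocks$t_end, stringsAsFactors = FALSE)
  }))
}

#' Invert a chain set
#'
#' Produces the chain mapping the target genome back to the source genome.
#' Lifting through a chain and then its inverse returns every mapped site to
#' its origin.
#'
#' @param chains A `chain_set`.
#' @return The inverted `chain_set`.
#' @export
invert_chain <- function(chains) {
  out <- lapply(chains, function(ch) {
    bl <- data.frame(s_start = ch$blocks$t_start, s_end = ch$blocks$t_end,
                     t_start = ch$blocks$s_start, t_end = ch$blocks$s_end)
    bl <- bl[order(bl$s_start), , drop = FALSE]
    rownames(bl) <- NULL
    new_chain(ch$id, ch$score, ch$t_chrom, ch$t_size,
              min(bl$s_start), max(bl$s_end),
              ch$s_chrom, ch$s_size, ch$strand,
              min(bl$t_start), max(bl$t_end), bl)
  })
  structure(out, class = "chain_set")
}
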