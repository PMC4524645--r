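# methylome_io: readers and writers for every external format the pipeline
# touches. All coordinates are 0-based half-open internally; wig-style
# 1-based inputs must be converted by the caller before construction.

#' Construct a per-CpG methylation call table
#'
#' The core container for single-CpG methylation evidence. Count-dialect
#' calls carry `meth_reads`/`total_reads`; fraction-dialect calls (public wig
#' exports that only report percentages) carry `fraction` with read counts
#' unknown (`NA`), and are treated as weight-1 sites in all averaging.
#'
#' @param chrom Chromosome names.
#' @param pos 0-based position of the CpG cytosine on the forward strand.
#' @param meth_reads,total_reads Read counts, `NA` for fraction-dialect calls.
#' @param fraction Methylation fraction in `[0, 1]`; computed from counts when
#'   omitted.
#' @return A `data.frame` of class `cpg_calls`, sorted by (chrom, pos), with
#'   columns `chrom`, `pos`, `meth_reads`, `total_reads`, `fraction`.
#' @export
cpg_calls <- function(chrom, pos, meth_reads = NA_integer_,
                      total_reads = NA_integer_, fraction = NULL) {
  n <- length(pos)
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   meth_reads = rep_len(as.numeric(meth_reads), n),
                   total_reads = rep_len(as.numeric(total_reads), n),
                   stringsAsFactors = FALSE)
  stop_if_not(all(df$pos >= 0), "positions must be >= 0")
  has_counts <- !is.na(df$total_reads)
  if (any(has_counts)) {
    bad <- which(has_counts &
                   (df$meth_reads < 0 | df$meth_reads > df$total_reads))
    if (length(bad))
      stop("meth_reads > total_reads (or negative) at row ", bad[1],
           call. = FALSE)
  }
  if (is.null(fraction)) {
    df$fraction <- ifelse(has_counts & df$total_reads > 0,
                          df$meth_reads / df$total_reads, NA_real_)
  } else {
    df$fraction <- as.numeric(fraction)
    stop_if_not(all(is.na(df$fraction) | (df$fraction >= -1e-9 & df$fraction <= 1 + 1e-9)),
                "fractions must lie in [0, 1]")
    df$fraction <- pmin(pmax(df$fraction, 0), 1)
  }
  o <- order(df$chrom, df$pos, method = "radix")
  if (is.unsorted(o)) df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cpg_calls", "data.frame")
  df
}

#' Merge symmetric CpG calls from the two DNA strands
#'
#' A CpG's methylation is symmetric: a forward-strand call at position `p` and
#' its reverse-strand partner at `p + 1` describe the same site. Merging sums
#' the read counts of such pairs and keeps position `p`. For fraction-dialect
#' calls the two fractions are averaged. The operation is idempotent: merging
#' an already-merged track changes nothing.
#'
#' @param calls A [cpg_calls] table.
#' @return A merged `cpg_calls` table.
#' @export
combine_strands <- function(calls) {
  if (nrow(calls) < 2L) return(calls)
  nxt_same <- c(calls$chrom[-1] == calls$chrom[-nrow(calls)] &
                  calls$pos[-1] == calls$pos[-nrow(calls)] + 1, FALSE)
  # a row is a partner only if it was not itself matched as a leader
  leader <- logical(nrow(calls))
  i <- 1L
  while (i < nrow(calls)) {
    if (nxt_same[i]) { leader[i] <- TRUE; i <- i + 2L } else i <- i + 1L
  }
  partner_idx <- which(leader) + 1L
  if (!length(partner_idx)) return(calls)
  li <- which(leader)
  m <- calls$meth_reads; t <- calls$total_reads; f <- calls$fraction
  counts <- !is.na(t[li]) & !is.na(t[partner_idx])
  m[li] <- ifelse(counts, m[li] + m[partner_idx], m[li])
  t[li] <- ifelse(counts, t[li] + t[partner_idx], t[li])
  f[li] <- ifelse(counts,
                  ifelse(t[li] > 0, m[li] / t[li], NA_real_),
                  rowMeans(cbind(f[li], f[partner_idx]), na.rm = TRUE))
  f[li][is.nan(f[li])] <- NA_real_
  out <- calls
  out$meth_reads <- m; out$total_reads <- t; out$fraction <- f
  out <- out[-partner_idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_calls", "data.frame")
  out
}

#' Read a per-CpG methylation track
#'
#' Understands two tab-delimited dialects: a count dialect
#' (`chrom  pos  meth_reads  total_reads`, 0-based positions) and a
#' bedGraph fraction dialect (`chrom  start  end  fraction`). The dialect is
#' auto-detected (a fraction dialect has `end == start + 1` rows and a
#' non-count 4th column) or can be forced.
#'
#' @param path File path. `track`/`#` header lines are skipped.
#' @param combine_strands Merge forward/reverse calls at `p`/`p + 1`
#'   (see [combine_strands()]).
#' @param dialect `"auto"`, `"counts"` or `"fraction"`.
#' @return A [cpg_calls] table, sorted; unsorted input is sorted with a
#'   warning.
#' @export
read_cpg_track <- function(path, combine_strands = FALSE,
                           dialect = c("auto", "counts", "fraction")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines))
    return(cpg_calls(character(0), numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L))
    stop("malformed line ", which(keep)[which(nf < 4L)[1]],
         ": expected 4 tab-separated fields", call. = FALSE)
  mat <- vapply(parts, function(p) p[1:4], character(4))
  c2 <- suppressWarnings(as.numeric(mat[2, ]))
  c3 <- suppressWarnings(as.numeric(mat[3, ]))
  c4 <- suppressWarnings(as.numeric(mat[4, ]))
  bad <- which(is.na(c2) | is.na(c3) | is.na(c4))
  if (length(bad))
    stop("malformed line ", which(keep)[bad[1]], ": non-numeric field",
         call. = FALSE)
  if (dialect == "auto") {
    looks_bedgraph <- all(c3 == c2 + 1) &&
      (any(c4 != round(c4)) || all(c4 <= 1))
    dialect <- if (looks_bedgraph) "fraction" else "counts"
  }
  if (dialect == "counts") {
    bad <- which(c3 > c4)
    if (length(bad))
      stop("validation error at line ", which(keep)[bad[1]],
           ": meth_reads > total_reads", call. = FALSE)
    out <- data.frame(chrom = mat[1, ], pos = c2, meth = c3, tot = c4,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = mat[1, ], pos = c2, meth = NA_real_,
                      tot = NA_real_, frac = c4, stringsAsFactors = FALSE)
  }
  o <- order(out$chrom, out$pos, method = "radix")
  if (is.unsorted(o)) {
    warning("input not sorted by (chrom, pos); sorting on load")
    out <- out[o, , drop = FALSE]
  }
  calls <- if (dialect == "counts")
    cpg_calls(out$chrom, out$pos, out$meth, out$tot)
  else
    cpg_calls(out$chrom, out$pos, fraction = out$frac)
  if (combine_strands) calls <- combine_strands(calls)
  calls
}

#' Write a per-CpG methylation track
#'
#' Count-dialect output when read counts are known for all sites, bedGraph
#' fraction dialect otherwise. Fractions are written with 6 decimals.
#'
#' @param calls A [cpg_calls] table.
#' @param path Output path.
#' @param dialect `"auto"`, `"counts"` or `"fraction"`.
#' @return `path`, invisibly.
#' @export
write_cpg_track <- function(calls, path,
                            dialect = c("auto", "counts", "fraction")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (all(!is.na(calls$total_reads))) "counts" else "fraction"
  if (dialect == "counts") {
    stop_if_not(all(!is.na(calls$total_reads)),
                "count-dialect output requires read counts for every site")
    lines <- sprintf("%s\t%d\t%d\t%d", calls$chrom, as.integer(calls$pos),
                     as.integer(calls$meth_reads),
                     as.integer(calls$total_reads))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%.6f", calls$chrom, as.integer(calls$pos),
                     as.integer(calls$pos) + 1L, calls$fraction)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a genomic interval table
#'
#' @param chrom,start,end 0-based half-open coordinates.
#' @param label Feature class (e.g. `gene`, `promoter`, `cpg_island`,
#'   `repeat:LINE`, `domain`).
#' @return Sorted `data.frame` of class `genomic_intervals` with columns
#'   `chrom`, `start`, `end`, `label`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   label = rep_len(as.character(label), length(start)),
                   stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("validation error: start >= end at row ", bad[1], call. = FALSE)
  df <- df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Read a BED3+ interval file
#'
#' 0-based half-open, as BED is defined. Overlapping intervals are allowed and
#' preserved.
#'
#' @param path BED file path.
#' @param label Label applied to every interval; when `NULL` the BED name
#'   column (4th) is used if present.
#' @return A [genomic_intervals] table.
#' @export
read_intervals <- function(path, label = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  lab <- if (!is.null(label)) label
         else if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  genomic_intervals(df[[1]], df[[2]], df[[3]], lab)
}

#' Write intervals as BED
#'
#' @param ivs A [genomic_intervals] table (or any data.frame with
#'   chrom/start/end and optional label/score columns).
#' @param path Output path.
#' @param score Optional numeric score vector (BED column 5).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(ivs, path, score = NULL) {
  name <- if ("label" %in% names(ivs)) ivs$label else "."
  name[is.na(name)] <- "."
  if (is.null(score)) {
    lines <- sprintf("%s\t%d\t%d\t%s", ivs$chrom, as.integer(ivs$start),
                     as.integer(ivs$end), name)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d", ivs$chrom, as.integer(ivs$start),
                     as.integer(ivs$end), name, as.integer(round(score)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene model table
#'
#' Gene bodies are the full transcribed span `[tx_start, tx_end)`.
#'
#' @param gene_id Gene identifiers.
#' @param chrom,tx_start,tx_end Transcribed span, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return Sorted `data.frame` of class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, strand, tx_start, tx_end) {
  stop_if_not(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom), strand = as.character(strand),
                   tx_start = as.numeric(tx_start), tx_end = as.numeric(tx_end),
                   stringsAsFactors = FALSE)
  stop_if_not(all(df$tx_start < df$tx_end), "tx_start must be < tx_end")
  df <- df[order(df$chrom, df$tx_start, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from BED6
#'
#' @param path BED6 file (chrom, start, end, gene_id, score, strand).
#' @return A [gene_models] table.
#' @export
read_genes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  stop_if_not(ncol(df) >= 6, "gene BED must have 6 columns (BED6)")
  gene_models(df[[4]], df[[1]], df[[6]], df[[2]], df[[3]])
}

#' Write gene models as BED6
#' @param genes A [gene_models] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom,
                   as.integer(genes$tx_start), as.integer(genes$tx_end),
                   genes$gene_id, genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-separated with header columns `gene_id` and `fpkm`.
#' @param path File path.
#' @return `data.frame` with `gene_id`, `fpkm` (validated non-negative).
#' @export
read_expression <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stop_if_not(all(c("gene_id", "fpkm") %in% names(df)),
              "expression table needs 'gene_id' and 'fpkm' columns")
  stop_if_not(all(df$fpkm >= 0), "fpkm must be non-negative")
  df[, c("gene_id", "fpkm")]
}

#' Write an expression table
#' @param expr `data.frame` with `gene_id` and `fpkm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  write.table(expr[, c("gene_id", "fpkm")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise ortholog table
#'
#' Tab-separated with header `gene_id_a`, `gene_id_b` (pivot species first).
#' @param path File path.
#' @return `data.frame` with the two id columns.
#' @export
read_orthologs <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stop_if_not(ncol(df) >= 2, "ortholog table needs two id columns")
  names(df)[1:2] <- c("gene_id_a", "gene_id_b")
  df[, 1:2]
}

#' Read a simplified synteny-block table
#'
#' Tab-separated with header `chrom`, `start`, `end`, `level` — the distilled
#' form of UCSC net files this pipeline consumes (fill level plus span).
#' @param path File path.
#' @return Sorted `data.frame` with `chrom`, `start`, `end`, `level`,
#'   `span_bp`.
#' @export
read_synteny <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stop_if_not(all(c("chrom", "start", "end", "level") %in% names(df)),
              "synteny table needs chrom/start/end/level columns")
  synteny_blocks(df$chrom, df$start, df$end, df$level)
}

#' Construct a synteny-block table
#' @param chrom,start,end 0-based half-open block span on the target genome.
#' @param level Net fill level (1 = top-level syntenic fill, 2 = fills inside
#'   level-1 gaps).
#' @return Sorted `data.frame` of class `synteny_blocks`.
#' @export
synteny_blocks <- function(chrom, start, end, level) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), level = as.integer(level),
                   stringsAsFactors = FALSE)
  stop_if_not(all(df$level >= 1L), "level must be >= 1")
  stop_if_not(all(df$end > df$start), "block span must be > 0")
  df$span_bp <- df$end - df$start
  df <- df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("synteny_blocks", "data.frame")
  df
}

#' Write a synteny-block table
#' @param blocks A [synteny_blocks] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synteny <- function(blocks, path) {
  write.table(blocks[, c("chrom", "start", "end", "level")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
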