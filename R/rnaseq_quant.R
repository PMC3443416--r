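# RPKM quantification for the sequencing cross-validation arm.
#
# RPKM = count / (exon-model length in kb) / (total mapped reads in
# millions) = count * 1e9 / (length * total). Downstream rank-based
# analyses (Spearman correlation, Spearman-distance clustering) are
# invariant to the subsequent log2 transform, which exists for display and
# Pearson-based clustering.

#' Reads per kilobase of exon model per million mapped reads
#'
#' @param counts nonnegative count vector/matrix (genes x samples).
#' @param gene_lengths positive exon-model lengths in nucleotides, one per
#'   gene (recycled for a vector of counts).
#' @param total_mapped_reads total mapped reads per sample; defaults to the
#'   column sums of `counts`.
#' @return RPKM values with the shape of `counts`.
#' @export
rpkm <- function(counts, gene_lengths, total_mapped_reads = NULL) {
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (is.matrix(counts)) {
    if (length(gene_lengths) != nrow(counts)) {
      stop("need one gene length per count row", call. = FALSE)
    }
    if (is.null(total_mapped_reads)) total_mapped_reads <- colSums(counts)
    if (any(total_mapped_reads <= 0)) {
      stop("total mapped reads must be > 0", call. = FALSE)
    }
    out <- sweep(counts * 1e9 / gene_lengths, 2L, total_mapped_reads, "/")
    dimnames(out) <- dimnames(counts)
    return(out)
  }
  if (is.null(total_mapped_reads)) {
    stop("total_mapped_reads required for vector counts", call. = FALSE)
  }
  if (any(total_mapped_reads <= 0)) {
    stop("total mapped reads must be > 0", call. = FALSE)
  }
  counts * 1e9 / (gene_lengths * total_mapped_reads)
}

#' RPKM table from a count table
#'
#' @param count_table list with `counts` (genes x samples) and `lengths`, as
#'   returned by [read_counts()].
#' @param total_mapped_reads optional per-sample totals (default: column
#'   sums of the count matrix).
#' @return list with `rpkm` (matrix) and `total_mapped_reads`.
#' @export
rpkm_table <- function(count_table, total_mapped_reads = NULL) {
  stopifnot(is.list(count_table), !is.null(count_table$counts),
            !is.null(count_table$lengths))
  counts <- count_table$counts
  lengths <- count_table$lengths[rownames(counts)]
  if (anyNA(lengths)) stop("missing length for some genes", call. = FALSE)
  if (is.null(total_mapped_reads)) total_mapped_reads <- colSums(counts)
  list(rpkm = rpkm(counts, lengths, total_mapped_reads),
       total_mapped_reads = total_mapped_reads)
}

#' log2 transform with pseudo-offset
#'
#' Elementwise `log2(x + offset)`. The default offset of 1 RPKM keeps
#' zero-expression genes finite at 0.
#'
#' @param x nonnegative RPKM vector or matrix.
#' @param offset pseudo-count added before the log; must be > 0 unless every
#'   value is strictly positive.
#' @return transformed values, same shape as `x`.
#' @export
log2_transform <- function(x, offset = 1) {
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  if (offset == 0 && any(x <= 0)) {
    stop("offset 0 requires strictly positive values", call. = FALSE)
  }
  log2(x + offset)
}
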