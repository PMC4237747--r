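# Gene annotation and SNP-to-gene assignment.
#
# A SNP belongs to a gene if it falls inside the transcribed region
# [tx_start, tx_end] (1-based inclusive) or within the 500-bp window
# immediately upstream of the transcription start site, taken strand-aware:
# [tx_start - 500, tx_start - 1] on the + strand, [tx_end + 1, tx_end + 500]
# on the - strand. A SNP may map to several overlapping genes.

UPSTREAM_BP <- 500L

#' Construct and validate a gene annotation table
#'
#' @param gene_id character vector of gene identifiers (unique).
#' @param chrom chromosome names (same convention as the SNP table).
#' @param tx_start,tx_end 1-based inclusive transcript interval.
#' @param strand `"+"` or `"-"`.
#' @return data.frame with those five columns.
#' @export
gene_annotation <- function(gene_id, chrom, tx_start, tx_end, strand) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   tx_start = as.integer(tx_start),
                   tx_end = as.integer(tx_end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stopf("duplicated gene_id '%s'",
                                       df$gene_id[anyDuplicated(df$gene_id)])
  if (any(df$tx_start > df$tx_end)) stopf("tx_start > tx_end")
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  df
}

#' Read / write a BED-like gene annotation TSV
#'
#' Tab-separated with header `chrom  tx_start  tx_end  gene_id  strand`
#' (1-based inclusive coordinates).
#' @param path file path.
#' @param genes data.frame per [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  gene_annotation(df$gene_id, df$chrom, df$tx_start, df$tx_end, df$strand)
}

#' @rdname read_gene_annotation
#' @export
write_gene_annotation <- function(genes, path) {
  utils::write.table(genes[c("chrom", "tx_start", "tx_end", "gene_id",
                             "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Assign SNPs to genes (transcribed region + 500 bp upstream)
#'
#' @param snps data.frame with columns `id`, `chrom`, `pos` (e.g. the `snps`
#'   component of a `freq_table`).
#' @param genes data.frame per [gene_annotation()].
#' @return named list: gene_id -> character vector of SNP ids (genes with no
#'   assigned SNP map to an empty vector). Invariant under reordering of
#'   either input.
#' @export
assign_snps_to_genes <- function(snps, genes) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(snps)))
  lo <- ifelse(genes$strand == "+", genes$tx_start - UPSTREAM_BP,
               genes$tx_start)
  hi <- ifelse(genes$strand == "-", genes$tx_end + UPSTREAM_BP, genes$tx_end)
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(lo, 1L), hi))
  gr_snps <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes)
  out <- stats::setNames(
    vector("list", nrow(genes)), genes$gene_id)
  for (g in seq_len(nrow(genes))) out[[g]] <- character(0)
  sp <- split(snps$id[S4Vectors_from(hits)], S4Vectors_to(hits))
  for (k in names(sp)) {
    gid <- genes$gene_id[as.integer(k)]
    out[[gid]] <- sort(unique(sp[[k]]))
  }
  out
}

# queryHits/subjectHits without importing S4Vectors into the namespace
S4Vectors_from <- function(h) methods::slot(h, "from")
S4Vectors_to <- function(h) methods::slot(h, "to")
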