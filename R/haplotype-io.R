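# Phased-VCF ingestion and export for haplotype panels.

#' Read a haplotype panel from a phased VCF
#'
#' Loads biallelic records with fully phased genotypes and expands each
#' diploid sample into two haplotype rows. Sites are polarized with the
#' `AA` INFO tag when present (alleles are recoded so that 1 = derived);
#' without the tag the REF allele is assumed ancestral.
#'
#' @param vcf path to a phased VCF.
#' @param samples optional sample subset (default: all samples).
#' @param population_id label stored on the panel.
#' @return a `haplotype_panel`.
#' @export
read_haplotype_panel <- function(vcf, samples = NULL,
                                 population_id = NA_character_) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (!any(bi)) stopf("no biallelic records in '%s'", vcf)
  gt <- vcfR::extract.gt(v, element = "GT")[bi, , drop = FALSE]
  fix <- vcfR::getFIX(v)[bi, , drop = FALSE]
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(gt))
    if (length(miss)) stopf("sample '%s' not in VCF", miss[1])
    gt <- gt[, samples, drop = FALSE]
  }
  if (any(is.na(gt)) || any(grepl("/", gt, fixed = TRUE)) ||
        any(grepl("\\.", gt)))
    stopf("haplotype panel requires fully phased, non-missing genotypes")
  n_site <- nrow(gt); n_sam <- ncol(gt)
  al <- matrix(0L, 2L * n_sam, n_site)
  for (j in seq_len(n_sam)) {
    sp <- strsplit(gt[, j], "|", fixed = TRUE)
    al[2L * j - 1L, ] <- as.integer(vapply(sp, `[`, "", 1L))
    al[2L * j, ] <- as.integer(vapply(sp, `[`, "", 2L))
  }
  # polarize: AA == ALT means allele 1 is ancestral -> flip
  aa <- tryCatch(vcfR::extract.info(v, "AA")[bi], error = function(e) NULL)
  if (!is.null(aa)) {
    flip <- !is.na(aa) & toupper(aa) == toupper(fix[, "ALT"])
    al[, flip] <- 1L - al[, flip, drop = FALSE]
  }
  ids <- fix[, "ID"]
  bad <- is.na(ids) | ids == "."
  ids[bad] <- paste0(fix[bad, "CHROM"], ":", fix[bad, "POS"])
  pos <- as.integer(fix[, "POS"])
  ord <- order(pos)
  haplotype_panel(al[, ord, drop = FALSE], pos[ord],
                  chrom = fix[1, "CHROM"], snp_ids = ids[ord],
                  population_id = population_id)
}

#' Write a haplotype panel as a phased VCF
#'
#' Consecutive haplotype rows are paired into diploid samples (the panel
#' must hold an even number of haplotypes). Alleles are written with REF =
#' ancestral (`A`), ALT = derived (`G`) and an `AA=A` INFO tag, so that
#' [read_haplotype_panel()] round-trips the 0/1 coding.
#'
#' @param panel a `haplotype_panel`.
#' @param path output path.
#' @export
write_haplotype_vcf <- function(panel, path) {
  n_hap <- nrow(panel$alleles)
  if (n_hap %% 2L != 0L) stopf("need an even number of haplotypes")
  n_sam <- n_hap %/% 2L
  sam <- sprintf("S%03d", seq_len(n_sam))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sam), collapse = "\t")), con)
  a <- panel$alleles
  for (s in seq_along(panel$positions)) {
    gts <- paste0(a[seq(1, n_hap, 2), s], "|", a[seq(2, n_hap, 2), s])
    writeLines(paste(c(panel$chrom, panel$positions[s], panel$snp_ids[s],
                       "A", "G", ".", "PASS", "AA=A", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}
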