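# Linkage disequilibrium between SNP pairs and LD-based collapsing of
# variant lists into approximately independent loci.

#' Squared correlation (r2) between two biallelic sites
#'
#' Computed over the same set of haplotypes (or genotypes coded as allele
#' dosages): the squared Pearson correlation, which on binary haplotype
#' vectors equals the classical D^2 / (pA pa pB pb).
#'
#' @param hap_a,hap_b numeric vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(hap_a, hap_b) {
  stopifnot(length(hap_a) == length(hap_b), length(hap_a) >= 2)
  if (stats::sd(hap_a) == 0 || stats::sd(hap_b) == 0)
    stopf("monomorphic site: r2 undefined")
  stats::cor(hap_a, hap_b)^2
}

#' Collapse SNPs in strong LD into single loci
#'
#' A single greedy pass in list (genomic) order: each candidate SNP is
#' compared against the already-retained set; if it is in LD (r2 >=
#' `threshold`) with exactly one retained SNP, a seeded coin flip decides
#' which of the two survives; if it conflicts with several retained SNPs it
#' is dropped. The result satisfies the audit that no two retained SNPs have
#' r2 >= threshold, and is deterministic for a given seed.
#'
#' @param snp_ids character vector in genomic order.
#' @param r2_fun function(id_i, id_j) returning pairwise r2.
#' @param threshold collapse at r2 >= threshold (default 0.4).
#' @param seed integer seed driving the within-pair random choice.
#' @return character vector of retained SNP ids (subset of `snp_ids`,
#'   original order).
#' @export
collapse_by_ld <- function(snp_ids, r2_fun, threshold = 0.4, seed = 1L) {
  stopifnot(is.character(snp_ids), !anyDuplicated(snp_ids))
  with_seed(seed, {
    kept <- character(0)
    for (s in snp_ids) {
      if (!length(kept)) { kept <- s; next }
      r2 <- vapply(kept, function(k) r2_fun(k, s), numeric(1))
      conflict <- which(r2 >= threshold)
      if (!length(conflict)) {
        kept <- c(kept, s)
      } else if (length(conflict) == 1L && stats::runif(1) < 0.5) {
        # candidate replaces the single conflicting SNP; it has no other
        # conflicts among kept, so the pairwise audit still holds
        kept <- c(kept[-conflict], s)
      } # else: keep-first, drop candidate
    }
    snp_ids[snp_ids %in% kept]
  })
}
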