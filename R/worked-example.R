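# Bundled worked-example data: the per-variant results of a published
# genome-wide photoperiod selection scan of the worldwide HGDP-CEPH panel.
# One table holds the 84 top variants from five circadian-biology gene sets
# (core clock, RNAi-screen hits, mouse circadian/sleep models, human sleep
# disorders, melanopsin signaling); the other holds 18 GWAS risk variants
# for affective disorders and restless leg syndrome that track
# delta-photoperiod. Each row carries the Kendall p-value, the MAF-binned
# tau percentile rank, F_ST percentile ranks for an extreme-contrast and a
# matched-photoperiod population pair, and lnRsb ranks for two non-African
# populations. Ranks are printed rounded (3 decimals for F_ST, 2 for
# lnRsb), so gate counting on these tables is inclusive: a printed 0.950
# was at the gate before rounding and is counted as significant.

fixture_path <- function(file) {
  system.file("extdata", file, package = "photoclines", mustWork = TRUE)
}

#' Load the worked-example variant tables
#'
#' @return data.frame of 84 circadian-gene variants
#'   (`load_circadian_hits`) or 18 disease-associated GWAS variants
#'   (`load_gwas_hits`).
#' @export
load_circadian_hits <- function() {
  df <- utils::read.table(fixture_path("circadian_scan_hits.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) != 84L) stopf("circadian hit table must have 84 rows")
  df
}

#' @rdname load_circadian_hits
#' @export
load_gwas_hits <- function() {
  df <- utils::read.table(fixture_path("gwas_scan_hits.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) != 18L) stopf("GWAS hit table must have 18 rows")
  df
}

#' Summary counts over the worked-example tables
#'
#' Recomputes, from the bundled variant tables, the headline counts of the
#' worked example: missense variants, F_ST-gate excesses in the two
#' featured population pairs, lnRsb significances per population,
#' disease-subset sizes and risk-allele directions, and the number of
#' core-clock genes surviving the dual significance gate (Bonferroni over
#' the 175 SNPs of that set and tau rank above 0.95). Gates on the
#' rounded printed ranks are inclusive (>= 0.95 high, <= 0.05 low).
#'
#' @param circadian data.frame from [load_circadian_hits()].
#' @param gwas data.frame from [load_gwas_hits()]; optional.
#' @param hi_gate,lo_gate rank gates (defaults 0.95 / 0.05).
#' @param core_n_tests Bonferroni denominator for the core-clock set
#'   (default 175, the number of SNPs genotyped in those 12 genes).
#' @return named list of integer counts.
#' @export
scan_hit_summary <- function(circadian, gwas = NULL, hi_gate = 0.95,
                             lo_gate = 0.05, core_n_tests = 175L) {
  out <- list(
    n_variants = nrow(circadian),
    n_missense = sum(startsWith(circadian$annotation, "missense")),
    fst_high_biaka_orcadian =
      sum(circadian$fst_rank_biaka_orcadian >= hi_gate),
    fst_low_biaka_maya = sum(circadian$fst_rank_biaka_maya <= lo_gate),
    lnrsb_sig_ceph = sum(circadian$lnrsb_rank_ceph >= hi_gate),
    lnrsb_sig_chbjpt = sum(circadian$lnrsb_rank_chbjpt >= hi_gate),
    core_circadian_sig_genes = with(
      circadian[circadian$set == "core_circadian", ],
      length(unique(gene[kendall_p < 0.05 / core_n_tests &
                           tau_rank >= hi_gate])))
  )
  if (!is.null(gwas)) {
    scz_bpd <- gwas$disease %in% c("BPD", "SCZ", "BPD and SCZ")
    out <- c(out, list(
      n_gwas_variants = nrow(gwas),
      n_scz_bpd = sum(scz_bpd),
      n_scz_bpd_risk_decreasing =
        sum(scz_bpd & gwas$risk_decreases_with_delta == "Yes"),
      n_mdd_depression = sum(gwas$disease %in% c("MDD", "Depression")),
      n_asd = sum(gwas$disease == "Asperger"),
      n_rls = sum(gwas$disease == "RLS")
    ))
  }
  out
}
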