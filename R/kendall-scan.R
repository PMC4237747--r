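# Environmental correlation scan: per-SNP Kendall rank correlation between
# allele frequency and an environmental variable, with empirical percentile
# ranks of |tau| computed inside 1%-wide bins of average MAF. The MAF
# binning corrects for the genome-wide effects of demography and for the
# reduced power of the rank test at low MAF (many tied frequencies); the
# percentile rank, not tau itself, carries the selection signal.

#' Kendall rank correlation (tau-b) with tie-corrected normal p-value
#'
#' Thin wrapper around [stats::cor.test()] with `method = "kendall"` and
#' `exact = FALSE`: the estimate is tau-b (tie-corrected in both margins)
#' and the two-sided p-value comes from the tie-adjusted normal
#' approximation of the concordance statistic — the appropriate regime for
#' ~52 populations with heavily tied frequency values.
#'
#' @param x,y numeric vectors; pairwise-incomplete entries are dropped.
#' @return list with elements `tau`, `p_value`, `n` (pairs used).
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("fewer than 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stopf("zero variance: constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Scan a frequency table against an environmental variable
#'
#' One Kendall test per SNP between its allele_b frequencies and the chosen
#' environmental variable across the shared populations. SNPs that cannot
#' be tested (constant frequencies, too few populations) are flagged in the
#' `status` column rather than dropped. Because the frequency refers to an
#' arbitrary allele label, the sign of tau is label-dependent; downstream
#' ranking uses |tau|.
#'
#' @param table a `freq_table`.
#' @param env environment table ([environment_table()]).
#' @param variable column of `env` to correlate (default
#'   `"delta_photoperiod"`).
#' @return data.frame (one row per SNP): `snp_id`, `chrom`, `pos`, `tau`,
#'   `p_value`, `n_pops`, `maf`, `tau_rank` (NA until
#'   [maf_binned_rank()]), `significant` (NA until [call_significant()]),
#'   `status` (`"ok"`, `"constant"` or `"too_few"`).
#' @export
env_scan <- function(table, env, variable = "delta_photoperiod") {
  stopifnot(inherits(table, "freq_table"))
  if (!variable %in% names(env))
    stopf("variable '%s' absent from environment table", variable)
  shared <- intersect(pop_ids(table), env$population_id)
  if (length(shared) < 3L)
    stopf("only %d populations shared between table and env", length(shared))
  ev <- env[[variable]][match(shared, env$population_id)]
  fr <- table$freq[, shared, drop = FALSE]
  maf <- average_maf(table)
  n <- nrow(fr)
  tau <- p <- rep(NA_real_, n)
  npops <- integer(n)
  status <- rep("ok", n)
  for (i in seq_len(n)) {
    f <- fr[i, ]
    ok <- !is.na(f)
    npops[i] <- sum(ok)
    if (npops[i] < 3L) { status[i] <- "too_few"; next }
    if (length(unique(f[ok])) < 2L || length(unique(ev[ok])) < 2L) {
      status[i] <- "constant"; next
    }
    kt <- kendall_tau(f, ev)
    tau[i] <- kt$tau; p[i] <- kt$p_value
  }
  data.frame(snp_id = table$snps$id, chrom = table$snps$chrom,
             pos = table$snps$pos, tau = tau, p_value = p, n_pops = npops,
             maf = unname(maf), tau_rank = NA_real_, significant = NA,
             status = status, stringsAsFactors = FALSE)
}

#' Empirical percentile rank of |tau| within MAF bins
#'
#' Bins SNPs by average MAF into right-open bins `[k w, (k+1) w)` of width
#' `bin_width` (MAF = 0.5 falls in the last bin) and assigns each testable
#' SNP the mid-rank percentile of |tau| within its bin: (number strictly
#' below + half the ties) / bin size. Bins containing a single testable SNP
#' get rank 0.5 with a warning.
#'
#' @param results scan data.frame from [env_scan()].
#' @param bin_width MAF bin width (default 0.01).
#' @return `results` with `tau_rank` filled for rows with `status == "ok"`.
#' @export
maf_binned_rank <- function(results, bin_width = 0.01) {
  stopifnot(all(c("tau", "maf", "tau_rank") %in% names(results)))
  ok <- which(results$status == "ok" & !is.na(results$tau))
  bin <- pmin(floor(results$maf[ok] / bin_width),
              floor(0.5 / bin_width) - 1L)
  for (b in unique(bin)) {
    idx <- ok[bin == b]
    if (length(idx) == 1L) {
      warnf("MAF bin [%g, %g) holds a single SNP; rank set to 0.5",
            b * bin_width, (b + 1) * bin_width)
      results$tau_rank[idx] <- 0.5
    } else {
      results$tau_rank[idx] <- mid_rank(abs(results$tau[idx]))
    }
  }
  results
}

#' Call significance at the dual gate
#'
#' A SNP is significant iff its Kendall p-value survives Bonferroni
#' correction for `n_tests` (p < 0.05 / n_tests) AND its MAF-binned |tau|
#' percentile rank exceeds 0.95. Rows without a p-value or rank are set to
#' FALSE.
#'
#' @param results scan data.frame with `tau_rank` filled.
#' @param n_tests number of tests for the Bonferroni correction (>= 1);
#'   conventionally the number of SNPs in the analyzed set.
#' @param alpha family-wise level (default 0.05).
#' @param rank_gate percentile gate (default 0.95, strict).
#' @return `results` with the logical `significant` column filled.
#' @export
call_significant <- function(results, n_tests, alpha = 0.05,
                             rank_gate = 0.95) {
  stopifnot(n_tests >= 1)
  sig <- !is.na(results$p_value) & !is.na(results$tau_rank) &
    results$p_value < alpha / n_tests & results$tau_rank > rank_gate
  results$significant <- sig
  results
}

#' Strongest significant SNP per gene
#'
#' For every gene carrying at least one significant SNP, returns the
#' significant SNP with maximal tau percentile rank; ties are broken by
#' smaller p-value, then by genomic position, so the choice is
#' deterministic.
#'
#' @param results scan data.frame with `significant` filled.
#' @param gene_map named list gene_id -> SNP ids ([assign_snps_to_genes()]).
#' @return data.frame `gene_id`, `snp_id` plus the scan columns of the
#'   chosen SNP; genes without significant SNPs are absent.
#' @export
top_snp_per_gene <- function(results, gene_map) {
  rows <- list()
  for (g in names(gene_map)) {
    sub <- results[results$snp_id %in% gene_map[[g]] &
                     results$significant %in% TRUE, , drop = FALSE]
    if (!nrow(sub)) next
    ord <- order(-sub$tau_rank, sub$p_value, sub$pos, sub$snp_id)
    rows[[g]] <- cbind(gene_id = g, sub[ord[1], , drop = FALSE])
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), snp_id = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MAF-matched control SNPs
#'
#' Samples, for each target SNP, `k_per_target` control SNPs whose average
#' MAF lies within `tol` of the target's, without replacement across the
#' whole selection and deterministically for a given seed. Target SNPs are
#' never chosen as controls.
#'
#' @param panel_results scan data.frame covering the whole panel (needs
#'   `snp_id`, `maf`).
#' @param targets SNP ids to match.
#' @param k_per_target controls per target (default 10).
#' @param tol MAF matching tolerance (default 0.01).
#' @param seed integer seed.
#' @return character vector of `length(targets) * k_per_target` control ids.
#' @export
sample_matched_controls <- function(panel_results, targets,
                                    k_per_target = 10L, tol = 0.01,
                                    seed = 1L) {
  stopifnot(all(targets %in% panel_results$snp_id))
  maf <- stats::setNames(panel_results$maf, panel_results$snp_id)
  pool <- setdiff(panel_results$snp_id, targets)
  with_seed(seed, {
    taken <- character(0)
    for (t in targets) {
      cand <- pool[abs(maf[pool] - maf[t]) <= tol]
      cand <- setdiff(cand, taken)
      if (length(cand) < k_per_target)
        stopf("only %d MAF-matched candidates for target '%s' (need %d)",
              length(cand), t, k_per_target)
      taken <- c(taken, sample_vec(cand, k_per_target))
    }
    taken
  })
}

#' Normalized derived-allele-frequency profiles
#'
#' Per-SNP z-scores of the derived allele frequency across populations
#' (mean 0, unit SD over non-missing populations), the summary used to
#' visualize frequency clines along the photoperiod gradient. SNPs with zero
#' frequency variance get an all-zero profile and are flagged. Columns are
#' ordered by geographic area (if given) and increasing delta-photoperiod
#' within area.
#'
#' @param table a `freq_table` restricted to the SNP set of interest (all
#'   SNPs must be ancestrally polarized).
#' @param env environment table (for the delta-photoperiod ordering);
#'   optional.
#' @param area optional named character vector population_id -> area label.
#' @return list with `profile` (matrix SNP x population of z-scores),
#'   `flagged` (ids of zero-variance SNPs) and `order` (population ids in
#'   plotting order).
#' @export
normalized_daf_profile <- function(table, env = NULL, area = NULL) {
  daf <- derived_frequencies(table, require_polarized = TRUE)
  mu <- rowMeans(daf, na.rm = TRUE)
  sd <- apply(daf, 1, stats::sd, na.rm = TRUE)
  flagged <- rownames(daf)[!is.na(sd) & sd == 0]
  z <- (daf - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  ord <- colnames(z)
  if (!is.null(env)) {
    dp <- env$delta_photoperiod[match(ord, env$population_id)]
    key <- if (is.null(area)) dp else order(area[ord], dp)
    ord <- if (is.null(area)) ord[order(dp)] else ord[key]
    z <- z[, ord, drop = FALSE]
  }
  list(profile = z, flagged = flagged, order = ord)
}
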