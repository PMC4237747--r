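# Resampling-based enrichment: empirical probabilities of observing as many
# significant genes (or SNPs) as seen, against random draws from the panel.
# Each resampled gene set receives its own Bonferroni correction computed
# from the number of SNPs it contains, mirroring the treatment of the
# observed set. Empirical p-values use the (count + 1) / (reps + 1)
# estimator, which can never return 0.

resample_result <- function(observed, reps, count_ge) {
  stopifnot(count_ge >= 0, count_ge <= reps)
  structure(list(observed = observed, reps = reps, count_ge = count_ge,
                 empirical_p = (count_ge + 1) / (reps + 1)),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf(
    "resample_result: observed %d; %d / %d resamples >= observed; empirical P = %.4g\n",
    x$observed, x$count_ge, x$reps, x$empirical_p))
  invisible(x)
}

# count genes (list of snp-index vectors) with >= 1 SNP passing the dual
# gate, with Bonferroni over the total number of SNPs in the drawn set
count_significant_genes <- function(gene_snps, pval, rank, alpha, rank_gate) {
  n_snp <- length(unique(unlist(gene_snps, use.names = FALSE)))
  if (n_snp == 0L) return(0L)
  thr <- alpha / n_snp
  sum(vapply(gene_snps, function(ix)
    any(pval[ix] < thr & rank[ix] > rank_gate, na.rm = TRUE), logical(1)))
}

# universe as list of integer index vectors into snp_stats rows
universe_index <- function(universe, snp_stats) {
  lapply(universe, function(ids) {
    ix <- match(ids, snp_stats$snp_id)
    if (anyNA(ix)) stopf("universe SNP '%s' absent from snp_stats",
                         ids[which(is.na(ix))[1]])
    ix
  })
}

#' Gene-set resampling enrichment
#'
#' Draws `reps` random sets of `m` genes (without replacement) from the
#' universe of genes covered by at least one scanned SNP; for each draw,
#' applies a Bonferroni correction over the total number of SNPs in the
#' drawn set and counts genes carrying at least one SNP passing the dual
#' significance gate. The empirical probability of the observed count is
#' (number of draws with count >= observed + 1) / (reps + 1).
#'
#' @param universe named list gene_id -> SNP ids (each gene must have >= 1
#'   scanned SNP).
#' @param m genes per resample.
#' @param observed_n observed number of significant genes.
#' @param snp_stats data.frame with `snp_id`, `p_value`, `tau_rank` for all
#'   universe SNPs.
#' @param reps number of resamples (default 10000).
#' @param seed integer seed.
#' @param alpha,rank_gate the dual gate (defaults 0.05 and 0.95).
#' @return a `resample_result`.
#' @export
gene_set_resample <- function(universe, m, observed_n, snp_stats,
                              reps = 10000L, seed = 1L, alpha = 0.05,
                              rank_gate = 0.95) {
  if (m > length(universe))
    stopf("m = %d exceeds universe size %d", m, length(universe))
  uix <- universe_index(universe, snp_stats)
  pv <- snp_stats$p_value; rk <- snp_stats$tau_rank
  with_seed(seed, {
    counts <- vapply(seq_len(reps), function(r) {
      sel <- sample.int(length(uix), m)
      count_significant_genes(uix[sel], pv, rk, alpha, rank_gate)
    }, integer(1))
    resample_result(observed_n, reps, sum(counts >= observed_n))
  })
}

#' SNP-count-matched gene-set resampling
#'
#' As [gene_set_resample()], but each random gene is drawn to match the SNP
#' count of one target gene: preferentially a gene with exactly the same
#' number of SNPs, otherwise the nearest count within a factor-of-two
#' window. Controls for large genes being more likely to carry at least one
#' significant SNP.
#'
#' @param universe named list gene_id -> SNP ids.
#' @param target_genes gene ids whose SNP counts are matched.
#' @param observed_n observed number of significant genes among the targets;
#'   if NULL it is computed from the target set with its own Bonferroni.
#' @inheritParams gene_set_resample
#' @return a `resample_result`.
#' @export
snp_matched_gene_resample <- function(universe, target_genes, snp_stats,
                                      observed_n = NULL, reps = 10000L,
                                      seed = 1L, alpha = 0.05,
                                      rank_gate = 0.95) {
  stopifnot(all(target_genes %in% names(universe)))
  uix <- universe_index(universe, snp_stats)
  pv <- snp_stats$p_value; rk <- snp_stats$tau_rank
  sizes <- lengths(uix)
  targ_sizes <- sizes[target_genes]
  if (is.null(observed_n))
    observed_n <- count_significant_genes(uix[target_genes], pv, rk,
                                          alpha, rank_gate)
  # candidate pool per target: exact SNP count, else nearest within a
  # factor-two window; the target's own gene is never its own control
  cand_for <- function(g) {
    s <- sizes[g]
    self <- match(g, names(uix))
    exact <- setdiff(which(sizes == s), self)
    if (length(exact)) return(exact)
    win <- setdiff(which(sizes >= s / 2 & sizes <= 2 * s), self)
    if (!length(win))
      stopf("gene '%s': no gene with SNP count near %d (window [%g, %g])",
            g, s, s / 2, 2 * s)
    win[abs(sizes[win] - s) == min(abs(sizes[win] - s))]
  }
  cands <- lapply(target_genes, cand_for)
  with_seed(seed, {
    counts <- vapply(seq_len(reps), function(r) {
      sel <- integer(0)
      for (cd in cands) {
        avail <- setdiff(cd, sel)
        if (!length(avail)) avail <- setdiff(seq_along(uix), sel)
        sel <- c(sel, sample_vec(avail, 1L))
      }
      count_significant_genes(uix[sel], pv, rk, alpha, rank_gate)
    }, integer(1))
    resample_result(observed_n, reps, sum(counts >= observed_n))
  })
}

#' SNP-set resampling enrichment
#'
#' Compares the number of significant SNPs in a target set against random
#' SNP sets of the same size drawn from a pool, optionally matched on
#' average MAF (each random SNP within `tol` of one target's MAF). The
#' per-SNP significance flags are taken as given (i.e. computed beforehand
#' at whatever gate applies).
#'
#' @param pool data.frame with `snp_id`, `maf`, `significant` for all
#'   candidate SNPs (must include the targets).
#' @param target_ids SNP ids of the observed set.
#' @param reps resamples (default 10000).
#' @param seed integer seed.
#' @param match_maf match controls on MAF within `tol`?
#' @param tol MAF tolerance (default 0.01).
#' @return a `resample_result` (observed = significant targets).
#' @export
snp_set_resample <- function(pool, target_ids, reps = 10000L, seed = 1L,
                             match_maf = FALSE, tol = 0.01) {
  stopifnot(all(target_ids %in% pool$snp_id))
  k <- length(target_ids)
  if (k > nrow(pool)) stopf("target set larger than pool")
  sig <- stats::setNames(pool$significant, pool$snp_id)
  maf <- stats::setNames(pool$maf, pool$snp_id)
  observed <- sum(sig[target_ids], na.rm = TRUE)
  all_ids <- pool$snp_id
  cands <- if (match_maf) {
    lapply(target_ids, function(t) {
      cd <- all_ids[abs(maf - maf[t]) <= tol]
      if (!length(cd)) stopf("no MAF-matched candidate for target '%s'", t)
      cd
    })
  } else NULL
  with_seed(seed, {
    counts <- vapply(seq_len(reps), function(r) {
      draw <- if (match_maf) {
        sel <- character(0)
        for (cd in cands) {
          avail <- setdiff(cd, sel)
          if (!length(avail))
            stopf("MAF-matched candidates exhausted during resampling")
          sel <- c(sel, sample_vec(avail, 1L))
        }
        sel
      } else sample_vec(all_ids, k)
      sum(sig[draw], na.rm = TRUE)
    }, integer(1))
    resample_result(observed, reps, sum(counts >= observed))
  })
}

#' Excess of significant counts over a fixed null rate
#'
#' Tests whether `observed_sig` significant results out of `total` exceed
#' the `null_rate` expectation (default 5%, the tail mass beyond the 0.95
#' empirical gate). Primary test: two-sided Fisher exact test on the 2x2
#' table \[observed, total - observed; expected, total - expected\] with
#' expected = round(null_rate * total). A one-sided binomial test is
#' reported as a cross-check.
#'
#' @param observed_sig number of significant results.
#' @param total number of results tested.
#' @param null_rate expected significant fraction under the null.
#' @return list `p_fisher`, `p_binomial` (one-sided, greater), `expected`,
#'   `fold` (observed / expected).
#' @export
excess_test <- function(observed_sig, total, null_rate = 0.05) {
  stopifnot(observed_sig >= 0, observed_sig <= total)
  expected <- round(null_rate * total)
  tab <- matrix(c(observed_sig, total - observed_sig,
                  expected, total - expected), 2, byrow = TRUE)
  p_f <- stats::fisher.test(tab)$p.value
  p_b <- stats::binom.test(observed_sig, total, null_rate,
                           alternative = "greater")$p.value
  list(p_fisher = p_f, p_binomial = p_b, expected = expected,
       fold = if (expected > 0) observed_sig / expected else NA_real_)
}
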