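# Pairwise population differentiation: the Weir & Cockerham (1984)
# theta-hat estimator for two populations at one biallelic locus, computed
# from genotype counts with observed (not HWE-expected) heterozygosity, and
# empirical percentile ranks of theta within 50 equal-width classes of
# average MAF. Negative theta values are retained: clamping at zero would
# distort the low tail, which carries its own signal (unusually low
# differentiation between distant populations under the same selective
# pressure).

# vectorized WC84 two-population variance components
# n1, n2: diploid sample sizes; p1, p2: allele frequencies; h1, h2:
# observed heterozygote proportions
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc, pbar = pbar)
}

#' Weir-Cockerham F_ST (theta) between two populations at one SNP
#'
#' @param counts_pop1,counts_pop2 integer vectors of genotype counts
#'   `c(hom_ref, het, hom_alt)`; each population needs >= 2 genotyped
#'   individuals.
#' @return theta-hat = a / (a + b + c); may be negative. NA (with a
#'   `monomorphic` attribute) when the site is monomorphic across both
#'   populations.
#' @export
wc_fst <- function(counts_pop1, counts_pop2) {
  stopifnot(length(counts_pop1) == 3L, length(counts_pop2) == 3L,
            all(counts_pop1 >= 0), all(counts_pop2 >= 0))
  n1 <- sum(counts_pop1); n2 <- sum(counts_pop2)
  if (n1 < 2 || n2 < 2) stopf("need >= 2 genotyped individuals per population")
  p1 <- (2 * counts_pop1[3] + counts_pop1[2]) / (2 * n1)
  p2 <- (2 * counts_pop2[3] + counts_pop2[2]) / (2 * n2)
  h1 <- counts_pop1[2] / n1
  h2 <- counts_pop2[2] / n2
  w <- wc_components(n1, p1, h1, n2, p2, h2)
  if (w$pbar <= 0 || w$pbar >= 1) {
    out <- NA_real_
    attr(out, "monomorphic") <- TRUE
    return(out)
  }
  unname(w$a / (w$a + w$b + w$c))
}

#' Pairwise per-SNP F_ST table across populations
#'
#' Computes Weir-Cockerham theta for every unordered population pair at
#' every SNP, from a genotype-count array. Pairs where either population
#' has fewer than `min_ind` genotyped individuals at a SNP are excluded
#' with status `"too_few"`; sites monomorphic across the pair are status
#' `"monomorphic"` with theta NA.
#'
#' @param geno array `n_snps x n_pops x 3` of genotype counts
#'   (hom_ref, het, hom_alt), with dimnames snp ids and population ids,
#'   e.g. from [simulate_genotypes()].
#' @param maf named per-SNP average MAF (for later binning); typically
#'   [average_maf()] on the matching frequency table.
#' @param pairs optional 2-column matrix / data.frame of population-id
#'   pairs; default all unordered pairs.
#' @param min_ind minimum genotyped individuals per population (default 2).
#' @return long data.frame: `pop1`, `pop2`, `snp_id`, `theta`, `maf`,
#'   `fst_rank` (NA until [maf_binned_fst_rank()]), `status`.
#' @export
pairwise_fst_matrix <- function(geno, maf, pairs = NULL, min_ind = 2L) {
  stopifnot(length(dim(geno)) == 3L, dim(geno)[3] == 3L)
  pops <- dimnames(geno)[[2]]
  snp_ids <- dimnames(geno)[[1]]
  if (is.null(pairs)) {
    pairs <- t(utils::combn(pops, 2))
  } else {
    pairs <- as.matrix(pairs)
  }
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pa <- pairs[k, 1]; pb <- pairs[k, 2]
    g1 <- geno[, pa, , drop = TRUE]; g2 <- geno[, pb, , drop = TRUE]
    if (is.null(dim(g1))) { g1 <- matrix(g1, 1); g2 <- matrix(g2, 1) }
    n1 <- rowSums(g1); n2 <- rowSums(g2)
    p1 <- (2 * g1[, 3] + g1[, 2]) / (2 * n1)
    p2 <- (2 * g2[, 3] + g2[, 2]) / (2 * n2)
    h1 <- g1[, 2] / n1; h2 <- g2[, 2] / n2
    w <- wc_components(n1, p1, h1, n2, p2, h2)
    theta <- w$a / (w$a + w$b + w$c)
    status <- rep("ok", length(theta))
    mono <- w$pbar <= 0 | w$pbar >= 1
    theta[mono] <- NA_real_; status[mono] <- "monomorphic"
    few <- n1 < min_ind | n2 < min_ind
    theta[few] <- NA_real_; status[few] <- "too_few"
    out[[k]] <- data.frame(pop1 = pa, pop2 = pb, snp_id = snp_ids,
                           theta = theta, maf = unname(maf[snp_ids]),
                           fst_rank = NA_real_, status = status,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Empirical percentile rank of theta within MAF classes
#'
#' For one population pair: bins SNPs into `n_classes` equal-width classes
#' of average MAF on \[0, 0.5\] and assigns each SNP the mid-rank percentile
#' of theta within its class. The per-class 95th percentile of theta is
#' attached as attribute `"p95"` (named by class index). Single-SNP classes
#' get rank 0.5 with a warning.
#'
#' @param results rows of [pairwise_fst_matrix()] for a single pair.
#' @param n_classes number of MAF classes (default 50).
#' @return `results` with `fst_rank` filled for `status == "ok"` rows.
#' @export
maf_binned_fst_rank <- function(results, n_classes = 50L) {
  stopifnot(length(unique(paste(results$pop1, results$pop2))) == 1L)
  width <- 0.5 / n_classes
  ok <- which(results$status == "ok" & !is.na(results$theta))
  cls <- pmin(floor(results$maf[ok] / width), n_classes - 1L)
  p95 <- stats::setNames(rep(NA_real_, n_classes), seq_len(n_classes) - 1L)
  for (b in unique(cls)) {
    idx <- ok[cls == b]
    if (length(idx) == 1L) {
      warnf("MAF class %d holds a single SNP; rank set to 0.5", b)
      results$fst_rank[idx] <- 0.5
    } else {
      results$fst_rank[idx] <- mid_rank(results$theta[idx])
    }
    p95[as.character(b)] <- stats::quantile(results$theta[idx], 0.95,
                                            names = FALSE)
  }
  attr(results, "p95") <- p95
  results
}

#' Count SNPs beyond the high/low rank gates
#'
#' @param results rank-filled rows for one population pair.
#' @param hi_gate upper gate (strict `>`, default 0.95).
#' @param lo_gate lower gate (strict `<`, default 0.05).
#' @return named integer vector `c(n_high = , n_low = )`.
#' @export
count_extreme <- function(results, hi_gate = 0.95, lo_gate = 0.05) {
  rk <- results$fst_rank
  c(n_high = sum(rk > hi_gate, na.rm = TRUE),
    n_low = sum(rk < lo_gate, na.rm = TRUE))
}
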