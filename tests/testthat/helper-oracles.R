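# Independent oracles and tiny fixture builders. Every oracle recomputes
# its statistic from first principles (pair enumeration, direct summation),
# never through the package's own code path.

# Kendall tau-b by O(n^2) concordant/discordant pair enumeration with tie
# correction in both margins.
brute_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(vapply(split(seq_len(n), x), function(g)
    length(g) * (length(g) - 1) / 2, numeric(1)))
  ty <- sum(vapply(split(seq_len(n), y), function(g)
    length(g) * (length(g) - 1) / 2, numeric(1)))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Weir-Cockerham (1984) two-population theta written out from the published
# component formulas, organized as explicit sums over populations.
hand_wc_theta <- function(c1, c2) {
  n <- c(sum(c1), sum(c2))
  p <- c((2 * c1[3] + c1[2]) / (2 * n[1]),
         (2 * c2[3] + c2[2]) / (2 * n[2]))
  h <- c(c1[2] / n[1], c2[2] / n[2])
  r <- 2
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# fraction of unordered haplotype pairs identical over columns `cols`
brute_pair_identity <- function(alleles, cols) {
  n <- nrow(alleles)
  same <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (all(alleles[i, cols] == alleles[j, cols])) same <- same + 1
  same / (n * (n - 1) / 2)
}

# mean pairwise hamming distance by exhaustive enumeration
brute_pairwise_div <- function(alleles, rows, cols) {
  h <- alleles[rows, cols, drop = FALSE]
  n <- nrow(h)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    tot <- tot + sum(h[i, ] != h[j, ])
  tot / (n * (n - 1) / 2)
}

# two-sided Fisher exact p for a 2x2 table by direct hypergeometric tail
# summation (sum of all tables with probability <= the observed one)
hyper_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  supp <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(supp, m, n2, k)
  sum(pr[pr <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# small well-formed frequency table
toy_freq_table <- function(freq = NULL, pops = c("A", "B")) {
  if (is.null(freq))
    freq <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8), 3, 2,
                   dimnames = list(NULL, pops))
  n <- nrow(freq)
  snps <- data.frame(id = sprintf("s%d", seq_len(n)), chrom = "1",
                     pos = seq_len(n) * 100L, allele_a = "A",
                     allele_b = "G", ancestral = "A",
                     stringsAsFactors = FALSE)
  frequency_table(snps, freq)
}

# random small haplotype panel (all sites kept, possibly monomorphic)
toy_panel <- function(n_hap = 6, n_site = 10, seed = 1) {
  set.seed(seed)
  al <- matrix(rbinom(n_hap * n_site, 1, 0.4), n_hap, n_site)
  haplotype_panel(al, positions = sort(sample.int(n_site * 100, n_site)))
}

# write a minimal VCF for ingestion tests
write_test_vcf <- function(path, rows, samples) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}
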