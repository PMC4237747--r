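test_that("kendall_tau matches perfect (anti)concordance and rejects bad input", {
  expect_equal(kendall_tau(1:3, c(10, 20, 30))$tau, 1)
  expect_equal(kendall_tau(1:3, c(3, 2, 1))$tau, -1)
  expect_error(kendall_tau(c(1, 1, 1), 1:3), "zero variance")
  expect_error(kendall_tau(c(1, 2), c(2, 1)), "fewer than 3")
  # pairwise-complete filtering
  kt <- kendall_tau(c(1, 2, NA, 3, 4), c(2, 4, 9, 5, NA))
  expect_equal(kt$n, 3L)
})

test_that("kendall_tau equals O(n^2) pair enumeration with tie correction", {
  expect_equal(kendall_tau(c(1, 2, 2, 3), c(1, 3, 2, 4))$tau,
               brute_tau(c(1, 2, 2, 3), c(1, 3, 2, 4)), tolerance = 1e-12)
  set.seed(17)
  for (k in 1:25) {
    n <- sample(5:40, 1)
    x <- sample.int(8, n, replace = TRUE)          # heavy ties
    y <- x * sample(c(-1, 1), 1) + rnorm(n, sd = 2)
    expect_equal(kendall_tau(x, y)$tau, brute_tau(x, y), tolerance = 1e-10)
  }
})

test_that("the scan flags untestable SNPs and respects allele labels", {
  set.seed(21)
  pops <- population_table(sprintf("p%02d", 1:10), seq(0, 63, 7))
  env <- environment_table(pops)
  fr <- matrix(runif(50, 0.3, 0.7), 5, 10,
               dimnames = list(NULL, pops$id))
  fr[1, ] <- seq(0.1, 0.9, length.out = 10)[rank(env$delta_photoperiod)]
  fr[2, ] <- 0.4                                   # constant
  fr[3, 3:10] <- NA                                # too few populations
  tab <- toy_freq_table(fr, pops = pops$id)
  res <- env_scan(tab, env)
  expect_equal(res$tau[1], 1)                      # planted perfect cline
  expect_equal(res$status[2:3], c("constant", "too_few"))
  expect_true(is.na(res$tau[2]))

  # swapping allele labels flips tau, keeps |tau| and p
  tab2 <- tab
  tab2$freq <- 1 - tab$freq
  res2 <- env_scan(tab2, env)
  ok <- res$status == "ok"
  expect_equal(res2$tau[ok], -res$tau[ok])
  expect_equal(res2$p_value[ok], res$p_value[ok])

  expect_error(env_scan(tab, env, "uv_flux"), "absent")
  expect_error(env_scan(tab, env[1:2, ]), "shared")
})

test_that("MAF-binned mid-ranks follow the rank formula", {
  # strict maximum of a 100-SNP bin sits at (100 - 0.5)/100
  res <- data.frame(snp_id = sprintf("s%d", 1:100), tau = seq(0.01, 1, 0.01),
                    p_value = 1e-6, maf = 0.25, tau_rank = NA_real_,
                    significant = NA, status = "ok")
  out <- maf_binned_rank(res)
  expect_equal(out$tau_rank[100], 0.995)
  expect_equal(out$tau_rank[1], 0.005)

  # total ties collapse to 0.5
  res$tau <- 0.4
  expect_true(all(maf_binned_rank(res)$tau_rank == 0.5))

  # a singleton bin warns and gets 0.5
  res$maf[1] <- 0.01
  expect_warning(out <- maf_binned_rank(res), "single SNP")
  expect_equal(out$tau_rank[1], 0.5)
})

test_that("significance needs both the Bonferroni and the rank gate", {
  res <- data.frame(snp_id = c("a", "b", "c"), tau = 0.5,
                    p_value = c(1.626e-4, 3e-4, 1e-9), maf = 0.3,
                    tau_rank = c(0.957, 0.99, 0.90), significant = NA,
                    status = "ok")
  out <- call_significant(res, n_tests = 175)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))

  # monotone: lowering p / raising rank never de-calls a SNP
  set.seed(4)
  base <- data.frame(snp_id = "x", tau = 0.5, p_value = runif(50, 0, 1e-3),
                     maf = 0.3, tau_rank = runif(50, 0.8, 1),
                     significant = NA, status = "ok")
  a <- call_significant(base, 100)$significant
  better <- base
  better$p_value <- better$p_value / 2
  better$tau_rank <- pmin(1, better$tau_rank + 0.02)
  b <- call_significant(better, 100)$significant
  expect_true(all(b[a]))
})

test_that("top_snp_per_gene matches an exhaustive per-gene argmax", {
  set.seed(8)
  res <- data.frame(snp_id = sprintf("s%02d", 1:10), chrom = "1",
                    pos = 1:10 * 100L, tau = runif(10, -1, 1),
                    p_value = runif(10, 1e-8, 1e-3), maf = 0.3,
                    tau_rank = round(runif(10, 0.9, 1), 3),
                    significant = rep(c(TRUE, FALSE), 5), status = "ok")
  gmap <- list(g1 = sprintf("s%02d", 1:4), g2 = sprintf("s%02d", 5:7),
               g3 = sprintf("s%02d", 8:10), g4 = character(0))
  top <- top_snp_per_gene(res, gmap)
  for (g in top$gene_id) {
    sub <- res[res$snp_id %in% gmap[[g]] & res$significant, ]
    best <- sub[order(-sub$tau_rank, sub$p_value, sub$pos), ][1, ]
    expect_equal(top$snp_id[top$gene_id == g], best$snp_id)
  }
  expect_false("g4" %in% top$gene_id)

  # a gene whose only SNPs are non-significant is omitted
  res$significant[8:10] <- FALSE
  expect_false("g3" %in% top_snp_per_gene(res, gmap)$gene_id)
})

test_that("matched controls respect the MAF tolerance and the seed", {
  set.seed(2)
  panel <- data.frame(snp_id = sprintf("s%04d", 1:2000),
                      maf = runif(2000, 0, 0.5))
  targets <- panel$snp_id[sample.int(2000, 12)]
  ctrl <- sample_matched_controls(panel, targets, k_per_target = 10,
                                  seed = 99)
  expect_length(ctrl, 120L)
  expect_false(anyDuplicated(ctrl) > 0)
  expect_true(length(intersect(ctrl, targets)) == 0)
  maf <- setNames(panel$maf, panel$snp_id)
  for (i in seq_along(targets)) {
    grp <- ctrl[(i - 1) * 10 + 1:10]
    expect_true(all(abs(maf[grp] - maf[targets[i]]) <= 0.01))
  }
  expect_identical(ctrl, sample_matched_controls(panel, targets, 10,
                                                 seed = 99))
  # an isolated target cannot be matched
  panel2 <- data.frame(snp_id = c("lone", sprintf("s%d", 1:30)),
                       maf = c(0.49, runif(30, 0, 0.2)))
  expect_error(sample_matched_controls(panel2, "lone", 5, seed = 1),
               "lone")
})

test_that("normalized DAF profiles are per-SNP z-scores ordered by photoperiod", {
  pops <- population_table(sprintf("p%02d", 1:8), seq(0, 63, 9))
  env <- environment_table(pops)
  fr <- matrix(runif(24, 0.2, 0.8), 3, 8, dimnames = list(NULL, pops$id))
  fr[2, ] <- 0.5                                  # flat SNP
  tab <- toy_freq_table(fr, pops = pops$id)
  pr <- normalized_daf_profile(tab, env)
  expect_equal(unname(rowMeans(pr$profile)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(apply(pr$profile[-2, ], 1, sd), c(1, 1),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(pr$flagged, "s2")
  expect_true(all(pr$profile[2, ] == 0))
  dp <- env$delta_photoperiod[match(pr$order, env$population_id)]
  expect_true(!is.unsorted(dp))

  # ancestral = allele_b flips the derived frequency
  tab2 <- tab
  tab2$snps$ancestral <- "G"
  pr2 <- normalized_daf_profile(tab2, env)
  expect_equal(pr2$profile[1, ], -pr$profile[1, ])

  tab$snps$ancestral[1] <- "unknown"
  expect_error(normalized_daf_profile(tab, env), "unknown ancestral")
})
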