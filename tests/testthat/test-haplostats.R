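test_that("window diversity equals exhaustive pair enumeration", {
  al <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0))
  p0 <- haplotype_panel(rbind(al, al), positions = c(10L, 20L, 30L, 40L))
  expect_equal(window_pairwise_diversity(p0, 1:4, 1:4), 0)

  al2 <- rbind(rep(0L, 40), c(rep(1L, 3), rep(0L, 37)), rep(0L, 40),
               rep(0L, 40))
  p2 <- haplotype_panel(al2, positions = seq_len(40) * 10L)
  expect_equal(window_pairwise_diversity(p2, 1:2, 1:40), 3)

  for (seed in 1:8) {
    pn <- toy_panel(n_hap = 4 + seed %% 3, n_site = 12, seed = seed)
    rows <- seq_len(nrow(pn$alleles))
    expect_equal(window_pairwise_diversity(pn, rows, 3:10),
                 brute_pairwise_div(pn$alleles, rows, 3:10),
                 tolerance = 1e-12)
  }
  expect_error(window_pairwise_diversity(p0, 1, 1:4), ">= 2 haplotypes")
})

test_that("dind reproduces brute-force diversity ratios and the cap rule", {
  # 6-haplotype toy panel: focal at site 5
  set.seed(12)
  al <- matrix(rbinom(6 * 9, 1, 0.5), 6, 9)
  al[, 5] <- c(1, 1, 1, 0, 0, 0)
  pn <- haplotype_panel(al, positions = seq_len(9) * 50L)
  d <- dind(pn, 5, flank = 4)
  win <- c(1:4, 6:9)
  ipa <- brute_pairwise_div(al, 4:6, win)
  ipd <- brute_pairwise_div(al, 1:3, win)
  expect_equal(d$i_pi_A, ipa, tolerance = 1e-12)
  expect_equal(d$i_pi_D, ipd, tolerance = 1e-12)
  expect_equal(d$dind, ipa / ipd, tolerance = 1e-12)
  expect_equal(d$daf, 0.5)
  expect_false(d$truncated)   # exactly 4 variants per side available
  expect_true(dind(pn, 2, flank = 4)$truncated)  # edge site is truncated

  # identical diversity on both sides gives exactly 1
  alx <- rbind(al[1:3, ], al[1:3, ])
  alx[, 5] <- c(1, 1, 1, 0, 0, 0)
  px <- haplotype_panel(alx, positions = seq_len(9) * 50L)
  dx <- dind(px, 5, flank = 4)
  expect_equal(dx$dind, 1)

  # swept fixture: derived carriers identical -> infinite ratio -> cap
  swept <- al
  swept[1:3, ] <- rep(c(0L, 1L), length.out = 9)[col(swept[1:3, ])]
  swept[, 5] <- c(1, 1, 1, 0, 0, 0)
  ps <- haplotype_panel(swept, positions = seq_len(9) * 50L)
  dset <- rbind(dind(ps, 5, flank = 4), d)
  capped <- apply_dind_cap(dset)
  expect_equal(attr(capped, "dind_cap"), d$dind + 20)
  expect_equal(capped$dind[1], d$dind + 20)

  # a single derived carrier is flagged, not computed
  al1 <- al; al1[, 5] <- c(1, 0, 0, 0, 0, 0)
  expect_equal(dind(haplotype_panel(al1, seq_len(9) * 50L), 5)$status,
               "too_few")
})

test_that("dind ignores sites monomorphic within both allele classes", {
  set.seed(3)
  al <- matrix(rbinom(8 * 11, 1, 0.5), 8, 11)
  al[, 6] <- rep(c(1, 0), each = 4)
  pn <- haplotype_panel(al, positions = seq_len(11) * 100L)
  base <- dind(pn, 6, flank = 5)
  # insert two sites monomorphic in every haplotype (both classes)
  al2 <- cbind(al[, 1:5], 0L, al[, 6, drop = FALSE], 1L, al[, 7:11])
  pn2 <- haplotype_panel(al2, positions = seq_len(13) * 100L)
  with_mono <- dind(pn2, 7, flank = 6)
  expect_equal(with_mono$dind, base$dind, tolerance = 1e-12)
})

test_that("dind significance gates on DAF-class 95th percentiles", {
  set.seed(44)
  bg <- data.frame(snp_id = sprintf("b%03d", 1:300), pos = 1:300,
                   daf = runif(300, 0.3, 0.7), n_window = 40,
                   i_pi_A = 1, i_pi_D = 1,
                   dind = rlnorm(300, 0, 0.3), truncated = FALSE,
                   status = "ok")
  # low-DAF classes dominated by i_pi_D = 0
  lo <- data.frame(snp_id = sprintf("l%03d", 1:60), pos = 1:60,
                   daf = runif(60, 0, 0.1), n_window = 40,
                   i_pi_A = 1, i_pi_D = 0, dind = Inf, truncated = FALSE,
                   status = "ok")
  background <- rbind(bg, lo)
  test <- data.frame(snp_id = c("hit", "null", "lowdaf"), pos = 1:3,
                     daf = c(0.5, 0.5, 0.05), n_window = 40,
                     i_pi_A = c(2, 1, 1), i_pi_D = c(0.01, 1, 0.5),
                     dind = c(200, 1, 2), truncated = FALSE, status = "ok")
  out <- dind_significance(test, background, n_daf_classes = 10L)
  expect_true(out$significant[1])            # above every background value
  expect_false(out$significant[2])
  expect_equal(out$status[3], "not_evaluable")
  expect_true(is.na(out$significant[3]))
  expect_equal(attr(out, "daf_floor"), 0.3)  # classes below 0.3 lack data
  expect_error(dind_significance(test, background[0, ]), "empty")
})

test_that("EHHS equals brute-force identical-pair fractions and decays", {
  for (seed in 1:6) {
    pn <- toy_panel(n_hap = 8, n_site = 12, seed = 100 + seed)
    focal <- 6
    cv <- ehhs(pn, focal, "both", floor = 0)   # no truncation: full audit
    h0 <- brute_pair_identity(pn$alleles, focal)
    for (r in seq_len(nrow(cv))) {
      j <- match(cv$pos[r], pn$positions)
      cols <- seq(min(j, focal), max(j, focal))
      expect_equal(cv$ehhs[r], brute_pair_identity(pn$alleles, cols) / h0,
                   tolerance = 1e-12)
    }
    # normalized to 1 at the focal site; non-increasing outward; in [0,1]
    expect_equal(cv$ehhs[cv$pos == pn$positions[focal]], 1)
    left <- cv$ehhs[cv$pos <= pn$positions[focal]]
    right <- cv$ehhs[cv$pos >= pn$positions[focal]]
    expect_true(all(diff(left) >= -1e-12))
    expect_true(all(diff(right) <= 1e-12))
    expect_true(all(cv$ehhs >= 0 & cv$ehhs <= 1))
  }

  # identical haplotypes keep EHHS at 1 to the region ends
  al <- matrix(rep(c(0L, 1L), each = 4), 4, 8)[, rep(1:2, 4)]
  pid <- haplotype_panel(rbind(al, al), positions = seq_len(8) * 1000L)
  cv1 <- ehhs(pid, 4, "both")
  expect_true(all(cv1$ehhs == 1))
  expect_equal(nrow(cv1), 8L)

  # truncation: values below the floor are dropped
  set.seed(7)
  big <- toy_panel(n_hap = 12, n_site = 30, seed = 9)
  tr <- ehhs(big, 15, "both", floor = 0.05)
  expect_true(all(tr$ehhs >= 0.05))
})

test_that("iES integrates the curve by trapezoid", {
  # rectangle: EHHS = 1 over 10 kb on both sides
  flat <- data.frame(pos = c(0, 5000, 10000), ehhs = 1)
  expect_equal(ies(flat), 10000)
  # triangle decaying 1 -> 0 over 1 kb each side
  tri <- data.frame(pos = c(0, 1000, 2000), ehhs = c(0, 1, 0))
  expect_equal(ies(tri), 1000)
  # fine-step Riemann sum agreement within 1%
  pos <- seq(0, 2000, by = 10)
  cv <- data.frame(pos = pos, ehhs = exp(-abs(pos - 1000) / 300))
  riemann <- sum(cv$ehhs[-1] * diff(pos))
  expect_lt(abs(ies(cv) - riemann) / riemann, 0.01)
  expect_error(ies(flat[1, ]), "single-point")
})

test_that("lnRsb is centered, ranked and antisymmetric", {
  cfg <- sim_config(n_haplotypes = 40, region_kb = 60, seed = 2)
  pr <- simulate_haplotype_pair(cfg, sweep_pop = 0, seed = 8)

  # identical panels: every raw log-ratio is exactly zero
  same <- lnrsb(pr$pop1, pr$pop1, pr$focal, region_halfwidth = 3e4)
  expect_true(all(same$lnrsb_raw == 0))

  rsb12 <- lnrsb(pr$pop1, pr$pop2, pr$focal, region_halfwidth = 3e4)
  rsb21 <- lnrsb(pr$pop2, pr$pop1, pr$focal, region_halfwidth = 3e4)
  expect_equal(median(rsb12$lnrsb), 0, tolerance = 1e-12)
  expect_equal(rsb12$lnrsb_raw, -rsb21$lnrsb_raw, tolerance = 1e-12)
  expect_equal(rsb12$lnrsb_rank, 1 - rsb21$lnrsb_rank, tolerance = 1e-12)
  expect_true(all(rsb12$lnrsb_rank > 0 & rsb12$lnrsb_rank < 1))
  expect_true(any(rsb12$focal))
  expect_error(lnrsb(pr$pop1, pr$pop2, "nosuch"), "not shared")
})

test_that("a planted sweep drives the focal lnRsb into the upper tail", {
  cfg <- sim_config(seed = 3)
  ranks <- vapply(51:53, function(s) {
    pr <- simulate_haplotype_pair(cfg, sweep_pop = 1, seed = s)
    rsb <- lnrsb(pr$pop1, pr$pop2, pr$focal)
    frow <- rsb[rsb$snp_id == pr$focal, ]
    expect_gt(frow$lnrsb, 0)   # centered log-ratio favours the swept pop
    frow$lnrsb_rank
  }, numeric(1))
  expect_gt(median(ranks), 0.9)
})

test_that("haplotype panels round-trip through phased VCF", {
  pn <- toy_panel(n_hap = 8, n_site = 10, seed = 33)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_haplotype_vcf(pn, tf)
  back <- read_haplotype_panel(tf, population_id = "roundtrip")
  expect_equal(unname(back$alleles), unname(pn$alleles))
  expect_equal(back$positions, pn$positions)

  # unphased input is refused
  lines <- readLines(tf)
  lines[6] <- gsub("|", "/", lines[6], fixed = TRUE)
  writeLines(lines, tf)
  expect_error(read_haplotype_panel(tf), "phased")
})
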