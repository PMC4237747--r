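test_that("frequency table validates shape, range and alleles", {
  tab <- toy_freq_table()
  expect_s3_class(tab, "freq_table")
  expect_equal(dim(tab$freq), c(3L, 2L))
  bad <- matrix(c(0.1, 1.2), 1, 2, dimnames = list(NULL, c("A", "B")))
  snps <- data.frame(id = "s1", chrom = "1", pos = 1L, allele_a = "A",
                     allele_b = "G", ancestral = "A")
  expect_error(frequency_table(snps, bad), "outside")
  snps$allele_b <- "A"
  expect_error(frequency_table(snps, bad * 0), "allele_a == allele_b")
})

test_that("frequency table TSV round trip is exact and errors are named", {
  set.seed(42)
  fr <- matrix(runif(120), 30, 4,
               dimnames = list(NULL, paste0("pop", 1:4)))
  fr[sample(length(fr), 10)] <- NA
  tab <- toy_freq_table(fr, pops = paste0("pop", 1:4))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_table(tab, tf)
  back <- read_frequency_table(tf)
  expect_identical(back$freq, tab$freq)     # bit-exact round trip
  expect_identical(back$snps, tab$snps)

  # malformed cell names its line; out-of-range cell is a validation error
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_table(toy_freq_table(), tf2)
  lines <- readLines(tf2)
  lines[3] <- "s2\t1\t200\tA\tG\tA\toops\t0.6"
  writeLines(lines, tf2)
  expect_error(read_frequency_table(tf2), "line 3")
  lines[3] <- "s2\t1\t200\tA\tG\tA\t1.7\t0.6"
  writeLines(lines, tf2)
  expect_error(read_frequency_table(tf2), "outside")
  writeLines(lines[1], tf2)
  expect_error(read_frequency_table(tf2), "no SNPs")
})

test_that("VCF ingestion counts alleles per population over non-missing calls", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  rows <- c("1\t100\trsA\tA\tG\t.\tPASS\tAA=G\tGT\t0/1\t1/1\t./.\t./.",
            "1\t200\trsB\tC\tT\t.\tPASS\tAA=C\tGT\t0/0\t0/1\t0/0\t1/1",
            "1\t300\trsC\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2\t0/0")
  write_test_vcf(tf, rows, c("s1", "s2", "s3", "s4"))
  map <- c(s1 = "P1", s2 = "P1", s3 = "P2", s4 = "P2")
  expect_warning(tab <- frequencies_from_genotypes(tf, map),
                 "multi-allelic")
  expect_equal(nrow(tab$freq), 2L)                 # rsC skipped
  expect_equal(tab$freq["rsA", "P1"], 0.75)        # 0/1 + 1/1
  expect_true(is.na(tab$freq["rsA", "P2"]))        # all calls missing
  expect_equal(tab$freq["rsB", "P2"], 0.5)
  expect_equal(tab$snps$ancestral, c("G", "C"))    # AA tag honoured
  expect_error(suppressWarnings(frequencies_from_genotypes(tf, map[-2])),
               "absent")
})

test_that("VCF frequencies equal a direct hand count on random diploids", {
  set.seed(9)
  n <- 10
  gts <- replicate(n, paste(sample(0:1, 2, TRUE), collapse = "/"))
  gts[3] <- "./."
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(tf, paste(c("1\t500\trsX\tA\tG\t.\tPASS\t.\tGT", gts),
                           collapse = "\t"), sprintf("i%02d", 1:n))
  map <- setNames(rep("P", n), sprintf("i%02d", 1:n))
  tab <- suppressWarnings(frequencies_from_genotypes(tf, map))
  alleles <- unlist(strsplit(gts[-3], "/"))
  expect_equal(tab$freq["rsX", "P"], sum(alleles == "1") / length(alleles))
})

test_that("average MAF folds the across-population mean frequency", {
  tab <- toy_freq_table(matrix(c(0.2, 0.9, 0.4, 0.9), 2, 2,
                               dimnames = list(NULL, c("A", "B"))))
  expect_equal(unname(average_maf(tab)), c(0.3, 0.1))

  set.seed(3)
  fr <- matrix(runif(52 * 5), 5, 52,
               dimnames = list(NULL, sprintf("p%02d", 1:52)))
  tab52 <- toy_freq_table(fr, pops = colnames(fr))
  expect_equal(unname(average_maf(tab52)),
               pmin(rowMeans(fr), 1 - rowMeans(fr)))

  fr[1, ] <- NA
  tabNA <- toy_freq_table(fr, pops = colnames(fr))
  expect_error(average_maf(tabNA), "missing in every population")
})

test_that("SNP-gene assignment honours the strand-aware upstream window", {
  genes <- gene_annotation(c("gplus", "gminus"), "1",
                           c(1000L, 1000L), c(2000L, 2000L), c("+", "-"))
  snps <- data.frame(id = sprintf("s%d", 1:6), chrom = "1",
                     pos = c(500L, 499L, 1500L, 2400L, 2501L, 2000L))
  m <- assign_snps_to_genes(snps, genes)
  expect_true("s1" %in% m$gplus)        # 500 = TSS - 500, lower edge
  expect_false("s2" %in% m$gplus)       # 499 just outside
  expect_true(all(c("s3", "s6") %in% m$gplus))
  expect_true("s4" %in% m$gminus)       # 2400 within downstream-strand window
  expect_false("s5" %in% m$gminus)      # 2501 outside
  expect_true("s3" %in% m$gminus)       # transcribed region is shared

  # invariance under gene reordering
  m2 <- assign_snps_to_genes(snps, genes[2:1, ])
  expect_identical(m[sort(names(m))], m2[sort(names(m2))])
})

test_that("ld_r2 equals the haplotype-count formula and flags monomorphic", {
  expect_equal(ld_r2(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(ld_r2(c(0, 1, 0, 1), c(1, 0, 1, 0)), 1)   # complementary
  expect_error(ld_r2(c(1, 1, 1, 1), c(0, 1, 0, 1)), "monomorphic")

  # 8-haplotype toy pair vs D / sqrt(pA pa pB pb), squared, from hand counts
  hA <- c(1, 1, 1, 0, 0, 0, 1, 0)
  hB <- c(1, 1, 0, 0, 0, 1, 1, 0)
  pA <- mean(hA); pB <- mean(hB); pAB <- mean(hA & hB)
  D <- pAB - pA * pB
  expect_equal(ld_r2(hA, hB),
               D^2 / (pA * (1 - pA) * pB * (1 - pB)), tolerance = 1e-12)
  expect_equal(ld_r2(hA, hB), ld_r2(hB, hA))

  set.seed(10)
  expect_lt(ld_r2(rbinom(1000, 1, 0.5), rbinom(1000, 1, 0.5)), 0.02)
})

test_that("LD collapsing keeps one of a duplicate pair and respects 0.39", {
  haps <- list(a = c(0, 1, 0, 1, 1, 0), b = c(0, 1, 0, 1, 1, 0))
  r2_fun <- function(i, j) ld_r2(haps[[i]], haps[[j]])
  expect_length(collapse_by_ld(c("a", "b"), r2_fun), 1L)

  # r2 just below the gate: both survive
  r2_low <- function(i, j) 0.39
  expect_equal(collapse_by_ld(c("a", "b"), r2_low), c("a", "b"))
})

test_that("LD collapsing always passes the pairwise audit (property)", {
  for (seed in 1:12) {
    set.seed(seed)
    n_snp <- 12; n_hap <- 40
    base <- rbinom(n_hap, 1, 0.5)
    haps <- lapply(1:n_snp, function(i) {
      h <- if (runif(1) < 0.5) base else rbinom(n_hap, 1, 0.5)
      flip <- runif(n_hap) < 0.1
      h[flip] <- 1 - h[flip]
      h
    })
    names(haps) <- sprintf("v%02d", 1:n_snp)
    poly <- names(haps)[vapply(haps, sd, numeric(1)) > 0]
    r2_fun <- function(i, j) ld_r2(haps[[i]], haps[[j]])
    kept <- collapse_by_ld(poly, r2_fun, threshold = 0.4, seed = seed)
    if (length(kept) > 1) {
      prs <- combn(kept, 2)
      audit <- apply(prs, 2, function(p) r2_fun(p[1], p[2]))
      expect_true(all(audit < 0.4))
    }
    expect_identical(kept, collapse_by_ld(poly, r2_fun, 0.4, seed = seed))
  }
})
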