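# The SNP x population allele-frequency table: the substrate of the
# environmental correlation scan. Frequencies refer to allele_b (the ALT
# allele when built from a VCF); missing cells stay NA and are excluded from
# per-SNP statistics.

#' Construct a frequency table
#'
#' @param snps data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `allele_a`, `allele_b` (single bases, distinct) and `ancestral`
#'   (one of the two alleles or `"unknown"`).
#' @param freq numeric matrix `n_snps x n_pops` of allele_b frequencies in
#'   \[0, 1\] (NA = missing); column names are population ids.
#' @param counts optional integer matrix of non-missing allele counts,
#'   same shape as `freq`.
#' @return an object of class `freq_table`.
#' @export
frequency_table <- function(snps, freq, counts = NULL) {
  stopifnot(is.data.frame(snps), is.matrix(freq))
  need <- c("id", "chrom", "pos", "allele_a", "allele_b", "ancestral")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stopf("snps table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(snps) == 0L) stopf("no SNPs")
  if (nrow(freq) != nrow(snps))
    stopf("freq has %d rows but %d SNPs", nrow(freq), nrow(snps))
  if (is.null(colnames(freq)) || anyDuplicated(colnames(freq)))
    stopf("freq must have unique population-id column names")
  if (anyDuplicated(snps$id)) stopf("duplicated SNP id '%s'",
                                    snps$id[anyDuplicated(snps$id)])
  if (any(snps$pos < 1)) stopf("SNP positions must be >= 1")
  if (any(snps$allele_a == snps$allele_b))
    stopf("allele_a == allele_b for SNP '%s'",
          snps$id[which(snps$allele_a == snps$allele_b)[1]])
  bad_anc <- !(snps$ancestral == snps$allele_a |
                 snps$ancestral == snps$allele_b |
                 snps$ancestral == "unknown")
  if (any(bad_anc)) stopf("ancestral state of SNP '%s' is neither allele",
                          snps$id[which(bad_anc)[1]])
  out <- freq[!is.na(freq)]
  if (any(out < 0 | out > 1)) stopf("frequency outside [0, 1]")
  if (!is.null(counts)) stopifnot(is.matrix(counts),
                                  all(dim(counts) == dim(freq)))
  rownames(freq) <- snps$id
  structure(list(snps = snps, freq = freq, counts = counts),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d SNPs x %d populations (%.1f%% missing)\n",
              nrow(x$freq), ncol(x$freq),
              100 * mean(is.na(x$freq))))
  invisible(x)
}

#' Population ids of a frequency table
#' @param table a `freq_table`.
#' @export
pop_ids <- function(table) colnames(table$freq)

SNP_COLS <- c("id", "chrom", "pos", "allele_a", "allele_b", "ancestral")

#' Read a frequency table from TSV
#'
#' Expected layout: header line, then one row per SNP with columns
#' `id  chrom  pos  allele_a  allele_b  ancestral` followed by one numeric
#' frequency column per population. Empty cells or `NA` are missing.
#'
#' @param path file path.
#' @return a `freq_table`.
#' @export
read_frequency_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"))
  miss <- setdiff(SNP_COLS, names(raw))
  if (length(miss)) stopf("frequency table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) stopf("no SNPs in '%s'", path)
  pops <- setdiff(names(raw), SNP_COLS)
  if (length(pops) == 0L) stopf("no population columns in '%s'", path)
  fr <- matrix(NA_real_, nrow(raw), length(pops),
               dimnames = list(raw$id, pops))
  for (j in seq_along(pops)) {
    cell <- raw[[pops[j]]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is.na(cell) & is.na(val)
    if (any(bad))
      stopf("cannot parse frequency '%s' (line %d, population %s)",
            cell[which(bad)[1]], which(bad)[1] + 1L, pops[j])
    fr[, j] <- val
  }
  snps <- data.frame(id = raw$id, chrom = raw$chrom,
                     pos = as.integer(raw$pos),
                     allele_a = raw$allele_a, allele_b = raw$allele_b,
                     ancestral = raw$ancestral, stringsAsFactors = FALSE)
  frequency_table(snps, fr)
}

#' Write a frequency table as TSV
#'
#' Frequencies are written with 17 significant digits so that a
#' write-then-read round trip reproduces every value exactly.
#'
#' @param table a `freq_table`.
#' @param path file path.
#' @export
write_frequency_table <- function(table, path) {
  stopifnot(inherits(table, "freq_table"))
  fr <- table$freq
  chr <- matrix("", nrow(fr), ncol(fr), dimnames = dimnames(fr))
  ok <- !is.na(fr)
  chr[ok] <- sprintf("%.17g", fr[ok])
  chr[!ok] <- "NA"
  out <- cbind(table$snps[SNP_COLS], as.data.frame(chr,
                                                   stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-population ALT-allele frequencies from a VCF
#'
#' Reads biallelic records from a (possibly phased) VCF and computes, for
#' each population in `pop_map`, the frequency of the ALT allele over
#' non-missing calls. Populations with no called allele at a SNP get a
#' missing cell. Multi-allelic records are skipped with a warning. The
#' ancestral state is taken from the `AA` INFO tag when present (matched
#' against REF/ALT), otherwise `"unknown"`.
#'
#' @param vcf path to a VCF file.
#' @param pop_map named character vector mapping sample id -> population id;
#'   must cover every sample in the VCF.
#' @return a `freq_table` with allele_a = REF, allele_b = ALT.
#' @export
frequencies_from_genotypes <- function(vcf, pop_map) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  bi <- vcfR::is.biallelic(v)
  if (any(!bi))
    warnf("skipping %d multi-allelic record(s)", sum(!bi))
  if (!any(bi)) stopf("no biallelic SNPs in '%s'", vcf)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]
  samples <- colnames(gt)
  unmapped <- setdiff(samples, names(pop_map))
  if (length(unmapped)) stopf("sample '%s' absent from pop_map", unmapped[1])
  pops <- unique(unname(pop_map[samples]))

  # allele-wise counts: each genotype string contributes its 0/1 alleles
  alt_cnt <- function(g) {
    al <- strsplit(ifelse(is.na(g), ".", g), "[/|]")
    nalt <- vapply(al, function(a) sum(a == "1"), integer(1))
    ntot <- vapply(al, function(a) sum(a %in% c("0", "1")), integer(1))
    cbind(nalt, ntot)
  }
  n_snp <- nrow(gt)
  fr <- matrix(NA_real_, n_snp, length(pops),
               dimnames = list(NULL, pops))
  cnt <- matrix(0L, n_snp, length(pops), dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- samples[pop_map[samples] == p]
    nalt <- matrix(0L, n_snp, length(cols))
    ntot <- matrix(0L, n_snp, length(cols))
    for (k in seq_along(cols)) {
      ac <- alt_cnt(gt[, cols[k]])
      nalt[, k] <- ac[, 1]; ntot[, k] <- ac[, 2]
    }
    tot <- rowSums(ntot)
    fr[, p] <- ifelse(tot > 0, rowSums(nalt) / tot, NA_real_)
    cnt[, p] <- tot
  }
  aa <- tryCatch(vcfR::extract.info(v, "AA")[bi], error = function(e) NULL)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  anc <- rep("unknown", n_snp)
  if (!is.null(aa)) {
    aa <- toupper(aa)
    anc[!is.na(aa) & aa == toupper(ref)] <- ref[!is.na(aa) &
                                                  aa == toupper(ref)]
    anc[!is.na(aa) & aa == toupper(alt)] <- alt[!is.na(aa) &
                                                  aa == toupper(alt)]
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  snps <- data.frame(id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     allele_a = ref, allele_b = alt, ancestral = anc,
                     stringsAsFactors = FALSE)
  frequency_table(snps, fr, counts = cnt)
}

#' Average minor allele frequency per SNP
#'
#' The per-SNP MAF used for empirical binning: the unweighted mean of the
#' allele_b frequency over non-missing populations, folded to the minor
#' allele: `min(fbar, 1 - fbar)`.
#'
#' @param table a `freq_table`.
#' @param snps optional SNP ids or indices (default: all SNPs).
#' @return named numeric vector in \[0, 0.5\].
#' @export
average_maf <- function(table, snps = NULL) {
  stopifnot(inherits(table, "freq_table"))
  fr <- table$freq
  if (!is.null(snps)) fr <- fr[snps, , drop = FALSE]
  n_ok <- rowSums(!is.na(fr))
  if (any(n_ok == 0L))
    stopf("SNP '%s' is missing in every population",
          rownames(fr)[which(n_ok == 0L)[1]])
  fbar <- rowMeans(fr, na.rm = TRUE)
  pmin(fbar, 1 - fbar)
}

#' Derived-allele frequencies
#'
#' Converts the allele_b frequencies to derived-allele frequencies using the
#' ancestral-state column. SNPs with unknown ancestral state raise an error
#' unless `require_polarized = FALSE` (then NA rows).
#'
#' @param table a `freq_table`.
#' @param require_polarized error on unpolarized SNPs?
#' @return matrix `n_snps x n_pops` of derived frequencies.
#' @export
derived_frequencies <- function(table, require_polarized = TRUE) {
  stopifnot(inherits(table, "freq_table"))
  anc <- table$snps$ancestral
  unk <- anc == "unknown"
  if (any(unk) && require_polarized)
    stopf("SNP '%s' has unknown ancestral state", table$snps$id[which(unk)[1]])
  daf <- table$freq
  flip <- anc == table$snps$allele_b      # allele_b ancestral -> derived = a
  daf[flip, ] <- 1 - daf[flip, , drop = FALSE]
  daf[unk, ] <- NA_real_
  daf
}
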