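# Haplotype-based selection statistics on phased, ancestrally polarized
# panels:
#
#  * DIND — the ratio of mean pairwise differences among ancestral-allele
#    carriers to that among derived-allele carriers (i_pi_A / i_pi_D) over a
#    fixed window of 40 flanking variants (20 per side). A sweep on the
#    derived allele empties its intra-allelic diversity, inflating the
#    ratio. Ratios with i_pi_D = 0 are set to the dataset-wide maximum
#    finite value plus 20, and significance is read off DAF-class-wise 95th
#    percentiles of a background distribution.
#
#  * EHHS / iES / lnRsb — site-specific extended haplotype homozygosity:
#    the probability that two haplotypes drawn without replacement are
#    identical over the interval from a focal SNP, normalized to 1 at the
#    focal site, truncated when it decays below 0.05; integrated over
#    physical position (trapezoid) into iES, and compared between two
#    populations as lnRsb = ln(iES_pop1 / iES_pop2), median-centered and
#    ranked against all SNPs in the surrounding regions.

#' Construct a phased haplotype panel
#'
#' @param alleles binary matrix `n_haplotypes x n_sites`, 0 = ancestral,
#'   1 = derived.
#' @param positions strictly increasing 1-based physical positions, one per
#'   site.
#' @param chrom chromosome name.
#' @param snp_ids optional site ids (default `chrom:pos`).
#' @param population_id optional population label.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, positions, chrom = "1", snp_ids = NULL,
                            population_id = NA_character_) {
  stopifnot(is.matrix(alleles), ncol(alleles) == length(positions))
  if (nrow(alleles) < 4L) stopf("need >= 4 haplotypes")
  if (!all(alleles %in% c(0L, 1L))) stopf("alleles must be 0/1")
  if (is.unsorted(positions, strictly = TRUE))
    stopf("positions must be strictly increasing")
  if (is.null(snp_ids)) snp_ids <- paste0(chrom, ":", positions)
  stopifnot(length(snp_ids) == length(positions), !anyDuplicated(snp_ids))
  colnames(alleles) <- snp_ids
  structure(list(alleles = alleles, positions = as.integer(positions),
                 chrom = chrom, snp_ids = snp_ids,
                 population_id = population_id),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel '%s': %d haplotypes x %d sites (%s:%d-%d)\n",
              x$population_id, nrow(x$alleles), ncol(x$alleles), x$chrom,
              min(x$positions), max(x$positions)))
  invisible(x)
}

site_index <- function(panel, snp) {
  i <- if (is.character(snp)) match(snp, panel$snp_ids) else as.integer(snp)
  if (is.na(i) || i < 1L || i > length(panel$positions))
    stopf("focal SNP '%s' not in panel", as.character(snp))
  i
}

#' Mean pairwise differences over a site window
#'
#' Average, over all unordered pairs of the selected haplotypes, of the
#' number of differing sites within the window. Computed by per-site allele
#' counts: sum_s n1_s (k - n1_s) / C(k, 2), which equals the exhaustive
#' pair enumeration.
#'
#' @param panel a `haplotype_panel`.
#' @param hap_rows haplotype row indices (>= 2).
#' @param site_cols site column indices.
#' @return mean pairwise difference (>= 0).
#' @export
window_pairwise_diversity <- function(panel, hap_rows, site_cols) {
  k <- length(hap_rows)
  if (k < 2L) stopf("need >= 2 haplotypes for pairwise diversity")
  h <- panel$alleles[hap_rows, site_cols, drop = FALSE]
  n1 <- colSums(h)
  sum(n1 * (k - n1)) / (k * (k - 1) / 2)
}

#' DIND statistic at one focal SNP
#'
#' Intra-allelic diversity ratio i_pi_A / i_pi_D over a window of `flank`
#' variants on each side of the focal SNP (focal excluded; truncated at
#' panel edges with `truncated = TRUE`). Requires >= 2 carriers of each
#' allele, otherwise status `"too_few"`. When i_pi_D = 0 the ratio is
#' returned as `Inf`; apply the dataset-wide cap with [apply_dind_cap()]
#' or let [dind_significance()] do it.
#'
#' @param panel a `haplotype_panel` (0 = ancestral, 1 = derived).
#' @param focal_snp site id or index.
#' @param flank flanking variants per side (default 20).
#' @return one-row data.frame: `snp_id`, `pos`, `daf`, `n_window`,
#'   `i_pi_A`, `i_pi_D`, `dind`, `truncated`, `status`.
#' @export
dind <- function(panel, focal_snp, flank = 20L) {
  i <- site_index(panel, focal_snp)
  win <- setdiff(seq(max(1L, i - flank), min(ncol(panel$alleles), i + flank)),
                 i)
  der <- which(panel$alleles[, i] == 1L)
  anc <- which(panel$alleles[, i] == 0L)
  daf <- length(der) / nrow(panel$alleles)
  row <- data.frame(snp_id = panel$snp_ids[i], pos = panel$positions[i],
                    daf = daf, n_window = length(win),
                    i_pi_A = NA_real_, i_pi_D = NA_real_, dind = NA_real_,
                    truncated = length(win) < 2L * flank,
                    status = "ok", stringsAsFactors = FALSE)
  if (length(der) < 2L || length(anc) < 2L) {
    row$status <- "too_few"
    return(row)
  }
  row$i_pi_A <- window_pairwise_diversity(panel, anc, win)
  row$i_pi_D <- window_pairwise_diversity(panel, der, win)
  row$dind <- if (row$i_pi_D == 0) Inf else row$i_pi_A / row$i_pi_D
  row
}

#' DIND at every site of a panel
#' @inheritParams dind
#' @return data.frame with one [dind()] row per site.
#' @export
dind_scan <- function(panel, flank = 20L) {
  out <- do.call(rbind, lapply(seq_along(panel$positions), dind,
                               panel = panel, flank = flank))
  rownames(out) <- NULL
  out
}

#' Cap infinite DIND values at the dataset maximum + 20
#'
#' Rows with i_pi_D = 0 (infinite ratio) are set to the maximum finite
#' DIND over the supplied rows plus 20, so they rank above every finite
#' value without leaving the scale.
#'
#' @param results data.frame of [dind()] rows (may pool several panels).
#' @return `results` with finite `dind`; the cap value is attribute
#'   `"dind_cap"`.
#' @export
apply_dind_cap <- function(results) {
  fin <- results$dind[is.finite(results$dind)]
  cap <- if (length(fin)) max(fin) + 20 else 20
  inf <- !is.na(results$dind) & !is.finite(results$dind)
  results$dind[inf] <- cap
  attr(results, "dind_cap") <- cap
  results
}

#' DIND significance against a DAF-binned background
#'
#' Pools the test rows with a background of DIND-DAF pairs (in practice a
#' large random-SNP scan), applies the i_pi_D = 0 cap over the pooled
#' dataset, bins the background into `n_daf_classes` equal-width DAF
#' classes, and flags a test SNP significant when its DIND exceeds its
#' class's 95th percentile. Classes whose 95th percentile is the cap value
#' (i.e. dominated by i_pi_D = 0, typical at low DAF) or that hold fewer
#' than `min_class` background SNPs are not evaluable; affected test SNPs
#' get status `"not_evaluable"`. The lowest evaluable class edge is
#' reported as attribute `"daf_floor"` — the empirical DAF floor below
#' which the test cannot be computed.
#'
#' @param results test rows from [dind()] / [dind_scan()].
#' @param background background rows (same columns; >= 1 required).
#' @param n_daf_classes number of DAF classes on \[0, 1\] (default 100).
#' @param gate percentile gate (default 0.95).
#' @param min_class minimum background SNPs per evaluable class (default 10).
#' @return `results` with capped `dind`, a logical `significant` column and
#'   updated `status`; attributes `"dind_cap"`, `"daf_floor"` and
#'   `"class_p95"`.
#' @export
dind_significance <- function(results, background, n_daf_classes = 100L,
                              gate = 0.95, min_class = 10L) {
  if (is.null(background) || !nrow(background)) stopf("empty DIND background")
  width <- 1 / n_daf_classes
  pool <- rbind(results[names(background)], background)
  pool <- apply_dind_cap(pool)
  cap <- attr(pool, "dind_cap")
  results$dind <- pool$dind[seq_len(nrow(results))]
  bg <- pool[-seq_len(nrow(results)), ]
  bg <- bg[bg$status == "ok" & !is.na(bg$dind), ]
  cls_of <- function(daf) pmin(floor(daf / width), n_daf_classes - 1L)
  bg_cls <- cls_of(bg$daf)
  p95 <- stats::setNames(rep(NA_real_, n_daf_classes),
                         seq_len(n_daf_classes) - 1L)
  for (b in unique(bg_cls)) {
    v <- bg$dind[bg_cls == b]
    if (length(v) >= min_class) {
      q <- stats::quantile(v, gate, names = FALSE)
      if (q < cap) p95[as.character(b)] <- q
    }
  }
  evaluable <- !is.na(p95)
  daf_floor <- if (any(evaluable))
    (min(which(evaluable)) - 1L) * width else NA_real_
  res_cls <- cls_of(results$daf)
  thr <- p95[as.character(res_cls)]
  sig <- rep(NA, nrow(results))
  ok <- results$status == "ok" & !is.na(results$dind)
  sig[ok & !is.na(thr)] <- results$dind[ok & !is.na(thr)] >
    thr[ok & !is.na(thr)]
  results$significant <- sig
  results$status[ok & is.na(thr)] <- "not_evaluable"
  attr(results, "dind_cap") <- cap
  attr(results, "daf_floor") <- daf_floor
  attr(results, "class_p95") <- p95
  results
}

# haplotype homozygosity of intervals focal..j as j walks outward:
# refine group labels site by site; H = sum n_g (n_g - 1) / (n (n - 1))
hh_walk <- function(alleles, focal, idx) {
  n <- nrow(alleles)
  denom <- n * (n - 1)
  g <- match(alleles[, focal], unique(alleles[, focal]))
  hh0 <- sum(table(g) * (table(g) - 1)) / denom
  vals <- numeric(length(idx))
  for (k in seq_along(idx)) {
    key <- g * 2L + alleles[, idx[k]]
    g <- match(key, unique(key))
    tab <- tabulate(g)
    vals[k] <- sum(tab * (tab - 1)) / denom
  }
  list(hh0 = hh0, vals = vals)
}

#' EHHS decay curve from a focal SNP
#'
#' Site-specific extended haplotype homozygosity: at each successive site,
#' the probability that two haplotypes drawn without replacement are
#' identical over the whole interval from the focal SNP to that site
#' (sum n_h (n_h - 1) / (n (n - 1)) over haplotype classes), normalized to
#' 1 at the focal site. The curve is truncated at the first site where it
#' falls below `floor` (that site excluded) or at the end of the data.
#'
#' @param panel a `haplotype_panel` (>= 4 haplotypes).
#' @param focal_snp site id or index.
#' @param direction `"left"`, `"right"` or `"both"`.
#' @param floor truncation threshold (default 0.05).
#' @return data.frame `pos`, `ehhs`, ordered by position; for
#'   `direction = "both"` the two arms share the focal point. The focal
#'   value is always 1.
#' @export
ehhs <- function(panel, focal_snp, direction = c("both", "left", "right"),
                 floor = 0.05) {
  direction <- match.arg(direction)
  i <- site_index(panel, focal_snp)
  arm <- function(idx) {
    w <- hh_walk(panel$alleles, i, idx)
    if (w$hh0 == 0) stopf("all haplotypes distinct at the focal site")
    v <- w$vals / w$hh0
    keep <- which(v < floor)
    if (length(keep)) idx <- idx[seq_len(keep[1] - 1L)]
    v <- v[seq_along(idx)]
    data.frame(pos = panel$positions[idx], ehhs = v)
  }
  focal_pt <- data.frame(pos = panel$positions[i], ehhs = 1)
  left <- if (direction %in% c("both", "left") && i > 1L)
    arm(rev(seq_len(i - 1L))) else NULL
  right <- if (direction %in% c("both", "right") &&
                 i < ncol(panel$alleles))
    arm(seq(i + 1L, ncol(panel$alleles))) else NULL
  out <- switch(direction,
    left = rbind(left[rev(seq_len(NROW(left))), , drop = FALSE], focal_pt),
    right = rbind(focal_pt, right),
    both = rbind(left[rev(seq_len(NROW(left))), , drop = FALSE], focal_pt,
                 right))
  rownames(out) <- NULL
  out
}

#' Integrated EHHS (iES)
#'
#' Trapezoid integral of a two-sided EHHS curve over physical position, in
#' base-pair x homozygosity units.
#'
#' @param curve data.frame `pos`, `ehhs` as returned by [ehhs()] with
#'   `direction = "both"` (at least 2 points, positions increasing).
#' @return iES (> 0).
#' @export
ies <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("pos", "ehhs") %in% names(curve)))
  if (nrow(curve) < 2L) stopf("single-point EHHS curve: iES undefined")
  stopifnot(!is.unsorted(curve$pos, strictly = TRUE))
  sum(diff(curve$pos) * (utils::head(curve$ehhs, -1) +
                           utils::tail(curve$ehhs, -1)) / 2)
}

#' lnRsb scan around selected SNPs
#'
#' For every SNP within `region_halfwidth` of any focal SNP (shared,
#' polymorphic in both panels), computes iES in the two populations and
#' lnRsb = ln(iES_pop1 / iES_pop2). Values are median-centered across all
#' region SNPs and assigned a mid-rank percentile in that pooled empirical
#' distribution; a SNP is significant at `rank >= gate` (the upper tail:
#' extended homozygosity in pop1 relative to pop2). Swapping the panels
#' flips signs and mirrors the ranks.
#'
#' @param panel_pop1,panel_pop2 `haplotype_panel`s sharing positions.
#' @param snp_set focal SNP ids (present in both panels).
#' @param region_halfwidth half-width of the scan region in bp
#'   (default 1e5, i.e. 200-kb regions).
#' @param floor EHHS truncation threshold (default 0.05).
#' @param gate rank gate for significance (default 0.95).
#' @return data.frame `snp_id`, `pos`, `ies_pop1`, `ies_pop2`,
#'   `lnrsb_raw`, `lnrsb` (centered), `lnrsb_rank`, `focal`, `significant`.
#'   SNPs with undefined iES in either population are skipped.
#' @export
lnrsb <- function(panel_pop1, panel_pop2, snp_set,
                  region_halfwidth = 1e5, floor = 0.05, gate = 0.95) {
  shared <- intersect(panel_pop1$snp_ids, panel_pop2$snp_ids)
  if (!all(snp_set %in% shared))
    stopf("focal SNP '%s' not shared by both panels",
          setdiff(snp_set, shared)[1])
  pos1 <- stats::setNames(panel_pop1$positions, panel_pop1$snp_ids)
  focal_pos <- pos1[snp_set]
  in_region <- vapply(shared, function(s)
    any(abs(pos1[s] - focal_pos) <= region_halfwidth), logical(1))
  region <- shared[in_region]
  rows <- lapply(region, function(s) {
    i1 <- site_index(panel_pop1, s); i2 <- site_index(panel_pop2, s)
    if (length(unique(panel_pop1$alleles[, i1])) < 2L ||
          length(unique(panel_pop2$alleles[, i2])) < 2L) return(NULL)
    c1 <- tryCatch(ies(ehhs(panel_pop1, s, "both", floor)),
                   error = function(e) NA_real_)
    c2 <- tryCatch(ies(ehhs(panel_pop2, s, "both", floor)),
                   error = function(e) NA_real_)
    if (is.na(c1) || is.na(c2)) return(NULL)
    data.frame(snp_id = s, pos = unname(pos1[s]), ies_pop1 = c1,
               ies_pop2 = c2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stopf("no SNP with defined iES in both populations")
  out$lnrsb_raw <- log(out$ies_pop1 / out$ies_pop2)
  out$lnrsb <- out$lnrsb_raw - stats::median(out$lnrsb_raw)
  out$lnrsb_rank <- mid_rank(out$lnrsb)
  out$focal <- out$snp_id %in% snp_set
  out$significant <- out$lnrsb_rank >= gate
  rownames(out) <- NULL
  out
}
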