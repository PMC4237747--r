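# Seeded generators for every input the pipeline consumes: a latitude
# chain of populations emulating a worldwide 52-population diversity panel,
# Balding-Nichols allele frequencies with drift increasing away from an
# equatorial origin (the out-of-Africa diversity gradient that the
# empirical MAF-binned ranks correct for), optional logit-linear frequency
# clines tracking delta-photoperiod at a chosen fraction of SNPs, HWE
# genotype draws, and founder-mosaic haplotype panels with planted hard
# sweeps (a single core haplotype copied with distance-decaying fidelity
# around the focal site).

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' calibration and power analyses: 52 populations spanning latitudes
#' 0--70 degrees (delta-photoperiod 0--24 h), Balding-Nichols drift growing
#' 0.002 per degree of latitude away from the equatorial origin (F up to
#' 0.14, a human-scale differentiation gradient), clines of 0.15 logit
#' units per hour of delta-photoperiod at 5% of SNPs (strong enough that
#' |tau| >= 0.5 across 52 populations), and 100-haplotype panels over
#' 200-kb regions with one segregating site per kb.
#'
#' @param n_pops number of populations (>= 3).
#' @param latitude_range degrees, `c(lo, hi)` with lo < hi.
#' @param origin_latitude latitude of the drift origin.
#' @param n_snps SNPs in the frequency table.
#' @param frac_selected fraction of SNPs carrying a cline.
#' @param drift_scale Balding-Nichols F per degree of latitude distance
#'   from the origin (> 0; F must stay < 1).
#' @param cline_strength logit-frequency shift per hour of
#'   delta-photoperiod at selected SNPs.
#' @param n_individuals diploid individuals genotyped per population.
#' @param n_haplotypes haplotypes per panel (even).
#' @param sweep_daf target derived-allele frequency at planted sweeps,
#'   in (0, 1).
#' @param mutation_density segregating sites per kb.
#' @param recomb_decay haplotype-identity decay length in kb: the scale of
#'   founder-mosaic segments and of core-haplotype copying at sweeps.
#' @param region_kb length of simulated haplotype regions in kb.
#' @param n_founders founder haplotypes behind the neutral mosaic; 1 (with
#'   `private_mut = 0`) gives a fully monomorphic panel.
#' @param private_mut per-site, per-haplotype private mutation rate.
#' @param seed integer seed; all generators are deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 52L, latitude_range = c(0, 70),
                       origin_latitude = 0, n_snps = 1000L,
                       frac_selected = 0.05, drift_scale = 0.002,
                       cline_strength = 0.15, n_individuals = 25L,
                       n_haplotypes = 100L, sweep_daf = 0.6,
                       mutation_density = 1, recomb_decay = 50,
                       region_kb = 200, n_founders = 6L,
                       private_mut = 0.005, seed = 1L) {
  cfg <- list(n_pops = as.integer(n_pops), latitude_range = latitude_range,
              origin_latitude = origin_latitude, n_snps = as.integer(n_snps),
              frac_selected = frac_selected, drift_scale = drift_scale,
              cline_strength = cline_strength,
              n_individuals = as.integer(n_individuals),
              n_haplotypes = as.integer(n_haplotypes),
              sweep_daf = sweep_daf, mutation_density = mutation_density,
              recomb_decay = recomb_decay, region_kb = region_kb,
              n_founders = as.integer(n_founders),
              private_mut = private_mut, seed = as.integer(seed))
  stopifnot(cfg$n_pops >= 3L, length(cfg$latitude_range) == 2L,
            cfg$frac_selected >= 0, cfg$frac_selected <= 1,
            cfg$drift_scale > 0, cfg$n_haplotypes %% 2L == 0L,
            cfg$mutation_density >= 0, cfg$recomb_decay > 0,
            cfg$n_founders >= 1L, cfg$private_mut >= 0)
  if (cfg$sweep_daf <= 0 || cfg$sweep_daf >= 1)
    stopf("sweep_daf must be in (0, 1)")
  if (diff(cfg$latitude_range) == 0)
    stopf("degenerate latitude range: all populations at one latitude")
  class(cfg) <- "sim_config"
  cfg
}

#' Populations evenly spaced along a latitude gradient
#'
#' @param config a [sim_config()].
#' @return list with `populations` (a [population_table()]) and `env`
#'   (the matching [environment_table()], including delta-photoperiod).
#' @export
make_populations <- function(config) {
  lat <- seq(config$latitude_range[1], config$latitude_range[2],
             length.out = config$n_pops)
  pops <- population_table(sprintf("pop%02d", seq_len(config$n_pops)),
                           latitude = lat,
                           n_individuals = config$n_individuals)
  list(populations = pops, env = environment_table(pops))
}

#' Balding-Nichols allele frequencies with optional photoperiod clines
#'
#' Each SNP draws an ancestral frequency from Uniform(0.05, 0.95); each
#' population k then draws its frequency from a Beta distribution centered
#' on the (possibly cline-shifted) ancestral value with drift parameter
#' F_k = `drift_scale` x |latitude_k - origin|. Selected SNPs (fraction
#' `frac_selected`) shift the Beta mean on the logit scale by
#' `cline_strength` x delta-photoperiod_k, with a random sign per SNP
#' (allele labels are arbitrary; the scan uses |tau|). The origin
#' population (F = 0) reproduces the (shifted) mean exactly.
#'
#' @param config a [sim_config()].
#' @param populations,env as returned by [make_populations()].
#' @param seed integer seed (default `config$seed`).
#' @return list: `table` (a `freq_table`, allele_a ancestral) and `truth`
#'   (data.frame `snp_id`, `selected`, `direction`, `ancestral_freq`).
#' @export
simulate_frequencies <- function(config, populations, env,
                                 seed = config$seed) {
  n_pop <- nrow(populations); n_snp <- config$n_snps
  f_k <- config$drift_scale *
    abs(populations$latitude - config$origin_latitude)
  if (any(f_k >= 1)) stopf("drift too large: F = %.3f >= 1", max(f_k))
  dp <- env$delta_photoperiod[match(populations$id, env$population_id)]
  with_seed(seed, {
    p0 <- stats::runif(n_snp, 0.05, 0.95)
    n_sel <- round(config$frac_selected * n_snp)
    sel <- rep(FALSE, n_snp)
    sel[sample.int(n_snp, n_sel)] <- TRUE
    dir <- ifelse(sel, sample(c(-1, 1), n_snp, replace = TRUE), 0)
    fr <- matrix(NA_real_, n_snp, n_pop,
                 dimnames = list(NULL, populations$id))
    for (k in seq_len(n_pop)) {
      mu <- stats::plogis(stats::qlogis(p0) +
                            dir * config$cline_strength * dp[k])
      if (f_k[k] < 1e-9) {
        fr[, k] <- mu
      } else {
        shape <- (1 - f_k[k]) / f_k[k]
        fr[, k] <- stats::rbeta(n_snp, mu * shape, (1 - mu) * shape)
      }
    }
    snps <- data.frame(id = sprintf("snp%05d", seq_len(n_snp)),
                       chrom = "1", pos = seq_len(n_snp) * 1000L,
                       allele_a = "A", allele_b = "G", ancestral = "A",
                       stringsAsFactors = FALSE)
    list(table = frequency_table(snps, fr),
         truth = data.frame(snp_id = snps$id, selected = sel,
                            direction = dir, ancestral_freq = p0,
                            stringsAsFactors = FALSE))
  })
}

#' Hardy-Weinberg genotype counts from a frequency table
#'
#' Draws, for each SNP and population, `n_individuals` diploid genotypes
#' with allele_b dosage Binomial(2, freq), and tabulates hom-ref / het /
#' hom-alt counts — the substrate of the F_ST module.
#'
#' @param table a `freq_table` (no missing cells).
#' @param populations a [population_table()] (supplies `n_individuals`).
#' @param seed integer seed.
#' @return integer array `n_snps x n_pops x 3` with dimnames
#'   (snp ids, population ids, c("hom_ref", "het", "hom_alt")).
#' @export
simulate_genotypes <- function(table, populations, seed = 1L) {
  fr <- table$freq
  stopifnot(!anyNA(fr))
  n_snp <- nrow(fr)
  geno <- array(0L, c(n_snp, ncol(fr), 3L),
                dimnames = list(rownames(fr), colnames(fr),
                                c("hom_ref", "het", "hom_alt")))
  with_seed(seed, {
    for (k in seq_len(ncol(fr))) {
      n <- populations$n_individuals[match(colnames(fr)[k],
                                           populations$id)]
      dos <- matrix(stats::rbinom(n_snp * n, 2L, rep(fr[, k], n)),
                    n_snp, n)
      geno[, k, 1] <- rowSums(dos == 0L)
      geno[, k, 2] <- rowSums(dos == 1L)
      geno[, k, 3] <- rowSums(dos == 2L)
    }
    geno
  })
}

# founder haplotypes: each site's derived allele is carried by a random
# non-empty, non-full subset of founders (so sites segregate), except with
# a single founder, where every site is ancestral
make_founders <- function(n_founders, n_sites) {
  if (n_founders == 1L) return(matrix(0L, 1L, n_sites))
  f <- matrix(0L, n_founders, n_sites)
  for (s in seq_len(n_sites)) {
    k <- sample.int(n_founders - 1L, 1L)
    f[sample.int(n_founders, k), s] <- 1L
  }
  f
}

# mosaic of founder segments with exponential(decay_bp) segment lengths
# plus per-site private mutations
mosaic_haplotypes <- function(n_hap, founders, positions, decay_bp,
                              private_mut) {
  n_site <- ncol(founders); k_f <- nrow(founders)
  switch_p <- c(1, 1 - exp(-diff(positions) / decay_bp))
  h <- matrix(0L, n_hap, n_site)
  for (i in seq_len(n_hap)) {
    seg <- cumsum(stats::runif(n_site) < switch_p)
    seg[seg == 0L] <- 1L
    f <- sample.int(k_f, max(seg), replace = TRUE)
    h[i, ] <- founders[cbind(f[seg], seq_len(n_site))]
  }
  if (private_mut > 0) {
    flip <- matrix(stats::runif(n_hap * n_site) < private_mut, n_hap,
                   n_site)
    h[flip] <- 1L - h[flip]
  }
  h
}

# overwrite sweep carriers with a decaying copy of one core haplotype
plant_sweep <- function(h, positions, focal, carriers, core, decay_bp) {
  d <- abs(positions - positions[focal])
  p_copy <- exp(-d / decay_bp)
  for (i in carriers) {
    take <- stats::runif(length(positions)) < p_copy
    h[i, take] <- core[take]
  }
  h[, focal] <- 0L
  h[carriers, focal] <- 1L
  h
}

#' Simulate a haplotype panel, optionally with a planted sweep
#'
#' Neutral background: haplotypes are mosaics of `n_founders` founder
#' sequences with exponentially distributed segment lengths (scale
#' `recomb_decay` kb) and per-site private mutations. With `sweep = TRUE`,
#' a derived allele at frequency `sweep_daf` is planted at the site nearest
#' the region midpoint; its carriers copy a single core haplotype with
#' fidelity decaying as exp(-distance / recomb_decay), producing the long
#' low-diversity derived background that DIND and lnRsb detect.
#'
#' @param config a [sim_config()].
#' @param sweep plant a sweep at the central site?
#' @param seed integer seed (default `config$seed`).
#' @param population_id label for the panel.
#' @return a `haplotype_panel`; when `sweep = TRUE`, the focal site id is
#'   attached as attribute `"focal"`.
#' @export
simulate_haplotypes <- function(config, sweep = FALSE, seed = config$seed,
                                population_id = "simpop") {
  region_bp <- round(config$region_kb * 1000)
  n_site <- round(config$mutation_density * config$region_kb)
  if (n_site < 2L) stopf("mutation_density x region_kb gives < 2 sites")
  decay_bp <- config$recomb_decay * 1000
  with_seed(seed, {
    positions <- sort(sample.int(region_bp, n_site))
    founders <- make_founders(config$n_founders, n_site)
    h <- mosaic_haplotypes(config$n_haplotypes, founders, positions,
                           decay_bp, config$private_mut)
    focal <- NULL
    if (sweep) {
      focal <- which.min(abs(positions - region_bp / 2))
      n_der <- round(config$sweep_daf * config$n_haplotypes)
      carriers <- sample.int(config$n_haplotypes, n_der)
      h <- plant_sweep(h, positions, focal, carriers, h[carriers[1], ],
                       decay_bp)
    }
    panel <- haplotype_panel(h, positions, chrom = "1",
                             population_id = population_id)
    if (sweep) attr(panel, "focal") <- panel$snp_ids[focal]
    panel
  })
}

#' Simulate a two-population haplotype pair sharing ancestral variation
#'
#' Both populations draw mosaic haplotypes from the same founder pool and
#' site map; a sweep is planted in population 1 (`sweep_pop = 1`), in
#' population 2 (`= 2`) or in neither (`= 0`). The focal site segregates
#' in both populations (half the founders carry the derived allele), so
#' the cross-population lnRsb contrast at the focal SNP is well defined.
#'
#' @param config a [sim_config()].
#' @param sweep_pop 0 (neutral pair), 1 or 2.
#' @param seed integer seed (default `config$seed`).
#' @return list `pop1`, `pop2` (panels), `focal` (site id).
#' @export
simulate_haplotype_pair <- function(config, sweep_pop = 1L,
                                    seed = config$seed) {
  stopifnot(sweep_pop %in% 0:2)
  region_bp <- round(config$region_kb * 1000)
  n_site <- round(config$mutation_density * config$region_kb)
  if (n_site < 2L) stopf("mutation_density x region_kb gives < 2 sites")
  decay_bp <- config$recomb_decay * 1000
  with_seed(seed, {
    positions <- sort(sample.int(region_bp, n_site))
    founders <- make_founders(config$n_founders, n_site)
    focal <- which.min(abs(positions - region_bp / 2))
    if (config$n_founders > 1L) {
      founders[, focal] <- 0L
      founders[seq_len(ceiling(config$n_founders / 2)), focal] <- 1L
    }
    panels <- lapply(1:2, function(p) {
      h <- mosaic_haplotypes(config$n_haplotypes, founders, positions,
                             decay_bp, config$private_mut)
      if (p == sweep_pop) {
        n_der <- round(config$sweep_daf * config$n_haplotypes)
        carriers <- sample.int(config$n_haplotypes, n_der)
        h <- plant_sweep(h, positions, focal, carriers, h[carriers[1], ],
                         decay_bp)
      }
      haplotype_panel(h, positions, chrom = "1",
                      population_id = sprintf("simpop%d", p))
    })
    list(pop1 = panels[[1]], pop2 = panels[[2]],
         focal = panels[[1]]$snp_ids[focal])
  })
}
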