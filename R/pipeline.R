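# End-to-end orchestration on synthetic data: simulate a latitude-
# stratified panel, run the environmental correlation scan against the
# truth labels, a gene-set enrichment resample, an extreme-contrast F_ST
# comparison, and the two haplotype tests on planted sweeps. Every stage
# derives its RNG stream from the single pipeline seed, so a rerun with the
# same configuration reproduces every output bit for bit.

PIPELINE_STAGES <- c("simulate", "scan", "enrich", "fst", "dind", "rsb")

#' Run the synthetic end-to-end pipeline
#'
#' Stages run in dependency order; requesting a stage without its
#' prerequisite is an error naming the missing stage. With `out_dir` set,
#' per-stage TSVs and a JSON run report are written; the report carries the
#' configuration, seeds, gate values and all stage counts, and fully
#' determines a bit-identical rerun.
#'
#' @param config a [sim_config()].
#' @param stages subset of `c("simulate", "scan", "enrich", "fst", "dind",
#'   "rsb")`.
#' @param out_dir optional output directory (created if needed).
#' @param reps resamples for the enrichment stage (default 1000).
#' @param alpha,rank_gate the dual significance gate (0.05 / 0.95).
#' @param genes_block SNPs per synthetic gene used for the enrichment
#'   universe (default 5).
#' @return the run report (a list), invisibly also written as JSON when
#'   `out_dir` is given.
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = PIPELINE_STAGES, out_dir = NULL,
                         reps = 1000L, alpha = 0.05, rank_gate = 0.95,
                         genes_block = 5L) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  need <- function(stage, product, have) {
    if (!have) stopf("stage '%s' requires the 'simulate' stage (missing %s)",
                     stage, product)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, file) {
    if (!is.null(out_dir))
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  report <- list(config = unclass(config),
                 gates = list(alpha = alpha, rank = rank_gate),
                 stages = stages)
  sim <- NULL

  if ("simulate" %in% stages) {
    mp <- make_populations(config)
    fq <- simulate_frequencies(config, mp$populations, mp$env)
    sim <- list(populations = mp$populations, env = mp$env,
                table = fq$table, truth = fq$truth)
    if (!is.null(out_dir)) {
      write_population_table(mp$populations,
                             file.path(out_dir, "populations.tsv"))
      write_environment_table(mp$env, file.path(out_dir, "environment.tsv"))
      write_frequency_table(fq$table, file.path(out_dir, "frequencies.tsv"))
      emit(fq$truth, "truth.tsv")
    }
    report$simulate <- list(n_pops = nrow(mp$populations),
                            n_snps = nrow(fq$table$freq),
                            n_selected = sum(fq$truth$selected))
  }

  scan <- NULL
  if ("scan" %in% stages) {
    need("scan", "frequency table", !is.null(sim))
    scan <- env_scan(sim$table, sim$env)
    scan <- maf_binned_rank(scan)
    scan <- call_significant(scan, n_tests = nrow(scan), alpha = alpha,
                             rank_gate = rank_gate)
    emit(scan, "scan.tsv")
    sel <- sim$truth$selected
    report$scan <- list(
      n_significant = sum(scan$significant),
      recall = mean(scan$significant[sel]),
      false_positive_rate = mean(scan$significant[!sel]))
  }

  if ("enrich" %in% stages) {
    need("enrich", "scan results", !is.null(scan))
    gene_of <- sprintf("gene%04d",
                       (seq_len(nrow(scan)) - 1L) %/% genes_block + 1L)
    universe <- split(scan$snp_id, gene_of)
    targets <- unique(gene_of[sim$truth$selected])
    obs <- count_significant_genes(
      universe_index(universe[targets], scan), scan$p_value, scan$tau_rank,
      alpha, rank_gate)
    rs <- gene_set_resample(universe, m = length(targets),
                            observed_n = obs, snp_stats = scan,
                            reps = reps, seed = config$seed + 11L,
                            alpha = alpha, rank_gate = rank_gate)
    report$enrich <- list(m = length(targets), observed = rs$observed,
                          reps = rs$reps, empirical_p = rs$empirical_p)
  }

  if ("fst" %in% stages) {
    need("fst", "frequency table", !is.null(sim))
    geno <- simulate_genotypes(sim$table, sim$populations,
                               seed = config$seed + 21L)
    pair <- c(sim$populations$id[1], sim$populations$id[nrow(sim$populations)])
    fst <- pairwise_fst_matrix(geno, average_maf(sim$table),
                               pairs = matrix(pair, 1))
    fst <- maf_binned_fst_rank(fst)
    emit(fst, "fst.tsv")
    sel_ids <- sim$truth$snp_id[sim$truth$selected]
    sel_rows <- fst[fst$snp_id %in% sel_ids, ]
    ext <- count_extreme(sel_rows, hi_gate = rank_gate)
    xt <- excess_test(ext["n_high"], sum(!is.na(sel_rows$fst_rank)),
                      null_rate = 1 - rank_gate)
    report$fst <- list(pair = pair,
                       n_high_selected = unname(ext["n_high"]),
                       n_selected_ranked = sum(!is.na(sel_rows$fst_rank)),
                       excess_p_fisher = xt$p_fisher)
  }

  if ("dind" %in% stages) {
    swept <- simulate_haplotypes(config, sweep = TRUE,
                                 seed = config$seed + 31L)
    neutral <- simulate_haplotypes(config, sweep = FALSE,
                                   seed = config$seed + 32L)
    bg <- dind_scan(neutral)
    res <- dind_significance(dind_scan(swept), bg,
                             n_daf_classes = 20L, gate = rank_gate)
    emit(res, "dind.tsv")
    focal <- attr(swept, "focal")
    frow <- res[res$snp_id == focal, ]
    report$dind <- list(focal = focal, focal_dind = frow$dind,
                        focal_daf = frow$daf,
                        focal_significant = isTRUE(frow$significant),
                        daf_floor = attr(res, "daf_floor"))
  }

  if ("rsb" %in% stages) {
    pair <- simulate_haplotype_pair(config, sweep_pop = 1L,
                                    seed = config$seed + 41L)
    rsb <- lnrsb(pair$pop1, pair$pop2, pair$focal,
                 region_halfwidth = config$region_kb * 500)
    emit(rsb, "lnrsb.tsv")
    frow <- rsb[rsb$focal, ]
    report$rsb <- list(focal = pair$focal,
                       focal_lnrsb = frow$lnrsb,
                       focal_rank = frow$lnrsb_rank,
                       focal_significant = isTRUE(frow$significant),
                       n_region_snps = nrow(rsb))
  }

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `config` (passed to [sim_config()]) and optional
#' `stages`, `reps`, `alpha`, `rank_gate`.
#'
#' @param path YAML file.
#' @return list of arguments for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  args <- list(config = do.call(sim_config, as.list(y$config)))
  for (k in c("stages", "reps", "alpha", "rank_gate"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  args
}
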