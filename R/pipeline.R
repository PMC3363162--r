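## End-to-end pipeline driver: simulate -> qc -> fit -> summarize ->
## call-qtl -> predict -> validate, with every interface file written to a
## run directory and a manifest sufficient to reproduce the run.

#' Pipeline run configuration
#'
#' Defaults are the reference analysis settings: pi0 = 0.98, variance ratio
#' 1:100, 52,000 cycles with 2,000 burn-in, MAF threshold 0.01, Bayes
#' factor thresholds 10 / 3.2, r^2 grouping threshold 0.7, target
#' heritability 0.30.  The `"desk"` scale preset reduces the design (20
#' sires x 5 dams x 6 offspring, 1,000 SNPs, 10,000 cycles) for interactive
#' use.
#'
#' @param scale `"desk"` or `"full"`.
#' @param seed master seed.
#' @param h2 simulated heritability.
#' @param maf_threshold QC MAF threshold.
#' @param n_cycles,burn_in MCMC run length (NULL = preset default).
#' @param r2_threshold,max_gap QTL grouping parameters.
#' @param qtl `TRUE` for the default QTL architecture, `FALSE` for a pure
#'   polygenic trait.
#' @param dominance fit dominance columns as well.
#' @return List of class `run_config`.
#' @export
run_config <- function(scale = c("desk", "full"), seed = 1L, h2 = 0.30,
                       maf_threshold = 0.01, n_cycles = NULL, burn_in = 2000L,
                       r2_threshold = 0.7, max_gap = 0.1, qtl = TRUE,
                       dominance = FALSE) {
  scale <- match.arg(scale)
  if (is.null(n_cycles)) n_cycles <- if (scale == "desk") 10000L else 52000L
  if (burn_in >= n_cycles)
    stop("burn_in (", burn_in, ") must be smaller than n_cycles (", n_cycles, ")")
  structure(list(scale = scale, seed = as.integer(seed), h2 = h2,
                 maf_threshold = maf_threshold,
                 n_cycles = as.integer(n_cycles), burn_in = as.integer(burn_in),
                 r2_threshold = r2_threshold, max_gap = max_gap,
                 qtl = isTRUE(qtl), dominance = isTRUE(dominance)),
            class = "run_config")
}

#' Run the whole pipeline into a directory
#'
#' Executes: population simulation, SNP QC, model fit, posterior
#' summarization, QTL calling, GEBV prediction and validation against the
#' simulated truth.  Writes genotype/pedigree/phenotype/truth TSVs, the QC
#' report, per-SNP and per-parameter summaries, QTL calls, GEBVs, the
#' validation report and a JSON manifest.  Rerunning with the same config
#' reproduces every output.
#'
#' @param config [run_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with all in-memory results (`sim`, `qc`,
#'   `chain`, `snp_table`, `param_table`, `qtl`, `gebv`, `validation`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(name) file.path(out_dir, name)

  sim <- simulate_population(
    preset = config$scale, h2 = config$h2,
    config = if (config$qtl) qtl_config() else NULL,
    seed = config$seed)
  write_genotypes_tsv(sim$geno, w("genotypes.tsv"))
  write_pedigree_tsv(sim$ped, w("pedigree.tsv"))
  write_phenotypes_tsv(sim$truth, w("phenotypes.tsv"))
  write_truth_tsv(sim$truth, w("truth.tsv"))
  write_architecture_json(sim$arch, w("architecture.json"))

  qc <- filter_snps(sim$geno, config$maf_threshold)
  qc_df <- data.frame(snp = sim$geno$map$snp, maf = qc$report$maf,
                      retained = qc$report$keep)
  write.table(qc_df, w("qc_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  chain <- fit_bvs(qc$geno, sim$truth, sim$ped,
                   config = bvs_config(n_cycles = config$n_cycles,
                                       burn_in = config$burn_in,
                                       seed = derive_seed(config$seed, 10L)),
                   dominance = config$dominance)

  snp_table <- summarize_snps(chain)
  write.table(snp_table, w("snp_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  param_table <- summarize_parameters(chain)
  write.table(param_table, w("parameter_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  qtl <- group_snps_to_qtl(snp_table, qc$geno,
                           r2_threshold = config$r2_threshold,
                           max_gap = config$max_gap)
  write.table(qtl, w("qtl_calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  gebv <- predict_gebv(chain, qc$geno)
  gebv$phenotyped <- sim$truth$phenotyped[match(gebv$id, sim$truth$id)]
  write.table(gebv, w("gebv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  unphen <- sim$truth$id[!sim$truth$phenotyped & sim$ped$sire != 0]
  val <- validate_gebv(gebv, sim$truth, subset = unphen)
  write.table(data.frame(metric = c("correlation", "slope", "n"),
                         value = c(val$correlation, val$slope, val$n)),
              w("validation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(
    package = "qtlbvs",
    version = as.character(utils::packageVersion("qtlbvs")),
    config = unclass(config),
    qc = list(n_monomorphic = qc$report$n_monomorphic,
              n_low_maf = qc$report$n_low_maf,
              n_retained = qc$report$n_retained),
    mh_acceptance = chain$mh_acceptance,
    h2_posterior_mean = estimate_heritability(chain)$mean,
    gebv_correlation = val$correlation)
  jsonlite::write_json(manifest, w("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(sim = sim, qc = qc, chain = chain, snp_table = snp_table,
                 param_table = param_table, qtl = qtl, gebv = gebv,
                 validation = val, manifest = manifest))
}
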