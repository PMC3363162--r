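## Bayesian Variable Selection MCMC: R-side configuration and driver around
## the compiled chain.

#' Prior settings for the mixture model
#'
#' Defaults follow the reference analysis: the mixture starts at
#' pi0 = 0.98 / pi1 = 0.02 with component variances 0.001 and 0.1 (in units
#' of the phenotypic variance); the two variances keep a constant 1:100
#' ratio while their common scale is estimated; the mixture proportion has a
#' slightly informative Beta(100, 1) prior on pi0 (equivalently Beta(1, 100)
#' on pi1, prior mean pi1 = 1/101); variances of all model effects carry
#' bounded-uniform priors.
#'
#' @param pi1_init initial proportion of large-effect SNPs.
#' @param sg0_init initial "null" component variance, in units of var(y).
#' @param ratio fixed variance ratio sigma_g1^2 / sigma_g0^2.
#' @param beta_pi0 Beta prior shape pair on pi0.
#' @param var_bound_mult upper bound of the uniform variance priors as a
#'   multiple of var(y).
#' @param mh_step_init initial Metropolis-Hastings log-scale step width.
#' @return List of class `bvs_priors`.
#' @export
bvs_priors <- function(pi1_init = 0.02, sg0_init = 0.001, ratio = 100,
                       beta_pi0 = c(100, 1), var_bound_mult = 10,
                       mh_step_init = 0.3) {
  stopifnot(ratio > 1, sg0_init > 0, length(beta_pi0) == 2)
  stop_if_not_scalar_prob(pi1_init, "pi1_init", open_left = TRUE, open_right = TRUE)
  structure(list(pi1_init = pi1_init, sg0_init = sg0_init, ratio = ratio,
                 beta_pi0 = beta_pi0, var_bound_mult = var_bound_mult,
                 mh_step_init = mh_step_init),
            class = "bvs_priors")
}

#' MCMC run configuration
#'
#' The reference run is one chain of 52,000 cycles with a 2,000-cycle
#' burn-in.  Running posterior means (inclusion probabilities, effects,
#' genetic values) use every post-burn-in cycle; the scalar trace is stored
#' thinned.
#'
#' @param n_cycles total MCMC cycles.
#' @param burn_in burn-in cycles (must be < n_cycles).
#' @param thin storage interval for the scalar trace.
#' @param pair_updates update SNP effects/indicators in random disjoint
#'   pairs with the indicator pair marginalized analytically (default);
#'   FALSE falls back to single-site updates.
#' @param prior_only run with the likelihood switched off (samples the
#'   prior; used for sampler validation).
#' @param tune_interval cycles per MH step-size adaptation window during
#'   burn-in (target acceptance 0.5; the step is frozen after burn-in).
#' @param recompute_interval cycles between full residual recomputations
#'   (round-off drift guard).
#' @param seed integer seed.
#' @return List of class `bvs_config`.
#' @export
bvs_config <- function(n_cycles = 52000L, burn_in = 2000L, thin = 10L,
                       pair_updates = TRUE, prior_only = FALSE,
                       tune_interval = 100L, recompute_interval = 1000L,
                       seed = NULL) {
  if (burn_in >= n_cycles) stop("burn_in must be smaller than n_cycles")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_cycles = as.integer(n_cycles), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), pair_updates = isTRUE(pair_updates),
                 prior_only = isTRUE(prior_only),
                 tune_interval = as.integer(tune_interval),
                 recompute_interval = as.integer(recompute_interval),
                 seed = seed),
            class = "bvs_config")
}

#' Run the Bayesian Variable Selection chain
#'
#' Fits `y = mu + Z a + sum_k x_k alpha_k + e` with `a ~ N(0, A sigma_a^2)`
#' and a two-component normal mixture prior on each `alpha_k` selected by a
#' binary mixture indicator.  One cycle updates, in order: the mean
#' (Gibbs), every polygenic effect (single-site Gibbs using the sparse
#' A-inverse), every SNP in random disjoint pairs with the four indicator
#' configurations marginalized analytically, the mixture proportion
#' (conjugate Beta), the polygenic and residual variances (truncated
#' scaled-inverse-chi-square conditionals under bounded-uniform priors),
#' and a Metropolis-Hastings move that rescales both mixture variances and
#' all SNP effects jointly while keeping their ratio fixed.
#'
#' @param y numeric phenotype vector (one record per phenotyped
#'   individual).
#' @param X centered design matrix, rows aligned with `y`.
#' @param Ainv sparse A-inverse over all pedigree individuals
#'   ([build_A_inverse()]).
#' @param obs_ind integer vector: pedigree position (1-based) of each
#'   record.
#' @param priors [bvs_priors()].
#' @param config [bvs_config()].
#' @return Object of class `bvs_chain`: `samples` (thinned scalar trace as
#'   a data.frame), `p_hat`, `alpha_mean`, `a_mean`, `mh_acceptance`,
#'   `mh_step_final`, `max_residual_drift`, plus the inputs' metadata.
#' @export
run_chain <- function(y, X, Ainv, obs_ind, priors = bvs_priors(),
                      config = bvs_config()) {
  stopifnot(length(y) == nrow(X), length(obs_ind) == length(y))
  n_ind <- nrow(Ainv)
  if (any(obs_ind < 1 | obs_ind > n_ind)) stop("obs_ind out of pedigree range")
  if (!is.null(config$seed)) set.seed(config$seed)
  vy <- if (length(y) > 1) var(y) else 1
  if (!is.finite(vy) || vy <= 0) vy <- 1
  plist <- list(
    ratio = priors$ratio,
    beta_a = priors$beta_pi0[2], beta_b = priors$beta_pi0[1],
    sa_bounds_lo = 1e-8 * vy, sa_bounds_hi = priors$var_bound_mult * vy,
    se_bounds_lo = 1e-8 * vy, se_bounds_hi = priors$var_bound_mult * vy,
    g0_bounds_lo = 1e-10 * vy,
    g0_bounds_hi = priors$var_bound_mult * vy / priors$ratio,
    mu_init = if (length(y)) mean(y) else 0,
    sa_init = 0.3 * vy, se_init = 0.5 * vy,
    sg0_init = priors$sg0_init * vy,
    pi1_init = priors$pi1_init,
    mh_step_init = priors$mh_step_init)
  A <- methods::as(methods::as(Ainv, "CsparseMatrix"), "generalMatrix")
  res <- .bvs_chain_cpp(as.numeric(y), as.integer(obs_ind) - 1L,
                        X, A@p, A@i, A@x, n_ind,
                        plist, unclass(config))
  samples <- as.data.frame(res$samples)
  names(res$p_hat) <- colnames(X)
  names(res$alpha_mean) <- colnames(X)
  names(res$a_mean) <- rownames(Ainv)
  structure(list(samples = samples, p_hat = res$p_hat,
                 alpha_mean = res$alpha_mean, a_mean = res$a_mean,
                 mh_acceptance = res$mh_acceptance,
                 mh_step_final = res$mh_step_final,
                 max_residual_drift = res$max_residual_drift,
                 n_kept = res$n_kept,
                 priors = priors, config = config,
                 centers = attr(X, "centers"),
                 snp_ids = colnames(X), ind_ids = rownames(Ainv),
                 pi1_prior_mean = priors$beta_pi0[2] /
                   sum(priors$beta_pi0)),
            class = "bvs_chain")
}

#' @exportS3Method base::print
print.bvs_chain <- function(x, ...) {
  cat("Bayesian Variable Selection chain\n")
  cat(sprintf("  cycles: %d (burn-in %d, %d stored)\n",
              x$config$n_cycles, x$config$burn_in, nrow(x$samples)))
  cat(sprintf("  SNPs: %d, individuals: %d\n",
              length(x$p_hat), length(x$a_mean)))
  cat(sprintf("  MH acceptance (post burn-in): %.3f, final step %.3f\n",
              x$mh_acceptance, x$mh_step_final))
  cat(sprintf("  posterior mean sigma_a2 %.4g, sigma_e2 %.4g, pi1 %.4g\n",
              mean(x$samples$sigma_a2), mean(x$samples$sigma_e2),
              mean(x$samples$pi1)))
  invisible(x)
}

#' Fit the model to a simulated or imported dataset
#'
#' Convenience driver: aligns phenotypes with the pedigree, builds the
#' sparse A-inverse, centers the SNP design, and runs the chain.
#'
#' @param geno `geno_matrix` covering every pedigree individual (rownames =
#'   ids), normally after [filter_snps()].
#' @param pheno data.frame with columns `id` and `phenotype` (NA =
#'   unphenotyped).
#' @param ped pedigree data.frame (`id`, `sire`, `dam`).
#' @param priors,config see [run_chain()].
#' @param dominance also fit dominance (heterozygote) columns.
#' @return A `bvs_chain`.
#' @export
fit_bvs <- function(geno, pheno, ped, priors = bvs_priors(),
                    config = bvs_config(), dominance = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"))
  ids <- as.character(ped$id)
  M <- geno$geno
  if (is.null(rownames(M))) rownames(M) <- ids
  if (!all(ids %in% rownames(M)))
    stop("genotypes missing for some pedigree individuals")
  M <- M[ids, , drop = FALSE]
  g2 <- geno; g2$geno <- M
  X_all <- code_design(g2, if (dominance) "additive+dominance" else "additive",
                       center = TRUE)
  phen <- pheno[!is.na(pheno$phenotype), , drop = FALSE]
  obs_ind <- match(as.character(phen$id), ids)
  if (anyNA(obs_ind)) stop("phenotyped individual absent from pedigree")
  Ainv <- build_A_inverse(ped)
  chain <- run_chain(phen$phenotype, X_all[obs_ind, , drop = FALSE],
                     Ainv, obs_ind, priors = priors, config = config)
  chain$map <- geno$map
  chain$X_centers <- attr(X_all, "centers")
  chain$ids <- ids
  chain
}
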