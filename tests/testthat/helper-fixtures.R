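# Shared fixtures built in code.

# A small geno_matrix with independent SNPs (no map structure games).
toy_geno <- function(n = 100, m = 20, maf = 0.5, seed = 1) {
  set.seed(seed)
  M <- matrix(rbinom(n * m, 2, maf), n, m)
  rownames(M) <- as.character(seq_len(n))
  colnames(M) <- paste0("s", seq_len(m))
  structure(list(geno = M, pat = NULL, mat = NULL,
                 map = data.frame(snp = colnames(M), chr = 1L,
                                  pos = seq_len(m) / m,
                                  stringsAsFactors = FALSE)),
            class = "geno_matrix")
}

# Founders-only pedigree (A = I).
founder_ped <- function(n) data.frame(id = seq_len(n), sire = 0L, dam = 0L)

# Random valid pedigree of n individuals: each non-founder picks two
# distinct earlier individuals as parents.
random_pedigree <- function(n, p_founder = 0.3) {
  sire <- integer(n); dam <- integer(n)
  for (i in seq_len(n)) {
    if (i <= 2 || runif(1) < p_founder) next
    par <- sample(i - 1L, 2L)
    sire[i] <- par[1]; dam[i] <- par[2]
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam)
}

# Run the compiled chain with explicit prior bounds (used to pin variances
# in conjugate-oracle tests).
raw_chain <- function(y, X, ped, obs_ind, plist_override = list(),
                      n_cycles = 5000, burn_in = 1000, seed = 1,
                      pair_updates = TRUE, prior_only = FALSE, thin = 1) {
  Ainv <- build_A_inverse(ped)
  Ag <- methods::as(methods::as(Ainv, "CsparseMatrix"), "generalMatrix")
  vy <- if (length(y) > 1) stats::var(y) else 1
  plist <- list(ratio = 100, beta_a = 1, beta_b = 100,
                sa_bounds_lo = 1e-8 * vy, sa_bounds_hi = 10 * vy,
                se_bounds_lo = 1e-8 * vy, se_bounds_hi = 10 * vy,
                g0_bounds_lo = 1e-10 * vy, g0_bounds_hi = 0.1 * vy,
                mu_init = if (length(y)) mean(y) else 0,
                sa_init = 0.3 * vy, se_init = 0.5 * vy,
                sg0_init = 0.001 * vy, pi1_init = 0.02, mh_step_init = 0.3)
  plist[names(plist_override)] <- plist_override
  cfg <- bvs_config(n_cycles = n_cycles, burn_in = burn_in, thin = thin,
                    pair_updates = pair_updates, prior_only = prior_only)
  set.seed(seed)
  res <- qtlbvs:::.bvs_chain_cpp(as.numeric(y), as.integer(obs_ind) - 1L, X,
                                 Ag@p, Ag@i, Ag@x, nrow(ped), plist,
                                 unclass(cfg))
  res$samples <- as.data.frame(res$samples)
  res
}

# Monte-Carlo standard error via ESS.
mc_se <- function(x) stats::sd(x) / sqrt(max(effective_sample_size(x), 2))
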