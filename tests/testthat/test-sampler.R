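test_that("configuration and prior constructors validate their inputs", {
  expect_error(bvs_config(n_cycles = 100, burn_in = 100), "burn_in")
  expect_error(bvs_priors(ratio = 0.5), "ratio")
  expect_error(bvs_priors(pi1_init = 1.2), "unit interval")
  cfg <- bvs_config(n_cycles = 500, burn_in = 100, thin = 10)
  expect_equal(cfg$thin, 10L)
})

test_that("mean-only chain matches the conjugate closed form", {
  # y = (2,2,2,2) on unrelated founders with the polygenic term pinned off:
  # mu full conditional ~ N(mean(y), sigma_e^2 / n)
  y <- c(2, 2, 2, 2)
  X <- matrix(numeric(0), nrow = 4, ncol = 0)
  res <- raw_chain(y, X, founder_ped(4), 1:4,
                   plist_override = list(sa_bounds_lo = 1e-10,
                                         sa_bounds_hi = 2e-10, sa_init = 1.5e-10,
                                         se_bounds_lo = 0.9999, se_bounds_hi = 1.0001,
                                         se_init = 1),
                   n_cycles = 12000, burn_in = 2000, seed = 21)
  mu <- res$samples$mu
  expect_lt(abs(mean(mu) - 2), 3 * mc_se(mu) + 0.02)
  expect_lt(abs(sd(mu) - 0.5), 0.1)

  # flat data: mu samples centered at 0
  res0 <- raw_chain(rep(0, 4), X, founder_ped(4), 1:4,
                    plist_override = list(sa_bounds_lo = 1e-10,
                                          sa_bounds_hi = 2e-10, sa_init = 1.5e-10,
                                          se_bounds_lo = 0.9999, se_bounds_hi = 1.0001,
                                          se_init = 1),
                    n_cycles = 6000, burn_in = 1000, seed = 22)
  expect_lt(abs(mean(res0$samples$mu)), 0.1)
})

test_that("polygenic effects reproduce mixed-model (BLUP) shrinkage", {
  # founders with one record each and pinned variances: posterior mean of
  # a_i is the shrinkage sa/(sa+se) * (y_i - mu)
  set.seed(23)
  n <- 30
  y <- rnorm(n, 5, sqrt(2))
  X <- matrix(numeric(0), nrow = n, ncol = 0)
  sa <- 1; se <- 1
  res <- raw_chain(y, X, founder_ped(n), 1:n,
                   plist_override = list(sa_bounds_lo = sa * 0.9999,
                                         sa_bounds_hi = sa * 1.0001, sa_init = sa,
                                         se_bounds_lo = se * 0.9999,
                                         se_bounds_hi = se * 1.0001, se_init = se),
                   n_cycles = 8000, burn_in = 2000, seed = 24)
  shrink <- coef(lm(res$a_mean ~ I(y - mean(y))))[[2]]
  expect_lt(abs(shrink - sa / (sa + se)), 0.05)

  # unphenotyped offspring of two founders: posterior mean = parent average
  ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  y2 <- c(3, -1)  # records for the two founders only
  res2 <- raw_chain(y2, matrix(numeric(0), 2, 0), ped, 1:2,
                    plist_override = list(sa_bounds_lo = 0.9999, sa_bounds_hi = 1.0001,
                                          sa_init = 1, se_bounds_lo = 0.9999,
                                          se_bounds_hi = 1.0001, se_init = 1),
                    n_cycles = 20000, burn_in = 2000, seed = 25)
  expect_lt(abs(res2$a_mean[3] - (res2$a_mean[1] + res2$a_mean[2]) / 2), 0.05)
})

test_that("single-SNP effect matches its conjugate normal posterior", {
  set.seed(26)
  n <- 200
  g <- rbinom(n, 2, 0.5)
  x <- g - mean(g)
  b <- 1.5
  y <- b * x + rnorm(n)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "s1"))
  se <- 1; sg1 <- 1  # pinned; ratio 100 => sg0 = 0.01
  res <- raw_chain(y, X, founder_ped(n), 1:n,
                   plist_override = list(
                     sa_bounds_lo = 1e-10, sa_bounds_hi = 2e-10, sa_init = 1.5e-10,
                     se_bounds_lo = 0.9999, se_bounds_hi = 1.0001, se_init = 1,
                     g0_bounds_lo = 0.00999, g0_bounds_hi = 0.01001,
                     sg0_init = 0.01),
                   n_cycles = 8000, burn_in = 2000, seed = 27)
  # strong signal: indicator saturates, alpha | delta=1 is conjugate normal
  expect_gt(res$p_hat[1], 0.95)
  c_post <- sum(x^2) / se + 1 / sg1
  m_post <- sum(x * y) / se / c_post
  expect_lt(abs(res$alpha_mean[1] - m_post), 0.05)
})

test_that("pair updates and single-site updates agree on a 10-SNP toy", {
  # orthogonalized columns: no LD, so every inclusion probability is either
  # saturated or at the prior level and Monte-Carlo error is small
  set.seed(28)
  n <- 150; m <- 10
  M <- matrix(rbinom(n * m, 2, 0.5), n, m)
  X <- qr.Q(qr(sweep(M, 2, colMeans(M)))) * sqrt(n)
  colnames(X) <- paste0("s", 1:m)
  y <- 2 * X[, 3] - 1.6 * X[, 7] + rnorm(n)
  run <- function(pair) raw_chain(y, X, founder_ped(n), 1:n,
                                  plist_override = list(sa_bounds_lo = 1e-10,
                                                        sa_bounds_hi = 2e-10,
                                                        sa_init = 1.5e-10),
                                  n_cycles = 12000, burn_in = 2000,
                                  seed = 29, pair_updates = pair)
  rp <- run(TRUE); rs <- run(FALSE)
  expect_lt(max(abs(rp$p_hat - rs$p_hat)), 0.08)
  expect_lt(max(abs(rp$alpha_mean - rs$alpha_mean)), 0.08)
})

test_that("a zero-variance SNP column draws its indicator from the mixture proportion", {
  set.seed(30)
  n <- 100
  X <- cbind(s1 = rep(0, n), s2 = rbinom(n, 2, 0.5) - 1)
  y <- rnorm(n)
  res <- raw_chain(y, X, founder_ped(n), 1:n,
                   plist_override = list(sa_bounds_lo = 1e-10,
                                         sa_bounds_hi = 2e-10, sa_init = 1.5e-10),
                   n_cycles = 10000, burn_in = 2000, seed = 31)
  pi1_mean <- mean(res$samples$pi1)
  expect_lt(abs(res$p_hat[1] - pi1_mean), 3 * mc_se(res$samples$pi1) + 0.01)
})

test_that("prior-only runs reproduce the prior distributions (Geweke-style)", {
  n <- 5; m <- 8
  X <- matrix(0, n, m)  # ignored under prior_only
  y <- rnorm(n)
  res <- raw_chain(y, X, founder_ped(n), 1:n,
                   plist_override = list(
                     sa_bounds_lo = 0.5, sa_bounds_hi = 1.5, sa_init = 1,
                     se_bounds_lo = 2, se_bounds_hi = 4, se_init = 3,
                     g0_bounds_lo = 0.01, g0_bounds_hi = 0.11, sg0_init = 0.05),
                   n_cycles = 42000, burn_in = 2000, seed = 32,
                   prior_only = TRUE, thin = 4)
  s <- res$samples
  # pi1 ~ Beta(1, 100): prior mean 1/101
  expect_lt(abs(mean(s$pi1) - 1 / 101), 3 * mc_se(s$pi1))
  # sigma_e2 ~ U(2, 4)
  expect_lt(abs(mean(s$sigma_e2) - 3), 3 * mc_se(s$sigma_e2))
  expect_lt(abs(var(s$sigma_e2) - 4 / 12), 0.05)
  # sigma_g02 ~ U(0.01, 0.11): validates the MH Jacobian of the joint
  # variance/effect rescaling move
  expect_lt(abs(mean(s$sigma_g02) - 0.06), 3 * mc_se(s$sigma_g02) + 0.003)
  # sigma_a2 ~ U(0.5, 1.5) via successive-conditional sampling with a
  expect_lt(abs(mean(s$sigma_a2) - 1.0), 3 * mc_se(s$sigma_a2) + 0.01)
  # ratio constraint holds exactly throughout
  expect_equal(s$sigma_g12, 100 * s$sigma_g02)
})

test_that("identity MH proposal is always accepted", {
  # step ~ 0 means f ~ 1: every proposal accepted (burn_in = 0 so the
  # adaptive tuner never inflates the step)
  set.seed(33)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  res <- raw_chain(y, X, founder_ped(n), 1:n,
                   plist_override = list(mh_step_init = 1e-12),
                   n_cycles = 300, burn_in = 0, seed = 34)
  expect_equal(res$mh_acceptance, 1)
})

test_that("step-size tuning reaches a moderate acceptance rate", {
  set.seed(35)
  n <- 120; m <- 60
  M <- matrix(rbinom(n * m, 2, 0.4), n, m)
  X <- sweep(M, 2, colMeans(M)); colnames(X) <- paste0("s", 1:m)
  y <- X[, 5] + rnorm(n)
  for (step0 in c(0.001, 3)) {
    res <- raw_chain(y, X, founder_ped(n), 1:n,
                     plist_override = list(mh_step_init = step0),
                     n_cycles = 8000, burn_in = 4000, seed = 36)
    expect_gte(res$mh_acceptance, 0.3)
    expect_lte(res$mh_acceptance, 0.7)
  }
})

test_that("variance-component conditionals recover a known residual variance", {
  # effects absent, pure noise with sigma_e2 = 1: posterior mean ~ 1
  set.seed(37)
  n <- 1000
  y <- rnorm(n, 0, 1)
  X <- matrix(numeric(0), n, 0)
  res <- raw_chain(y, X, founder_ped(n), 1:n,
                   plist_override = list(sa_bounds_lo = 1e-10,
                                         sa_bounds_hi = 2e-10, sa_init = 1.5e-10),
                   n_cycles = 4000, burn_in = 1000, seed = 38)
  se <- res$samples$sigma_e2
  # conjugate oracle: with mu integrated out, sigma_e2 | y is scaled
  # inverse-chi-square(df = n - 2, scale S), posterior mean S / (n - 4)
  S <- sum((y - mean(y))^2)
  expect_lt(abs(mean(se) - S / (n - 4)), 3 * mc_se(se) + 0.01)
})

test_that("run_chain bookkeeping: storage count, determinism, residual drift", {
  sim <- simulate_population("desk", seed = 40, n_burn_generations = 40)
  qc <- filter_snps(sim$geno)
  cfg <- bvs_config(n_cycles = 1500, burn_in = 500, thin = 10, seed = 41)
  ch1 <- fit_bvs(qc$geno, sim$truth, sim$ped, config = cfg)
  ch2 <- fit_bvs(qc$geno, sim$truth, sim$ped, config = cfg)
  expect_equal(nrow(ch1$samples), (1500 - 500) / 10)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$p_hat, ch2$p_hat)
  expect_lt(ch1$max_residual_drift, 1e-8)
  expect_s3_class(ch1, "bvs_chain")
  expect_output(print(ch1), "Bayesian Variable Selection")
})

test_that("null simulation keeps inclusion probabilities at the prior mean", {
  sim <- simulate_population("desk", seed = 43, config = NULL,
                             n_burn_generations = 60)
  qc <- filter_snps(sim$geno)
  ch <- fit_bvs(qc$geno, sim$truth, sim$ped,
                config = bvs_config(n_cycles = 4000, burn_in = 1000, seed = 44))
  # mean posterior inclusion across SNPs close to the prior mean 1/101
  expect_lt(abs(mean(ch$p_hat) - 1 / 101), 0.01)
})
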