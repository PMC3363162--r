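## Posterior summaries: Bayes factors, evidence classes, HPD intervals,
## effective sample size, heritability, per-SNP and per-parameter tables.

#' Bayes factor from a posterior inclusion probability
#'
#' Odds ratio between the posterior and prior probabilities of a SNP
#' belonging to the large-effect component:
#' `BF = [p / (1 - p)] / [pi1 / (1 - pi1)]`.  A saturated `p_hat = 1` maps
#' to `Inf` (capped to 1e6 in exported tables).
#'
#' @param p_hat posterior inclusion probability in \[0, 1\].
#' @param pi1_prior prior inclusion probability in (0, 1); default 1/101,
#'   the prior mean under Beta(100, 1) on pi0.
#' @return Bayes factor (dimensionless, vectorized).
#' @export
bayes_factor <- function(p_hat, pi1_prior = 1 / 101) {
  if (any(pi1_prior <= 0 | pi1_prior >= 1)) stop("pi1_prior must lie in (0, 1)")
  if (any(p_hat < 0 | p_hat > 1, na.rm = TRUE)) stop("p_hat must lie in [0, 1]")
  prior_odds <- pi1_prior / (1 - pi1_prior)
  ifelse(p_hat >= 1, Inf, (p_hat / (1 - p_hat)) / prior_odds)
}

#' Evidence class of a Bayes factor
#'
#' `BF > 10` is "significant" (strong evidence), `3.2 <= BF <= 10` is
#' "putative", smaller values are "none".
#'
#' @param bf Bayes factor(s), >= 0.
#' @return Character vector in {"significant", "putative", "none"}.
#' @export
classify_evidence <- function(bf) {
  if (any(bf < 0, na.rm = TRUE)) stop("Bayes factors must be non-negative")
  ifelse(bf > 10, "significant", ifelse(bf >= 3.2, "putative", "none"))
}

#' Highest posterior density interval
#'
#' Shortest interval containing `mass` of the draws (sorted-window method).
#'
#' @param samples numeric vector of posterior draws (>= 100 recommended).
#' @param mass probability mass in (0, 1); default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  stop_if_not_scalar_prob(mass, "mass", open_left = TRUE, open_right = TRUE)
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2) return(c(x[1], x[1]))
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Effective sample size of an MCMC trace
#'
#' `n / (1 + 2 sum rho_t)` with autocorrelations truncated by Geyer's
#' initial positive sequence rule; capped at `n`.
#'
#' @param samples numeric trace.
#' @return ESS (NA for a zero-variance trace).
#' @export
effective_sample_size <- function(samples) {
  x <- samples[is.finite(samples)]
  n <- length(x)
  if (n < 2 || var(x) == 0) return(NA_real_)
  max_lag <- min(n - 1L, 10L * floor(sqrt(n)))
  rho <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1]
  # Geyer initial positive sequence on paired sums
  npair <- floor(length(rho) / 2)
  ssum <- 0
  if (npair >= 1) {
    for (k in seq_len(npair)) {
      g <- rho[2 * k - 1] + rho[2 * k]
      if (g <= 0) break
      ssum <- ssum + g
    }
  }
  ess <- n / (1 + 2 * ssum)
  min(ess, n)
}

#' Posterior heritability samples from a chain
#'
#' Per stored cycle, `h2 = (sigma_a^2 + V_SNP) / (sigma_a^2 + V_SNP +
#' sigma_e^2)`, where `V_SNP` is the empirical variance across phenotyped
#' individuals of the summed SNP effects at that cycle.  `type =
#' "polygenic"` drops `V_SNP` from the numerator only (the model still fits
#' SNPs).
#'
#' @param chain `bvs_chain`.
#' @param type `"total"` (default) or `"polygenic"`.
#' @return List with `samples`, `mean`, `sd`, `hpd95`.
#' @export
estimate_heritability <- function(chain, type = c("total", "polygenic")) {
  type <- match.arg(type)
  s <- chain$samples
  denom <- s$sigma_a2 + s$v_snp + s$sigma_e2
  num <- if (type == "total") s$sigma_a2 + s$v_snp else s$sigma_a2
  h2 <- num / denom
  list(samples = h2, mean = mean(h2), sd = sd(h2), hpd95 = hpd_interval(h2))
}

#' Per-SNP posterior summary table
#'
#' One row per SNP: map location, posterior inclusion probability, mean
#' effect, Bayes factor and evidence class.  This is the table behind a
#' Manhattan plot of the analysis.
#'
#' @param chain `bvs_chain` from [fit_bvs()].
#' @param bf_cap cap substituted for infinite Bayes factors (saturated
#'   p_hat); default 1e6.
#' @return data.frame with columns `snp`, `chr`, `pos`, `p_hat`,
#'   `mean_effect`, `bf`, `bf_capped`, `class`.
#' @export
summarize_snps <- function(chain, bf_cap = 1e6) {
  pi1 <- chain$pi1_prior_mean %||% (1 / 101)
  bf <- bayes_factor(chain$p_hat, pi1)
  capped <- !is.finite(bf)
  bf_out <- ifelse(capped, bf_cap, bf)
  map <- chain$map
  data.frame(
    snp = chain$snp_ids %||% names(chain$p_hat),
    chr = if (!is.null(map)) map$chr else NA_integer_,
    pos = if (!is.null(map)) map$pos else NA_real_,
    p_hat = as.numeric(chain$p_hat),
    mean_effect = as.numeric(chain$alpha_mean),
    bf = bf_out, bf_capped = capped,
    class = classify_evidence(bf_out),
    stringsAsFactors = FALSE)
}

#' Scalar-parameter posterior summary table
#'
#' @param chain `bvs_chain`.
#' @return data.frame: one row per scalar parameter with posterior mean,
#'   sd, 95% HPD bounds and ESS.
#' @export
summarize_parameters <- function(chain) {
  pars <- c("mu", "sigma_a2", "sigma_e2", "sigma_g02", "sigma_g12", "pi1")
  rows <- lapply(pars, function(p) {
    x <- chain$samples[[p]]
    h <- hpd_interval(x)
    data.frame(parameter = p, mean = mean(x), sd = sd(x),
               hpd95_lo = h[1], hpd95_hi = h[2],
               ess = effective_sample_size(x), stringsAsFactors = FALSE)
  })
  h2 <- estimate_heritability(chain)
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = "h2", mean = h2$mean, sd = h2$sd,
    hpd95_lo = h2$hpd95[1], hpd95_hi = h2$hpd95[2],
    ess = effective_sample_size(h2$samples), stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
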