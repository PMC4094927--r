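# shared fixture builders; everything generated in code, nothing stored

# small two-population panel
make_panel <- function(n = c(a = 60, b = 40), K = 50, seed = 42, ...) {
  impute_missing(simulate_genotypes(
    population_spec(populations = n, K = K, seed = seed, ...)))
}

# hand-built architecture, bypassing the sampler, for deterministic checks
make_arch <- function(K, qtl = integer(0), alpha = numeric(0),
                      beta = c(0, 0, 0), sigma_g2 = 1, sigma_e2 = 1,
                      thresholds = c(0.61, 1.41, 2.05),
                      locus_ids = paste0("snp", seq_len(K))) {
  delta <- integer(K)
  delta[qtl] <- 1L
  eff <- numeric(K)
  eff[qtl] <- alpha
  structure(list(qtl_indicator = delta, qtl_effects = eff,
                 sigma_g2 = sigma_g2, pi_sim = 1 - length(qtl) / K,
                 sigma_alpha2 = if (length(qtl)) var(alpha) else 0,
                 beta = beta, sigma_e2 = sigma_e2,
                 thresholds = thresholds, locus_ids = locus_ids),
            class = "trait_architecture")
}

# batch-means Monte Carlo standard error for autocorrelated chains
mcse <- function(x, n_batch = 50) {
  n <- length(x)
  m <- floor(n / n_batch)
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], nrow = m))
  sd(bm) / sqrt(n_batch)
}
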