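small_fit_data <- function(n = 120, K = 60, seed = 51, sigma_g2 = 1,
                           pi_sim = 0.9) {
  G <- make_panel(n = c(a = n), K = K, seed = seed)
  arch <- sample_architecture(G, pi_sim = pi_sim, sigma_g2 = sigma_g2,
                              seed = seed + 1)
  ph <- simulate_phenotypes(G, arch, seed = seed + 2)
  list(G = G, arch = arch, ph = ph)
}

test_that("identical data, prior, settings and seed give identical chains", {
  d <- small_fit_data()
  cfg <- mcmc_config(n_iter = 300, burn_in = 50, seed = 7)
  f1 <- fit_bayescpi(d$ph$y3, d$ph$fixed_level, d$G, "threshold",
                     config = cfg)
  f2 <- fit_bayescpi(d$ph$y3, d$ph$fixed_level, d$G, "threshold",
                     config = cfg)
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$traces, f2$traces)
  expect_identical(f1$threshold_means, f2$threshold_means)
  f3 <- fit_bayescpi(d$ph$y3, d$ph$fixed_level, d$G, "threshold",
                     config = mcmc_config(n_iter = 300, burn_in = 50,
                                          seed = 8))
  expect_false(identical(f1$traces$pi, f3$traces$pi))
})

test_that("the threshold chain keeps its identification constraints", {
  d <- small_fit_data()
  fit <- fit_bayescpi(d$ph$y4, d$ph$fixed_level, d$G, "threshold",
                      config = mcmc_config(n_iter = 400, burn_in = 100,
                                           seed = 3))
  expect_true(all(fit$traces$sigma_e2 == 1))
  expect_equal(fit$tau_trace[, 1], rep(0, 400))      # tau_1 never moves
  expect_true(all(fit$tau_trace[, 2] > 0))
  expect_true(all(fit$tau_trace[, 3] > fit$tau_trace[, 2]))
  expect_true(fit$mh_acceptance > 0 && fit$mh_acceptance < 1)
  # binary path never runs the threshold Metropolis-Hastings update
  fit2 <- fit_bayescpi(d$ph$y2, d$ph$fixed_level, d$G, "threshold",
                       config = mcmc_config(n_iter = 200, burn_in = 50,
                                            seed = 3))
  expect_true(is.na(fit2$mh_acceptance))
})

test_that("pi and the number of fitted markers move in opposite directions", {
  d <- small_fit_data(sigma_g2 = 1.5, pi_sim = 0.8)
  fit <- fit_bayescpi(d$ph$liability, d$ph$fixed_level, d$G, "linear",
                      prior = prior_spec(planning_sigma_g2 = 1.5,
                                         planning_pi = 0.8),
                      config = mcmc_config(n_iter = 1500, burn_in = 300,
                                           seed = 5))
  expect_lt(cor(fit$traces$pi, fit$traces$m), 0)
})

test_that("degenerate responses are rejected with informative errors", {
  d <- small_fit_data(n = 40, K = 10)
  expect_error(
    fit_bayescpi(rep(1, 40), d$ph$fixed_level, d$G, "linear"),
    class = "bcpi_degenerate_response")
  y_gap <- rep(c(1L, 3L), 20)   # category 2 unobserved
  expect_error(
    fit_bayescpi(y_gap, d$ph$fixed_level, d$G, "threshold"),
    class = "bcpi_missing_category")
  Gna <- d$G
  Gna$values[1, 1] <- NA
  expect_error(
    fit_bayescpi(d$ph$liability, d$ph$fixed_level, Gna, "linear"),
    class = "bcpi_missing_genotypes")
})

test_that("joint Gibbs sweeps match grid integration on a tiny instance", {
  # n = 10, K = 1, c = 3 threshold model with sigma_a2 and pi held fixed:
  # the kernel-composed chain targets p(beta, a, delta, tau2 | y), which a
  # 3-D grid plus indicator enumeration computes directly
  set.seed(61)
  n <- 10
  z <- c(0, 1, 2, 1, 0, 2, 1, 1, 2, 0)
  X <- matrix(1, n, 1)
  Z <- matrix(z, n, 1)
  y <- c(1L, 1L, 3L, 2L, 1L, 3L, 2L, 1L, 3L, 1L)
  sigma_a2 <- 0.6
  pi_excl <- 0.5

  loglik_y <- function(beta, a, t2) {
    mu <- beta + z * a
    ext <- c(-Inf, 0, t2, Inf)
    p <- pnorm(ext[y + 1] - mu) - pnorm(ext[y] - mu)
    if (any(p <= 0)) -Inf else sum(log(p))
  }
  ng <- 81
  bg <- seq(-6, 3, length.out = ng)
  ag <- seq(-4, 4, length.out = ng)
  tg <- seq(0.01, 6, length.out = ng)
  # delta = 1 block: weight (1 - pi) N(a; 0, sigma_a2) over the (b, a, t) grid
  w1 <- array(0, c(ng, ng, ng))
  for (ib in seq_len(ng)) for (ia in seq_len(ng)) {
    ll <- vapply(tg, function(t2) loglik_y(bg[ib], ag[ia], t2), numeric(1))
    w1[ib, ia, ] <- exp(ll) * dnorm(ag[ia], 0, sqrt(sigma_a2)) * (1 - pi_excl)
  }
  # delta = 0 block: a = 0 exactly
  w0 <- matrix(0, ng, ng)
  for (ib in seq_len(ng)) {
    w0[ib, ] <- exp(vapply(tg, function(t2) loglik_y(bg[ib], 0, t2),
                           numeric(1))) * pi_excl
  }
  da <- diff(ag)[1]
  tot1 <- sum(w1) * da
  tot0 <- sum(w0)
  p_incl_exact <- tot1 / (tot1 + tot0)
  e_beta_exact <- (sum(apply(w1, 1, sum) * bg) * da + sum(rowSums(w0) * bg)) /
    (tot1 + tot0)
  e_tau_exact <- (sum(apply(w1, 3, sum) * tg) * da + sum(colSums(w0) * tg)) /
    (tot1 + tot0)

  st <- mcmc_state(l = rep(0.5, n), X = X, Z = Z, sigma_a2 = sigma_a2,
                   pi = pi_excl, tau = c(0, 1), ncat = 3,
                   model = "threshold")
  n_it <- 30000
  keep <- matrix(0, n_it, 3)
  set.seed(62)
  for (i in seq_len(n_it)) {
    st <- sample_thresholds(st, y, mh_step = 0.6)
    st <- sample_liabilities(st, y)
    st <- sample_beta(st, X)
    st <- sample_locus(st, Z)
    keep[i, ] <- c(st$beta[1], st$delta[1], st$tau[2])
  }
  expect_lt(abs(mean(keep[, 1]) - e_beta_exact), 3 * mcse(keep[, 1]) + 0.02)
  expect_lt(abs(mean(keep[, 2]) - p_incl_exact), 3 * mcse(keep[, 2]) + 0.02)
  expect_lt(abs(mean(keep[, 3]) - e_tau_exact), 3 * mcse(keep[, 3]) + 0.02)
})

test_that("pi estimates fall as training data grow on a polygenic trait", {
  # directional property: when the trait is effectively polygenic relative
  # to what the training data can resolve, more records support more
  # markers, so the posterior mean of pi drifts down with n
  G <- make_panel(n = c(a = 500), K = 300, seed = 71)
  arch <- sample_architecture(G, pi_sim = 0.5, sigma_g2 = 1.5, seed = 72)
  ph <- simulate_phenotypes(G, arch, seed = 73)
  pr <- prior_spec(planning_sigma_g2 = 1.5, planning_pi = 0.5)
  fit_n <- function(n, s) {
    fit_bayescpi(ph$liability[1:n], ph$fixed_level[1:n], G[1:n, ], "linear",
                 prior = pr,
                 config = mcmc_config(n_iter = 1500, burn_in = 400,
                                      seed = s))$pi_mean
  }
  pi_small <- mean(vapply(74:76, function(s) fit_n(100, s), numeric(1)))
  pi_large <- mean(vapply(74:76, function(s) fit_n(500, s), numeric(1)))
  expect_lt(pi_large, pi_small)
})

test_that("tidy, glance and autoplot views expose the posterior summaries", {
  d <- small_fit_data(n = 60, K = 30)
  fit <- fit_bayescpi(d$ph$liability, d$ph$fixed_level, d$G, "linear",
                      config = mcmc_config(n_iter = 200, burn_in = 50,
                                           seed = 9))
  td <- tidy(fit)
  expect_equal(nrow(td), 30)
  expect_named(td, c("locus_id", "effect_mean", "inclusion_prob"))
  expect_true(all(td$inclusion_prob >= 0 & td$inclusion_prob <= 1))
  gl <- glance(fit)
  expect_equal(gl$n, 60)
  expect_true(gl$pi_mean >= 0 && gl$pi_mean <= 1)
  expect_s3_class(autoplot(fit), "ggplot")
  # posterior mean effect is the inclusion-weighted mean with zeros counted
  expect_true(all(abs(td$effect_mean[td$inclusion_prob == 0]) < 1e-12))
  d2 <- withr::local_tempdir()
  write_fit_summary(fit, d2, traces = TRUE)
  expect_true(file.exists(file.path(d2, "effects.csv")))
  expect_true(file.exists(file.path(d2, "run-metadata.txt")))
  expect_true(file.exists(file.path(d2, "traces.csv")))
})
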