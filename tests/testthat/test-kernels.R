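# Each full-conditional kernel is checked against an independent oracle:
# a closed-form distribution, an exact enumeration, a grid integration or a
# rejection sampler, on small fixed states.

make_state <- function(l, X, Z, ...) {
  mcmc_state(l = l, X = X, Z = Z, ...)
}

test_that("fixed-effect draws follow their closed-form normal conditional", {
  # one record, x = 1, no marker signal: beta | l = 2 ~ N(2, 1)
  X <- matrix(1, 1, 1)
  Z <- matrix(0, 1, 1)
  st <- make_state(l = 2, X = X, Z = Z, model = "linear")
  set.seed(1)
  draws <- vapply(1:20000, function(i) {
    st <<- sample_beta(st, X)
    st$beta[1]
  }, numeric(1))
  ks <- stats::ks.test(draws, "pnorm", mean = 2, sd = 1)
  expect_gt(ks$p.value, 0.001)

  # n_m records at sigma_e2 = 1: conditional variance 1 / n_m
  n <- 25
  X2 <- matrix(1, n, 1)
  st2 <- make_state(l = rnorm(n), X = X2, Z = matrix(0, n, 1),
                    model = "linear")
  set.seed(2)
  d2 <- vapply(1:20000, function(i) {
    st2 <<- sample_beta(st2, X2)
    st2$beta[1]
  }, numeric(1))
  expect_lt(abs(var(d2) - 1 / n), 4 * (1 / n) * sqrt(2 / 20000))
  expect_error(sample_beta(st2, matrix(0, n, 1)),
               class = "bcpi_degenerate_design")
})

test_that("locus draws reduce to their closed forms in limiting cases", {
  n <- 10
  X <- matrix(1, n, 1)
  z <- c(rep(1, 5), rep(0, 5)) * 2
  Z <- matrix(z, n, 1)
  # forced inclusion (pi -> 0) with z'r = 0: a ~ N(0, sigma_e2 / C_k)
  st0 <- make_state(l = numeric(n), X = X, Z = Z, sigma_a2 = 0.5, pi = 0,
                    model = "linear")
  set.seed(3)
  draws <- vapply(1:20000, function(i) {
    up <- sample_locus(st0, Z)        # state reset each time: r stays 0
    up$a[1]
  }, numeric(1))
  Ck <- sum(z^2) + 1 / 0.5
  ks <- stats::ks.test(draws, "pnorm", mean = 0, sd = sqrt(1 / Ck))
  expect_gt(ks$p.value, 0.001)
  expect_error(sample_locus(make_state(l = numeric(n), X = X, Z = Z,
                                       sigma_a2 = 0, model = "linear"), Z),
               class = "bcpi_invalid_state")

  # a monomorphic locus carries no information: inclusion follows the prior
  Zm <- matrix(0, n, 1)
  stm <- make_state(l = rnorm(n), X = X, Z = Zm, sigma_a2 = 0.5, pi = 0.8,
                    model = "linear")
  set.seed(4)
  incl <- vapply(1:20000, function(i) sample_locus(stm, Zm)$delta[1],
                 integer(1))
  expect_lt(abs(mean(incl) - 0.2), 3 * sqrt(0.2 * 0.8 / 20000))
})

test_that("long-run locus inclusion matches the exact enumerated posterior", {
  # 3 records, 2 loci, fixed hyperparameters; oracle enumerates the four
  # indicator configurations with Gaussian marginal likelihoods
  r0 <- c(1.2, -0.4, 0.9)
  Z <- cbind(c(2, 1, 0), c(0, 1, 2))
  sigma_a2 <- 0.4
  sigma_e2 <- 1
  pi_excl <- 0.6
  lml <- function(cols) {
    S <- diag(sigma_e2, 3)
    if (length(cols)) {
      Zg <- Z[, cols, drop = FALSE]
      S <- S + sigma_a2 * tcrossprod(Zg)
    }
    -0.5 * (3 * log(2 * pi) + determinant(S)$modulus +
              drop(r0 %*% solve(S, r0)))
  }
  configs <- list(integer(0), 1L, 2L, c(1L, 2L))
  logw <- vapply(configs, function(g) {
    lml(g) + length(g) * log(1 - pi_excl) + (2 - length(g)) * log(pi_excl)
  }, numeric(1))
  w <- exp(logw - max(logw)); w <- w / sum(w)
  p1_exact <- w[2] + w[4]
  p2_exact <- w[3] + w[4]

  X <- matrix(0, 3, 1)   # no fixed effects in this state
  st <- mcmc_state(l = r0, X = X, Z = Z, sigma_a2 = sigma_a2, pi = pi_excl,
                   model = "linear")
  set.seed(5)
  n_it <- 40000
  incl <- matrix(0L, n_it, 2)
  for (i in seq_len(n_it)) {
    st <- sample_locus(st, Z)
    incl[i, ] <- st$delta
  }
  for (k in 1:2) {
    se <- mcse(incl[, k])
    expect_lt(abs(mean(incl[, k]) - c(p1_exact, p2_exact)[k]), 3 * se + 0.005)
  }
})

test_that("effect-variance draws obey the scaled-inverse-chi-square identities", {
  # empty model reduces to the prior: check the median against closed form
  st <- mcmc_state(l = rnorm(5), X = matrix(1, 5, 1), Z = matrix(0, 5, 1),
                   model = "linear")
  pr <- prior_spec(nu_a = 4, scale_a = 0.3)
  set.seed(6)
  d0 <- vapply(1:20000, function(i) sample_sigma_a2(st, pr)$sigma_a2,
               numeric(1))
  expect_lt(abs(stats::median(d0) - 4 * 0.3 / stats::qchisq(0.5, 4)), 0.02)

  # with M included effects: mean = (nu S^2 + sum a^2) / (nu + M - 2)
  K <- 30
  a <- rnorm(K, 0, 0.5)
  stM <- mcmc_state(l = rnorm(5), X = matrix(1, 5, 1),
                    Z = matrix(0, 5, K), a = a, delta = rep(1L, K),
                    model = "linear")
  set.seed(7)
  dM <- vapply(1:20000, function(i) sample_sigma_a2(stM, pr)$sigma_a2,
               numeric(1))
  nu_t <- 4 + K
  m_exact <- (4 * 0.3 + sum(a^2)) / (nu_t - 2)
  v_exact <- 2 * m_exact^2 * (nu_t - 2) / ((nu_t - 2) * (nu_t - 4)) # inv-gamma
  expect_lt(abs(mean(dM) - m_exact), 3 * sqrt(v_exact / 20000))
})

test_that("pi draws follow Beta(K - M + 1, M + 1)", {
  K <- 10
  st <- mcmc_state(l = rnorm(4), X = matrix(1, 4, 1), Z = matrix(0, 4, K),
                   a = c(rep(1, 3), rep(0, 7)),
                   delta = c(rep(1L, 3), rep(0L, 7)), model = "linear")
  set.seed(8)
  d <- vapply(1:20000, function(i) sample_pi(st)$pi, numeric(1))
  # Beta(8, 4): mean 2/3
  expect_lt(abs(mean(d) - 8 / 12), 3 * sqrt(8 * 4 / (12^2 * 13) / 20000))
  # all-loci-in limit concentrates near 0
  stK <- mcmc_state(l = rnorm(4), X = matrix(1, 4, 1), Z = matrix(0, 4, K),
                    a = rep(1, K), delta = rep(1L, K), model = "linear")
  set.seed(9)
  dK <- vapply(1:5000, function(i) sample_pi(stK)$pi, numeric(1))
  expect_lt(mean(dK), 0.2)  # Beta(1, 11) mean = 1/12
})

test_that("liability draws are truncated normals on the category intervals", {
  n <- 1000
  X <- matrix(1, n, 1)
  Z <- matrix(0, n, 1)
  # binary trait, all scores 1, zero mean: draws from N(0,1) truncated above 0
  y <- rep(1L, n)
  st <- mcmc_state(l = rep(-0.5, n), X = X, Z = Z, tau = 0, ncat = 2,
                   model = "threshold")
  set.seed(10)
  acc <- c()
  for (i in 1:20) {
    st <- sample_liabilities(st, y)
    acc <- c(acc, st$l)
  }
  expect_true(all(acc <= 0))
  half_normal_mean <- -sqrt(2 / pi)
  se <- sqrt((1 - 2 / pi) / length(acc))
  expect_lt(abs(mean(acc) - half_normal_mean), 4 * se)

  # interior category of a 3-category trait vs a rejection-sampler oracle
  tau2 <- 0.8
  mu <- 0.3
  st3 <- mcmc_state(l = rep(0.4, n), X = matrix(mu, n, 1), Z = Z,
                    beta = 1, tau = c(0, tau2), ncat = 3, model = "threshold")
  y2 <- rep(2L, n)
  set.seed(11)
  kern <- c()
  for (i in 1:20) {
    st3 <- sample_liabilities(st3, y2)
    kern <- c(kern, st3$l)
  }
  expect_true(all(kern > 0 & kern <= tau2))
  rej <- rnorm(4e5, mu, 1)
  rej <- rej[rej > 0 & rej <= tau2]
  tol <- 3 * sqrt(var(kern) / length(kern) + var(rej) / length(rej))
  expect_lt(abs(mean(kern) - mean(rej)), tol)
  expect_lt(abs(var(kern) - var(rej)), 6 * var(rej) * sqrt(2 / length(rej)))
})

test_that("threshold updates preserve ordering and are a no-op for binary traits", {
  n <- 30
  st2 <- mcmc_state(l = rnorm(n), X = matrix(0, n, 1), Z = matrix(0, n, 1),
                    tau = 0, ncat = 2, model = "threshold")
  y2 <- rep(c(1L, 2L), n / 2)
  out <- sample_thresholds(st2, y2)
  expect_identical(out$tau, st2$tau)
  expect_true(is.na(out$mh_accepted))

  set.seed(12)
  st4 <- mcmc_state(l = rnorm(n, 1), X = matrix(1, n, 1), Z = matrix(0, n, 1),
                    tau = c(0, 0.7, 1.4), ncat = 4, model = "threshold")
  y4 <- rep(1:4, length.out = n) |> as.integer() |> sort()
  for (i in 1:500) {
    st4 <- sample_thresholds(st4, y4, mh_step = 0.3)
    expect_true(st4$tau[1] == 0 && !is.unsorted(st4$tau, strictly = TRUE))
  }
})

test_that("long-run threshold distribution matches 1-D grid integration", {
  # n = 12, c = 3, fixed location parameters: the Metropolis-Hastings chain
  # targets p(tau2 | y, mu) exactly, computable by quadrature
  mu <- c(-0.8, -0.3, 0.1, 0.4, 0.6, 0.9, 1.1, 1.4, 0.2, -0.1, 0.7, 1.8)
  y <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 2L, 1L, 2L, 3L)
  loglik <- function(t2) {
    ext <- c(-Inf, 0, t2, Inf)
    sum(log(pnorm(ext[y + 1] - mu) - pnorm(ext[y] - mu)))
  }
  grid <- seq(0.001, 6, length.out = 4000)
  lw <- vapply(grid, loglik, numeric(1))
  w <- exp(lw - max(lw)); w <- w / sum(w)
  e_exact <- sum(grid * w)

  n <- 12
  st <- mcmc_state(l = mu + 0.01, X = matrix(mu, n, 1), Z = matrix(0, n, 1),
                   beta = 1, tau = c(0, 1), ncat = 3, model = "threshold")
  set.seed(13)
  tdraws <- vapply(1:40000, function(i) {
    st <<- sample_thresholds(st, y, mh_step = 0.5)
    st$tau[2]
  }, numeric(1))
  expect_lt(abs(mean(tdraws) - e_exact), 3 * mcse(tdraws) + 0.01)
})

test_that("residual-variance draws apply to the linear model only", {
  n <- 40
  r_fix <- rnorm(n, 0, 1.5)
  st <- mcmc_state(l = r_fix, X = matrix(0, n, 1), Z = matrix(0, n, 1),
                   model = "linear")
  pr <- prior_spec(nu_a = 4, scale_a = 1, nu_e = 6, scale_e = 0.5)
  set.seed(14)
  d <- vapply(1:20000, function(i) sample_sigma_e2(st, pr)$sigma_e2,
              numeric(1))
  nu_t <- 6 + n
  m_exact <- (6 * 0.5 + sum(r_fix^2)) / (nu_t - 2)
  v_exact <- 2 * m_exact^2 / (nu_t - 4)
  expect_lt(abs(mean(d) - m_exact), 3 * sqrt(v_exact / 20000))

  st_thr <- mcmc_state(l = r_fix, X = matrix(0, n, 1), Z = matrix(0, n, 1),
                       tau = 0, ncat = 2, model = "threshold")
  expect_error(sample_sigma_e2(st_thr, pr), class = "bcpi_mode_error")
})
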