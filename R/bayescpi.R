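#' Prior specification for Bayes C-pi models
#'
#' The marker-effect variance `sigma_a2` gets a scaled-inverse-chi-square
#' prior with `nu_a` degrees of freedom (default 4) and scale `scale_a`; when
#' `scale_a` is not given it is derived at fit time from planning values as
#' `planning_sigma_g2 * (nu_a - 2) / (K * (1 - planning_pi) * 2pq-bar * nu_a)`.
#' The exclusion probability `pi` has a uniform (0, 1) prior (chain starts at
#' 0.5), fixed effects and thresholds have flat priors, and the residual
#' variance is fixed at 1 in the threshold model or given a
#' scaled-inverse-chi-square `(nu_e, scale_e)` prior in the linear model;
#' a missing `scale_e` defaults to `var(y) * (1 - planning_h2) *
#' (nu_e - 2) / nu_e` so the prior mean matches the planning residual
#' variance.
#'
#' @param nu_a degrees of freedom of the effect-variance prior (> 2).
#' @param scale_a scale of the effect-variance prior, or `NULL` to derive it.
#' @param planning_sigma_g2 planning genetic variance used to derive
#'   `scale_a`; default 1 for the threshold model (liability scale) and
#'   `var(y) * planning_h2` for the linear model.
#' @param planning_pi planning exclusion probability used to derive `scale_a`.
#' @param planning_h2 planning heritability used for linear-model defaults.
#' @param nu_e,scale_e residual-variance prior (linear model).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(nu_a = 4, scale_a = NULL,
                       planning_sigma_g2 = NULL, planning_pi = 0.999,
                       planning_h2 = 0.5,
                       nu_e = 4, scale_e = NULL) {
  if (nu_a <= 2) {
    abort("nu_a must exceed 2", class = "bcpi_invalid_prior")
  }
  if (!is.null(scale_a) && scale_a <= 0) {
    abort("scale_a must be positive", class = "bcpi_invalid_prior")
  }
  structure(list(nu_a = nu_a, scale_a = scale_a,
                 planning_sigma_g2 = planning_sigma_g2,
                 planning_pi = planning_pi, planning_h2 = planning_h2,
                 nu_e = nu_e, scale_e = scale_e),
            class = "prior_spec")
}

resolve_prior <- function(prior, y, K, het, model) {
  out <- prior
  if (is.null(out$scale_a)) {
    sg2 <- out$planning_sigma_g2 %||%
      if (model == "threshold") 1 else var(y) * out$planning_h2
    out$scale_a <- sg2 * (out$nu_a - 2) /
      (K * (1 - out$planning_pi) * het * out$nu_a)
  }
  if (model == "linear" && is.null(out$scale_e)) {
    out$scale_e <- var(y) * (1 - out$planning_h2) * (out$nu_e - 2) / out$nu_e
  }
  if (model == "threshold") out$scale_e <- 1
  out
}

#' Chain settings for the Bayes C-pi samplers
#'
#' @param n_iter kept MCMC cycles after burn-in (default 40000).
#' @param burn_in discarded cycles (default 5000).
#' @param thin keep every `thin`-th kept cycle.
#' @param seed integer seed; identical settings and seed give bit-identical
#'   chains.
#' @param mh_step initial proposal scale for the threshold
#'   Metropolis-Hastings update.
#' @param adapt_mh adapt `mh_step` toward a 20-50% acceptance rate during
#'   burn-in only (frozen afterwards, preserving detailed balance).
#' @param refresh_every recompute the working residual from scratch every
#'   this many sweeps to bound floating-point drift.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 40000, burn_in = 5000, thin = 1, seed = 1L,
                        mh_step = 0.05, adapt_mh = TRUE,
                        refresh_every = 1000) {
  stopifnot(n_iter >= 0, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 mh_step = mh_step, adapt_mh = isTRUE(adapt_mh),
                 refresh_every = as.integer(refresh_every)),
            class = "mcmc_config")
}

#' Fit a Bayes C-pi whole-genome regression
#'
#' Runs the Gibbs sampler for the Bayes C-pi model: every marker effect is
#' zero with probability `pi` or drawn from `N(0, sigma_a2)` otherwise, with
#' `pi`, `sigma_a2`, fixed effects and (in the linear model) the residual
#' variance all sampled from their full conditionals. For ordered categorical
#' responses the threshold (liability) model augments the chain with latent
#' liabilities drawn from truncated normals and updates the free thresholds
#' by a Cowles-style Metropolis-Hastings step; identifiability is enforced by
#' fixing the residual variance at 1 and the first threshold at 0.
#'
#' @param y response: numeric vector (linear model) or integer scores
#'   `1..ncat` (threshold model; every category must be observed).
#' @param fixed fixed-effect factor (one class effect) or incidence matrix.
#' @param G imputed [genotype_matrix] of marker covariates (QTL-masked panel
#'   for simulation studies).
#' @param model `"linear"` or `"threshold"`.
#' @param prior a [prior_spec].
#' @param config an [mcmc_config].
#' @return An object of class `bcpi_fit`; see [tidy.bcpi_fit()] and
#'   [glance.bcpi_fit()] for tibble views of the posterior summaries.
#' @export
fit_bayescpi <- function(y, fixed, G, model = c("linear", "threshold"),
                         prior = prior_spec(), config = mcmc_config()) {
  model <- match.arg(model)
  stopifnot(inherits(G, "genotype_matrix"), inherits(prior, "prior_spec"),
            inherits(config, "mcmc_config"))
  Z <- G$values
  if (anyNA(Z)) {
    abort("genotype matrix contains missing values; impute first",
          class = "bcpi_missing_genotypes")
  }
  if (anyNA(y)) {
    abort("missing responses are not supported", class = "bcpi_missing_response")
  }
  X <- if (is.matrix(fixed)) fixed else fixed_design_matrix(fixed)
  stopifnot(nrow(X) == length(y), nrow(Z) == length(y))

  ncat <- 0L
  tau_init <- numeric(0)
  l_init <- numeric(0)
  if (model == "threshold") {
    ncat <- max(y)
    if (!all(y %in% seq_len(ncat)) || !all(seq_len(ncat) %in% y)) {
      abort("every category 1..c must be observed at least once; collapse categories first",
            class = "bcpi_missing_category")
    }
    if (ncat < 2) {
      abort("threshold model needs at least 2 categories",
            class = "bcpi_invalid_response")
    }
    # anchor tau_1 = 0; start remaining cut points at the quantiles implied
    # by the observed category frequencies
    cum <- cumsum(tabulate(y, ncat) / length(y))[seq_len(ncat - 1L)]
    tau_init <- qnorm(cum) - qnorm(cum[1])
    # liabilities start at interval midpoints
    mids <- c(tau_init[1] - 0.5,
              if (ncat > 2) (tau_init[-(ncat - 1L)] + tau_init[-1]) / 2,
              tau_init[ncat - 1L] + 0.5)
    l_init <- mids[y]
  } else {
    if (var(y) == 0) {
      abort("constant response", class = "bcpi_degenerate_response")
    }
  }

  het <- mean_heterozygosity(G)
  pr <- resolve_prior(prior, y, ncol(Z), het, model)

  set.seed(config$seed)
  raw <- cpp_bcpi_chain(as.numeric(y), X, Z,
                        model = if (model == "threshold") 1L else 0L,
                        ncat = ncat,
                        nu_a = pr$nu_a, scale_a = pr$scale_a,
                        nu_e = pr$nu_e, scale_e = pr$scale_e %||% 1,
                        n_iter = config$n_iter, burn_in = config$burn_in,
                        thin = config$thin, mh_step = config$mh_step,
                        adapt_mh = config$adapt_mh,
                        tau_init = tau_init, l_init = l_init,
                        refresh_every = config$refresh_every)

  nk <- raw$n_kept
  effects <- tibble(
    locus_id = locus_ids(G),
    effect_mean = as.numeric(raw$effect_sum) / nk,
    inclusion_prob = as.numeric(raw$incl_sum) / nk
  )
  traces <- tibble(
    iteration = seq_len(nk),
    pi = as.numeric(raw$pi),
    sigma_a2 = as.numeric(raw$sigma_a2),
    sigma_e2 = as.numeric(raw$sigma_e2),
    m = as.integer(raw$m),
    h2 = as.numeric(raw$h2)
  )
  structure(list(
    model = model, ncat = if (model == "threshold") ncat else NA_integer_,
    n = length(y), K = ncol(Z),
    effects = effects,
    beta_mean = setNames(as.numeric(raw$beta_sum) / nk, colnames(X)),
    pi_mean = mean(traces$pi), pi_se = sd(traces$pi) / sqrt(nk),
    sigma_a2_mean = mean(traces$sigma_a2),
    sigma_e2_mean = mean(traces$sigma_e2),
    threshold_means = if (model == "threshold" && ncat >= 2)
      as.numeric(raw$tau_sum) / nk else NULL,
    h2_samples = traces$h2, h2_mean = mean(traces$h2),
    mh_acceptance = raw$mh_acceptance,
    mh_step_final = raw$mh_step_final,
    traces = traces,
    tau_trace = if (model == "threshold") raw$tau_trace else NULL,
    prior = pr, config = config
  ), class = "bcpi_fit")
}

#' @export
print.bcpi_fit <- function(x, ...) {
  cat("<bcpi_fit> Bayes C-pi ", x$model, " model",
      if (x$model == "threshold") paste0(" (", x$ncat, " categories)"),
      "\n", sep = "")
  cat(sprintf("n = %d, K = %d markers; %d kept samples (burn-in %d)\n",
              x$n, x$K, nrow(x$traces), x$config$burn_in))
  cat(sprintf("pi_hat = %.5f (SE %.5f), sigma_a2 = %.4g, h2 = %.3f\n",
              x$pi_mean, x$pi_se, x$sigma_a2_mean, x$h2_mean))
  if (!is.null(x$threshold_means) && length(x$threshold_means) > 1) {
    cat("thresholds:", sprintf("%.3f", x$threshold_means),
        sprintf("(MH acceptance %.2f)", x$mh_acceptance), "\n")
  }
  invisible(x)
}

#' Write posterior summaries and run metadata
#'
#' Writes per-locus posterior means and inclusion probabilities as CSV, plus
#' a plain-text metadata file with all settings, seeds and acceptance rates;
#' optionally the per-iteration traces as CSV.
#'
#' @param fit a [bcpi_fit].
#' @param dir output directory (created if needed).
#' @param traces also write per-iteration traces.
#' @return `dir`, invisibly.
#' @export
write_fit_summary <- function(fit, dir, traces = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(fit$effects, file.path(dir, "effects.csv"))
  meta <- c(
    sprintf("model: %s", fit$model),
    sprintf("categories: %s", fit$ncat),
    sprintf("n: %d", fit$n), sprintf("K: %d", fit$K),
    sprintf("chain: %d kept after %d burn-in, thin %d, seed %d",
            fit$config$n_iter, fit$config$burn_in, fit$config$thin,
            fit$config$seed),
    sprintf("prior: nu_a %g, scale_a %g, nu_e %g, scale_e %g",
            fit$prior$nu_a, fit$prior$scale_a, fit$prior$nu_e,
            fit$prior$scale_e %||% NA),
    sprintf("pi_mean: %.6f (se %.6f)", fit$pi_mean, fit$pi_se),
    sprintf("sigma_a2_mean: %g", fit$sigma_a2_mean),
    sprintf("sigma_e2_mean: %g", fit$sigma_e2_mean),
    sprintf("h2_mean: %.4f", fit$h2_mean),
    sprintf("thresholds: %s",
            paste(sprintf("%.4f", fit$threshold_means %||% NA),
                  collapse = " ")),
    sprintf("mh_acceptance: %s", format(fit$mh_acceptance)),
    sprintf("mh_step_final: %s", format(fit$mh_step_final))
  )
  writeLines(meta, file.path(dir, "run-metadata.txt"))
  if (traces) readr::write_csv(fit$traces, file.path(dir, "traces.csv"))
  invisible(dir)
}
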