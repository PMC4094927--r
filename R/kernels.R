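#' MCMC state for the Bayes C-pi samplers
#'
#' Bundles the current values of all unknowns in the Gibbs chain: fixed
#' effects `beta`, marker effects `a` with inclusion indicators `delta`,
#' common effect variance `sigma_a2`, residual variance `sigma_e2`, exclusion
#' probability `pi`, thresholds `tau` (first fixed at 0 in the threshold
#' model), liabilities `l` and the working residual `r = l - X beta - Z a`.
#' These kernel-level functions update one block at a time and are the same
#' compiled routines the full chain in [fit_bayescpi()] runs; they exist so
#' that each full conditional can be exercised and checked on its own.
#'
#' @param l response / liability vector.
#' @param X fixed-effect incidence matrix.
#' @param Z marker covariate matrix.
#' @param beta,a,delta,sigma_a2,sigma_e2,pi,tau initial values.
#' @param model `"linear"` or `"threshold"`.
#' @param ncat number of categories (threshold model).
#' @return A list of class `mcmc_state`.
#' @export
mcmc_state <- function(l, X, Z, beta = NULL, a = NULL, delta = NULL,
                       sigma_a2 = 0.01, sigma_e2 = 1, pi = 0.5,
                       tau = NULL, model = c("threshold", "linear"),
                       ncat = NULL) {
  model <- match.arg(model)
  beta <- beta %||% numeric(ncol(X))
  a <- a %||% numeric(ncol(Z))
  delta <- delta %||% as.integer(a != 0)
  if (model == "threshold") {
    sigma_e2 <- 1
    ncat <- ncat %||% (length(tau %||% 0) + 1L)
    tau <- tau %||% seq(0, length.out = ncat - 1L)
    stopifnot(tau[1] == 0, !is.unsorted(tau))
  }
  r <- as.numeric(l - X %*% beta - Z %*% a)
  structure(list(beta = beta, a = a, delta = as.integer(delta),
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, pi = pi,
                 tau = tau, l = as.numeric(l), r = r,
                 model = model, ncat = ncat),
            class = "mcmc_state")
}

#' Kernel updates of the Bayes C-pi full conditionals
#'
#' Each function draws one block from its full conditional posterior and
#' returns the updated state (working residual kept consistent).
#' `sample_beta` draws each fixed-effect level from
#' `N(beta_hat_m, sigma_e2 / (x_m' x_m))`; `sample_locus` jointly draws every
#' locus's (indicator, effect) pair from the mixture full conditional;
#' `sample_sigma_a2` draws the common effect variance from its
#' scaled-inverse-chi-square full conditional with degrees of freedom
#' `nu + M(t)`; `sample_pi` draws `Beta(K - M + 1, M + 1)`;
#' `sample_liabilities` draws each latent liability from a truncated normal;
#' `sample_thresholds` performs the Cowles-style Metropolis-Hastings update
#' of the free thresholds; `sample_sigma_e2` (linear model only) draws the
#' residual variance.
#'
#' @param state an [mcmc_state].
#' @param X fixed-effect incidence matrix.
#' @param Z marker covariate matrix.
#' @param y integer scores in `1..ncat`.
#' @param prior a [prior_spec].
#' @param mh_step Metropolis-Hastings proposal scale.
#' @return The updated `mcmc_state`; `sample_thresholds` additionally sets
#'   `state$mh_accepted`.
#' @name kernels
NULL

#' @rdname kernels
#' @export
sample_beta <- function(state, X) {
  if (any(colSums(X^2) == 0)) {
    abort("degenerate design: empty fixed-effect level",
          class = "bcpi_degenerate_design")
  }
  up <- cpp_sample_beta(state$r, X, state$beta, state$sigma_e2)
  state$beta <- as.numeric(up$beta)
  state$r <- as.numeric(up$r)
  state
}

#' @rdname kernels
#' @export
sample_locus <- function(state, Z) {
  if (state$sigma_a2 <= 0) {
    abort("invalid state: sigma_a2 must be positive",
          class = "bcpi_invalid_state")
  }
  up <- cpp_sample_loci(state$r, Z, state$a, state$delta,
                        state$sigma_a2, state$sigma_e2, state$pi)
  state$a <- as.numeric(up$a)
  state$delta <- as.integer(up$delta)
  state$r <- as.numeric(up$r)
  state
}

#' @rdname kernels
#' @export
sample_sigma_a2 <- function(state, prior) {
  state$sigma_a2 <- cpp_sample_sigma_a2(state$a, state$delta,
                                        prior$nu_a, prior$scale_a)
  state
}

#' @rdname kernels
#' @export
sample_pi <- function(state) {
  K <- length(state$a)
  M <- sum(state$delta)
  state$pi <- cpp_sample_pi(K, M)
  state
}

#' @rdname kernels
#' @export
sample_liabilities <- function(state, y) {
  stopifnot(state$model == "threshold", all(y >= 1), all(y <= state$ncat))
  up <- cpp_sample_liabilities(state$r, state$l, as.integer(y),
                               state$tau, state$ncat)
  state$l <- as.numeric(up$l)
  state$r <- as.numeric(up$r)
  state
}

#' @rdname kernels
#' @export
sample_thresholds <- function(state, y, mh_step = 0.05) {
  stopifnot(state$model == "threshold")
  if (state$ncat <= 2) {
    state$mh_accepted <- NA
    return(state)
  }
  mu <- state$l - state$r
  up <- cpp_sample_thresholds(state$tau, as.integer(y), mu, mh_step,
                              state$ncat)
  state$tau <- as.numeric(up$tau)
  state$mh_accepted <- up$accepted
  state
}

#' @rdname kernels
#' @export
sample_sigma_e2 <- function(state, prior) {
  if (state$model != "linear") {
    abort("sample_sigma_e2 applies to the linear model only (sigma_e2 is fixed at 1 in the threshold model)",
          class = "bcpi_mode_error")
  }
  state$sigma_e2 <- cpp_sample_sigma_e2(state$r, prior$nu_e, prior$scale_e)
  state
}
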