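#' True genomic merit from the simulated architecture
#'
#' `g_i = sum_q z_iq alpha_q` over the QTL loci of the architecture, matched
#' to the validation panel by locus ID.
#'
#' @param G_val [genotype_matrix] of the validation individuals; must contain
#'   every QTL locus of `arch`.
#' @param arch a [trait_architecture].
#' @return numeric merit vector, one entry per validation individual.
#' @export
true_merit <- function(G_val, arch) {
  stopifnot(inherits(G_val, "genotype_matrix"),
            inherits(arch, "trait_architecture"))
  qtl <- which(arch$qtl_indicator == 1L)
  if (length(qtl) == 0L) return(numeric(nrow(G_val$values)))
  ids <- arch$locus_ids[qtl]
  hit <- match(ids, locus_ids(G_val))
  if (anyNA(hit)) {
    abort(paste0("QTL loci absent from validation panel: ",
                 paste(ids[is.na(hit)], collapse = ", ")),
          class = "bcpi_missing_qtl")
  }
  as.numeric(G_val$values[, hit, drop = FALSE] %*% arch$qtl_effects[qtl])
}

#' Genomic estimated breeding values
#'
#' `ghat_i = sum_k z_ik ahat_k` with `ahat_k` the posterior-mean substitution
#' effects, aligned to the validation panel by locus ID (the fitted panel is
#' typically the QTL-masked marker set).
#'
#' @param G_val [genotype_matrix] of the validation individuals.
#' @param effects a [bcpi_fit], or a tibble with columns `locus_id` and
#'   `effect_mean`.
#' @return numeric GEBV vector.
#' @export
gebv <- function(G_val, effects) {
  stopifnot(inherits(G_val, "genotype_matrix"))
  if (inherits(effects, "bcpi_fit")) effects <- effects$effects
  stopifnot(all(c("locus_id", "effect_mean") %in% names(effects)))
  hit <- match(effects$locus_id, locus_ids(G_val))
  if (anyNA(hit)) {
    abort(paste0("fitted loci absent from validation panel: ",
                 paste(effects$locus_id[is.na(hit)][1:5], collapse = ", ")),
          class = "bcpi_locus_mismatch")
  }
  as.numeric(G_val$values[, hit, drop = FALSE] %*% effects$effect_mean)
}

#' Accuracy of prediction pooled across populations
#'
#' Within each population the sample covariance between true and predicted
#' merit and the two sample variances are computed; each statistic is then
#' pooled across populations with weights equal to its degrees of freedom
#' (`n_b - 1`), and the pooled correlation
#' `pooled_cov / sqrt(pooled_var_g * pooled_var_ghat)` is returned. With a
#' single population this is the ordinary sample correlation. Populations
#' with fewer than 2 individuals are excluded with a warning.
#'
#' @param g true merit vector.
#' @param ghat predicted merit (GEBV) vector.
#' @param labels population label per individual; a single label pools over
#'   everyone.
#' @return scalar pooled correlation in `[-1, 1]`, with the per-population
#'   breakdown in attribute `"per_population"`.
#' @export
pooled_accuracy <- function(g, ghat, labels = "all") {
  stopifnot(length(g) == length(ghat))
  if (length(labels) == 1L) labels <- rep(labels, length(g))
  labels <- factor(labels)
  per <- tibble(population = levels(labels),
                n = as.integer(table(labels))) |>
    dplyr::mutate(
      cov = purrr::map_dbl(.data$population, function(b) {
        i <- labels == b
        if (sum(i) < 2) NA_real_ else cov(g[i], ghat[i])
      }),
      var_g = purrr::map_dbl(.data$population, function(b) {
        i <- labels == b
        if (sum(i) < 2) NA_real_ else var(g[i])
      }),
      var_ghat = purrr::map_dbl(.data$population, function(b) {
        i <- labels == b
        if (sum(i) < 2) NA_real_ else var(ghat[i])
      })
    )
  small <- per$n < 2
  if (any(small)) {
    warn(paste0("populations with fewer than 2 individuals excluded: ",
                paste(per$population[small], collapse = ", ")))
  }
  use <- per[!small, ]
  if (nrow(use) == 0) {
    abort("no population with at least 2 individuals",
          class = "bcpi_degenerate_validation")
  }
  w <- use$n - 1
  pc <- sum(w * use$cov) / sum(w)
  pv_g <- sum(w * use$var_g) / sum(w)
  pv_h <- sum(w * use$var_ghat) / sum(w)
  out <- pc / sqrt(pv_g * pv_h)
  attr(out, "per_population") <- per
  out
}

#' Bias slope of prediction
#'
#' Ordinary least-squares slope of true merit on predicted merit,
#' `cov(g, ghat) / var(ghat)`; 1 indicates unbiased prediction.
#'
#' @inheritParams pooled_accuracy
#' @return scalar slope.
#' @export
bias_regression <- function(g, ghat) {
  stopifnot(length(g) == length(ghat))
  if (var(ghat) == 0) {
    abort("undefined slope: predicted merit has zero variance",
          class = "bcpi_undefined_slope")
  }
  cov(g, ghat) / var(ghat)
}

#' Spearman rank correlation between alternative predictors
#'
#' Rank correlation with average ranks for ties.
#'
#' @param ghat_a,ghat_b merit vectors of equal length (>= 3).
#' @return scalar Spearman rho.
#' @export
rank_correlation <- function(ghat_a, ghat_b) {
  stopifnot(length(ghat_a) == length(ghat_b), length(ghat_a) >= 3)
  if (sd(ghat_a) == 0 || sd(ghat_b) == 0) {
    abort("undefined rank correlation: constant predictor",
          class = "bcpi_undefined_correlation")
  }
  cor(rank(ghat_a), rank(ghat_b))
}

#' Posterior heritability summary
#'
#' Mean and standard error of a vector of heritability values (per-iteration
#' posterior samples within a fit, or per-replicate posterior means across a
#' study).
#'
#' @param h2_samples numeric vector.
#' @return tibble with columns `mean` and `se`.
#' @export
summarize_h2 <- function(h2_samples) {
  stopifnot(length(h2_samples) >= 1)
  tibble(mean = mean(h2_samples),
         se = if (length(h2_samples) > 1)
           sd(h2_samples) / sqrt(length(h2_samples)) else NA_real_)
}

#' Validation report for a fitted model on a validation panel
#'
#' Computes GEBV and true merit for the validation individuals and assembles
#' the accuracy (pooled across populations by degrees of freedom), the bias
#' slope of true on predicted merit, and the per-population breakdown.
#'
#' @param G_val validation [genotype_matrix].
#' @param arch the generating [trait_architecture].
#' @param fit a [bcpi_fit] (or effects tibble).
#' @return A list of class `validation_report`: `summary` (one-row tibble
#'   with `accuracy`, `bias_slope`, `n`), `per_population` tibble, and the
#'   `gebv`/`true_merit` vectors.
#' @export
validation_report <- function(G_val, arch, fit) {
  g <- true_merit(G_val, arch)
  gh <- gebv(G_val, fit)
  acc <- pooled_accuracy(g, gh, populations(G_val))
  slope <- tryCatch(bias_regression(g, gh), error = function(e) NA_real_)
  per <- attr(acc, "per_population")
  per$bias_slope <- purrr::map_dbl(per$population, function(b) {
    i <- populations(G_val) == b
    if (sum(i) < 3 || var(gh[i]) == 0) NA_real_
    else cov(g[i], gh[i]) / var(gh[i])
  })
  structure(list(
    summary = tibble(n = length(g), accuracy = as.numeric(acc),
                     bias_slope = slope),
    per_population = per,
    gebv = gh, true_merit = g,
    populations = populations(G_val)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n =", x$summary$n, "\n")
  cat(sprintf("pooled accuracy r(g, ghat) = %.3f, bias slope b = %.3f\n",
              x$summary$accuracy, x$summary$bias_slope))
  print(x$per_population)
  invisible(x)
}
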