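#' Tidy a Bayes C-pi fit into a per-locus tibble
#'
#' @param x a [bcpi_fit].
#' @param ... unused.
#' @return Tibble with one row per marker: `locus_id`, `effect_mean`
#'   (posterior-mean substitution effect, zeros from excluded iterations
#'   included) and `inclusion_prob` (posterior inclusion probability).
#' @export
tidy.bcpi_fit <- function(x, ...) {
  x$effects
}

#' One-row summary of a Bayes C-pi fit
#'
#' @param x a [bcpi_fit].
#' @param ... unused.
#' @return One-row tibble with `model`, `ncat`, `n`, `K`, `pi_mean`, `pi_se`,
#'   `sigma_a2_mean`, `sigma_e2_mean`, `h2_mean`, `m_mean` (average number of
#'   fitted markers) and `mh_acceptance`.
#' @export
glance.bcpi_fit <- function(x, ...) {
  tibble(model = x$model, ncat = x$ncat, n = x$n, K = x$K,
         pi_mean = x$pi_mean, pi_se = x$pi_se,
         sigma_a2_mean = x$sigma_a2_mean, sigma_e2_mean = x$sigma_e2_mean,
         h2_mean = x$h2_mean, m_mean = mean(x$traces$m),
         mh_acceptance = x$mh_acceptance)
}

#' Trace plots for a Bayes C-pi chain
#'
#' Per-iteration traces of the exclusion probability `pi`, the common effect
#' variance `sigma_a2`, the number of fitted markers `M(t)` and the
#' heritability, faceted on the free scale.
#'
#' @param object a [bcpi_fit].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bcpi_fit <- function(object, ...) {
  object$traces |>
    tidyr::pivot_longer(c("pi", "sigma_a2", "m", "h2"),
                        names_to = "parameter", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "kept iteration", y = NULL,
                  title = "Bayes C-pi chain traces")
}

#' Tidy a validation report
#'
#' @param x a [validation_report].
#' @param ... unused.
#' @return The per-population tibble of `n`, covariance, variances and bias
#'   slope.
#' @export
tidy.validation_report <- function(x, ...) {
  x$per_population
}

#' One-row summary of a validation report
#' @param x a [validation_report].
#' @param ... unused.
#' @export
glance.validation_report <- function(x, ...) {
  x$summary
}

#' Scatter plot of predicted against true merit
#'
#' @param object a [validation_report].
#' @param ... unused.
#' @return A ggplot object: GEBV against true merit by population, with the
#'   pooled bias-regression line and the identity line.
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tibble(true_merit = object$true_merit, gebv = object$gebv,
               population = object$populations)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gebv, y = .data$true_merit,
                                   colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = object$summary$bias_slope,
                         intercept = mean(df$true_merit) -
                           object$summary$bias_slope * mean(df$gebv)) +
    ggplot2::labs(
      x = "GEBV", y = "true genomic merit",
      title = sprintf("accuracy %.2f, bias slope %.2f",
                      object$summary$accuracy, object$summary$bias_slope))
}

#' Plot accuracy across study scenarios
#'
#' @param accuracy_table the accuracy tibble from [run_study()].
#' @return A ggplot object: mean accuracy with one-SE error bars by
#'   heritability, model, number of categories and validation population.
#' @export
plot_study_accuracy <- function(accuracy_table) {
  accuracy_table |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$h2), y = .data$accuracy,
                                 colour = .data$model,
                                 shape = factor(.data$ncat))) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$accuracy - .data$accuracy_se,
                   ymax = .data$accuracy + .data$accuracy_se),
      width = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_grid(validation ~ n_train,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "heritability", y = "accuracy r(g, ghat)",
                  colour = "model", shape = "categories")
}
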