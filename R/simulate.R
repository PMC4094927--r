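#' Sample a trait architecture for a genotyped panel
#'
#' Designates each locus a QTL independently with probability `1 - pi_sim`,
#' draws substitution effects for the QTL from `N(0, sigma_alpha2)` with
#' `sigma_alpha2 = sigma_g2 / (K (1 - pi_sim) 2pq-bar)` so the expected
#' genetic variance on the liability scale equals `sigma_g2`, and draws one
#' fixed class effect with three levels from the standard normal. The residual
#' variance on the liability scale is fixed at 1, so the design heritability
#' is `sigma_g2 / (sigma_g2 + 1)`.
#'
#' @param G imputed [genotype_matrix] the trait is simulated on.
#' @param pi_sim probability that a locus is *not* a QTL, in (0, 1).
#' @param sigma_g2 genetic variance on the liability scale; 1, 0.33 and 0.12
#'   give design heritabilities 0.50, 0.25 and 0.10.
#' @param thresholds strictly increasing liability cut points for four
#'   categories; the default `(0.61, 1.41, 2.05)` yields category frequencies
#'   of about 73/19/6/2% for a standard-normal liability, as observed for
#'   calving-difficulty scores.
#' @param seed integer seed.
#'
#' @return An object of class `trait_architecture`: list with `qtl_indicator`
#'   (0/1 per locus), `qtl_effects` (alpha, zero for non-QTL), `sigma_g2`,
#'   `pi_sim`, `sigma_alpha2`, `beta` (3 fixed-effect level values),
#'   `sigma_e2 = 1`, `thresholds`, `locus_ids`.
#' @export
sample_architecture <- function(G, pi_sim = 0.999, sigma_g2 = 1,
                                thresholds = c(0.61, 1.41, 2.05),
                                seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (pi_sim <= 0 || pi_sim >= 1 || sigma_g2 <= 0) {
    abort("need 0 < pi_sim < 1 and sigma_g2 > 0",
          class = "bcpi_invalid_parameter")
  }
  if (any(diff(thresholds) <= 0)) {
    abort("thresholds must be strictly increasing",
          class = "bcpi_invalid_parameter")
  }
  het <- mean_heterozygosity(G)
  if (het <= 0) {
    abort("monomorphic panel: mean heterozygosity is zero",
          class = "bcpi_degenerate_panel")
  }
  K <- ncol(G$values)
  set.seed(seed)
  delta <- rbinom(K, 1L, 1 - pi_sim)
  sigma_alpha2 <- sigma_g2 / (K * (1 - pi_sim) * het)
  alpha <- numeric(K)
  nq <- sum(delta)
  if (nq > 0) alpha[delta == 1L] <- rnorm(nq, 0, sqrt(sigma_alpha2))
  beta <- rnorm(3L)
  structure(
    list(qtl_indicator = delta, qtl_effects = alpha,
         sigma_g2 = sigma_g2, pi_sim = pi_sim,
         sigma_alpha2 = sigma_alpha2, beta = beta,
         sigma_e2 = 1, thresholds = thresholds,
         locus_ids = locus_ids(G)),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("<trait_architecture> ", length(x$qtl_indicator), " loci, ",
      sum(x$qtl_indicator), " QTL\n", sep = "")
  cat(sprintf("sigma_g2 = %.3g (design h2 = %.3f), sigma_alpha2 = %.3g\n",
              x$sigma_g2, x$sigma_g2 / (x$sigma_g2 + 1), x$sigma_alpha2))
  invisible(x)
}

#' Simulate liabilities under an additive QTL model
#'
#' Generates the latent (underlying) phenotype
#' `l_i = x_i' beta + sum_j z_ij alpha_j delta_j + e_i` with standard-normal
#' residuals, assigning each individual one of the three fixed-effect levels
#' uniformly at random.
#'
#' @param G imputed [genotype_matrix]; must have the same loci as `arch`.
#' @param arch a [trait_architecture].
#' @param seed integer seed (controls level assignment and residuals).
#' @return A tibble with columns `id`, `population`, `fixed_level`,
#'   `genetic_value`, `liability`; the 3-column fixed-effect incidence matrix
#'   is attached as attribute `"fixed_design"`.
#' @export
simulate_liabilities <- function(G, arch, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"),
            inherits(arch, "trait_architecture"))
  if (ncol(G$values) != length(arch$qtl_indicator)) {
    abort("genotype matrix and architecture have different locus counts",
          class = "bcpi_dimension_mismatch")
  }
  n <- nrow(G$values)
  set.seed(seed)
  lev <- factor(sample(1:3, n, replace = TRUE), levels = 1:3,
                labels = paste0("L", 1:3))
  X <- model.matrix(~ lev - 1)
  colnames(X) <- levels(lev)
  g <- as.numeric(G$values %*% (arch$qtl_effects * arch$qtl_indicator))
  l <- as.numeric(X %*% arch$beta) + g + rnorm(n, 0, sqrt(arch$sigma_e2))
  out <- tibble(id = individual_ids(G),
                population = as.character(populations(G)),
                fixed_level = lev,
                genetic_value = g,
                liability = l)
  attr(out, "fixed_design") <- X
  out
}

#' Map liabilities to four ordered categories
#'
#' Assigns category `j` when the liability falls in the half-open interval
#' `(tau_{j-1}, tau_j]` (with `tau_0 = -Inf`, `tau_4 = +Inf`): a liability
#' exactly equal to a threshold belongs to the lower category.
#'
#' @param l numeric liability vector.
#' @param thresholds strictly increasing cut points `(tau1, tau2, tau3)`.
#' @return integer vector of scores in `1..4` (generally, `length(thresholds)
#'   + 1` categories).
#' @export
map_to_categories <- function(l, thresholds = c(0.61, 1.41, 2.05)) {
  if (any(diff(thresholds) <= 0)) {
    abort("thresholds must be strictly increasing",
          class = "bcpi_invalid_parameter")
  }
  findInterval(l, thresholds, left.open = TRUE) + 1L
}

#' Collapse four-category scores to two or three categories
#'
#' Two categories merge `{2,3,4}` into 2; three categories merge `{2,3}` into
#' 2 and map 4 to 3.
#'
#' @param y4 integer scores in `1..4`.
#' @param c target number of categories, 2 or 3.
#' @return integer scores in `1..c`.
#' @export
collapse_categories <- function(y4, c) {
  stopifnot(all(y4 %in% 1:4))
  if (!c %in% c(2L, 3L)) {
    abort("c must be 2 or 3", class = "bcpi_invalid_parameter")
  }
  if (c == 2L) ifelse(y4 == 1L, 1L, 2L)
  else c(1L, 2L, 2L, 3L)[y4]
}

#' Simulate a full phenotype set (liability plus ordinal scores)
#'
#' Convenience wrapper: simulates liabilities, maps them to four categories
#' with the architecture's thresholds, and collapses to three- and
#' two-category scores.
#'
#' @inheritParams simulate_liabilities
#' @return A tibble with columns `id`, `population`, `fixed_level`,
#'   `genetic_value`, `liability`, `y2`, `y3`, `y4`; fixed-effect incidence
#'   matrix in attribute `"fixed_design"`.
#' @export
simulate_phenotypes <- function(G, arch, seed = 1L) {
  ph <- simulate_liabilities(G, arch, seed = seed)
  y4 <- map_to_categories(ph$liability, arch$thresholds)
  ph$y2 <- collapse_categories(y4, 2L)
  ph$y3 <- collapse_categories(y4, 3L)
  ph$y4 <- y4
  ph
}

#' Read and write phenotype tables and architecture sidecars
#'
#' Phenotypes are written as CSV with columns `id`, `population`,
#' `fixed_level`, `genetic_value`, `liability`, `y2`, `y3`, `y4`; the
#' architecture sidecar is a CSV of `locus_id`, `delta`, `alpha`.
#'
#' @param pheno phenotype tibble from [simulate_phenotypes()].
#' @param arch a [trait_architecture].
#' @param path file path.
#' @return readers return the tibble; writers return `path` invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_csv(pheno, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tbl$fixed_level <- factor(tbl$fixed_level)
  tbl
}

#' @rdname write_phenotypes
#' @export
write_architecture <- function(arch, path) {
  readr::write_csv(tibble(locus_id = arch$locus_ids,
                          delta = arch$qtl_indicator,
                          alpha = arch$qtl_effects), path)
  invisible(path)
}

fixed_design_matrix <- function(fixed_level) {
  lev <- factor(fixed_level)
  X <- model.matrix(~ lev - 1)
  colnames(X) <- levels(lev)
  X
}
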