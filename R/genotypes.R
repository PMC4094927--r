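#' SNP dosage matrix with population labels
#'
#' Container for an individuals-by-loci matrix of additive SNP covariates
#' (counts of the B allele: 0, 1 or 2; fractional values may arise after
#' mean imputation; `NA` marks missing genotypes), together with locus
#' identifiers, individual identifiers and the population (breed) label of
#' each individual.
#'
#' @param values numeric matrix, individuals in rows and loci in columns.
#'   Non-missing entries must lie in `[0, 2]`.
#' @param locus_ids character vector of unique locus identifiers (defaults to
#'   existing column names, else `snp1..snpK`).
#' @param individual_ids character vector of unique individual identifiers
#'   (defaults to existing row names, else `id1..idn`).
#' @param populations factor or character vector giving the population of each
#'   individual; recycled if length 1.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `populations`.
#' @export
genotype_matrix <- function(values, locus_ids = NULL, individual_ids = NULL,
                            populations = "pop1") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    abort("dosage covariates must lie in [0, 2]", class = "bcpi_invalid_genotype")
  }
  if (is.null(locus_ids)) {
    locus_ids <- colnames(values) %||% paste0("snp", seq_len(ncol(values)))
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(values) %||% paste0("id", seq_len(nrow(values)))
  }
  if (anyDuplicated(locus_ids)) {
    abort("locus_ids must be unique", class = "bcpi_invalid_genotype")
  }
  if (anyDuplicated(individual_ids)) {
    abort("individual_ids must be unique", class = "bcpi_invalid_genotype")
  }
  stopifnot(length(locus_ids) == ncol(values),
            length(individual_ids) == nrow(values))
  if (length(populations) == 1L) {
    populations <- rep(populations, nrow(values))
  }
  stopifnot(length(populations) == nrow(values))
  dimnames(values) <- list(individual_ids, locus_ids)
  structure(
    list(values = values, populations = factor(populations)),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$values), " individuals x ",
      ncol(x$values), " loci\n", sep = "")
  cat("populations: ",
      paste(sprintf("%s (%d)", levels(x$populations), table(x$populations)),
            collapse = ", "), "\n", sep = "")
  nm <- sum(is.na(x$values))
  if (nm > 0) cat("missing entries: ", nm, "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$values

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Individual, locus and population accessors
#' @param G a [genotype_matrix]
#' @return character vector of identifiers, or the population factor.
#' @export
locus_ids <- function(G) colnames(G$values)

#' @rdname locus_ids
#' @export
individual_ids <- function(G) rownames(G$values)

#' @rdname locus_ids
#' @export
populations <- function(G) G$populations

#' Subset a genotype matrix by individuals and/or loci
#' @param x a [genotype_matrix]
#' @param i,j row (individual) and column (locus) indices
#' @param ... unused
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  genotype_matrix(x$values[i, j, drop = FALSE],
                  populations = x$populations[i])
}

#' Specification of a synthetic multi-population SNP panel
#'
#' Describes a set of populations with allele frequencies diverged from a
#' common ancestral pool, and within-chromosome linkage disequilibrium (LD)
#' between adjacent loci. The generator emulates the structure of a purebred
#' training panel plus purebred and multibreed validation panels: several
#' breeds of unequal size whose allele frequencies drifted apart from shared
#' ancestral frequencies.
#'
#' @param populations named integer vector of population sizes, e.g.
#'   `c(angus = 500, hereford = 120)`.
#' @param K number of loci.
#' @param ancestral_maf_range interval from which ancestral allele frequencies
#'   are drawn uniformly.
#' @param divergence Balding-Nichols drift parameter (a fixation index
#'   F_ST-like quantity) in `[0, 1)` controlling how far each population's
#'   frequencies drift from the ancestral frequency; 0 means no divergence.
#' @param ld_decay correlation of the latent Gaussian field between adjacent
#'   loci on a haplotype, in `[0, 1)`; 0 gives linkage equilibrium. The same
#'   parameter smooths the ancestral allele frequencies along the locus
#'   index, as allele frequencies of markers in linkage disequilibrium are
#'   themselves correlated; the default 0.95 makes flanking markers tag a
#'   masked locus about as well as a dense SNP chip does.
#' @param missing_rate fraction of entries set missing, in `[0, 0.01]`.
#' @param seed integer seed making the draw reproducible.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(populations, K,
                            ancestral_maf_range = c(0.05, 0.95),
                            divergence = 0.03, ld_decay = 0.95,
                            missing_rate = 0, seed = 1L) {
  if (is.null(names(populations))) {
    names(populations) <- paste0("pop", seq_along(populations))
  }
  if (any(populations <= 0) || K <= 0) {
    abort("population sizes and K must be positive",
          class = "bcpi_invalid_spec")
  }
  if (divergence < 0 || divergence >= 1 || ld_decay < 0 || ld_decay >= 1) {
    abort("divergence and ld_decay must lie in [0, 1)",
          class = "bcpi_invalid_spec")
  }
  if (missing_rate < 0 || missing_rate > 0.01) {
    abort("missing_rate must lie in [0, 0.01]", class = "bcpi_invalid_spec")
  }
  stopifnot(length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] <= ancestral_maf_range[2],
            ancestral_maf_range[1] >= 0, ancestral_maf_range[2] <= 1)
  structure(
    list(populations = as.integer(round(populations)) |>
           setNames(names(populations)),
         K = as.integer(K),
         ancestral_maf_range = ancestral_maf_range,
         divergence = divergence, ld_decay = ld_decay,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Simulate a multi-population SNP dosage panel
#'
#' Draws ancestral allele frequencies from `spec$ancestral_maf_range` (each
#' marginally uniform on the range, smoothed along the locus index by an
#' AR(1) latent field with correlation `ld_decay`, since frequencies of
#' linked markers are themselves correlated), diverges them per population
#' with a Balding-Nichols beta draw (`Beta(p(1-F)/F, (1-p)(1-F)/F)` with
#' `F = divergence`), and generates two haplotypes per individual with
#' first-order dependence along the locus index: each haplotype is thresholded
#' from a latent AR(1) Gaussian field with autocorrelation `ld_decay`, so the
#' marginal allele frequency at every locus is exact while adjacent loci are
#' correlated. Genotype dosage is the sum of the two haplotypes. With
#' `ld_decay = 0` genotypes are independent Binomial(2, p) draws
#' (Hardy-Weinberg proportions).
#'
#' @param spec a [population_spec].
#' @return A [genotype_matrix] with `sum(sizes)` rows and `K` columns.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  K <- spec$K
  rho <- spec$ld_decay
  up <- numeric(K)
  up[1] <- rnorm(1)
  if (K > 1) {
    for (j in 2:K) up[j] <- rho * up[j - 1] + sqrt(1 - rho^2) * rnorm(1)
  }
  p_anc <- spec$ancestral_maf_range[1] +
    diff(spec$ancestral_maf_range) * pnorm(up)
  blocks <- vector("list", length(spec$populations))
  labels <- character(0)
  for (b in seq_along(spec$populations)) {
    n_b <- spec$populations[b]
    f <- spec$divergence
    if (f > 0) {
      shape1 <- p_anc * (1 - f) / f
      shape2 <- (1 - p_anc) * (1 - f) / f
      p_b <- rbeta(K, shape1, shape2)
    } else {
      p_b <- p_anc
    }
    # two haplotypes per individual; latent AR(1) Gaussian thresholded at
    # qnorm(p) keeps marginal freq exact while inducing adjacent-locus LD
    n_hap <- 2L * n_b
    u <- matrix(0, n_hap, K)
    u[, 1] <- rnorm(n_hap)
    if (K > 1) {
      innov_sd <- sqrt(1 - rho^2)
      for (j in 2:K) {
        u[, j] <- rho * u[, j - 1] + innov_sd * rnorm(n_hap)
      }
    }
    hap <- sweep(u, 2, qnorm(p_b), "<") + 0
    blocks[[b]] <- hap[seq_len(n_b), , drop = FALSE] +
      hap[n_b + seq_len(n_b), , drop = FALSE]
    labels <- c(labels, rep(names(spec$populations)[b], n_b))
  }
  values <- do.call(rbind, blocks)
  if (spec$missing_rate > 0) {
    n_miss <- round(spec$missing_rate * length(values))
    if (n_miss > 0) {
      idx <- sample.int(length(values), n_miss)
      values[idx] <- NA_real_
    }
  }
  genotype_matrix(values,
                  locus_ids = paste0("snp", seq_len(K)),
                  individual_ids = paste0(labels, "_", stats::ave(
                    seq_along(labels), labels, FUN = seq_along)),
                  populations = labels)
}

#' Replace missing dosages with the locus mean
#'
#' Each missing entry is replaced by the mean of the non-missing covariates at
#' that locus; non-missing entries are unchanged, so the per-locus mean
#' covariate is preserved.
#'
#' @param G a [genotype_matrix].
#' @return A [genotype_matrix] with no missing values.
#' @export
impute_missing <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  values <- G$values
  miss <- is.na(values)
  if (!any(miss)) return(G)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing)) {
    abort(paste0("cannot impute fully missing locus: ",
                 paste(colnames(values)[all_missing], collapse = ", ")),
          class = "bcpi_unimputable_locus")
  }
  col_means <- colMeans(values, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  values[miss] <- col_means[idx[, 2]]
  genotype_matrix(values, populations = G$populations)
}

#' Per-locus B-allele frequency estimates
#' @param G a [genotype_matrix] (imputed).
#' @return numeric vector `mean(z_j)/2` per locus.
#' @export
allele_freq <- function(G) {
  colMeans(G$values, na.rm = TRUE) / 2
}

#' Mean heterozygosity of a SNP panel
#'
#' Computes the mean across loci of `2 p (1 - p)` with `p` the sample B-allele
#' frequency, i.e. the expected heterozygosity under Hardy-Weinberg
#' proportions, written `2 p-bar q-bar`. This statistic scales the total
#' genetic variance into a per-QTL substitution-effect variance in the trait
#' simulator and the effect-variance prior.
#'
#' @param G a [genotype_matrix], imputed (no missing values).
#' @return scalar in `[0, 0.5]`.
#' @export
mean_heterozygosity <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (length(G$values) == 0) {
    abort("empty genotype matrix", class = "bcpi_empty_matrix")
  }
  p <- allele_freq(G)
  mean(2 * p * (1 - p))
}
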