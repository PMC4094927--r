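#' Remove QTL columns from a marker panel
#'
#' Returns the genotype matrix without the columns the architecture sampled
#' as QTL, emulating analysis with a realistic panel in which the causal loci
#' themselves are not among the fitted markers. Locus IDs are preserved so
#' fitted effects align with validation panels.
#'
#' @param G a [genotype_matrix].
#' @param arch a [trait_architecture] drawn for the same loci.
#' @return A [genotype_matrix] with the QTL columns removed.
#' @export
mask_qtl_panel <- function(G, arch) {
  stopifnot(inherits(G, "genotype_matrix"),
            inherits(arch, "trait_architecture"))
  qtl_ids <- arch$locus_ids[arch$qtl_indicator == 1L]
  if (length(qtl_ids) == 0L) return(G)
  keep <- !(locus_ids(G) %in% qtl_ids)
  G[, keep]
}

# counter-based seed split: adding scenarios never perturbs earlier draws,
# and every derived seed stays below 2^31
derive_seed <- function(master, replicate, stage) {
  as.integer((as.double(master) * 1009 + replicate * 97 + stage) %% 2147483629)
}

sigma_g2_for_h2 <- function(h2) {
  # design values: 0.12, 0.33 and 1 give expected heritabilities of about
  # 0.10, 0.25 and 0.50 with residual variance 1
  lookup <- c("0.1" = 0.12, "0.25" = 0.33, "0.5" = 1)
  key <- as.character(h2)
  ifelse(key %in% names(lookup), unname(lookup[key]), h2 / (1 - h2))
}

#' Configuration of a replicated factorial simulation study
#'
#' Describes the full design: the synthetic genotype panel (one training
#' breed providing the training pool and a purebred validation subset, plus
#' further breeds forming the multibreed validation set), the factorial of
#' heritabilities, training sizes, analysis models and category counts, the
#' number of replicates, and chain settings. Genotypes are generated once
#' and fixed across replicates; the fixed effects, QTL positions and
#' substitution effects are resampled independently in each replicate.
#'
#' @param spec a [population_spec]; the first population is the training
#'   breed and must be at least `max(train_sizes) + n_pv` individuals. Its
#'   last `n_pv` individuals form the purebred validation (PV) subset, which
#'   together with all remaining populations forms the multibreed validation
#'   (MV) set.
#' @param n_pv number of training-breed individuals reserved for validation.
#' @param heritabilities design heritabilities on the liability scale.
#' @param train_sizes training-set sizes, drawn without replacement from the
#'   training pool.
#' @param category_counts numbers of ordinal categories analysed.
#' @param models any of `"linear_liability"` (linear model on the simulated
#'   underlying variable), `"threshold"` (threshold model on scores),
#'   `"linear_scores"` (linear model treating scores as continuous).
#' @param replicates replicates per scenario.
#' @param pi_sim probability that a locus is not a QTL in the simulation.
#' @param chain an [mcmc_config]; its seed is overridden per fit.
#' @param master_seed master seed from which all per-replicate seeds derive.
#' @param null_trait simulate phenotypes with all QTL effects zeroed (pure
#'   noise response) while keeping the drawn architecture as the truth that
#'   GEBV are validated against.
#' @param output_dir optional directory for per-replicate CSVs (enables
#'   resuming) and aggregated tables.
#' @return An object of class `study_config`.
#' @export
study_config <- function(spec, n_pv,
                         heritabilities = c(0.10, 0.25, 0.50),
                         train_sizes = c(1000, 2250),
                         category_counts = c(2, 3, 4),
                         models = c("linear_liability", "threshold",
                                    "linear_scores"),
                         replicates = 32, pi_sim = 0.999,
                         chain = mcmc_config(), master_seed = 1L,
                         null_trait = FALSE, output_dir = NULL) {
  stopifnot(inherits(spec, "population_spec"), inherits(chain, "mcmc_config"))
  models <- match.arg(models, several.ok = TRUE)
  if (spec$populations[1] < max(train_sizes) + n_pv) {
    abort("first population must cover max(train_sizes) + n_pv individuals",
          class = "bcpi_invalid_config")
  }
  structure(list(spec = spec, n_pv = as.integer(n_pv),
                 heritabilities = heritabilities,
                 train_sizes = as.integer(train_sizes),
                 category_counts = as.integer(category_counts),
                 models = models, replicates = as.integer(replicates),
                 pi_sim = pi_sim, chain = chain,
                 master_seed = as.integer(master_seed),
                 null_trait = isTRUE(null_trait),
                 output_dir = output_dir),
            class = "study_config")
}

#' Desk-scale study configuration
#'
#' A reduced-size default for running the full factorial on a single CPU in
#' minutes rather than days: 2000 loci, a training breed of 650 (training
#' pool 500 + 150 PV) and three further breeds of 100 each (MV = 450), an
#' expected 50 QTL (`pi_sim = 0.975`), and a 1000 + 5000 cycle chain.
#'
#' @param ... overrides passed to [study_config()].
#' @param K number of loci.
#' @param seed genotype seed.
#' @export
desk_study_config <- function(..., K = 2000, seed = 1L) {
  spec <- population_spec(
    populations = c(angus = 650, breed_b = 100, breed_c = 100, breed_d = 100),
    K = K, divergence = 0.1, seed = seed)
  defaults <- list(spec = spec, n_pv = 150L,
                   train_sizes = c(250L, 500L),
                   replicates = 10L, pi_sim = 1 - 50 / K,
                   chain = mcmc_config(n_iter = 5000, burn_in = 1000),
                   master_seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(study_config, args)
}

#' Run a replicated factorial genomic-prediction study
#'
#' For each replicate: draw a fresh trait architecture and fixed effects per
#' heritability, simulate liabilities and ordinal scores for the training
#' pool, remove the QTL columns from the marker panel, fit each requested
#' model at each training size, predict the purebred (PV) and multibreed
#' (MV) validation sets, and compute accuracy, bias slope, `pi` and
#' heritability estimates. Within a replicate all models see identical
#' genotypes, architecture and training/validation splits, so model
#' comparisons are paired. Results are aggregated as mean and standard error
#' across replicates; Spearman rank correlations among the GEBV of
#' alternative models are also reported.
#'
#' @param cfg a [study_config].
#' @param progress print per-replicate progress.
#' @return A list of class `study_result`: `results` (per-replicate long
#'   tibble), `spearman_results` (per-replicate rank correlations), and
#'   aggregated tibbles `accuracy`, `bias`, `pi`, `h2`, `spearman`.
#' @export
run_study <- function(cfg, progress = interactive()) {
  stopifnot(inherits(cfg, "study_config"))
  G <- simulate_genotypes(cfg$spec)
  G <- impute_missing(G)
  breed1 <- names(cfg$spec$populations)[1]
  idx1 <- which(populations(G) == breed1)
  pool_idx <- idx1[seq_len(length(idx1) - cfg$n_pv)]
  pv_idx <- idx1[(length(idx1) - cfg$n_pv + 1):length(idx1)]
  mv_idx <- c(pv_idx, which(populations(G) != breed1))
  G_pool <- G[pool_idx, ]
  G_pv <- G[pv_idx, ]
  G_mv <- G[mv_idx, ]

  out_dir <- cfg$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  rep_results <- vector("list", cfg$replicates)
  rep_spearman <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    res_path <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("replicate_%03d.csv", r)) else NULL
    rho_path <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("replicate_%03d_spearman.csv", r)) else NULL
    if (!is.null(res_path) && file.exists(res_path)) {
      rep_results[[r]] <- readr::read_csv(res_path, show_col_types = FALSE,
                                          progress = FALSE)
      if (file.exists(rho_path)) {
        rep_spearman[[r]] <- readr::read_csv(rho_path, show_col_types = FALSE,
                                             progress = FALSE)
      }
      next
    }
    reprow <- run_replicate(cfg, r, G_pool, G_pv, G_mv)
    rep_results[[r]] <- reprow$results
    rep_spearman[[r]] <- reprow$spearman
    if (!is.null(res_path)) {
      readr::write_csv(reprow$results, res_path)
      if (nrow(reprow$spearman) > 0) readr::write_csv(reprow$spearman, rho_path)
    }
    if (progress) {
      message(sprintf("replicate %d/%d done", r, cfg$replicates))
    }
  }
  results <- dplyr::bind_rows(rep_results)
  spearman_results <- dplyr::bind_rows(rep_spearman)
  agg <- aggregate_study(results, spearman_results)
  out <- structure(c(list(results = results,
                          spearman_results = spearman_results,
                          config = cfg), agg),
                   class = "study_result")
  if (!is.null(out_dir)) {
    readr::write_csv(results, file.path(out_dir, "results_replicates.csv"))
    for (nm in names(agg)) {
      readr::write_csv(agg[[nm]], file.path(out_dir, paste0("table_", nm, ".csv")))
    }
  }
  out
}

# one replicate of the factorial; paired across models within replicate
run_replicate <- function(cfg, r, G_pool, G_pv, G_mv) {
  rows <- list()
  rhos <- list()
  chain <- cfg$chain
  scen <- 0L
  for (h2 in cfg$heritabilities) {
    sg2 <- sigma_g2_for_h2(h2)
    arch <- sample_architecture(G_pool, pi_sim = cfg$pi_sim, sigma_g2 = sg2,
                                seed = derive_seed(cfg$master_seed, r,
                                                   round(h2 * 1000)))
    arch_pheno <- arch
    if (cfg$null_trait) arch_pheno$qtl_effects[] <- 0
    pheno <- simulate_phenotypes(G_pool, arch_pheno,
                                 seed = derive_seed(cfg$master_seed, r,
                                                    round(h2 * 1000) + 1L))
    panel_pool <- mask_qtl_panel(G_pool, arch)
    panel_pv <- mask_qtl_panel(G_pv, arch)
    panel_mv <- mask_qtl_panel(G_mv, arch)
    g_true <- list(PV = true_merit(G_pv, arch), MV = true_merit(G_mv, arch))

    for (n_train in cfg$train_sizes) {
      sub_seed <- derive_seed(cfg$master_seed, r, round(h2 * 1000) + 2L +
                                match(n_train, cfg$train_sizes))
      set.seed(sub_seed)
      take <- sort(sample.int(nrow(G_pool$values), n_train))
      G_tr <- panel_pool[take, ]
      ph_tr <- pheno[take, ]
      gebvs <- list()  # keyed by model/ncat for rank correlations

      for (model in cfg$models) {
        cats <- if (model == "linear_liability") NA_integer_
                else cfg$category_counts
        for (ncat in cats) {
          scen <- scen + 1L
          cfg_fit <- chain
          cfg_fit$seed <- derive_seed(cfg$master_seed, r, 10000L + scen)
          fit <- tryCatch(
            fit_one(model, ncat, ph_tr, G_tr, cfg_fit,
                    sigma_g2 = sg2, pi_sim = cfg$pi_sim),
            error = function(e) {
              warn(sprintf("replicate %d scenario %s/%s failed: %s",
                           r, model, ncat, conditionMessage(e)))
              NULL
            })
          if (is.null(fit)) next
          key <- paste0(model, if (!is.na(ncat)) paste0("_c", ncat))
          for (val in c("PV", "MV")) {
            panel_val <- if (val == "PV") panel_pv else panel_mv
            gh <- gebv(panel_val, fit)
            gebvs[[paste0(key, "__", val)]] <- gh
            labels <- if (val == "PV") populations(G_pv) else populations(G_mv)
            acc <- tryCatch(
              as.numeric(pooled_accuracy(g_true[[val]], gh, labels)),
              error = function(e) NA_real_)
            slope <- tryCatch(bias_regression(g_true[[val]], gh),
                              error = function(e) NA_real_)
            rows[[length(rows) + 1L]] <- tibble(
              replicate = r, h2 = h2, n_train = n_train,
              model = model, ncat = ncat, validation = val,
              n_val = length(gh), accuracy = acc, bias_slope = slope,
              pi_mean = fit$pi_mean, h2_mean = fit$h2_mean,
              mh_acceptance = fit$mh_acceptance)
          }
        }
      }
      # Spearman rank correlations among alternative predictors, per c
      for (ncat in cfg$category_counts) {
        for (val in c("PV", "MV")) {
          con <- gebvs[[paste0("linear_liability__", val)]]
          th <- gebvs[[paste0("threshold_c", ncat, "__", val)]]
          li <- gebvs[[paste0("linear_scores_c", ncat, "__", val)]]
          pairs <- list(con_threshold = list(con, th),
                        con_linear = list(con, li),
                        threshold_linear = list(th, li))
          for (pn in names(pairs)) {
            a <- pairs[[pn]][[1]]; b <- pairs[[pn]][[2]]
            if (is.null(a) || is.null(b)) next
            rhos[[length(rhos) + 1L]] <- tibble(
              replicate = r, h2 = h2, n_train = n_train, ncat = ncat,
              validation = val, pair = pn,
              rho = tryCatch(rank_correlation(a, b),
                             error = function(e) NA_real_))
          }
        }
      }
    }
  }
  list(results = dplyr::bind_rows(rows), spearman = dplyr::bind_rows(rhos))
}

fit_one <- function(model, ncat, ph_tr, G_tr, cfg_fit, sigma_g2, pi_sim) {
  # planning values of the effect-variance prior match the generating model;
  # the linear model on scores plans from the score variance instead since
  # its response is not on the liability scale
  pr_liab <- prior_spec(planning_sigma_g2 = sigma_g2, planning_pi = pi_sim)
  pr_score <- prior_spec(planning_pi = pi_sim,
                         planning_h2 = sigma_g2 / (sigma_g2 + 1))
  switch(model,
    linear_liability = fit_bayescpi(ph_tr$liability, ph_tr$fixed_level, G_tr,
                                    model = "linear", prior = pr_liab,
                                    config = cfg_fit),
    threshold = fit_bayescpi(score_column(ph_tr, ncat), ph_tr$fixed_level,
                             G_tr, model = "threshold", prior = pr_liab,
                             config = cfg_fit),
    linear_scores = fit_bayescpi(as.numeric(score_column(ph_tr, ncat)),
                                 ph_tr$fixed_level, G_tr,
                                 model = "linear", prior = pr_score,
                                 config = cfg_fit))
}

score_column <- function(pheno, ncat) {
  pheno[[paste0("y", ncat)]]
}

aggregate_study <- function(results, spearman_results) {
  agg_one <- function(col) {
    results |>
      dplyr::group_by(.data$h2, .data$n_train, .data$model, .data$ncat,
                      .data$validation) |>
      dplyr::summarise(n_reps = sum(!is.na(.data[[col]])),
                       "{col}_se" := {
                         x <- .data[[col]][!is.na(.data[[col]])]
                         if (length(x) > 1) sd(x) / sqrt(length(x))
                         else NA_real_
                       },
                       "{col}" := mean(.data[[col]], na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::relocate(dplyr::all_of(c(col, paste0(col, "_se"))),
                      .before = "n_reps")
  }
  sp <- if (nrow(spearman_results) > 0) {
    spearman_results |>
      dplyr::group_by(.data$h2, .data$n_train, .data$ncat, .data$validation,
                      .data$pair) |>
      dplyr::summarise(rho = mean(.data$rho, na.rm = TRUE),
                       .groups = "drop")
  } else tibble()
  list(accuracy = agg_one("accuracy"), bias = agg_one("bias_slope"),
       pi = agg_one("pi_mean"), h2_table = agg_one("h2_mean"),
       spearman = sp)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> ", max(x$results$replicate), " replicates, ",
      nrow(x$accuracy), " aggregated scenarios\n", sep = "")
  print(x$accuracy, n = 20)
  invisible(x)
}
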