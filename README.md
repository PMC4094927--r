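# bcpi

Bayes C-pi whole-genome regression for continuous and **ordered
categorical** traits, with the simulation machinery to quantify how much
genomic-prediction accuracy is lost when a continuous trait is recorded as
ordinal scores (calving difficulty, disease susceptibility, ...), and
whether a liability threshold model recovers part of that loss relative to
naively treating scores as Gaussian.

It is written for quantitative geneticists running genomic
prediction/selection studies: it fits the models, simulates the genotype
panels and traits a replicated study design needs, and produces the
accuracy, bias, rank-correlation and heritability tables such studies
report.

## The model

For a continuous response the linear model is

    y_i = x_i' beta + sum_k z_ik a_k + e_i,   e_i ~ N(0, sigma_e^2),

with z_ik in {0,1,2} the SNP dosage and the Bayes C-pi mixture prior on
marker effects: a_k = 0 with probability pi, a_k ~ N(0, sigma_a^2)
otherwise; pi ~ U(0,1), sigma_a^2 scaled-inverse-chi-square(nu = 4, S_a^2).
For an ordinal score y_i in 1..c the threshold (liability) model puts the
same regression on a latent liability l_i with sigma_e^2 = 1, and

    y_i = j  <=>  tau_{j-1} < l_i <= tau_j,     tau_1 = 0 fixed.

Estimation is by Gibbs sampling with a Cowles-style Metropolis–Hastings
update for the free thresholds. GEBV are `ghat_i = sum_k z_ik ahat_k` with
`ahat_k` posterior means; accuracy is the correlation between GEBV and true
simulated merit, pooled across breeds by degrees of freedom; bias is the
OLS slope of true merit on GEBV.

## Worked example

Simulate a two-breed panel with LD, a 50-QTL trait at heritability 0.5,
score it into 4 categories, fit the threshold model on the QTL-masked
panel, and validate on the held-out animals:

```r
library(bcpi)
spec <- population_spec(c(angus = 650, hereford = 120), K = 1500, seed = 1)
G    <- impute_missing(simulate_genotypes(spec))
arch <- sample_architecture(G, pi_sim = 1 - 50/1500, sigma_g2 = 1, seed = 2)
ph   <- simulate_phenotypes(G, arch, seed = 3)

train <- which(ph$population == "angus")[1:500]
panel <- mask_qtl_panel(G, arch)
fit <- fit_bayescpi(ph$y4[train], ph$fixed_level[train], panel[train, ],
                    model  = "threshold",
                    prior  = prior_spec(planning_sigma_g2 = 1,
                                        planning_pi = 1 - 50/1500),
                    config = mcmc_config(n_iter = 5000, burn_in = 1000,
                                         seed = 4))
fit
#> <bcpi_fit> Bayes C-pi threshold model (4 categories)
#> n = 500, K = 1442 markers; 5000 kept samples (burn-in 1000)
#> pi_hat = 0.94773 (SE 0.00037), sigma_a2 = 0.04336, h2 = 0.523
#> thresholds: 0.000 0.837 1.502 (MH acceptance 0.29)

val <- setdiff(seq_len(nrow(G)), train)
validation_report(G[val, ], arch, fit)   # gebv() aligns loci by ID
#> <validation_report> n = 270
#> pooled accuracy r(g, ghat) = 0.674, bias slope b = 0.924
#> # A tibble: 2 x 6
#>   population     n   cov var_g var_ghat bias_slope
#>   <chr>      <int> <dbl> <dbl>    <dbl>      <dbl>
#> 1 angus        150 0.610  1.22    0.649      0.939
#> 2 hereford     120 0.561  1.17    0.620      0.906
```

`pi_hat = 0.948` says the sampler kept about 5% of the 1442 markers in the
model on average (the trait was simulated with ~3% causal loci plus LD);
`h2 = 0.523` is the posterior-mean liability-scale heritability (design
value 0.50); the recovered threshold gaps (0.84, 1.50) sit near the
generating gaps (0.80, 1.44) after anchoring tau_1 = 0. Validation accuracy
0.674 with bias slope 0.92 (1 = unbiased). `tidy(fit)` returns the
per-marker posterior means and inclusion probabilities, `glance(fit)` the
one-row summary, `autoplot(fit)` the chain traces.

Replicated factorial studies (heritability x training size x model x
category count, paired within replicate) run through
`run_study(desk_study_config(...))` and return Table-style tibbles
(`$accuracy`, `$bias`, `$pi`, `$h2_table`, `$spearman`). A thin CLI over
the same functions lives in `inst/cli/bcpi.R`.

## Package layout

| Where | What |
|---|---|
| `R/genotypes.R`, `R/genotype-io.R` | dosage-panel container, multi-breed LD simulator, imputation, mean heterozygosity, delimited/PLINK-raw IO |
| `R/simulate.R` | trait architectures, liabilities, category mapping/collapsing |
| `R/bayescpi.R`, `R/kernels.R`, `src/bcpi.cpp` | priors, chain settings, the Gibbs/MH sampler and its exposed kernels |
| `R/predict.R` | true merit, GEBV, pooled accuracy, bias slope, rank correlations |
| `R/experiment.R` | QTL masking, study configuration and the replicated study runner |
| `vignettes/bayes-cpi-threshold-model.Rmd` | the methods vignette: model, sampler, simulator, design choices, regime notes |
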