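---
title: "Bayes C-pi regression for continuous and ordered categorical traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayes C-pi regression for continuous and ordered categorical traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcpi)
```

## The problem

Many traits in animal breeding — calving difficulty, disease
susceptibility, reproductive outcomes — are recorded as ordered categorical
scores because scores are cheaper to collect than continuous measurements.
Genomic prediction estimates the effects of tens of thousands of SNP markers
in a *training* population and combines them with the genotypes of
*validation* (selection-candidate) animals into genomic estimated breeding
values (GEBV). Categorising a continuous trait throws away information, so
the accuracy of GEBV for a scored trait is lower than for the underlying
continuous trait; `bcpi` exists to quantify that loss and to compare the two
analysis routes open to a breeder holding scores: a liability threshold
model, or a linear model that pretends the scores are Gaussian.

## The model

All three analyses are Bayes C-pi whole-genome regressions. For a continuous
response $y_i$ (the *linear model*),

$$y_i = \mathbf{x}_i'\boldsymbol\beta + \sum_{k=1}^K z_{ik} a_k + e_i,
\qquad e_i \sim N(0, \sigma_e^2),$$

with $z_{ik} \in \{0,1,2\}$ the B-allele dosage at marker $k$ and one fixed
class effect. Each marker effect has the spike-and-slab mixture prior

$$a_k \mid \pi, \sigma_a^2 =
\begin{cases} 0 & \text{with probability } \pi \\
N(0, \sigma_a^2) & \text{with probability } 1 - \pi, \end{cases}$$

with $\pi \sim U(0,1)$ (started at 0.5), $\sigma_a^2$ scaled-inverse-
$\chi^2(\nu = 4, S_a^2)$, flat priors on $\boldsymbol\beta$, and, in the
linear model, a scaled-inverse-$\chi^2$ prior on $\sigma_e^2$.

For an ordinal score $y_i \in \{1,\dots,c\}$ (the *threshold model*), a
latent liability $l_i$ follows the same regression with $\sigma_e^2$ fixed
at 1, and the score is determined by cut points
$\tau_1 < \dots < \tau_{c-1}$ through
$y_i = j \iff \tau_{j-1} < l_i \le \tau_j$. The first threshold is fixed at
0; together with $\sigma_e^2 = 1$ this identifies location and scale.

### The Gibbs sampler

One sweep updates, in order: the free thresholds (for $c \ge 3$) by a
Cowles-style Metropolis–Hastings step whose acceptance uses the marginal
probability of the observed scores with liabilities integrated out; the
liabilities from their truncated-normal full conditionals; each fixed-effect
level from its normal full conditional; each marker's
(inclusion indicator, effect) pair jointly — the indicator from the prior
odds $[(1-\pi)/\pi]$ times the Bayes factor of $\mathbf{z}_k'\mathbf{r}_k$
under $a_k \sim N(0,\sigma_a^2)$ versus $a_k = 0$, and, if included, the
effect from $N(\mathbf{z}_k'\mathbf{r}_k / C_k,\; \sigma_e^2 C_k^{-1})$ with
$C_k = \mathbf{z}_k'\mathbf{z}_k + \sigma_e^2/\sigma_a^2$; then
$\sigma_a^2$ from a scaled-inverse-$\chi^2$ with $\nu + M^{(t)}$ degrees of
freedom ($M^{(t)}$ = number of markers currently in the model); $\pi$ from
$\mathrm{Beta}(K - M^{(t)} + 1, M^{(t)} + 1)$; and, in the linear model,
$\sigma_e^2$. A working residual is carried through all updates and
refreshed from scratch every 1000 sweeps to bound floating-point drift.

The per-locus joint (indicator, effect) update deserves a note: conditioning
the effect on the *sampled indicator only* (rather than on the current
effect value) is what makes the $\mathrm{Beta}(K-M+1, M+1)$ update for
$\pi$ coherent, and is the standard Bayes C-pi construction. The kernels
are exposed individually (`sample_beta()`, `sample_locus()`,
`sample_sigma_a2()`, `sample_pi()`, `sample_liabilities()`,
`sample_thresholds()`, `sample_sigma_e2()`) so each full conditional can be
verified against closed forms, exact enumeration, grid integration or
rejection sampling — the test suite does exactly that.

### Numerical choices

* Truncated-normal draws use the inverse-CDF method with the uniform draw
  clamped away from 0 and 1; a sampled liability is clamped strictly inside
  its category interval.
* The Metropolis–Hastings proposal scale starts at 0.05 and is adapted every
  50 burn-in iterations toward a 20–50% acceptance rate, then frozen, so
  detailed balance holds for every kept sample.
* Thresholds are initialised at the normal quantiles of the observed
  cumulative category frequencies (shifted so $\tau_1 = 0$); liabilities at
  their category midpoints; effects at zero; $\sigma_a^2$ at its prior mode;
  $\pi$ at 0.5.
* Markers are updated in fixed ascending order each sweep, for exact
  reproducibility of chains given a seed.
* Dosage covariates are used raw (0/1/2), not centred: the regression
  absorbs the allele-frequency means into the fixed effects.
* A liability exactly equal to a threshold belongs to the lower category
  (half-open intervals); a probability-zero event fixed for determinism.

### Priors and planning values

The prior scale for the marker-effect variance is derived from *planning
values* as
$S_a^2 = \sigma_g^2 (\nu - 2) / (K (1-\pi_0) \, 2\bar p \bar q \, \nu)$,
where $2\bar p\bar q$ is the panel's mean heterozygosity: if roughly
$K(1-\pi_0)$ markers share the genetic variance $\sigma_g^2$, each needs
variance $\sigma_g^2 / (K(1-\pi_0) 2\bar p\bar q)$, and the scale makes the
prior mean of $\sigma_a^2$ match it. The defaults plan with
$\pi_0 = 0.999$; analyses of simulated data should pass the simulation's
own $\sigma_g^2$ and $\pi$ as planning values. In the linear model the
residual-variance prior scale defaults to
$\mathrm{var}(y)(1 - h_0^2)(\nu_e - 2)/\nu_e$ (prior mean matches the
planning residual variance, $h_0^2 = 0.5$ by default); the model is told
nothing else about the data.

### Heritability estimator

Per kept iteration the genetic variance is the sample variance across
training individuals of the fitted genetic values
$g_i^{(t)} = \sum_k z_{ik} a_k^{(t)}$, and
$h^{2(t)} = \sigma_g^{2(t)} / (\sigma_g^{2(t)} + \sigma_e^{2(t)})$ with
$\sigma_e^{2(t)} = 1$ in the threshold model. This realized-variance
convention is the one genomic-prediction software customarily reports; it
is upward-biased when the model overfits (small $n/K$) and downward-biased
when signal is missed, which is visible in the study tables.

## The simulator

### Genotypes

`simulate_genotypes()` emulates the structure the study design needs —
several breeds with divergent allele frequencies, within-chromosome LD, a
purebred training pool with a purebred validation subset, and a multibreed
validation set — with the smallest model that has those features:

* ancestral allele frequencies marginally uniform on a range, smoothed
  along the locus index by an AR(1) latent field (frequencies of linked
  markers are themselves correlated);
* per-breed frequencies from a Balding–Nichols
  $\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ draw around the ancestral
  frequency, $F$ = `divergence` (defaults to 0.1 in the study
  configurations, the order of $F_{ST}$ among beef breeds);
* haplotypes thresholded from a latent AR(1) Gaussian field with
  autocorrelation `ld_decay` (default 0.95), so marginal frequencies are
  exact while adjacent loci are correlated; dosage = sum of two haplotypes.

With the defaults, the best flanking marker tags a masked locus at
$r^2 \approx 0.5$, comparable to a dense SNP chip. What the generator does
*not* emulate: pedigree relatedness within and across the training and
validation sets, breed-specific LD phase beyond what frequency divergence
induces, mutation/selection history, and chip ascertainment bias. Real-data
accuracies lean heavily on family structure, so passing desk-scale tests
says the *method* ranks and calibrates correctly under the stated
conditions, not that any particular accuracy value transfers to field data.

### Traits

`sample_architecture()` draws each locus as a QTL with probability
$1-\pi_{sim}$ ($\pi_{sim} = 0.999$ at full scale, scaled so the expected
QTL count stays near 50 at desk scale), effects
$\alpha_j \sim N(0, \sigma_g^2 / (K(1-\pi_{sim}) 2\bar p\bar q))$, a
three-level fixed class effect from the standard normal, and
$\sigma_e^2 = 1$, so $\sigma_g^2 \in \{0.12, 0.33, 1\}$ give design
heritabilities 0.10, 0.25, 0.50. Liabilities are mapped to four categories
through thresholds $(0.61, 1.41, 2.05)$ — category frequencies 73/19/6/2%,
as observed for calving scores — and collapsed to three ($\{1\},\{2,3\},
\{4\}$) and two ($\{1\},\{2,3,4\}$) categories. Fixed effects, QTL and
effects are redrawn independently in each replicate; genotypes are fixed
across replicates within a study.

## Validation statistics

Accuracy is the correlation between GEBV and *true simulated genomic merit*
(not phenotype). In multibreed validation sets the covariance and both
variances are computed within breed and pooled with degrees-of-freedom
weights $(n_b - 1)$ before forming the correlation, so breed-mean
differences do not inflate the correlation; the per-breed breakdown is
always emitted so other poolings can be recomputed. Bias is the OLS slope
of true merit on GEBV (1 = unbiased), computed over the whole validation
set. Spearman rank correlations compare the GEBV of alternative analyses.

## The study runner

`run_study()` executes the factorial (heritability × training size × model
× category count) with paired replicates: within a replicate every model
sees identical genotypes, architecture and training/validation splits. All
seeds derive from a master seed through a counter-based split, so re-running
a study is bit-identical and adding scenarios never perturbs existing
replicates. Failed fits (e.g. a training draw in which a category is
unobserved) are logged and the scenario aggregates over surviving
replicates.

## Desk-scale behaviour and regime notes

The shipped desk configuration (`desk_study_config()`: $K = 2000$, training
pool 500 + 150 purebred validation, three further breeds of 100, ~50 QTL,
chain 1000 + 5000) runs the full factorial in minutes on one CPU. Three
regime effects are worth knowing:

* **Tail-category occupancy.** With frequencies 73/19/6/2 the top category
  holds only $\sim 0.02 n$ records. Below roughly $n = 500$ the threshold
  model's advantage over the linear model on scores disappears and can
  reverse (at $n = 250$ only ~4 records support the top threshold); the
  directional model-comparison checks therefore use training sizes 500 and
  1000, matching the occupancy of the full-scale design (its smallest
  training set, 1000, keeps ~20 top-category records).
* **Direction of the $\pi$ trend.** When the trait is effectively polygenic
  relative to what $n$ can resolve, growing $n$ supports more markers and
  $\hat\pi$ drifts down — the trend reported at full scale. With a very
  sparse simulated truth the direction reverses: small-$n$ overfitting
  includes spurious markers and $\hat\pi$ climbs toward the true $\pi$ as
  $n$ grows. The trend test runs in the polygenic regime.
* **Spurious inclusion under the uniform $\pi$ prior.** Integrating the
  uniform prior on $\pi$ makes the prior on $M^{(t)}$ uniform over
  $0..K$, which is permissive: on a pure-noise trait with a strongly
  LD-correlated panel the chain still averages a few dozen included markers
  at $K = 1000$, $n = 500$. Parameter-recovery checks therefore use a
  linkage-equilibrium panel, where the Occam factor dominates and
  $\hat\pi > 0.99$ on noise.

Problem sizes used by the test suite and the acceptance script —
$K = 1000$, training 500–1000, 6–20 replicates, chains of 1000 + 5000
cycles — were chosen as the smallest sizes at which these regimes are
cleanly separated; full-scale settings (53k markers, 45k cycles, 32
replicates) are reached by passing larger values to the same functions.

## Known limitations

* No pedigree/family structure in the generator; no breed-specific LD phase.
* No BayesA/B/LASSO alternatives; single-trait, additive effects only.
* Convergence monitoring is limited to traces and Metropolis–Hastings
  acceptance rates.
* The threshold sampler requires every category observed in training; the
  caller is expected to collapse categories otherwise.

## A short example

```{r example, eval = FALSE}
spec <- population_spec(c(angus = 650, hereford = 120), K = 1500, seed = 1)
G <- impute_missing(simulate_genotypes(spec))
arch <- sample_architecture(G, pi_sim = 1 - 50 / 1500, sigma_g2 = 1, seed = 2)
ph <- simulate_phenotypes(G, arch, seed = 3)

train <- which(ph$population == "angus")[1:500]
panel <- mask_qtl_panel(G, arch)
fit <- fit_bayescpi(ph$y4[train], ph$fixed_level[train], panel[train, ],
                    model = "threshold",
                    prior = prior_spec(planning_sigma_g2 = 1,
                                       planning_pi = 1 - 50 / 1500),
                    config = mcmc_config(n_iter = 5000, burn_in = 1000,
                                         seed = 4))
glance(fit)
val <- setdiff(seq_len(nrow(G)), train)
report <- validation_report(G[val, ], arch, fit)  # gebv() aligns by locus ID
glance(report)
autoplot(report)
```
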