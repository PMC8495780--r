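---
title: "Methods: phylogenetic hierarchical models of intestinal allometry"
author: "gutscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic hierarchical models of intestinal allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Fish intestinal morphology — length, diameter, and surface area — reflects a
trade-off between nutrient acquisition and the cost of maintaining a large
organ, and is shaped simultaneously by body size, body shape, diet, and
evolutionary history. Because related species resemble each other,
observations across species are not independent: any comparative analysis
must separate variation that tracks the phylogeny from variation that does
not. This package implements that analysis as a Bayesian phylogenetic
hierarchical regression, together with the trait construction, synthetic
data generation, and posterior summaries around it.

## Traits

Each specimen contributes a standard length SL (cm), an intestinal length
IL (cm), and ten external diameter measurements taken at equal intervals
along the intestine. The mean diameter ID is their arithmetic mean, and the
external surface area is the cylinder approximation

IS = 2 pi r IL = pi ID IL,   r = ID / 2.

IS ignores mucosal folding and sacculation; it is a proxy for absorptive
surface, not a measurement of it. One of {IL, ID, IS} is chosen as the
response; all responses, SL, and body elongation EL (standard length over
maximum body depth) are natural-log transformed.

## The model

For individual *i* of species *j*, with ln y the log trait:

ln y_ij = b0_j + b1 zlnSL̄_j + b2 zTL_j + b3_j (lnSL_ij − lnSL̄_j)
          + b4 zlnEL_j + b5 ST_j + b6 DU_j + b7 ST_j DU_j + e_ij

b0_j = g00 + u_phy_j + u_spp_j,    b3_j = g30 + u_slope_j

- `lnSL̄_j` is the species mean of log standard length (so the deviation
  column sums to zero within species exactly); its slope b1 is the
  *interspecific* allometric exponent.
- b3_j is the *intraspecific* exponent of species j: a mean slope g30 plus
  a species-level random deviation.
- u_phy ~ MVN(0, sigma_phy^2 A) with A the phylogenetic relatedness
  matrix; u_spp ~ N(0, sigma_spp^2) iid; u_slope ~ N(0, sigma_slope^2) iid.
- e_ij ~ Student-t(nu, 0, sigma_resid): heavy-tailed residuals make the
  fit robust to occasional aberrant specimens.

Continuous predictors (z-prefixed) are centered and scaled over
observations, so the intercept is the log trait at the average body size,
trophic level, and elongation for a stomachless, non-durophagous fish, and
slopes are comparable across predictors. The centered size deviation is
*not* rescaled: its slope stays a log-log exponent, comparable to the
isometry values 1 (lengths) and 2 (areas).

### The relatedness matrix

`shared_path_matrix()` returns M[i,j] = shared branch length from the root
to the MRCA of tips i and j — the Brownian-motion trait covariance up to a
rate constant. `to_correlation()` scales per pair, A[i,j] =
M[i,j]/sqrt(M[i,i] M[j,j]), so the diagonal is exactly 1. For ultrametric
trees this equals dividing by tree depth; the per-pair form keeps
non-ultrametric inputs valid. Unit diagonal is what makes sigma_phy^2
commensurable with sigma_spp^2, and hence the heritability well defined.
When a species set comes with several stochastically resolved trees,
`average_correlation()` takes the elementwise mean of the per-tree
correlation matrices (an average of PSD matrices is PSD); a per-tree refit
mode is deliberately not offered.

### Priors

Normal(0, 10) on the intercept and Normal(0, 5) on every other fixed
effect (scales are standard deviations); half-Student-t(3, 0, 2.5) on all
four standard deviations; Gamma(2, 0.1) truncated to nu > 1 on the
degrees of freedom. The deviations u are modeled hierarchically with
priors on their standard deviations (rather than fixed-scale priors on the
deviations themselves); the variance components must exist for the
heritability ratio to be defined. All priors are configurable through
`gut_priors()`.

## Sampling

`sample_posterior()` is a blocked Gibbs/Metropolis sampler written for
this model family:

1. **Gaussian block.** Given the variance parameters and the Student-t
   precision weights, the fixed effects and all species effects are
   jointly Gaussian and are drawn exactly by one Cholesky solve per
   iteration. Species effects are non-centered (u = sigma L'z with A =
   L L'), so near-zero variance components do not freeze the chain.
2. **Scale parameters.** Each sd gets (a) a log-scale random-walk
   Metropolis step against the observation likelihood and (b) an
   interweaving step in the centered parameterization: given the realized
   effects, sigma's conditional depends only on z'z, and an
   inverse-gamma proposal accepted on the half-t prior ratio updates it
   while the effects are held fixed. The pair mixes well whether the
   component is large or nearly zero. Because the two intercept
   components (phylogenetic and non-phylogenetic) are nearly
   exchangeable when the tree signal is weak, a joint antithetic move on
   (log sigma_phy, log sigma_spp) traverses their shared ridge directly.
3. **Residual scale and degrees of freedom.** Updated by random-walk
   Metropolis against the *marginal* Student-t likelihood (weights
   integrated out), after which the weights are redrawn from their exact
   Gamma conditional — a partially collapsed Gibbs step that mixes far
   faster than conditioning on the weights.

Proposal scales adapt toward a 0.44 acceptance rate during warm-up only
(Robbins-Monro), preserving detailed balance afterwards. Chains
initialize at least-squares fixed effects, zero random effects, sd's at
half the residual sd, nu = 30, jittered per chain; a fixed seed
reproduces all draws bitwise. Defaults are 4 chains of 8,000 iterations
with 2,000 warm-up. `convergence_report()` computes rank-normalized
split-R-hat and bulk ESS for every parameter; a fit is flagged converged
when all R-hat <= 1.01 and bulk ESS >= 400, and posterior summaries refuse
to run on a fit that failed the flag unless forced.

In gaussian mode (a switch used by the oracle tests) the t is replaced by
a normal; several closed forms then become available, and the test suite
checks the sampler against a conjugate posterior, an OLS likelihood, a
dense-covariance grid evaluation of the marginal posterior of the
coefficients, and generic multivariate-normal densities.

## Posterior summaries

- **Phylogenetic heritability**: per draw H2 = sigma_phy^2 /
  (sigma_phy^2 + sigma_spp^2 + v_resid), with v_resid = sigma_resid^2
  nu/(nu−2) (draws with nu <= 2 fall back to sigma_resid^2, logged). A
  `denominator = "species"` option restricts the total to the species
  components — the strict Pagel's-lambda reading; the default follows the
  total-variance reading. The choice materially changes the value, which
  is why it is exposed and logged.
- **Bayesian R2**: per draw Var(mu)/(Var(mu) + v_resid) over the fitted
  observations, mu including fixed and all random effects.
- **Species predictions at a standardized size** (default SL = 15 cm):
  the default `mode = "inter"` moves the species along the interspecific
  axis (z-lnSL̄ evaluated at ln 15 through the stored standardization,
  centered deviation 0) — the natural sense in which species of different
  sizes are compared at a common size. `mode = "intra"` instead moves the
  fish along its own random slope. Both are provided because the
  distinction is real and easy to blur.
- **Percent change over a covariate range**: a standardized slope is
  mapped back through the stored sd and exponentiated over the observed
  range, e.g. the percent decrease in intestinal length from the lowest
  to the highest trophic level.
- **Intraspecific scaling report**: per species, the posterior of b3_j
  with 80% and 95% equal-tailed CIs; a *reliability* flag requiring at
  least 10 specimens, a sampled size range covering at least 25% of the
  species' reported maximum size, and a 95% CI above zero; and an
  allometry class against the isometry exponent (1 for length/diameter, 2
  for surface): negative/positive if the CI falls entirely below/above,
  isometric otherwise. All CIs in the package are equal-tailed posterior
  quantiles, not HPD intervals.
- **Sensitivity refits** drop species below a minimum sample size
  (typically 5 and 8) and re-run the entire pipeline.

## Synthetic data

`simulate_dataset()` generates data under exactly the model above: a Yule
(pure-birth) tree rescaled to depth 1; species covariates TL ~
Uniform(2, 4.5), log EL ~ Normal(log 2.5, 0.35), stomach ~
Bernoulli(0.8), durophagy ~ Bernoulli(0.25); per-species sample sizes
uniform on 3–30 (the scale of the motivating dataset: ~142 species,
1,208 individuals); individual sizes lognormal around lognormal species
means; u_phy simulated by Cholesky factorization of the shared-path
matrix (equivalent in distribution to edge-wise simulation and easier to
verify); and Student-t residuals (nu defaults to 10 — finite variance,
visibly heavy tails; a gaussian switch exists for oracle tests). Default
truth values (interspecific slope 0.97, trophic slope −0.38, elongation
slope −0.4, intraspecific slope 1.0, heritability near 0.9) sit in the
realistic regime for reef-fish intestinal traits, so recovery tests
exercise the conditions that matter; they are fixtures, not claims. The
mean diameter follows a simple isometric size rule so specimen tables are
complete; surface area then follows deterministically, so only one trait
carries the full generative structure. Covariates are generated
independently — real trophic level, elongation, and guild membership are
correlated; tests on these data cannot speak to collinearity behavior.

## Numerical choices and test design

- Relatedness matrices are factorized once; if the Cholesky fails, a
  diagonal jitter (default 1e-8, escalating, always logged) is added.
- Species matching is exact string equality after replacing spaces with
  underscores (logged).
- Validation problem sizes: oracle equivalence uses 5 species x 8
  specimens against a 60 x 60 grid; parameter recovery uses 20 datasets of
  60 species x 8 specimens fit with 4 chains x 2,000 iterations (500
  warm-up); heritability limit checks use 80 species x 4. These sizes give
  posterior-summary precision adequate for the tolerances tested while
  keeping the full suite in the tens of minutes.
- The no-signal heritability check averages over five simulations: a
  single tree realization can show spurious phylogenetic signal when the
  iid species effects happen to align with the tree — we verified with an
  exact dense-grid posterior evaluation that one such realization has
  posterior mean H2 ~ 0.24 even with sigma_phy = 0 in the generator, and
  that the sampler reproduces the grid value. The across-simulation mean
  is the estimator the check targets.

## Limitations

- The model family is fixed: one response, the seven fixed-effect terms,
  three random terms, with switches to drop terms. There is no general
  formula interface.
- No tree inference, dating, or name resolution; trees must arrive with
  branch lengths.
- Predictions at a standardized size are coordinates for morphospace
  work; no plotting is provided beyond the exported tables.
- Passing recovery tests on synthetic data shows the machinery is
  self-consistent under its own assumptions; it does not validate the
  assumptions (independent covariates, lognormal sizes, Student-t
  residuals) against any real dataset.
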