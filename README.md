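# ordinalDCM

Diagnostic classification models (DCMs) for **ordinal** item responses.

DCMs are confirmatory latent class models: a Q-matrix declares which of
*K* binary attributes each item measures, and respondents are classified
into one of the 2^K attribute profiles α ∈ {0,1}^K.  Most polytomous
DCMs treat response options as nominal, so every option of every item
needs its own intercept and effect parameters — models too large for
the sample sizes typical of attitude surveys and classroom tests.  This
package implements two parsimonious ordinal alternatives alongside the
nominal baseline:

* **NRDM** — nominal response diagnostic model:
  `P(X_i = m | α) ∝ exp[λ_{0,i,m} + λ_{i,m}' h(α, q_i)]`,
  one intercept and effect vector per non-baseline option.
* **ORDM** — ordinal response diagnostic model, an adjacent-category
  (partial-credit style) constraint:
  `P(X_i = m | α) ∝ exp Σ_{j≤m} [λ_{0,i,j} + λ_i' h(α, q_i)]`,
  one positive effect vector per item, intercepts non-increasing in m.
* **MORDM** — modified ORDM: intercepts decompose as
  `λ_{0,i,m} = λ_{0,i} + λ^v_{0,m}`, with option intercepts shared
  among items measuring the same attribute set (the W-matrix).

On the shipped reference design (8 items, 4 options, 2 attributes) the
three models need **48, 32 and 22** free item parameters.  Order
constraints are enforced by construction through a cumulative
pseudo-parameterization (`λ_{z,m} = λ_{z,1} + λ'_{z,2} + … + λ'_{z,m}`
with sign-constrained increments).

The package covers the full pipeline: design tools
(Q-matrix/W-matrix/profile space/parameter counting), exact probability
kernels, response simulation, Bayesian estimation (blockwise adaptive
Metropolis with N(0, 20) priors and Dirichlet(2) prevalence prior, plus
a deterministic penalized-likelihood fallback), split-chain Rhat and
PSIS-LOO diagnostics, respondent classification with agreement
statistics (Cohen's kappa, RMSD), and a parameter-recovery simulation
harness reporting bias, RMSE and classification accuracy.

## Worked example

```r
library(ordinalDCM)

design <- example_design()      # 8 items, 4 options, K = 2
sapply(c("nrdm", "ordm", "mordm"), count_item_parameters, Q = design)
#>  nrdm  ordm mordm
#>    48    32    22

# simulate 500 respondents from the shipped calibrated ORDM truth
truth <- example_truth("ordm")
dat <- generate_dataset(truth, design, example_prevalence(),
                        N = 500, seed = 1)
fit1 <- fit("ordm", dat, design, sampler_config(seed = 1),
            method = "map")     # method = "mcmc" for the full sampler
fit1
#> DCM fit: ORDM via map
#> log-likelihood at point estimate: -3410.78
#> prevalence: 0.375 0.073 0.112 0.44
#> converged

cl <- classify(dat, fit1$params, fit1$prevalence, design)
table(cl$map_profile)
#> (0,0) (0,1) (1,0) (1,1)
#>   189    50    34   227

# agreement of attribute-1 calls with the generating-parameter calls
orc <- classify(dat, truth, example_prevalence(), design)
agreement(cl$calls[, "A1"], orc$calls[, "A1"], levels = 0:1)
#> Agreement: 484/500 (96.8%), Cohen's kappa = 0.94

rmsd_scores(cl$marginals[, 1], orc$marginals[, 1])   # 0.025
attr(response_option_curves(fit1$params, design, 1), "crossover_option")
#> [1] 1    # masters overtake non-masters from option 1 upward
```

The prevalence estimates sit within sampling noise of the generating
vector (0.351, 0.074, 0.156, 0.419); the crossover summary says that
respondents possessing attribute 1 are more likely than non-possessors
to select option 1 and above on item 1.  (This particular replicate
contains a knife-edge response pattern discussed in the vignette, which
is why attribute-1 agreement is 96.8% rather than ~99%.)

At scale, `run_recovery_study()` replicates the reference simulation
design (R replicates × N = 500, multinomial profiles, truth from the
shipped parameter tables) and reports per-parameter bias/RMSE (the RMSE
uses the stated R−1 divisor), prevalence recovery against both the
generating and realized compositions, and per-attribute classification
accuracy descriptives.

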