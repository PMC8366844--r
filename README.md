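# tpbinom

Hierarchical Bayesian **two-part binomial (TPB)** models for
frequency-of-occurrence data whose outcome is not always reported — built
for multispecies syntheses of plant occurrence in the scat and stomach
contents of obligate carnivores, where many source studies either ignore
plant material or mention it without counting it.

## Who this is for

Ecologists synthesizing frequency-of-occurrence records across published
diet studies (one row per study: `y` of `N` samples contained the item),
where `y` is missing not-at-random in a specific, modelable way: a study
either reports the count, mentions the item without quantifying it, or
says nothing. Dropping unreported records or treating them as zeros
biases every downstream estimate; the TPB likelihood keeps them in.

## The model

Each record `i` (species `j`) has sample size `N_i`, latent occurrence
frequency `p_i`, and a reporting probability ψ:

```
TPB(y_i | N_i, ψ, p_i) = Bernoulli(0 | ψ)                            y_i = NA
                       = Bernoulli(1 | ψ) · Binomial(y_i | N_i, p_i)  y_i ≠ NA
```

Two hierarchical structures sit on the logit scale:

* **Model 1** (species means): `logit(p_i) = α_j + τ_i`,
  `τ_i ~ N(0, θ_j²)` — a per-species record-level overdispersion scale.
* **Model 2** (covariates): `logit(p_i) = α_j + Σ_k β_k X_env[i,k] + τ_i`
  with `α_j = I + Σ_l ε_l X_sp[j,l] + φ_j`, `φ_j ~ N(0, ω²)`. Record-level
  predictors: island, normalized precipitation, max/min temperature,
  NDVI, six season dummies, sample type. Species-level predictors: log
  body mass and phylogenetic eigenvectors (principal coordinates of the
  patristic distance matrix, retained by the broken-stick rule).

Priors: Student-t(3, 0, 5) on intercepts and coefficients,
Exponential(1) on scales, Uniform(0, 1) on ψ. Everything is sampled
jointly by a No-U-Turn Sampler with analytic gradients (compiled);
convergence is judged by rank-normalized split-Rhat ≤ 1.01. Records that
*mention* the item (`y ≥ 1` but uncounted) can be multiply imputed —
uniformly over a 0.01-step frequency grid, or from the record's own
posterior under the non-imputed fit — with replicate posteriors pooled.
Estimates are reported as MAP (KDE mode) with an 89% highest-density
interval and EAP with 95%/90% credible intervals, plus two significance
verdicts: the HDI+ROPE rule (ROPE = [−0.1, 0.1] on the logit scale) and
zero-exclusion of the 95% CI.

## Worked example

Everything runs on synthetic data with known ground truth — no downloads:

```r
library(tpbinom)

truth  <- simulation_truth(n_species = 6, psi = 0.5, seed = 1, n_pv_axes = 2)
design <- diet_design(n_records = 100, n_species = 6, seed = 1)
sim    <- simulate_diet_data(truth, design)
sim
#> Synthetic diet-record bundle: 100 records, 6 species
#>   reported: 60 (psi = 0.50)  mentioned-but-unquantified: 2

fit <- tpb(sim$records, model = 1,
           config = tpb_config(chains = 4, iter = 1500, warmup = 750, seed = 7))
fit
#> Two-part binomial fit (model1)
#>   records: 100  species: 6
#>   draws: 750 iterations x 4 chains
#>   max Rhat: 1.010  divergences: 10  converged: TRUE

species_frequency(fit, sim$records)
#>   species_id n_records n_reported   MAP hdi_lower hdi_upper   EAP ci95_lower ci95_upper
#> 1       sp04        63         44 0.012     0.009     0.015 0.012      0.008      0.016
#> 2       sp01        17          8 0.014     0.005     0.025 0.015      0.005      0.030
#> 3       sp02        15          7 0.005     0.002     0.010 0.006      0.002      0.012
#> 4       sp03         2          1 0.012     0.000     0.095 0.055      0.002      0.436
#> 5       sp06         2          0 0.020     0.000     0.999 0.497      0.000      1.000
#> 6       sp05         1          0 0.021     0.000     0.999 0.485      0.000      1.000
```

The table is the per-species occurrence frequency `plogis(α_j)`: MAP with
89% HDI, EAP with 95% CI. Well-sampled species are pinned tightly (sp04's
true frequency is 0.010; the fit says 0.012 [0.009, 0.015]); species
whose records never report the count (sp05, sp06) correctly show
prior-wide posteriors rather than false zeros. ψ itself is estimated from
the reported/unreported split (`summary(fit, pars = "psi")`).

For the covariate model, pass the species table and `model = 2`
(`summary(fit)` then reports one row per fixed effect with the %HDI-in-ROPE
column and both significance verdicts), and for the imputed variants use
`method = "random"` or `method = "posterior"`. `run_tpb_pipeline()` runs
the full grid — both models × {none, random, posterior} — from a record
CSV, species CSV and Newick tree to summary tables, posterior predictive
checks and a manifest, with every seed derived from one master seed.

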