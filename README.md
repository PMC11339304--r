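# mmtraj: multimorbidity trajectory clustering with dynamic Bayesian network relevance scores

`mmtraj` stratifies a population by the *temporal trajectory of its
disease burden around a target disease* (the motivating application is
major depressive disorder, MDD, coded F32/F33). From long-format
first-onset records (participant, ICD-10 three-character category, onset
age) it

1. discretizes each trajectory into binary indicators over cumulative age
   intervals `[0–20], [0–40], [0–60], [0–70]`, with censoring-aware
   inclusion;
2. estimates, per interval, the posterior probability that each disease is
   **strongly relevant** to the target — a member of the target's Markov
   boundary in an inhomogeneous dynamic Bayesian network — by
   Metropolis-coupled structure MCMC with a BDeu score:

   `P(strongly-relevant(X, Y) | D) = Σ_G P(G | D) · I( X→Y or Y→X or ∃Z: X→Z and Y→Z )`

   where prior-slice variables may only act as parents, with an exact
   DAG-enumeration oracle for small panels;
3. turns relevance scores into per-participant **weighted multimorbidity
   scores**, `score⁽ᵗ⁾(i) = Σ_d I(onset(i,d) ≤ t) · relevance⁽ᵗ⁾(d)`,
   and fits a k-means model (default k = 7) on participants observed
   through the last interval; soft memberships follow
   `likelihood_j = exp(−‖p_i − c_j‖)`, `P_j = softmax(−distance)`,
   `log-odds_j = ln(P_j / (1 − P_j))`, with nearest-centre assignment on
   the observed coordinates for partially observed trajectories. A
   count-based federated fit lets several sites cluster jointly without
   sharing rows;
4. profiles the clusters clinically — posterior-weighted Cox models with
   the duplicated-row design (each participant enters with dummy 1 at
   weight `P_j` and dummy 0 at weight `1 − P_j`), weighted Kaplan–Meier
   curves, and risk-factor regressions on the posterior log-odds with age
   splines (knots at 40 and 60 years) and Bonferroni correction;
5. quantifies module-level **pleiotropy** on an interactome: random walk
   with restart (restart 0.5) from gene evidence scores (−log adjusted
   p), Kneedle knee-point selection of the top genes, spectral-clustering
   modules, and a degree-aware permutation test of the propagated
   target-disease signal;
6. evaluates clustering fidelity under reduced disease sets, with greedy
   forward selection and random/uniform membership null models.

Real cohorts of this kind are access-restricted, so the package ships a
synthetic-cohort generator (`synthetic_config()`, `generate_cohort()`)
with planted ground truth: seven latent trajectory clusters with
age-band-specific onset hazards, a target disease with designated direct
parents, mediated diseases acting only through a mediator, heterogeneous
right-censoring, and covariates. Every downstream stage is tested against
this recoverable truth.

## Worked example

```r
library(mmtraj)

sim   <- generate_cohort(synthetic_config(n_participants = 5000, seed = 1))
panel <- discretize(sim$cohort, time_grid())

rel <- relevance_scores(
  subset_panel(panel, c("F32", paste0("D0", 1:7))),
  target     = "F32",
  covariates = sim$cohort$covariates[c("participant_id", "sex", "income")],
  settings   = mcmc_settings(burn_in = 1e4, n_samples = 5e4, thin = 10, seed = 2),
  provenance = "synthetic")
rel
#> Relevance table (synthetic): 7 diseases x 4 intervals
#>        20    40    60    70
#> D01 0.973 0.762 0.927 0.826
#> D02 1.000 1.000 0.023 0.027
#> D03 0.132 1.000 0.681 0.023
#> D04 0.017 0.000 0.000 0.011
#> D05 0.007 0.000 0.002 0.035
#> D06 0.036 0.026 0.003 0.009
#> D07 0.064 0.009 0.000 0.022

select_diseases(list(rel), cutoff = 0.5)
#> [1] "D01" "D02" "D03"
```

The planted direct parents of the target (D01–D03) exceed the 0.5
selection rule in at least one interval; the mediated diseases (D04, D05)
and the background diseases (D06, D07) do not — the Markov-boundary
posterior separates direct from merely associated comorbidity.

```r
truth_rel <- planted_relevance(sim$truth)
scores <- multimorbidity_scores(subset_panel(panel, rownames(truth_rel)), truth_rel)
fit    <- fit_clusters(scores, k = 7, seed = 3)
fit
#> Trajectory cluster model: k = 7 over 4 intervals
#> fitted on 2016 complete trajectories; inertia 4511; mean silhouette 0.526

mem  <- assign_clusters(scores, fit)   # likelihoods, posteriors, log-odds
keep <- confidence_filter(mem, ages = sim$cohort$covariates$censor_age)
sum(keep)
#> [1] 4965
```

Cluster profiles then come from `weighted_cox()`, `weighted_km()` and
`riskfactor_regression()`; network pleiotropy from `rwr()`,
`select_top_genes()`, `spectral_modules()` and
`module_pleiotropy_test()`; reduced-panel fidelity from
`evaluate_subset()`, `greedy_select()` and `null_performance()`.

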