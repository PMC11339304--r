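---
title: "Methods: multimorbidity trajectory clustering with Markov-boundary relevance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimorbidity trajectory clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtraj)
```

# The problem

Complex diseases such as major depressive disorder (MDD) are heterogeneous
in presentation and comorbidity. `mmtraj` operationalizes one route to
biologically meaningful subtypes: describe each participant not by a
single diagnosis but by the *timing* of the diseases most informative
about the target across the lifespan, and cluster those trajectories.
Two statistical ideas carry the whole pipeline:

* **Strong relevance (Markov-boundary membership).** A disease is strongly
  relevant to the target when it carries information about the target that
  no other variable supplies — a direct (nonmediated) dependence in either
  direction, or an interaction through a shared child. Diseases associated
  with the target only through intermediaries are deliberately discarded,
  concentrating downstream analyses on shared, nonmediated factors.
* **Soft trajectory clustering.** Participants are embedded in a
  low-dimensional space of relevance-weighted disease counts over
  cumulative age intervals, clustered by k-means, and retained as *soft*
  memberships, so that every later analysis can weight by membership
  probability instead of forcing a hard label.

# Trajectory discretization

Onsets are reduced to first onsets per (participant, disease) and coded as
binary indicators over cumulative intervals `[0, e_t]`, default ends
`20, 40, 60, 70` years. The indicator is 1 when the first onset age is
`<=` the interval end — the closed right end matches the interval
notation; whether a boundary onset belongs to the earlier interval is
otherwise arbitrary, and the convention is fixed here once. A participant
enters interval `t` only when their censoring age is at least `e_t`
(complete observation through the interval), so the panel never mixes
observed zeros with unobserved futures. Indicators are therefore
non-decreasing along the interval axis and inclusion is monotone
decreasing — both are asserted as test invariants.

# Strong-relevance estimation

For each interval the package builds an inhomogeneous dynamic Bayesian
network over: the current-slice disease indicators (the target possibly an
OR-composite of several codes, e.g. F32/F33), covariates (sex, household
income) as current-slice nodes, and the previous interval's indicators,
which may act only as parents — no edge may point into the earlier slice.
The posterior probability that disease `X` is strongly relevant to target
`Y` is the structure-posterior expectation of the indicator

> edge X→Y, or edge Y→X, or a common child Z with X→Z and Y→Z.

Structures are scored by the BDeu marginal likelihood (Dirichlet–
multinomial with equivalent sample size `ess`, default 1) under a uniform
prior over valid structures; BDeu with a uniform prior is the standard
default for discrete structure learning, and the equivalent sample size is
configurable. The score is decomposable, so each proposal
re-evaluates a single family, and family scores are memoized by parent-set
bitmask (the compiled sampler therefore supports at most 32 variables).

The sampler is Metropolis-coupled MCMC: by default four chains on a
geometric temperature ladder (ratio 1.5), adjacent-chain swap proposals
every 100 steps, and a symmetric move kernel mixing single-edge toggles
(probability 0.85) with edge reversals (0.15), with validity rejection
(acyclicity, parent limit — default 8 parents per node). The default
settings are sized for production cohorts — a burn-in of 2×10⁶ steps and
10⁷ collected samples; the tests and the acceptance script run
reduced but converged settings (burn-in 10⁴–2×10⁴, 5×10⁴–10⁵ samples) —
problem sizes chosen so the planted effects are decisive, as the margins
in the acceptance output show. Every 10th cold-chain sample is recorded;
convergence is monitored by Geweke z-scores on the indicator traces
(first 10% vs last 50%, AR-spectral variance at frequency zero; |z| ≤ 2
flags convergence, and a constant trace is defined as z = 0).

Two safeguards keep the sampler honest. First, an exact oracle
(`exact_relevance_posterior()`) enumerates all DAGs over up to five
current-slice variables — previous-slice parent subsets are summed
analytically per family — under exactly the same score, prior and
constraints; sampled posteriors must match it within 0.02 on small
panels. Second, with zero data rows every structure ties and the
posterior reduces to a countable fraction of the structure space, which
is asserted directly.

Constant candidate variables (e.g. a disease with no onsets among the
included participants) carry no information and are excluded with a
warning; their relevance is reported as 0.

# From relevance to clusters

Cohort-specific relevance tables are averaged cell-wise across cohorts
with uniform weights (configurable), restricted to diseases available in
every cohort, and diseases are selected when their posterior strictly
exceeds 0.5 in at least one interval of at least one cohort. The
multimorbidity score of participant `i` at interval `t` is the sum of
their cumulative onset indicators weighted by the per-interval relevance
scores — raw, unstandardized, since the membership likelihood is defined
on this score space directly.

k-means (k = 7 by default; the cluster count is a scientific choice to be
revisited per application, supported by the reported silhouette) is fitted
on participants with complete score trajectories, i.e. observed through
the last interval end. Initialization is k-means++ with 50 restarts; the
restart with the lowest inertia wins, and the seed fixes the whole
procedure. If fewer distinct points than `k` exist the fit is flagged
degenerate and centres repeat the distinct points.

Membership of any participant — including partially observed ones — uses
Euclidean distance to the centres on the observed coordinates only,
without rescaling by the number of observed dimensions — the minimal
reading of a nearest-centre rule for partial trajectories; a
per-dimension mean-squared alternative would change only how strongly
early intervals dominate for young participants. Likelihood, posterior (softmax of negative distances,
computed via a log-sum-exp so rows sum to 1 within 1e-9) and posterior
log-odds (computed from the same log-scale quantities so that
`plogis(log-odds)` reproduces the posterior to 1e-9) follow. Argmax ties
break toward the lowest cluster index. The confidence filter excludes
participants under 60 years whose maximum posterior does not exceed 0.25
— young trajectories the model cannot yet place.

The federated fit replaces rows by counts on a shared quantization
lattice (hypercube bins of side `bin_width`); pooled counts feed a
count-weighted k-means on bin midpoints (k-means++ seeding, Lloyd
iterations). Two properties are tested: sites whose pooled counts match a
centralized cohort give the *identical* model, and the centres approach
the centralized fit as `bin_width → 0` (each centre is within
`bin_width·√T` of a centralized centre on well-separated data).

# Cluster profiles

*Disease risk.* For each (cluster, disease) pair a Cox proportional
hazards model on the age axis uses the duplicated-row design: every
participant appears with dummy 1 at weight `P_j` and dummy 0 at weight
`1 − P_j` (weights summing to 1; weights below 1e-12 are dropped).
Covariates default to sex, income and the standardized birth year
((x − mean)/SD). Ties use the Efron approximation;
confidence intervals are Wald on the log scale, with robust (sandwich)
standard errors available via `robust = TRUE` — robustness to the
duplicated design is the reason both are offered, Wald being the default.
With degenerate 0/1 posteriors the fit equals the hard-label Cox model to
1e-8, and with all posteriors 0.5 the dummy carries no information and
the hazard ratio is exactly 1 — both are asserted. P-values are adjusted
by Benjamini–Hochberg within each cohort. Weighted Kaplan–Meier curves
use the same weights through the product-limit estimator and are
invariant to uniform weight rescaling.

*Risk factors.* Per cluster, the standardized posterior log-odds is
regressed on standardized factors: simple mode fits one factor at a time
with sex and a cubic B-spline in age (knots at 40 and 60 years; knots
outside the observed age span are dropped automatically, so a cohort
whose age range admits only one knot still fits); complex mode fits all factors jointly after
k-nearest-neighbour imputation (k = 5, standardized-Euclidean distances
on co-observed coordinates — written in-package since no imputation
library is part of the declared dependency set). Zero-variance factors
are skipped with a warning. Bonferroni correction spans all
factor-by-cluster tests of the call.

# Network pleiotropy

Gene evidence (−log adjusted p-values, normalized to a probability
vector over the seed genes) is propagated by random walk with restart:
the fixed point of `s = r·e + (1 − r)·W s` with column-stochastic `W`
(binary adjacency; isolated nodes keep their own mass via a self-loop so
conservation holds on disconnected graphs), solved by power iteration to
L1 tolerance 1e-10. Restart defaults to 0.5; module statistics are
rank-insensitive to this choice on fixtures (Spearman ≥ 0.9 between
restart 0.3 and 0.7), which is asserted as a test.

Top genes are selected by the Kneedle knee of the sorted score curve
(axes normalized to the unit square; knee = argmax of the chord-minus-
curve difference, accepted only above `sensitivity/(n−1)`; a straight
line has no knee and callers fall back to a configured quantile).
Modules come from normalized-Laplacian spectral embedding (unit
self-loop regularization keeps isolated nodes well-defined) plus k-means
on the row-normalized eigenvectors; the module count defaults to the
largest eigengap capped at √n.

The pleiotropy test compares a module's summed propagated target score
with a null that reassigns seed genes uniformly within logarithmic
(factor-2) degree bins — the degree-aware principle made concrete; the
binning scheme itself is a package choice exposed in code. The
permutation p-value `(1 + #{null ≥ observed})/(B + 1)` respects the
`1/(B+1)` floor. Because propagation is linear in the seed vector, the
module statistic is evaluated through a single adjoint propagation
(`v = u + (1 − r)·Wᵀv`, statistic `r·vᵀe`), making each permutation an
inner product; equality with the direct propagation route is asserted to
1e-8. Under no signal the p-values are uniform (Kolmogorov–Smirnov
check over 1,000 module tests).

# Reduced disease panels

`evaluate_subset()` recomputes scores from a disease subset, reassigns
with the *frozen* full-set centres, and reports accuracy, balanced
accuracy, and the MAE/MSE of the posterior vectors against the full-set
reference, averaged over repeated random participant draws (reference
scale: 10,000 participants drawn 100 times; tests use smaller draws).
The full subset reproduces the reference exactly — identical arithmetic,
so accuracy is exactly 1 and MAE exactly 0. Greedy forward selection
adds, at each step, the disease with the highest accuracy gain, ties
broken by disease-code order; the first pick provably dominates every
singleton (asserted by exhaustive scan), and greedy expansion may be
suboptimal at later steps. The random null draws membership vectors from
the flat Dirichlet — any exchangeable choice yields `1/k` accuracy,
which is the property the tests pin down (14.3% at k = 7); the uniform
null sets all posteriors to `1/k` with a uniform random tie-break for
the hard label.

# The synthetic generator: what it emulates and what it does not

`generate_cohort()` draws, per participant: a latent cluster (default
seven, uniform mixture), a censoring age (uniform 40–90 years), sex
(Bernoulli 0.5), a three-level income category and a birth year. Disease
onsets follow piecewise-constant hazards over the age bands induced by
the time grid, with per-cluster multipliers; first-event times are drawn
by inversion of the cumulative hazard. Three planted mechanisms define
the ground truth:

* **Direct parents** (default D01–D03) multiply the target's hazard by
  `exp(effect_direct)` (default 3-fold) from the moment of their first
  onset.
* **Mediated diseases** (D04, D05) multiply the *mediator's* (D01)
  hazard only; they never touch the target. Conditionally on the
  mediator's exact onset age they are independent of the target — the
  property test stratifies finely on the mediator's onset (5-year bins,
  fixed censoring) and applies a Cochran–Mantel–Haenszel test.
* **Trajectory markers** (T01–T16, four groups of four) have a high
  onset hazard inside one age band, active in cluster-specific band
  patterns, giving seven well-separated mean score trajectories. Marker,
  mediated and mediator hazards are cluster-invariant where needed to
  keep the planted Markov boundary of the target exactly
  {direct parents, covariates}.

Covariate effects apply to the target hazard only (default: sex,
log-hazard 0.4), so covariates are genuine Markov-boundary members the
relevance stage should detect.

What the generator does **not** emulate: a realistic ICD-10 ontology and
disease co-occurrence structure; calendar-time and healthcare-system
effects on ascertainment; chronic-versus-acute distinctions; informative
censoring; genotypes (gene scores are drawn directly, uniform for null
genes and stochastically small for signal genes; the interactome is a
planted-partition graph, not a protein network). Passing tests therefore
demonstrate that the machinery recovers the structures it is designed to
detect under its own assumptions — not that those assumptions hold in any
real cohort.

# Numerical choices and degenerate inputs

* BDeu ess = 1, uniform structure prior; arity inferred from the data
  (minimum 2) so all-zero columns remain binary.
* Sampler RNG is an internal splitmix64 stream fully determined by the
  seed; identical settings give byte-identical traces.
* Posterior/log-odds arithmetic is log-scale throughout (tolerances
  1e-9); RWR converges to L1 1e-10; the exact oracle and the sampler
  share every constraint.
* Empty data: zero rows score 0 (all structures tie); an empty candidate
  set yields an empty trace; an empty trace is an error for
  summarization.
* k-means ties and degeneracies: argmax ties to the lowest index;
  duplicate-point fits flagged degenerate; `k` larger than the number of
  complete rows is an error.
* Kneedle on a flat or linear curve returns "none" (NA) and callers fall
  back to a quantile.
* Problem sizes in tests and the acceptance script (cohorts of
  2,000–20,000; 10⁵-sample chains; B = 199–999 permutations) were chosen
  once as the smallest sizes at which the planted effects are decisive.

# Limitations

Strong relevance is a structural, observational notion: it does not
license causal claims, and latent confounders or selection bias can
promote diseases into the estimated boundary. The BDeu/uniform-prior
choice is a default, not a fitted prior; posteriors are prior-sensitive
at small n. The 32-variable limit of the compiled sampler suits
prevalence-filtered panels per interval, not genome-scale variable sets.
k-means assumes roughly isotropic clusters in score space; the membership
likelihood `exp(−distance)` is a modelling convention, not a fitted
density. The kNN imputer is a pragmatic in-package tool, not a
substitute-quality multiple-imputation procedure.
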