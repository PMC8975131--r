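---
title: "Functional CTBNs: model, learning and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional CTBNs: model, learning and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fctbn)
```

## The model and its assumptions

A functional continuous-time Bayesian network (FCTBN) represents a set
of binary condition nodes evolving as conditional Markov processes in
continuous time. Node x with parents u has, per transition direction,
a conditional intensity that is log-linear in the subject covariates
z ∈ R^m:

log q = z̃·β_baseline + Σ_{k active} z̃·β_k,  with z̃ = (1, z).

The assumptions this encodes:

* **Markov dynamics.** Sojourn times in a joint state are exponential
  with the current total exit rate; intensities are time-homogeneous.
  No semi-Markov sojourns, no time-varying covariates.
* **Multiplicative parent effects.** Each active parent contributes a
  rate *factor* exp(z̃·β_k); parents never interact beyond their
  product. This is what keeps the parameter count at
  n·(m+1)·2·(p+1) (`parameter_count(..., "multiplicative")`) rather
  than n·(m+1)·2·2^p.
* **Binary states downstream.** For a binary node the exit rate from a
  state *is* the single transition rate, so one Poisson regression per
  (node, direction) suffices. The CTMP primitives (`sufficient_stats`,
  `mle_intensities`, `enumerate_joint_states`) stay general-finite-state.
* **Complete observation with right censoring.** Every transition inside
  the observation window is recorded; the final sojourn is censored.
  Censored sojourns contribute exposure (the `q·t_d` term) but no count —
  the standard event-history treatment. Partially observed trajectories
  (EM) are out of scope.

The likelihood decomposes over records d = ⟨z, u, x_i|u, t_d, x_j|u⟩:
during every sojourn *each* node accrues exposure at its active exit
rate, and the transitioning node of a non-censored record adds log q.
Each (node, direction) block is therefore exactly a Poisson regression
with log-exposure offset — which is why `fit_unpenalized` delegates to
IRLS (`glm.fit`) — and the total negative log-likelihood is convex.

## Learning: adaptive group lasso + FISTA

Structure learning adds the penalty Σ_j √k_j · λ · w_j · ‖β_j‖₂ over
the penalized groups. Choices that matter:

* **Groups are (child, parent) pairs across both transition
  directions** (`fista_opts(grouping = "edge")`), so an edge dies as a
  unit; `"direction"` penalizes each direction separately for users who
  want asymmetric edges. Baseline groups are *never* penalized: zeroing
  a parent group removes an edge, zeroing a baseline would destroy a
  node's base rate.
* **Group-size factor √k_j** is the conventional group-lasso size
  correction; the literal-k reading of "group size" is available as
  `group_size = "linear"`.
* **Adaptive weights** w_j = 1/max(‖β̃_j‖, 1e-4) come from the
  unpenalized fit on the standardized scale. The floor (default 1e-4)
  prevents infinite penalties when β̃_j ≈ 0; its exact value is
  uncritical because such groups are zeroed at any λ ≥ 1 anyway.
* **Intercepts of parent groups are penalized** — the parent group *is*
  its full coefficient vector including the rate-ratio intercept.
* **Covariates are standardized internally** (zero mean, unit variance
  over subjects) so the penalty treats slopes comparably; results are
  reported on the original scale. Exact zeros survive the
  back-transformation, so the learned structure is scale-invariant.
* **Solver.** Monotone FISTA (the objective trace never increases,
  which makes it testable) with backtracking line search — the Poisson
  likelihood has unbounded curvature, so no global Lipschitz constant
  exists. Step sizes are re-enlarged by 1/1.5 per iteration so the
  backtracked L can recover. Convergence: relative objective change
  below `tol` (default 1e-7) sustained for `patience` (default 10)
  iterations, capped at 50,000. Divergent extrapolations (non-finite
  objective at the momentum point) restart momentum from the last
  accepted iterate. When an equivalence to the IRLS optimum at λ = 0 is
  asserted numerically we run the solver at tol 1e-10; the default
  stopping rule resolves the objective only to ~1e-7 relative.
* **λ selection.** Subject-level k-fold cross-validation (default 5)
  over the grid {0, 10⁰, …, 10⁶}, scored by held-out negative
  log-likelihood per record; ties break toward the larger (sparser) λ.
  Warm starts run small → large λ along the path.

## GMM sparsification and early stopping

Long solver tails mostly push small coefficients toward zero. The
`fit_sparse` pipeline stops early when the relative objective change
stays below 1e-5 for 50 iterations (the "no significant change"
trigger; both configurable), pools all penalized coefficients, fits a
K = 2 one-dimensional Gaussian mixture (EM, best of 5 seeded restarts,
log-likelihood tolerance 1e-8, variance floor 1e-10), zeroes every
penalized coefficient within ±3σ of the component whose mean is nearest
zero, and runs one refinement pass. K = 2 reflects the expected
null/non-null split; intercepts are included in the pool because they
are penalized coefficients (the alternative — slopes only — is a
one-line change via `pooled_penalized`). With an exact proximal solver
the early-stopped iterate often already carries exact zeros; the GMM
step is then a no-op and the refinement simply certifies convergence —
the invariant worth testing is that the final active set matches the
fully converged run's.

## Exact inference

Queries go through amalgamation: the joint generator over the 2^n joint
states (capped at 4,096; the five-condition case study has 32) with
nonzero rates only between states differing in one node. Distributions
propagate as p(t) = p0·exp(Qt) via `Matrix::expm`, cross-checked in the
tests against an independent uniformization expansion to 1e-8.
`risk_trajectory` sums the propagated mass over condition-present
states. `predict_next_years` uses the *ever-in-year* convention
matching the annual 0/1 coding of `discretize_annual`: the probability
of escaping the condition-absent state set during (y−1, y] is an exact
taboo probability computed from the sub-generator restricted to those
states; for progressive (no-remission) models this coincides with the
endpoint marginal. Predictions propagate from the baseline state only —
conditioning on each intermediate observed year is a variant the
harness does not implement. The "most probable trajectory" of a
condition is reported as its marginal risk curve, which is what a
probability-versus-time plot shows.

## The synthetic-data generator

`generate_cohort` draws covariates (normal or categorical, one-hot
encoded), then samples each subject's trajectory with the Gillespie
scheme: exponential holding time at the total rate, then a categorical
node pick proportional to the rates — exactly two RNG draws per event,
in that order, so runs are reproducible across platforms from one seed.
Trajectories are right-censored at the horizon.

The reference network (`fixture_model`) has five conditions typical of
veteran multimorbidity cohorts (TBI, BaPa, PTSD, Depr, SuAb),
one standard-normal covariate ("age score"), and six true edges.
Baseline acquisition rates are 0.07–0.20 per year, parent hazard ratios
1.8–3.0, covariate effects |β1| ≤ 0.4 — plausible magnitudes for
chronic-condition incidence. The default variant is progressive (no
remission), matching chronic diagnoses; a reversible variant with a
constant remission rate exp(−1.9)/year is shipped for studies of
relapsing conditions. The default study conditions for recovery
experiments are 5,000 subjects followed for 10 years from the
no-condition state (≈ 25,000 records).

What the generator does *not* emulate — and hence what passing recovery
tests do not establish about real cohorts: informative dropout
(censoring is administrative at a fixed horizon), measurement error in
diagnosis dates, realistic demographic marginals and their
correlations, calendar-time effects, and unmodelled confounding between
covariates and intensities.

## Numerical choices and degenerate inputs

* Rates are parameterised on the log scale, so fitted intensities are
  strictly positive; a frozen zero rate exists only via the progressive
  flag (no 1→0 coefficients at all).
* Sufficient-statistics cells with zero exposure are flagged
  inestimable, reported, and excluded — never 0/0.
* `enumerate_joint_states` orders configurations lexicographically by
  node declaration order (first node most significant) and caps the
  count (default 2^16) with an informative capacity error.
* All-zero-rate trajectories yield a single censored record spanning
  the horizon — a valid dataset, not an error.
* Dataset files store numbers with 17 significant digits, making
  write → read → write byte-stable.
* Time is dimensionless; the unit is declared in the dataset metadata
  and never rescaled.

## Problem sizes used by the checks

The shipped checks run at desk scale, chosen to keep the full suite in
a few minutes while leaving comfortable statistical margins: recovery
at n = 5,000 subjects (edge F1 and coefficient RMSE), exact-inference
calibration against 20,000 simulated trajectories (total-variation
tolerance 0.02 ≈ 4× the Monte-Carlo noise floor), sojourn KS tests at
n = 5,000, hazard-ratio recovery at n = 10,000, GMM early-stop
equivalence on 2,000-subject subsets, and a 400-subject held-out AUC.

## Known limitations

* Exact inference only; beyond ~12 nodes the joint state space makes
  amalgamation impractical and approximate schemes would be needed.
* Linear PCA only for covariate compression; kernel variants are not
  provided.
* The learned graph is an association structure under the multiplicative
  parametric model — edges are not causal claims.
* Discrete-time AUC evaluation propagates from the baseline year only;
  per-year re-conditioning on observed states is not implemented.
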