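---
title: "A presence-only joint species distribution model with a shared CAR field and taxonomic background data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A presence-only joint species distribution model with a shared CAR field and taxonomic background data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Global occurrence archives (GBIF and the like) record where organisms were
*seen*, never where they were verifiably absent. A species distribution
model fitted naively to such data confounds two very different processes:
whether a place is ecologically suitable, and whether anyone ever looked
there. `pojsdm` implements a Bayesian hierarchical model that separates the
two for several taxa at once, using only presence records, per-cell
environmental and anthropogenic covariates, and the taxonomic tree itself.

## The model

All quantities live on an areal lattice of `k` cells with binary adjacency
matrix `W`. For taxon `i` at cell `x`:

* **Ecological suitability** —
  `logit P_i(x) = beta_pi' d_e(x) + G(x)`,
  with `d_e` the ecological covariates (intercept included).
* **Sampling effort**, common to all taxa —
  `logit S(x) = beta_s' d_a(x) + G(x)`,
  with `d_a` anthropogenic covariates (road distance, population, land
  use...).
* **Observation probability** — the convex mixture
  `Q_i(x) = alpha_i P_i(x) + (1 - alpha_i) S(x)`, with
  `alpha_i` in `[0, 1]` the taxon's *contribution to ecological
  suitability*; `1 - alpha_i` measures how much of the observed pattern is
  sampling bias. The mixture acts on the probability scale, not on logits.
* **Responses** — `y_i(x) ~ Bernoulli(Q_i(x))` for each taxon and
  `y_c(x) ~ Bernoulli(S(x))` for the complementary (background) response.
* **Shared spatial field** — a single proper conditional autoregressive
  (CAR) field ties everything together:
  `G ~ N(0, Q^-1)`, `Q = tau * (D - lambda * W)`, with `D` the diagonal
  degree matrix. `Q` is positive definite for `lambda` in (0, 1) on a
  connected lattice. Because `G` enters every linear predictor with
  coefficient 1, it acts as the conduit through which taxa inform one
  another and through which observed cells inform unobserved ones.

### The tau parameterisation

We write the CAR precision as `tau * (D - lambda * W)`, so `tau` is a
precision multiplier and `1 / tau` the overall variance of the field
(conditional variances are `1 / (tau * d_k)`). The inverse-gamma prior
(default shape 1, rate 0.01) is placed on the variance `1 / tau`, which is
the same thing as a Gamma(1, 0.01) prior on `tau`; this makes the `tau`
update conjugate. Posterior tables report `tau`; multiply by `-1` powers at
your own risk elsewhere.

### Identification: the complementary sample

With presences only, `S` would be unidentifiable. The package derives an
*informed background* from the taxonomy: given the occurrence records'
classification paths, it builds the taxonomic tree, takes the lowest common
ancestor (LCA) of the taxa of interest, and declares every taxon under that
LCA but outside the taxa-of-interest subtrees (and off the spine joining
them to the LCA) *complementary*. Records of complementary taxa mark cells
that were certainly visited; cells holding only taxa-of-interest records
become *pseudo-absences* of the complementary response (someone sampled,
but recorded none of the background taxa); cells with no records at all are
either missing (policy `"no-information-missing"`) or absences (policy
`"none"`, the regime that assumes the sampling effort is fully known).

One boundary rule deserves a note: when the taxa of interest have an LCA
that is itself a taxon of interest (a single taxon, or a nested set), the
complement under the strict definition is empty. The package then steps up
to the LCA's parent, so the taxon's siblings form the background — this is
the behaviour the worked examples assume (one genus of a family against the
rest of the family), and it is stated here as the package's normative rule.

### Missing data

Missing cell responses are treated as unknowns of the model. For Bernoulli
outcomes, sampling them explicitly and summing them out are exactly
equivalent; the sampler uses the marginal form (a missing cell contributes
no likelihood term), and `impute_missing()` reconstructs the posterior
presence probability of each missing cell from the joint draws of the
latent processes (`Q_i` for a taxon response, `S` for the complementary
response). Through the shared field, those probabilities are informed by
neighbouring cells — the acceptance suite demonstrates the effect by
flipping the neighbours of a masked cell from absent to present and
watching the imputed probability rise.

## Priors and defaults

| parameter | prior | default |
|---|---|---|
| all regression coefficients | Normal(0, `beta_var`) | `beta_var = 100` for normalised covariates (use 1e4 for raw scales) |
| `alpha_i` | Beta(5, 5) | — |
| `lambda` | Beta(5, 5) | keeps the proper-CAR constraint `0 < lambda < 1` |
| `1 / tau` (CAR variance) | Inv-Gamma(1, 0.01) | conjugate Gibbs update |

Covariate normalisation (z-scoring per column) is on by default in
`model_data()`; the wide coefficient priors are calibrated to that scale.

## Posterior computation

The sampler is an adaptive Metropolis-within-Gibbs scheme written in C++:

* single-site random-walk updates of the field `G` (the CAR full
  conditional of `G_k` given its neighbours completes a cheap local
  target), with per-site adapted proposal scales;
* a **level-shift move** `G -> G - c`, all intercepts `-> + c`: every
  linear predictor is invariant, so this move directly resolves the weak
  identifiability between the field's level and the intercepts;
* an **amplitude move** `G -> s G` and an **interweaved rescale**
  `(G, tau) -> (s G, tau / s^2)`. The centred CAR parameterisation has a
  funnel: a momentarily small field drives the conjugate `tau` update to
  very large values, which in turn clamps the site-wise field moves. The
  rescale move keeps `tau * G'(D - lambda W)G` invariant and therefore
  walks along the funnel's axis at likelihood cost only;
* component-wise adaptive random walks plus **joint adaptive-covariance
  blocks** over each taxon's `(beta_pi, logit alpha_i)` — the directions
  that are strongly correlated a posteriori — and over `beta_s`;
* logit-scale random walk for `lambda`, using the spectral identity
  `log det(D - lambda W) = sum(log d) + sum(log(1 - lambda e_j))` with
  `e_j` the eigenvalues of the degree-normalised adjacency (computed once),
  so each proposal costs O(n);
* Gibbs for `tau`.

Proposal scales and covariances adapt only during burn-in (targets 0.44 for
scalar moves, 0.234 for blocks), so the retained chains are valid MCMC. All
randomness flows from R's RNG: a fit is bit-reproducible from its seed.

Correctness was established two independent ways: a *prior-recovery* run
(all responses missing) must reproduce every prior exactly — Beta(5, 5)
for `alpha` and `lambda`, Gamma(1, 0.01) for `tau`, Normal(0, 100) for
coefficients, and the CAR prior for `G` (checked against direct draws) —
and the reduced model (one taxon, `alpha = 1`, background unobserved) must
agree with an independent implementation of Bayesian spatial logistic
regression in JAGS. Both checks live in the test suite.

Default `fit_config()` mirrors a full-scale protocol (4 chains of 35 000
iterations, burn-in 17 500, thinning 35). The test and acceptance runs use
reduced settings (4 x 2000 for the headline recovery run; 2 x 2000
elsewhere) — both are plain configuration, chosen so the whole suite runs
in minutes on one core.

Convergence is judged by split R-hat (< 1.1 per parameter), computed on the
retained draws; effective sample sizes use Geyer's initial-positive-
sequence truncation. A fit that fails the R-hat rule is returned *flagged*
with a warning, never silently. Summary percentiles (2.5 / 50 / 97.5) use
linear interpolation (R's default quantile type 7); the significance flag
marks 95% intervals excluding zero.

## The simulator

`simulate_dataset()` draws from the model's own generative process: exact
sparse-Cholesky draws of the CAR field, standard-normal covariates
(optionally neighbour-smoothed), logistic processes, Bernoulli responses,
and completely-at-random masking of a configurable fraction of cells (a
covariate-dependent missingness option exists for stress tests). Defaults
emulate the study conditions the model targets — lattices of a few hundred
cells, two to three taxa, two covariates per process, mixing weights spread
over (0, 1), strong spatial dependence (`lambda = 0.9`), unit field
precision — at sizes where a fit takes seconds to a minute.

What the simulator deliberately does *not* emulate: record-level noise
(coordinate error, duplicated records, taxonomic misidentification),
non-stationary sampling, and real covariate maps. Passing recovery tests on
simulated data therefore demonstrates the *inferential machinery*, not
robustness to the messiness of real archives.

## Prediction and validation

`posterior_maps()` returns per-cell posterior means and 95% intervals of
every `P_i`, `S` and `Q_i`. Mixtures are computed draw by draw and then
averaged — the mean of mixtures is not the mixture of means, and the test
suite pins this distinction on a two-draw example.

`kfold_auc()` cross-validates at the model's support, the cell: observed
cells are partitioned into `k` seeded folds stratified by their joint
response pattern, each fold is refit with the held-out responses masked as
missing, and held-out cells are scored by their imputed probabilities
(`Q_i` for taxon responses, `S` for the background response). AUC is
computed by the rank statistic with mid-ranks for ties, which the suite
verifies equals trapezoidal ROC integration to 1e-12; both per-fold,
per-response and pooled AUCs are reported, since with several taxa there is
no single canonical aggregation.

## Numerical choices and degenerate inputs

* Cells are half-open rectangles, so boundary points belong to exactly one
  cell; point-in-polygon masking uses cell centroids.
* Rook adjacency is the default; queen is a flag. Isolated cells (degree
  zero) make the proper CAR singular and are rejected with a clear error.
* Degenerate probabilities meeting contradicting observations return a
  `-Inf` log-posterior, never an exception.
* `lambda` is kept strictly inside (0, 1) by its Beta prior and logit-scale
  updates; no further boundary handling is needed.
* Constant (zero-variance) draw vectors define R-hat as exactly 1 (the
  degenerate-but-converged convention) so that fixed parameters do not
  poison convergence summaries.

## Design decisions that were genuinely open

* **Sampler family.** A gradient-based sampler (NUTS) is the obvious
  modern default, but a carefully constructed Metropolis-within-Gibbs
  scheme with the three global moves described above mixes this model well
  at desk scale, is fully self-contained, and is verifiable against exact
  prior recovery — which we considered the stronger correctness argument
  for a from-scratch implementation.
* **Calibration protocol.** The coverage study draws the generating
  parameters from the fitting priors. In that regime 95% posterior
  intervals have exactly nominal coverage when (and only when) the
  inference is implemented correctly, so the pooled binomial check is a
  sharp correctness test rather than a vague benchmark.
* **Fixed-truth recovery.** The headline recovery run fixes
  `alpha = (0.8, 0.5, 0.2)`, `lambda = 0.9`, `tau = 1` and moderate
  coefficients (|beta| <= 1, in line with posterior magnitudes reported
  for normalised covariates in comparable analyses). Two corners of that
  configuration are intentionally hard at this scale, and the suite
  reports them honestly rather than burying them (below).

## Known limitations

* **`lambda` near its prior boundary.** `lambda = 0.9` sits at roughly the
  99th percentile of its Beta(5, 5) prior. A 625-cell lattice observed
  through four Bernoulli responses per cell carries only part of the
  field-smoothness information (the posterior of `lambda` given the *true*
  field covers 0.9 comfortably; given only the binary data it shrinks
  toward the prior). Desk-scale coverage of this particular corner is
  therefore not guaranteed, and the recovery test can fail on `lambda`
  while every other parameter is covered — a prior-likelihood tension, not
  a sampler defect (the same machinery passes exact prior recovery and the
  prior-draw calibration study).
* **Weakly identified taxa.** For a taxon with small `alpha_i`, `P_i` is
  nearly invisible in the likelihood and its coefficients inflate toward
  extreme values that binary-modulate the mixture; credible intervals for
  such coefficients can exclude moderate truths. More cells, more
  informative responses, or a tighter coefficient prior all relieve this.
* **Field on/off geometry.** With weak field signal the posterior
  genuinely supports both a structured field (`tau` near its generating
  value) and a near-zero field (`tau` large, prior-dominated); the
  interweaved rescale move is what lets chains traverse between the two.
  Posterior `tau` intervals can be wide and right-skewed at desk scale.
* The model's support is the cell: nothing below the lattice resolution is
  represented, and aggregation choices (resolution, coarsening of the
  background response) are part of the model, not preprocessing trivia.
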