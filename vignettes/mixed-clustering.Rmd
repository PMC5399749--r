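---
title: "Co-clustering mixed binary and continuous data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-clustering mixed binary and continuous data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixedclust)
```

## The problem and the model

Many integrative analyses describe each entity by a mix of binary and
continuous measurements: a gene by which transcription factors (TFs) bind
its promoter and by its expression across time points; a tumour sample by
which genes are somatically mutated and by the expression of its most
variable genes. `mixedclust` clusters such entities under a joint
probabilistic model: the data are assumed generated from a finite mixture
of `N_m` components, where component `m` has mixing weight `alpha_m`, an
independent Bernoulli parameter `p_mj` for each binary variable and an
independent normal `N(mu_ml, sigma_ml)` for each continuous variable,

$$p(r_i, e_i) \;=\; \sum_{m=1}^{N_m} \alpha_m \prod_{j=1}^{n_r}
  B(r_{ij}; p_{mj}) \prod_{l=1}^{n_e} N(e_{il}; \mu_{ml}, \sigma_{ml}).$$

The assumptions worth stating explicitly:

* **conditional independence within a component** — variables are coupled
  only through cluster membership; there is no covariance between
  continuous variables (diagonal Gaussians) and no direct binary–continuous
  dependence;
* **component-specific noise** — every `sigma_ml` is free, so clusters can
  be tight in some expression dimensions and loose in others;
* **probabilistic tolerance of errors** — a false-positive binding call in
  a cluster with `p_mj` near 1, or a passenger mutation with `p_mj` near
  its background rate, costs likelihood smoothly instead of breaking a hard
  pattern;
* **no missing data** — the model has no missingness mechanism, and inputs
  with missing cells are rejected at load time.

Either block may be empty: dropping the binary block reproduces
expression-only clustering, which is useful as a baseline to show what the
joint model adds.

## Model selection and the search

The number of clusters is unknown, so fitting minimises the penalised
objective $O(L, k) = -2L + k\,\lambda(N)$ over partitions *and* cluster
numbers, where `k = (N_m - 1) + N_m n_r + 2 N_m n_e` counts free
parameters (free mixing weights; one Bernoulli parameter per binary
variable per component; a mean and an SD per continuous variable per
component — `sigma_ml` is indexed per component and per variable, hence
counted free). Supported penalty multipliers: constants in `[1, 5]`
(`lambda = 2` is the standard AIC), `ln N` (BIC), `2 ln ln N`
(Hannan–Quinn) and `1 + ln N` (consistent AIC).

Two likelihoods appear deliberately:

* **during the search**, `L` is the *classification* log-likelihood: each
  entity contributes `log alpha_{z_i} + log f_{z_i}(x_i)` under per-cluster
  maximum-likelihood estimates with `alpha_m = n_m / N`. It is exactly
  updatable from per-cluster sufficient statistics, which makes annealing
  moves cheap;
* **after EM refinement**, the reported log-likelihood is the full mixture
  marginal, which the classification value never exceeds.

The search is Monte-Carlo simulated annealing over hard partitions. Moves
are drawn uniformly among the applicable types — REASSIGN (one entity to
another cluster), SPLIT (a random non-empty bipartition of one cluster),
MERGE (two clusters), NEW (one entity into a fresh singleton) — and
accepted by the Metropolis rule on the objective difference at the current
temperature; the state admitting no move (a single entity) yields a
no-op. Candidates are *evaluated before being applied*: the affected
clusters' statistics are recomputed into scratch buffers, so a rejected
reassign/merge/new costs `O(n_r + n_e)` and a rejected split
`O(size · (n_r + n_e))`, and there is no revert path. Cached totals are
recomputed from scratch at every temperature level to cancel
floating-point drift, and the returned best objective is verified against
a full R-side recomputation (tolerance 1e-6).

Schedule defaults (`anneal_schedule()`): `t_init = 10`, `t_final = 0.01`,
cooling factor 0.95, `50 N` proposed moves per temperature level, early
stop after 20 levels without improving the best state, and 3 restarts with
derived seeds, of which the best result is kept. These are generous
settings chosen so the search attains the exhaustively enumerated global
optimum on problems small enough to enumerate (203 partitions at N = 6,
877 at N = 7) and recovers the generating partition on the calibration
designs below; all are configurable. The initial state assigns entities
uniformly at random to `max(2, N/20)` clusters. Ties between
equal-objective states resolve to the first one encountered, so a fixed
seed gives a fully reproducible trajectory. All randomness flows from R's
RNG seeded per run; consequently results are reproducible per seed, but
the proposal stream is tied to entity order — permuting the input rows
with the same seed can legitimately return a differently-labelled
(equally scored) solution.

## EM refinement

The annealing solution (hard MLEs) seeds a standard EM under the full
mixture likelihood: the E-step computes responsibilities
`gamma_im ∝ alpha_m f_m(x_i)` in log space with log-sum-exp stabilisation,
and the M-step applies the closed-form weighted updates — these are the
unique maximisers of the expected complete-data log-likelihood for this
density family. Convergence is declared when the log-likelihood changes by
less than `tol = 1e-6` (an absolute criterion, matching the monotone
quantity being optimised) or after 500 iterations. The trace must be
non-decreasing within 1e-8; a larger decrease raises an internal error
rather than being silently accepted. Components whose effective count
drops below `1e-6` are removed with a warning (the component count can
only shrink, never grow). In well-separated regimes the refinement barely
moves the annealing estimates — the hard solution is already an
approximate fixed point — which is itself a useful diagnostic.

## Numerical floors and the degeneracy they control

Bernoulli parameters are clamped to `[p_floor, 1 - p_floor]`
(`p_floor = 0.001`) and Gaussian SDs floored at `sigma_floor`, so every
log-density is finite even for pure or singleton clusters.

The SD floor deserves care, because it interacts with model selection.
A Gaussian mixture's likelihood is unbounded at point masses: a singleton
cluster contributes about `-log(sigma_floor)` per continuous variable,
so with a very small floor the penalised objective can be *minimised* by
shattering the data into micro-clusters — the penalty per extra cluster,
`(1 + n_r + 2 n_e) · lambda`, grows linearly in the variable count while
the degenerate likelihood gain grows like `n_e · log(sigma/sigma_floor)`.
With 20 + 20 variables and within-cluster noise `sigma = 0.01`, a floor of
0.001 makes all-singletons beat the generating partition at `lambda = 2`;
a floor of 0.005 (half that noise scale) keeps the generating partition
optimal with a comfortable margin. The default is therefore
`sigma_floor = 0.005`, and the practical guidance is to set the floor to a
modest fraction (about a half) of the smallest noise scale the analysis
should resolve — for heavier-noise data (e.g. the noisy regime below with
`sigma = 0.3`, or z-scored expression) the default is conservative, and
floors far below the noise scale should be avoided with AIC-type
penalties. Variance estimates use the population (divide-by-n) convention
inside likelihood fitting, and the sample (n−1) convention in data
normalisation, matching MLE consistency on one side and conventional
z-scoring on the other.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` reproduce the calibration study the
method was tuned on: equal-size clusters (sizes 10 or 20; 100–1000
points), 20 binary and 20 continuous variables, and two noise regimes —
*tight* (`p ∈ {0.9, 0.1}`, `sigma = 0.01`) and *noisy*
(`p ∈ {0.9, 0.4}`, `sigma = 0.3`). Each component draws a distinct random
binary pattern (each parameter `p_high` or `p_low` with probability 1/2 —
the symmetric default, as only "distinct random patterns" is prescribed)
and means uniform on `[-1, 1]`; with `sigma = 0.01` any order-1 spread
separates clusters, and with `sigma = 0.3` this range produces the
intended partial overlap. Sampling is stratified — exactly `cluster_size`
entities per component, not a multinomial draw — because the design calls
for exactly equal cluster sizes.

What the generator deliberately does **not** emulate: unequal cluster
sizes, correlated continuous variables, batch effects, missingness, or
variables irrelevant to every cluster. Passing recovery tests on this
design therefore demonstrates correctness of the machinery under the
model's own assumptions, not robustness to real-data violations of them.

`recovery_metrics()` scores a fitted partition by the difference in
cluster number and the adjusted Rand index against the generating labels.
On the tight design the pipeline at `lambda = 2` recovers
`delta_k = 0, ARI = 1` across seeds at 100–500 points (the acceptance
script recomputes this); very low penalties (`lambda = 1`) over-split,
and strong penalties (BIC, consistent AIC) collapse to too few clusters —
a failure of the stochastic search on a surface where the likelihood
gives little downhill guidance relative to the penalty, rather than of
the objective itself.

## Data preparation for the two application settings

For regulatory data: binding p-values binarize at `p < 0.001` (strict);
expression rows normalise to zero mean, unit sample SD. TF preselection
asks whether the genes a TF binds are enriched for highly correlated
expression pairs: with `rho` the 95th percentile of Pearson correlations
over *all* entity pairs (computed before any factor-specific subsetting),
the observed proportion of bound-pair correlations above `rho` is compared
with `n_random = 1000` random same-size gene sets (drawn without
replacement), giving the add-one empirical p-value
`(1 + #{random >= observed}) / (1 + n_random)` — never exactly zero, with
the `>=` (conservative) comparison; factors with `p < 0.1` are retained,
factors binding fewer than two entities cannot be evaluated and are
auto-rejected. Entities bound by no retained factor are then dropped.

For mutation data: genes mutated in at least two samples are kept first,
then samples left without any mutation are removed (the order matters and
is fixed). Feature selection ranks expression features by sample SD and by
absolute coefficient of variation, averages the two ranks and keeps the
top `k = 500`; "rank-based" is read as this rank combination (rather than
statistics computed on ranked data), features with near-zero mean take the
maximal CV rank because their CV is unstable, and ties break by SD rank
then column order.

## Reporting

A cluster is *clear* when its members' average pairwise expression
correlation strictly exceeds 0.5 and at least one binary variable has
fitted probability strictly above 0.5. Singletons are never clear — their
average correlation is undefined (and thresholds are strict, so boundary
values fail). Clear clusters yield one network edge per (factor, cluster)
pair with probability above the threshold, written as a three-column TSV
loadable by standard network tools; the mixture parameters serialize to a
long-format table (component, variable, type, param1, param2, plus mixing
rows so the table round-trips).

## Problem sizes used by the tests

The suite exercises the designs at desk scale: oracle agreement at
N = 6–7 (exhaustive enumeration), recovery at 100 and 200 points over ten
seeds, the penalty ladder at 500 points over five seeds, EM monotonicity
over 100 random initialisations, and parameter recovery at 100 points
with clusters of 20. For a size-20 cluster the empirical Bernoulli
proportion has SD ≈ 0.067 at `p = 0.9`, so individual estimates a few
standard errors off are expected by chance when hundreds of parameters
are examined; the calibrated check therefore bounds the *fraction* of
parameters outside the exact-binomial 99.99% envelope rather than
demanding that every estimate land within ~2 standard errors.

## Known limitations

* The conditional-independence assumption ignores covariance among
  continuous variables; strongly co-varying expression within clusters is
  absorbed into inflated `sigma` estimates.
* Ordinal or nominal variables and latent-continuous dichotomisation are
  out of scope.
* Strong penalties (BIC, consistent AIC) are vulnerable to search failure
  on large tight datasets (too few clusters returned); constants near 2
  with a few restarts are the recommended operating point.
* With continuous noise far above `sigma_floor`, AIC-type penalties can
  still favour micro-clusters (see the floors section); choose the floor
  relative to the believed noise scale.
* Preselection p-values are Monte-Carlo estimates; with `n_random = 1000`
  their resolution is about 0.001.
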