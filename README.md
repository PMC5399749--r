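# mixedclust

Model-based co-clustering of entities described by **mixed binary and
continuous variables**. The motivating problems come from molecular
biology: genes characterised by transcription-factor (TF) binding
(binary) together with expression profiles (continuous), or tumour
samples characterised by somatic mutations (binary) together with
expression of the most variable genes. Joint clustering of both data
types finds modules — co-regulated gene sets, or tumour subtypes — that
neither data type reveals alone, and each cluster comes with directly
interpretable parameters (binding/mutation probabilities and a mean
expression pattern).

## The model

N entities carry `n_r` binary variables `r_ij ∈ {0,1}` and `n_e`
continuous variables `e_il`. Their joint density is a finite mixture of
`N_m` components, each a product of independent Bernoulli and univariate
normal terms:

```
p(r_i, e_i) = Σ_m α_m  Π_j B(r_ij; p_mj)  Π_l N(e_il; μ_ml, σ_ml)
```

The number of components and the assignment of entities are selected by
minimising the penalised objective

```
O(L, k) = −2 L + k · λ(N)
```

where `L` is the maximised log-likelihood, `k` the number of free
parameters (`(N_m − 1) + N_m·n_r + 2·N_m·n_e`) and `λ(N)` a penalty
multiplier: a constant in `[1, 5]` (`λ = 2` is the standard AIC), `ln N`
(BIC), `2 ln ln N` (Hannan–Quinn) or `1 + ln N` (consistent AIC).
Optimisation is a Monte-Carlo simulated-annealing search over hard
partitions (reassign / split / merge / new-singleton moves, Metropolis
acceptance, geometric cooling), followed by EM refinement of the
selected solution under the full mixture likelihood. See the methods
vignette (`vignettes/mixed-clustering.Rmd`) for the full account.

## Worked example

Simulate the tight calibration design (100 entities, 10 clusters of 10,
20 binary + 20 continuous variables), cluster with the AIC objective and
refine with EM:

```r
library(mixedclust)

sim    <- simulate_dataset(sim_config(n_points = 100, cluster_size = 10, seed = 7))
search <- anneal(sim$data, penalty_spec("aic"), anneal_schedule(seed = 7))
em     <- run_em(sim$data, search$model)
z      <- posterior_assignments(em$gamma)

search
#> search_result: 10 clusters, objective -10337.64
em
#> em_result: 10 components, log-likelihood 5777.82 (converged)
unlist(recovery_metrics(z, sim$truth))
#> delta_k     ari
#>       0       1
```

The search recovers exactly the 10 generating clusters (`delta_k = 0`,
adjusted Rand index 1). Per-cluster reporting flags *clear* clusters —
average pairwise expression correlation > 0.5 **and** at least one
binary variable with fitted probability > 0.5 — the unit one would read
as a regulatory hypothesis, and exports factor→cluster network edges:

```r
rep <- clear_clusters(em$model, z, sim$data)
rep[1, c("cluster", "size", "avg_pairwise_expression_correlation",
         "max_binding_probability", "is_clear")]
#>   cluster size avg_pairwise_expression_correlation max_binding_probability is_clear
#> 1       1   10                           0.9997384                     0.9     TRUE
nrow(network_edges(rep, em$model, sim$data$binary_names))
#> [1] 95
```

Preprocessing utilities cover the standard preparation steps for real
data: `binarize_binding()` (p < 0.001 calls), `normalize_expression()`
(per-gene z-scoring), `preselect_binary_variables()` (empirical-p TF
preselection against random gene sets), `drop_unbound_entities()`,
`filter_mutations()` (recurrence ≥ 2, remove mutation-free samples) and
`select_variable_features()` (top-k by combined SD/CV rank).

A command-line interface wrapping the same functions is installed at
`inst/cli/mixedclust.R` with subcommands `simulate`, `preselect`,
`cluster`, `refine`, `report` and `pipeline`; all tables are labelled
TSV files.

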