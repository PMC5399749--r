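#' Simulation scenario presets
#'
#' Two noise regimes for the calibration study: `tight` (well-separated
#' clusters: Bernoulli parameters 0.9 / 0.1, Gaussian SD 0.01) and `noisy`
#' (partially overlapping clusters: 0.9 / 0.4, SD 0.3). Cluster means are
#' drawn uniformly from `mu_range`.
#'
#' @param name `"tight"` or `"noisy"`.
#' @param mu_range interval from which Gaussian cluster means are drawn.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(name = c("tight", "noisy"), mu_range = c(-1, 1)) {
  name <- match.arg(name)
  stopifnot(length(mu_range) == 2, mu_range[1] < mu_range[2])
  pars <- switch(name,
    tight = list(p_high = 0.9, p_low = 0.1, sigma = 0.01),
    noisy = list(p_high = 0.9, p_low = 0.4, sigma = 0.3))
  structure(c(list(name = name, mu_range = mu_range), pars),
            class = "sim_scenario")
}

#' Simulation configuration
#'
#' Equal-size clusters: `n_points` must be divisible by `cluster_size`;
#' the number of generating clusters is their ratio. Default variable
#' counts are 20 binary and 20 continuous, matching the calibration-study
#' design.
#'
#' @param n_points number of entities to generate.
#' @param cluster_size size of every generating cluster.
#' @param n_r,n_e numbers of binary / continuous variables.
#' @param scenario a [sim_scenario()] or its name.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_points, cluster_size, n_r = 20, n_e = 20,
                       scenario = "tight", seed = 1L) {
  if (is.character(scenario)) scenario <- sim_scenario(scenario)
  stopifnot(inherits(scenario, "sim_scenario"),
            n_points >= 1, cluster_size >= 1,
            n_r >= 0, n_e >= 0, n_r + n_e >= 1)
  if (n_points %% cluster_size != 0) {
    stop("n_points (", n_points, ") must be divisible by cluster_size (",
         cluster_size, ")")
  }
  structure(list(n_points = as.integer(n_points),
                 cluster_size = as.integer(cluster_size),
                 n_clusters = as.integer(n_points / cluster_size),
                 n_r = as.integer(n_r), n_e = as.integer(n_e),
                 scenario = scenario, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw the generating mixture model for a simulation
#'
#' Each component receives an independent Bernoulli pattern (each of the
#' `n_r` parameters is `p_high` or `p_low` with probability 1/2), Gaussian
#' means drawn uniformly from the scenario's `mu_range`, and the scenario's
#' constant SD. Patterns are redrawn (up to 1000 retries) if two components
#' coincide, so every cluster has a distinct signature. Mixing weights are
#' equal (`cluster_size / n_points`).
#'
#' @param config a [sim_config()]; the draw is seeded by `config$seed`.
#' @return a [mixture_model()] with `config$n_clusters` components.
#' @export
make_true_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config$scenario
  m <- config$n_clusters
  with_seed(config$seed, {
    draw_one <- function() {
      list(p = sample(c(sc$p_high, sc$p_low), config$n_r, replace = TRUE),
           mu = runif(config$n_e, sc$mu_range[1], sc$mu_range[2]))
    }
    comps <- vector("list", m)
    seen <- character(0)
    for (k in seq_len(m)) {
      for (try in seq_len(1000)) {
        cand <- draw_one()
        key <- paste(c(cand$p, round(cand$mu, 6)), collapse = ",")
        if (!(key %in% seen)) break
        if (try == 1000) {
          stop("could not draw ", m, " distinct cluster patterns with n_r = ",
               config$n_r, ", n_e = ", config$n_e)
        }
      }
      seen <- c(seen, key)
      comps[[k]] <- cand
    }
    mixture_model(
      alpha = rep(config$cluster_size / config$n_points, m),
      p = do.call(rbind, lapply(comps, `[[`, "p")),
      mu = do.call(rbind, lapply(comps, `[[`, "mu")),
      sigma = matrix(sc$sigma, m, config$n_e))
  })
}

#' Sample a dataset from a generating model
#'
#' Stratified design: exactly `cluster_size` entities are generated from
#' every component (not a multinomial draw), matching the equal-cluster
#' simulation design. Binary entries are Bernoulli draws, continuous
#' entries normal draws. The sampling stream is seeded with
#' `config$seed + 1` so it is independent of the model draw.
#'
#' @param model a [mixture_model()], typically from [make_true_model()].
#' @param config the matching [sim_config()].
#' @return list with `data` (a [mixed_dataset()]) and `truth` (class
#'   `sim_truth`: `labels`, the generating cluster of each entity, and
#'   `model`).
#' @export
sample_dataset <- function(model, config) {
  stopifnot(inherits(model, "mixture_model"), inherits(config, "sim_config"))
  m <- model$n_components
  if (m != config$n_clusters) {
    stop("model has ", m, " components but config expects ",
         config$n_clusters)
  }
  n <- config$n_points
  cs <- config$cluster_size
  labels <- rep(seq_len(m), each = cs)
  with_seed(config$seed + 1L, {
    R <- if (config$n_r) {
      do.call(rbind, lapply(seq_len(m), function(k) {
        matrix(rbinom(cs * config$n_r, 1, rep(model$p[k, ], each = cs)),
               nrow = cs)
      }))
    } else NULL
    E <- if (config$n_e) {
      do.call(rbind, lapply(seq_len(m), function(k) {
        matrix(stats::rnorm(cs * config$n_e,
                            mean = rep(model$mu[k, ], each = cs),
                            sd = rep(model$sigma[k, ], each = cs)),
               nrow = cs)
      }))
    } else NULL
    data <- mixed_dataset(R = R, E = E,
                          entity_ids = sprintf("e%04d", seq_len(n)))
    list(data = data,
         truth = structure(list(labels = labels, model = model),
                           class = "sim_truth"))
  })
}

#' Generate a simulated dataset in one call
#'
#' @param config a [sim_config()].
#' @return as [sample_dataset()].
#' @export
simulate_dataset <- function(config) {
  sample_dataset(make_true_model(config), config)
}

#' Recovery metrics against the generating partition
#'
#' @param found integer assignment vector from the search/EM.
#' @param truth a `sim_truth` (or an integer vector of true labels).
#' @return list with `delta_k` (found minus true number of clusters) and
#'   `ari` (adjusted Rand index; 1 means identical up to relabelling).
#' @export
recovery_metrics <- function(found, truth) {
  labels <- if (inherits(truth, "sim_truth")) truth$labels else truth
  if (length(found) != length(labels)) {
    stop("found assignment has length ", length(found),
         " but truth has ", length(labels))
  }
  list(delta_k = length(unique(found)) - length(unique(labels)),
       ari = mclust::adjustedRandIndex(found, labels))
}
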