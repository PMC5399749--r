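#' Annealing schedule for the partition search
#'
#' Geometric cooling: the temperature starts at `t_init`, is multiplied by
#' `cooling` after every level of `moves_per_temperature` proposed moves,
#' and the run stops at `t_final` or after `max_no_improve` consecutive
#' levels without improving the best objective. Defaults are generous
#' enough to reach the exhaustively verified global optimum on small
#' problems and to recover the generating partition on the simulation-study
#' designs.
#'
#' @param t_init initial temperature (> 0).
#' @param t_final final temperature (> 0, < `t_init`).
#' @param cooling multiplicative cooling factor in (0, 1).
#' @param moves_per_temperature proposed moves per temperature level;
#'   `NULL` means `50 * N`, filled in by [anneal()].
#' @param max_no_improve stop after this many levels without improvement.
#' @param seed integer seed driving every stochastic choice of the run.
#' @return an object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_init = 10, t_final = 0.01, cooling = 0.95,
                            moves_per_temperature = NULL,
                            max_no_improve = 20, seed = 1L) {
  stopifnot(t_init > 0, t_final > 0, t_final < t_init,
            cooling > 0, cooling < 1, max_no_improve >= 1)
  if (!is.null(moves_per_temperature)) {
    stopifnot(moves_per_temperature >= 1)
  }
  structure(list(t_init = t_init, t_final = t_final, cooling = cooling,
                 moves_per_temperature = moves_per_temperature,
                 max_no_improve = as.integer(max_no_improve),
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

## Runs expr with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Random initial clustering
#'
#' Assigns each entity uniformly at random to one of `k_init` clusters and
#' compacts away any cluster that received no members.
#'
#' @param data a [mixed_dataset()].
#' @param k_init number of initial clusters, `1 <= k_init <= N`.
#' @param seed integer seed (the caller's RNG state is restored).
#' @return integer assignment vector with labels `1..N_m`, `N_m <= k_init`.
#' @export
initialize_clustering <- function(data, k_init, seed = 1L) {
  n <- data$n
  if (k_init < 1 || k_init > n) {
    stop("k_init must be between 1 and the number of entities (", n, ")")
  }
  with_seed(seed, {
    compact_assignment(sample.int(k_init, n, replace = TRUE))
  })
}

#' Propose one random partition move
#'
#' Draws uniformly among the applicable move types: `REASSIGN` (move one
#' entity to another existing cluster), `SPLIT` (random non-empty
#' bipartition of a cluster of size >= 2), `MERGE` (fuse two clusters) and
#' `NEW` (move one entity into a fresh singleton cluster). States admitting
#' no move (a single entity) return the incumbent unchanged with label
#' `NOOP`. Uses the current RNG stream; the incumbent vector is not
#' modified.
#'
#' @param assignment integer assignment vector (labels `1..N_m`).
#' @return list with elements `assignment` (candidate) and `move` (label).
#' @export
propose_move <- function(assignment) {
  n <- length(assignment)
  m <- max(assignment)
  can <- c(REASSIGN = m >= 2, SPLIT = m < n, MERGE = m >= 2, NEW = m < n)
  if (!any(can)) {
    return(list(assignment = assignment, move = "NOOP"))
  }
  pick <- function(x) x[sample.int(length(x), 1)]   # safe for length-1 x
  mv <- pick(names(can)[can])
  z <- assignment
  if (mv == "REASSIGN") {
    i <- sample.int(n, 1)
    while (sum(z == z[i]) == n) i <- sample.int(n, 1)
    z[i] <- pick(setdiff(seq_len(m), z[i]))
  } else if (mv == "SPLIT") {
    sizes <- tabulate(z, m)
    c0 <- pick(which(sizes >= 2))
    members <- which(z == c0)
    pair <- sample(members, 2)            # pair[1] stays, pair[2] moves
    rest <- setdiff(members, pair)
    movers <- c(pair[2], rest[runif(length(rest)) < 0.5])
    z[movers] <- m + 1L
  } else if (mv == "MERGE") {
    ab <- sample.int(m, 2)
    z[z == ab[2]] <- ab[1]
  } else { # NEW
    sizes <- tabulate(z, m)
    i <- sample.int(n, 1)
    while (sizes[z[i]] < 2) i <- sample.int(n, 1)
    z[i] <- m + 1L
  }
  list(assignment = compact_assignment(z), move = mv)
}

#' Simulated-annealing search for the best penalised clustering
#'
#' Monte-Carlo search over hard partitions (including the number of
#' clusters) minimising `-2 L + k * lambda(N)`, where `L` is the
#' classification log-likelihood under per-cluster ML estimates. Candidate
#' moves (reassign / split / merge / new-singleton) are accepted by the
#' Metropolis rule at the current temperature; the best state ever visited
#' is returned. Several restarts with derived seeds are run and the best
#' result kept.
#'
#' @param data a [mixed_dataset()].
#' @param spec a [penalty_spec()] (default: AIC, constant lambda = 2).
#' @param schedule an [anneal_schedule()].
#' @param k_init initial number of clusters; default `max(2, round(N / 20))`.
#' @param n_restarts independent restarts (distinct derived seeds).
#' @param p_floor,sigma_floor numerical floors (see [mixedclust-floors]).
#' @return an object of class `search_result`: list with `assignment`,
#'   `n_clusters`, `best_objective`, `model` (hard-MLE [mixture_model()]),
#'   `classification_loglik`, `trace` (one row per temperature level:
#'   temperature, current/best objective, cluster count), `restart_seeds`,
#'   `penalty`.
#' @export
anneal <- function(data, spec = penalty_spec("constant", 2),
                   schedule = anneal_schedule(), k_init = NULL,
                   n_restarts = 3,
                   p_floor = .default_p_floor,
                   sigma_floor = .default_sigma_floor) {
  stopifnot(inherits(data, "mixed_dataset"), inherits(spec, "penalty_spec"))
  n <- data$n
  if (is.null(k_init)) k_init <- max(2L, as.integer(round(n / 20)))
  k_init <- min(as.integer(k_init), n)
  mpt <- schedule$moves_per_temperature
  if (is.null(mpt)) mpt <- 50L * n
  lam <- penalty_value(spec, n)
  restart_seeds <- with_seed(schedule$seed,
                             sample.int(.Machine$integer.max - 1L, n_restarts))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- with_seed(restart_seeds[r], {
      z0 <- compact_assignment(sample.int(k_init, n, replace = TRUE))
      .anneal_core(data$R, data$E, as.integer(z0), lam,
                   p_floor, sigma_floor,
                   schedule$t_init, schedule$t_final, schedule$cooling,
                   as.integer(mpt), schedule$max_no_improve)
    })
    if (is.null(best) || res$best_objective < best$best_objective) {
      best <- res
      best$restart <- r
    }
  }
  assignment <- compact_assignment(best$assignment)
  model <- hard_mle_model(data, assignment, p_floor, sigma_floor)
  ll <- classification_log_likelihood(data, assignment, p_floor, sigma_floor)
  obj <- penalized_objective(
    ll, count_parameters(max(assignment), data$n_r, data$n_e), spec, n)
  if (abs(obj - best$best_objective) > 1e-6 * max(1, abs(obj))) {
    stop("internal error: incremental objective (", best$best_objective,
         ") disagrees with full recomputation (", obj, ")")
  }
  structure(list(assignment = assignment,
                 n_clusters = max(assignment),
                 best_objective = obj,
                 model = model,
                 classification_loglik = ll,
                 trace = best$trace,
                 restart_seeds = restart_seeds,
                 chosen_restart = best$restart,
                 penalty = spec),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result:", x$n_clusters, "clusters, objective",
      format(x$best_objective, digits = 8), "\n")
  invisible(x)
}

#' Write an annealing trace as TSV
#'
#' @param result a `search_result` from [anneal()].
#' @param path output path.
#' @export
write_trace_tsv <- function(result, path) {
  tr <- result$trace
  tr$step <- seq_len(nrow(tr))
  write.table(tr[, c("step", "temperature", "current_objective",
                     "best_objective", "n_clusters")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
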