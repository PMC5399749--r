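# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's internal code paths: brute-force
# probability-space evaluation, naive per-cluster recomputation, and
# exhaustive set-partition enumeration.

# All set partitions of n elements as restricted-growth label vectors
# (Bell numbers: B(6) = 203, B(7) = 877).
all_partitions <- function(n) {
  parts <- list(integer(0))
  for (i in seq_len(n)) {
    new <- vector("list", 0)
    for (p in parts) {
      m <- if (length(p)) max(p) else 0L
      for (k in seq_len(m + 1L)) new[[length(new) + 1L]] <- c(p, k)
    }
    parts <- new
  }
  parts
}

# Mixture log-likelihood by naive probability-space evaluation (no
# log-sum-exp); only safe for small, well-scaled toys.
naive_mixture_loglik <- function(model, data) {
  tot <- 0
  for (i in seq_len(data$n)) {
    dens <- 0
    for (m in seq_len(model$n_components)) {
      f <- model$alpha[m]
      if (data$n_r > 0) {
        for (j in seq_len(data$n_r)) {
          f <- f * if (data$R[i, j] == 1) model$p[m, j] else 1 - model$p[m, j]
        }
      }
      if (data$n_e > 0) {
        for (l in seq_len(data$n_e)) {
          f <- f * dnorm(data$E[i, l], model$mu[m, l], model$sigma[m, l])
        }
      }
      dens <- dens + f
    }
    tot <- tot + log(dens)
  }
  tot
}

# Hard-assignment penalised objective recomputed from first principles.
naive_hard_objective <- function(data, z, lam,
                                 p_floor = 0.001, s_floor = 0.005) {
  z <- as.integer(factor(z, levels = unique(z)))
  m <- max(z)
  n <- length(z)
  L <- 0
  for (k in seq_len(m)) {
    idx <- which(z == k)
    nm <- length(idx)
    L <- L + nm * log(nm / n)
    if (data$n_r > 0) {
      for (j in seq_len(data$n_r)) {
        cnt <- sum(data$R[idx, j])
        p <- min(max(cnt / nm, p_floor), 1 - p_floor)
        L <- L + cnt * log(p) + (nm - cnt) * log(1 - p)
      }
    }
    if (data$n_e > 0) {
      for (l in seq_len(data$n_e)) {
        x <- data$E[idx, l]
        mu <- mean(x)
        sdv <- max(sqrt(mean((x - mu)^2)), s_floor)
        L <- L + sum(dnorm(x, mu, sdv, log = TRUE))
      }
    }
  }
  k_par <- (m - 1) + m * data$n_r + 2 * m * data$n_e
  -2 * L + k_par * lam
}

# Best objective over all partitions of a tiny dataset (exhaustive oracle).
exhaustive_best_objective <- function(data, lam) {
  min(vapply(all_partitions(data$n), function(z) {
    naive_hard_objective(data, z, lam)
  }, numeric(1)))
}

# Tiny dataset drawn with the scenario's parameters but arbitrary cluster
# sizes (the package generator enforces equal sizes; oracle tests need
# N = 7 too).
tiny_scenario_data <- function(sizes, scenario = "tight", n_r = 5, n_e = 5,
                               seed = 1) {
  sc <- sim_scenario(scenario)
  set.seed(seed)
  blocks <- lapply(sizes, function(nk) {
    p <- sample(c(sc$p_high, sc$p_low), n_r, replace = TRUE)
    mu <- runif(n_e, -1, 1)
    list(
      R = matrix(rbinom(nk * n_r, 1, rep(p, each = nk)), nrow = nk),
      E = matrix(rnorm(nk * n_e, rep(mu, each = nk), sc$sigma), nrow = nk))
  })
  mixed_dataset(R = do.call(rbind, lapply(blocks, `[[`, "R")),
                E = do.call(rbind, lapply(blocks, `[[`, "E")))
}

# Map each true cluster to the found cluster with the largest overlap.
match_components <- function(true_labels, found) {
  tab <- table(true_labels, found)
  apply(tab, 1, which.max)
}

# A small random valid responsibility matrix.
random_gamma <- function(n, m) {
  g <- matrix(runif(n * m), n, m)
  g / rowSums(g)
}
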