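#' Numerical floors
#'
#' Bernoulli parameters are clamped to `[p_floor, 1 - p_floor]` and Gaussian
#' standard deviations floored at `sigma_floor` so that every log-density the
#' package returns is finite, including for pure or singleton clusters. The
#' SD floor also bounds the well-known likelihood degeneracy of Gaussian
#' mixtures: a singleton cluster's density scales like `1/sigma_floor` per
#' continuous variable, and if the floor is far below the real noise scale
#' the penalised objective can prefer splitting points into micro-clusters.
#' The default (0.005, half the tightest noise level the simulation designs
#' use) keeps the objective's optimum at the generating partition there;
#' set it to a small fraction of the believed noise scale of your data.
#' @name mixedclust-floors
#' @keywords internal
NULL

.default_p_floor <- 0.001
.default_sigma_floor <- 0.005

#' Parameters of one mixture component
#'
#' A component couples a vector of Bernoulli success probabilities (one per
#' binary variable) with diagonal-Gaussian means and standard deviations
#' (one pair per continuous variable) and a mixing weight.
#'
#' @param p numeric vector of Bernoulli parameters (may be length 0).
#' @param mu numeric vector of Gaussian means (may be length 0).
#' @param sigma numeric vector of Gaussian SDs, same length as `mu`.
#' @param alpha mixing weight in (0, 1]; may be `NA` until set by the caller.
#' @param p_floor,sigma_floor numerical floors; see [mixedclust-floors].
#' @return an object of class `component_params`.
#' @export
component_params <- function(p = numeric(0), mu = numeric(0),
                             sigma = numeric(0), alpha = NA_real_,
                             p_floor = .default_p_floor,
                             sigma_floor = .default_sigma_floor) {
  p <- as.numeric(p); mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  if (length(mu) != length(sigma)) {
    stop("mu and sigma must have the same length")
  }
  p <- pmin(pmax(p, p_floor), 1 - p_floor)
  sigma <- pmax(sigma, sigma_floor)
  structure(list(alpha = alpha, p = p, mu = mu, sigma = sigma),
            class = "component_params")
}

#' Log-density of one data point under one component
#'
#' Sum of independent Bernoulli log-masses over the binary variables and
#' univariate normal log-densities over the continuous variables. Either
#' block may be empty, in which case its contribution is 0.
#'
#' @param comp a [component_params()].
#' @param r binary vector (0/1), length matching `comp$p`.
#' @param e numeric vector, length matching `comp$mu`.
#' @return a finite scalar log-density.
#' @export
log_component_density <- function(comp, r = numeric(0), e = numeric(0)) {
  if (length(r) != length(comp$p)) {
    stop("binary block mismatch: point has ", length(r),
         " binary variables, component has ", length(comp$p))
  }
  if (length(e) != length(comp$mu)) {
    stop("continuous block mismatch: point has ", length(e),
         " continuous variables, component has ", length(comp$mu))
  }
  lb <- if (length(r)) sum(r * log(comp$p) + (1 - r) * log1p(-comp$p)) else 0
  lg <- if (length(e)) sum(dnorm(e, comp$mu, comp$sigma, log = TRUE)) else 0
  lb + lg
}

#' A Bernoulli-Gaussian finite mixture model
#'
#' Parameters are stored as matrices with one row per component: `p`
#' (components x n_r Bernoulli parameters), `mu` and `sigma` (components x
#' n_e). Mixing weights `alpha` must sum to 1.
#'
#' @param alpha numeric vector of mixing weights summing to 1 (within 1e-9).
#' @param p matrix of Bernoulli parameters (may have 0 columns).
#' @param mu,sigma matrices of Gaussian means / SDs (may have 0 columns).
#' @param p_floor,sigma_floor numerical floors applied on construction.
#' @return an object of class `mixture_model` with elements `alpha`, `p`,
#'   `mu`, `sigma`, `n_components`, `n_r`, `n_e`.
#' @export
mixture_model <- function(alpha, p = NULL, mu = NULL, sigma = NULL,
                          p_floor = .default_p_floor,
                          sigma_floor = .default_sigma_floor) {
  m <- length(alpha)
  if (m < 1) stop("a mixture needs at least one component")
  fix <- function(M) {
    if (is.null(M)) return(matrix(numeric(0), nrow = m, ncol = 0))
    M <- as.matrix(M)
    if (nrow(M) != m) stop("parameter matrix rows must equal length(alpha)")
    M
  }
  p <- fix(p); mu <- fix(mu); sigma <- fix(sigma)
  if (!identical(dim(mu), dim(sigma))) stop("mu and sigma dimensions differ")
  if (abs(sum(alpha) - 1) > 1e-9) {
    stop("mixing weights must sum to 1 (got ", format(sum(alpha)), ")")
  }
  if (any(alpha <= 0)) stop("mixing weights must be positive")
  p[] <- pmin(pmax(p, p_floor), 1 - p_floor)
  sigma[] <- pmax(sigma, sigma_floor)
  structure(list(alpha = as.numeric(alpha), p = p, mu = mu, sigma = sigma,
                 n_components = m, n_r = ncol(p), n_e = ncol(mu)),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("mixture_model:", x$n_components, "components over", x$n_r,
      "binary and", x$n_e, "continuous variables\n")
  invisible(x)
}

#' Keep a subset of mixture components
#'
#' Retains the components in `idx` and renormalises the mixing weights.
#'
#' @param model a [mixture_model()].
#' @param idx integer vector of component indices to keep.
#' @return a [mixture_model()] with `length(idx)` components.
#' @export
subset_model <- function(model, idx) {
  a <- model$alpha[idx]
  mixture_model(alpha = a / sum(a),
                p = model$p[idx, , drop = FALSE],
                mu = model$mu[idx, , drop = FALSE],
                sigma = model$sigma[idx, , drop = FALSE])
}

#' Extract one component of a mixture model
#'
#' @param model a [mixture_model()].
#' @param m component index.
#' @return a [component_params()].
#' @export
model_component <- function(model, m) {
  component_params(p = model$p[m, ], mu = model$mu[m, ],
                   sigma = model$sigma[m, ], alpha = model$alpha[m])
}

## N x M matrix of per-component log-densities, log-space throughout.
component_logdensity_matrix <- function(model, data) {
  if (data$n_r != model$n_r || data$n_e != model$n_e) {
    stop("dataset has (", data$n_r, ",", data$n_e,
         ") variables but model expects (", model$n_r, ",", model$n_e, ")")
  }
  n <- data$n; m <- model$n_components
  ld <- matrix(0, n, m)
  if (data$n_r > 0) {
    lp <- log(model$p); lq <- log1p(-model$p)            # M x n_r
    ld <- ld + data$R %*% t(lp) + (1 - data$R) %*% t(lq)
  }
  if (data$n_e > 0) {
    inv <- 1 / (model$sigma^2)                           # M x n_e
    cst <- -0.5 * rowSums(log(2 * pi * model$sigma^2)) -
      0.5 * rowSums(model$mu^2 * inv)
    ld <- ld - 0.5 * (data$E^2) %*% t(inv) + data$E %*% t(model$mu * inv)
    ld <- sweep(ld, 2, cst, "+")
  }
  ld
}

logsumexp_rows <- function(x) {
  mx <- apply(x, 1, max)
  mx + log(rowSums(exp(x - mx)))
}

#' Mixture log-likelihood of a dataset
#'
#' `sum_i log sum_m alpha_m f_m(x_i)`, evaluated in log space with a
#' log-sum-exp guard so that component densities spanning hundreds of log
#' units neither overflow nor underflow.
#'
#' @param model a [mixture_model()].
#' @param data a [mixed_dataset()].
#' @return scalar log-likelihood.
#' @export
log_likelihood_mixture <- function(model, data) {
  ld <- component_logdensity_matrix(model, data)
  ld <- sweep(ld, 2, log(model$alpha), "+")
  sum(logsumexp_rows(ld))
}

#' Maximum-likelihood component parameters for a set of members
#'
#' Bernoulli parameters are member means (clamped), Gaussian means are
#' member means, and SDs are population (divide-by-n) standard deviations
#' floored at `sigma_floor`; a singleton member set therefore gets
#' `sigma = sigma_floor` everywhere. The mixing weight is left `NA` for the
#' caller to fill (typically `n_m / N`).
#'
#' @param data a [mixed_dataset()].
#' @param members integer vector of row indices (non-empty).
#' @param p_floor,sigma_floor numerical floors.
#' @return a [component_params()].
#' @export
fit_component_mle <- function(data, members,
                              p_floor = .default_p_floor,
                              sigma_floor = .default_sigma_floor) {
  if (length(members) == 0) stop("member set must be non-empty")
  Rm <- data$R[members, , drop = FALSE]
  Em <- data$E[members, , drop = FALSE]
  nm <- length(members)
  p <- if (data$n_r) colMeans(Rm) else numeric(0)
  mu <- if (data$n_e) colMeans(Em) else numeric(0)
  sigma <- if (data$n_e) {
    v <- colMeans(Em^2) - mu^2
    sqrt(pmax(v, 0))
  } else numeric(0)
  component_params(p = p, mu = mu, sigma = sigma, alpha = NA_real_,
                   p_floor = p_floor, sigma_floor = sigma_floor)
}

#' Build the hard-assignment MLE mixture model for a clustering
#'
#' Per-cluster ML parameter estimates with mixing weights `n_m / N`.
#'
#' @param data a [mixed_dataset()].
#' @param assignment integer vector of cluster labels `1..N_m` (every label
#'   present at least once).
#' @param p_floor,sigma_floor numerical floors.
#' @return a [mixture_model()].
#' @export
hard_mle_model <- function(data, assignment,
                           p_floor = .default_p_floor,
                           sigma_floor = .default_sigma_floor) {
  assignment <- validate_assignment(assignment, data$n)
  m <- max(assignment)
  comps <- lapply(seq_len(m), function(k) {
    fit_component_mle(data, which(assignment == k),
                      p_floor = p_floor, sigma_floor = sigma_floor)
  })
  alpha <- tabulate(assignment, m) / data$n
  mixture_model(alpha = alpha,
                p = do.call(rbind, lapply(comps, `[[`, "p")),
                mu = do.call(rbind, lapply(comps, `[[`, "mu")),
                sigma = do.call(rbind, lapply(comps, `[[`, "sigma")),
                p_floor = p_floor, sigma_floor = sigma_floor)
}

## Checks a hard clustering vector: labels 1..N_m with no gaps.
validate_assignment <- function(assignment, n) {
  assignment <- as.integer(assignment)
  if (length(assignment) != n) {
    stop("assignment length ", length(assignment),
         " does not match entity count ", n)
  }
  m <- max(assignment)
  if (min(assignment) < 1L || !all(seq_len(m) %in% assignment)) {
    stop("cluster labels must be 1..N_m with every label non-empty")
  }
  assignment
}

## Relabels an arbitrary label vector to compact 1..N_m (first appearance
## order), preserving the partition.
compact_assignment <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

#' Classification (hard-assignment) log-likelihood of a clustering
#'
#' The quantity the annealing search maximises: with per-cluster ML
#' parameter estimates and mixing weights `n_m / N`,
#' `sum_i [ log alpha_{z_i} + log f_{z_i}(x_i) ]`.
#'
#' @inheritParams hard_mle_model
#' @return scalar log-likelihood.
#' @export
classification_log_likelihood <- function(data, assignment,
                                          p_floor = .default_p_floor,
                                          sigma_floor = .default_sigma_floor) {
  assignment <- validate_assignment(assignment, data$n)
  model <- hard_mle_model(data, assignment, p_floor, sigma_floor)
  ld <- component_logdensity_matrix(model, data)
  idx <- cbind(seq_len(data$n), assignment)
  sum(log(model$alpha[assignment])) + sum(ld[idx])
}

#' Number of free parameters of a mixture
#'
#' `(N_m - 1)` free mixing weights, one Bernoulli parameter per binary
#' variable per component, and a mean and SD per continuous variable per
#' component: `(N_m - 1) + N_m * n_r + 2 * N_m * n_e`.
#'
#' @param n_components number of mixture components (>= 1).
#' @param n_r number of binary variables.
#' @param n_e number of continuous variables.
#' @return integer parameter count.
#' @export
count_parameters <- function(n_components, n_r, n_e) {
  if (n_components < 1) stop("n_components must be >= 1")
  as.integer((n_components - 1) + n_components * n_r + 2 * n_components * n_e)
}

#' Penalty specification for the model-selection objective
#'
#' The objective is `-2 L + k * lambda(N)`. Supported penalty families:
#' a constant `lambda` in `[1, 5]` (with `lambda = 2` the standard AIC),
#' `ln N` (BIC), `2 ln ln N` (Hannan-Quinn) and `1 + ln N` (consistent AIC).
#'
#' @param kind one of `"constant"`, `"bic"`, `"hannan_quinn"`, `"caic"`, or
#'   a shorthand string: `"aic"` (constant 2), `"const:<lambda>"`, `"hq"`.
#' @param lam the constant multiplier (used only when `kind = "constant"`).
#' @return an object of class `penalty_spec`.
#' @export
penalty_spec <- function(kind = "constant", lam = 2.0) {
  kind <- as.character(kind)
  if (kind == "aic") { kind <- "constant"; lam <- 2.0 }
  if (grepl("^const:", kind)) {
    lam <- as.numeric(sub("^const:", "", kind)); kind <- "constant"
  }
  if (kind == "hq") kind <- "hannan_quinn"
  kind <- match.arg(kind, c("constant", "bic", "hannan_quinn", "caic"))
  if (kind == "constant") {
    if (!is.finite(lam) || lam <= 0) stop("constant penalty needs lam > 0")
  }
  structure(list(kind = kind, lam = lam), class = "penalty_spec")
}

#' Evaluate the penalty multiplier lambda(N)
#'
#' @param spec a [penalty_spec()].
#' @param n number of data points.
#' @return scalar penalty multiplier.
#' @export
penalty_value <- function(spec, n) {
  switch(spec$kind,
    constant = spec$lam,
    bic = {
      if (n < 2) stop("BIC penalty needs N >= 2")
      log(n)
    },
    hannan_quinn = {
      if (n < 3) stop("Hannan-Quinn penalty needs N >= 3 (ln ln N > 0)")
      2 * log(log(n))
    },
    caic = {
      if (n < 2) stop("consistent-AIC penalty needs N >= 2")
      1 + log(n)
    })
}

#' Penalised model-selection objective
#'
#' `O(L, k) = -2 L + k * lambda(N)`; lower is better.
#'
#' @param loglik maximised log-likelihood `L`.
#' @param k number of free parameters.
#' @param spec a [penalty_spec()].
#' @param n number of data points.
#' @return scalar objective value.
#' @export
penalized_objective <- function(loglik, k, spec, n) {
  if (k < 0) stop("parameter count must be >= 0")
  -2 * loglik + k * penalty_value(spec, n)
}

#' Objective of a hard clustering
#'
#' Convenience wrapper: classification log-likelihood, parameter count from
#' the number of clusters, and the penalised objective in one call.
#'
#' @inheritParams classification_log_likelihood
#' @param spec a [penalty_spec()].
#' @return scalar objective value (lower is better).
#' @export
clustering_objective <- function(data, assignment, spec,
                                 p_floor = .default_p_floor,
                                 sigma_floor = .default_sigma_floor) {
  assignment <- validate_assignment(assignment, data$n)
  L <- classification_log_likelihood(data, assignment, p_floor, sigma_floor)
  k <- count_parameters(max(assignment), data$n_r, data$n_e)
  penalized_objective(L, k, spec, data$n)
}
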