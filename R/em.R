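#' E-step: posterior membership probabilities
#'
#' Computes responsibilities `gamma[i, m] = alpha_m f_m(x_i) / sum_m' ...`
#' in log space with a log-sum-exp guard; every row sums to 1.
#'
#' @param model a [mixture_model()].
#' @param data a [mixed_dataset()].
#' @return list with `gamma` (N x M responsibility matrix) and `loglik`
#'   (the mixture log-likelihood of `model` on `data`).
#' @export
e_step <- function(model, data) {
  ld <- component_logdensity_matrix(model, data)
  ld <- sweep(ld, 2, log(model$alpha), "+")
  lse <- logsumexp_rows(ld)
  gamma <- exp(ld - lse)
  gamma <- gamma / rowSums(gamma)  # exact renormalisation
  list(gamma = gamma, loglik = sum(lse))
}

#' M-step: weighted parameter updates
#'
#' Standard mixture updates: `alpha_m = sum_i gamma_im / N`, Bernoulli
#' parameters are responsibility-weighted means (clamped), Gaussian means
#' weighted means and SDs weighted population SDs (floored). Components
#' whose effective count falls below `epsilon_w` are dropped with a warning
#' and the weights renormalised.
#'
#' @param data a [mixed_dataset()].
#' @param gamma N x M responsibility matrix (rows summing to 1).
#' @param epsilon_w effective-count threshold below which a component is
#'   dropped.
#' @param p_floor,sigma_floor numerical floors.
#' @return a [mixture_model()].
#' @export
m_step <- function(data, gamma, epsilon_w = 1e-6,
                   p_floor = .default_p_floor,
                   sigma_floor = .default_sigma_floor) {
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != data$n) stop("gamma rows must match entity count")
  nk <- colSums(gamma)
  keep <- nk >= epsilon_w
  if (!all(keep)) {
    warning("dropping ", sum(!keep),
            " component(s) with effective count < ", epsilon_w)
    gamma <- gamma[, keep, drop = FALSE]
    nk <- nk[keep]
  }
  if (length(nk) == 0) stop("all components were dropped")
  alpha <- nk / sum(nk)
  p <- if (data$n_r) crossprod(gamma, data$R) / nk else NULL
  mu <- NULL; sigma <- NULL
  if (data$n_e) {
    mu <- crossprod(gamma, data$E) / nk
    s2 <- crossprod(gamma, data$E^2) / nk - mu^2
    sigma <- sqrt(pmax(s2, 0))
  }
  mixture_model(alpha = alpha, p = if (data$n_r) p else NULL,
                mu = mu, sigma = sigma,
                p_floor = p_floor, sigma_floor = sigma_floor)
}

#' EM refinement of a mixture model
#'
#' Alternates [e_step()] and [m_step()] from `init` until the mixture
#' log-likelihood changes by less than `tol` or `max_iter` iterations.
#' The log-likelihood trace is checked to be non-decreasing (within 1e-8;
#' the reference resets if a near-empty component is dropped, which changes
#' the model dimension). The number of components can only shrink.
#'
#' @param data a [mixed_dataset()].
#' @param init a [mixture_model()] to start from, e.g. the hard-MLE model
#'   of an annealing solution.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param epsilon_w component-dropping threshold passed to [m_step()].
#' @param p_floor,sigma_floor numerical floors.
#' @return an object of class `em_result`: list with `model`, `gamma`,
#'   `loglik` (final mixture log-likelihood), `loglik_trace`, `converged`,
#'   `n_iter`.
#' @export
run_em <- function(data, init, tol = 1e-6, max_iter = 500,
                   epsilon_w = 1e-6,
                   p_floor = .default_p_floor,
                   sigma_floor = .default_sigma_floor) {
  stopifnot(inherits(init, "mixture_model"))
  model <- init
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  iter <- 0L
  es <- e_step(model, data)
  repeat {
    trace <- c(trace, es$loglik)
    if (es$loglik < prev - 1e-8) {
      stop("internal error: EM log-likelihood decreased at iteration ",
           iter, " (", prev, " -> ", es$loglik, ")")
    }
    if (iter >= 1 && abs(es$loglik - prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    prev <- es$loglik
    m_old <- model$n_components
    model <- m_step(data, es$gamma, epsilon_w, p_floor, sigma_floor)
    if (model$n_components < m_old) prev <- -Inf   # dimension changed
    iter <- iter + 1L
    es <- e_step(model, data)
  }
  structure(list(model = model, gamma = es$gamma, loglik = es$loglik,
                 loglik_trace = trace, converged = converged,
                 n_iter = iter),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat("em_result:", x$model$n_components, "components, log-likelihood",
      format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' Hard assignments from responsibilities
#'
#' Assigns each entity to the component with the largest responsibility;
#' ties break toward the lowest component index, and components left with
#' no members are compacted away.
#'
#' @param gamma N x M responsibility matrix.
#' @return integer assignment vector with compact labels `1..N_m`.
#' @export
posterior_assignments <- function(gamma) {
  z <- max.col(as.matrix(gamma), ties.method = "first")
  compact_assignment(z)
}

#' Write responsibilities as a labelled TSV
#'
#' @param gamma N x M responsibility matrix.
#' @param path output path.
#' @param entity_ids optional row labels.
#' @export
write_responsibilities_tsv <- function(gamma, path, entity_ids = NULL) {
  gamma <- as.matrix(gamma)
  if (is.null(entity_ids)) entity_ids <- rownames(gamma)
  if (is.null(entity_ids)) entity_ids <- paste0("e", seq_len(nrow(gamma)))
  colnames(gamma) <- paste0("component_", seq_len(ncol(gamma)))
  rownames(gamma) <- entity_ids
  write_matrix_tsv(gamma, path, id_col = "entity")
}
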