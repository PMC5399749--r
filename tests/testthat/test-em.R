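# EM refinement: E-step normalisation, M-step reductions, monotone
# likelihood, convergence contracts and hard assignment extraction.

test_that("E-step responsibilities are normalised and follow symmetry", {
  set.seed(31)
  d <- mixed_dataset(R = matrix(rbinom(12, 1, 0.5), 4, 3),
                     E = matrix(rnorm(8), 4, 2))
  dup <- mixture_model(alpha = c(0.5, 0.5),
                       p = rbind(c(0.6, 0.4, 0.5), c(0.6, 0.4, 0.5)),
                       mu = rbind(c(0, 0), c(0, 0)),
                       sigma = rbind(c(1, 1), c(1, 1)))
  es <- e_step(dup, d)
  expect_equal(unname(es$gamma), matrix(0.5, 4, 2))
  single <- mixture_model(alpha = 1, p = rbind(c(0.6, 0.4, 0.5)),
                          mu = rbind(c(0, 0)), sigma = rbind(c(1, 1)))
  expect_equal(unname(e_step(single, d)$gamma), matrix(1, 4, 1))
  # dominance: a point at one component's mean, 100 SDs from the other
  d1 <- mixed_dataset(E = matrix(0, 1, 1))
  far <- mixture_model(alpha = c(0.5, 0.5), mu = rbind(0, 100),
                       sigma = rbind(1, 1))
  g <- e_step(far, d1)$gamma
  expect_gte(g[1, 1], 1 - 1e-10)
  # random models: every row sums to one
  set.seed(32)
  for (rep in 1:10) {
    m <- mixture_model(alpha = c(0.3, 0.3, 0.4),
                       p = matrix(runif(9, 0.05, 0.95), 3, 3),
                       mu = matrix(rnorm(6), 3, 2),
                       sigma = matrix(runif(6, 0.2, 2), 3, 2))
    g <- e_step(m, d)$gamma
    expect_equal(unname(rowSums(g)), rep(1, 4))
  }
})

test_that("one-hot responsibilities reduce the M-step to per-cluster MLEs", {
  set.seed(33)
  d <- mixed_dataset(R = matrix(rbinom(30, 1, 0.6), 10, 3),
                     E = matrix(rnorm(20), 10, 2))
  z <- rep(1:2, each = 5)
  gamma <- matrix(0, 10, 2)
  gamma[cbind(1:10, z)] <- 1
  m <- m_step(d, gamma)
  ref <- hard_mle_model(d, z)
  expect_equal(m$alpha, ref$alpha)
  expect_equal(unname(m$p), unname(ref$p))
  expect_equal(unname(m$mu), unname(ref$mu))
  expect_equal(unname(m$sigma), unname(ref$sigma))
})

test_that("uniform responsibilities give identical midpoint components", {
  d <- mixed_dataset(E = matrix(c(0, 2), 2, 1))
  g <- matrix(0.5, 2, 2)
  m <- m_step(d, g)
  expect_equal(unname(m$mu), rbind(1, 1))
  expect_equal(m$alpha, c(0.5, 0.5))
  expect_equal(unname(m$sigma), rbind(1, 1))  # population SD of {0,2}
  # all mass on one component: global moments
  d2 <- mixed_dataset(E = matrix(c(1, 2, 3), 3, 1))
  m2 <- m_step(d2, matrix(1, 3, 1))
  expect_equal(unname(m2$mu), rbind(2))
  expect_equal(unname(m2$sigma), rbind(sqrt(2 / 3)))
})

test_that("near-empty components are dropped with a warning", {
  d <- mixed_dataset(E = matrix(rnorm(10), 10, 1))
  g <- cbind(rep(1 - 1e-9, 10), rep(1e-9, 10))
  expect_warning(m <- m_step(d, g), "dropping")
  expect_identical(m$n_components, 1L)
  expect_equal(m$alpha, 1)
})

test_that("EM log-likelihood never decreases from random initialisations", {
  set.seed(35)
  d <- tiny_scenario_data(c(8, 8), scenario = "noisy", n_r = 4, n_e = 4,
                          seed = 35)
  for (rep in 1:20) {
    init <- mixture_model(alpha = rep(1 / 3, 3),
                          p = matrix(runif(12, 0.1, 0.9), 3, 4),
                          mu = matrix(runif(12, -1, 1), 3, 4),
                          sigma = matrix(runif(12, 0.1, 1), 3, 4))
    res <- run_em(d, init, max_iter = 40)
    expect_true(all(diff(res$loglik_trace) >= -1e-8))
  }
})

test_that("EM from generating parameters recovers the tight partition fast", {
  sim <- simulate_dataset(sim_config(60, 20, seed = 44))
  res <- run_em(sim$data, sim$truth$model)
  expect_lte(res$n_iter, 5)
  z <- posterior_assignments(res$gamma)
  expect_equal(recovery_metrics(z, sim$truth)$ari, 1)
})

test_that("convergence contracts: tol = Inf means a single iteration", {
  d <- tiny_scenario_data(c(5, 5), n_r = 3, n_e = 3, seed = 9)
  init <- hard_mle_model(d, rep(1:2, each = 5))
  res <- run_em(d, init, tol = Inf)
  expect_identical(res$n_iter, 1L)
  expect_true(res$converged)
})

test_that("well-separated point masses are an EM fixed point", {
  # two clusters of exactly repeated points far apart
  E <- rbind(matrix(0, 5, 2), matrix(50, 5, 2))
  R <- rbind(matrix(0, 5, 2), matrix(1, 5, 2))
  d <- mixed_dataset(R = R, E = E)
  init <- hard_mle_model(d, rep(1:2, each = 5))
  res <- run_em(d, init, max_iter = 3)
  expect_lt(max(abs(res$model$mu - init$mu)), 1e-9)
  expect_lt(max(abs(res$model$p - init$p)), 1e-9)
  expect_lt(max(abs(res$model$alpha - init$alpha)), 1e-9)
})

test_that("EM started from an annealing solution never lowers its likelihood", {
  sim <- simulate_dataset(sim_config(40, 10, scenario = "noisy", seed = 12))
  s <- anneal(sim$data, penalty_spec("aic"), anneal_schedule(seed = 12),
              n_restarts = 1)
  init_ll <- log_likelihood_mixture(s$model, sim$data)
  res <- run_em(sim$data, s$model)
  expect_gte(res$loglik, init_ll - 1e-8)
  expect_equal(res$loglik_trace[1], init_ll)
  expect_lte(res$model$n_components, s$model$n_components)
})

test_that("posterior assignments take the row-wise argmax with low-index ties", {
  g <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  expect_identical(posterior_assignments(g), c(1L, 2L, 1L))
  set.seed(50)
  g2 <- random_gamma(30, 4)
  z <- posterior_assignments(g2)
  brute <- apply(g2, 1, function(r) which(r == max(r))[1])
  expect_identical(z, as.integer(match(brute, unique(brute))))
})
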