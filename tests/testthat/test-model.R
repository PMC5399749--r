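# Model core: densities, likelihoods, MLE fitting, parameter counting and
# the penalised objective.

test_that("log_component_density matches closed forms and hand evaluation", {
  # Bernoulli(0.5) at r = 1
  c1 <- component_params(p = 0.5)
  expect_equal(log_component_density(c1, r = 1), log(0.5))
  # standard normal at its mode
  c2 <- component_params(mu = 0, sigma = 1)
  expect_equal(log_component_density(c2, e = 0), -0.5 * log(2 * pi))
  # mixed block: independent term-by-term sum
  c3 <- component_params(p = c(0.9, 0.1), mu = 2, sigma = 0.5)
  expect_equal(log_component_density(c3, r = c(1, 0), e = 2.5),
               log(0.9) + log(1 - 0.1) + dnorm(2.5, 2, 0.5, log = TRUE))
  expect_equal(log_component_density(c3, r = c(1, 0), e = 2.5),
               -0.9365124, tolerance = 1e-6)
})

test_that("log_component_density reports which block mismatches", {
  comp <- component_params(p = c(0.5, 0.5), mu = 0, sigma = 1)
  expect_error(log_component_density(comp, r = 1, e = 0), "binary")
  expect_error(log_component_density(comp, r = c(1, 0), e = c(0, 1)),
               "continuous")
})

test_that("mixture log-likelihood agrees with naive probability-space sums", {
  set.seed(42)
  d <- mixed_dataset(R = matrix(rbinom(6, 1, 0.5), 3, 2),
                     E = matrix(rnorm(6), 3, 2))
  m <- mixture_model(alpha = c(0.3, 0.7),
                     p = rbind(c(0.8, 0.2), c(0.4, 0.6)),
                     mu = rbind(c(0, 1), c(-1, 0)),
                     sigma = rbind(c(1, 0.5), c(0.7, 1.2)))
  expect_equal(log_likelihood_mixture(m, d), naive_mixture_loglik(m, d))
})

test_that("duplicated components collapse to the single-component value", {
  set.seed(7)
  d <- mixed_dataset(R = matrix(rbinom(8, 1, 0.5), 4, 2),
                     E = matrix(rnorm(8), 4, 2))
  single <- mixture_model(alpha = 1, p = rbind(c(0.7, 0.3)),
                          mu = rbind(c(0.5, -0.5)), sigma = rbind(c(1, 1)))
  dup <- mixture_model(alpha = c(0.5, 0.5),
                       p = rbind(c(0.7, 0.3), c(0.7, 0.3)),
                       mu = rbind(c(0.5, -0.5), c(0.5, -0.5)),
                       sigma = rbind(c(1, 1), c(1, 1)))
  expect_equal(log_likelihood_mixture(dup, d),
               log_likelihood_mixture(single, d))
  # single component, one data point: identity with the component density
  d1 <- mixed_dataset(R = matrix(c(1, 0), 1, 2), E = matrix(c(0.2, 0.1), 1, 2))
  expect_equal(log_likelihood_mixture(single, d1),
               log_component_density(model_component(single, 1),
                                     r = c(1, 0), e = c(0.2, 0.1)))
})

test_that("log-sum-exp keeps likelihoods finite across extreme separations", {
  # one point at 0; second component centred 60 SDs away: naive
  # exponentiation would underflow to a zero mixture density
  d <- mixed_dataset(E = matrix(rep(0, 30), 1, 30))
  m <- mixture_model(alpha = c(0.5, 0.5),
                     mu = rbind(rep(0, 30), rep(60, 30)),
                     sigma = matrix(1, 2, 30))
  ll <- log_likelihood_mixture(m, d)
  expect_true(is.finite(ll))
  expect_equal(ll, log(0.5) + 30 * dnorm(0, log = TRUE), tolerance = 1e-10)
})

test_that("mixture likelihood is invariant to permuting components/entities", {
  set.seed(11)
  d <- mixed_dataset(R = matrix(rbinom(20, 1, 0.5), 5, 4),
                     E = matrix(rnorm(15), 5, 3))
  m <- mixture_model(alpha = c(0.2, 0.5, 0.3),
                     p = matrix(runif(12, 0.1, 0.9), 3, 4),
                     mu = matrix(rnorm(9), 3, 3),
                     sigma = matrix(runif(9, 0.5, 2), 3, 3))
  perm <- c(3, 1, 2)
  m2 <- mixture_model(alpha = m$alpha[perm], p = m$p[perm, ],
                      mu = m$mu[perm, ], sigma = m$sigma[perm, ])
  expect_equal(log_likelihood_mixture(m2, d), log_likelihood_mixture(m, d))
  rows <- c(4, 2, 5, 1, 3)
  d2 <- mixed_dataset(R = d$R[rows, ], E = d$E[rows, ],
                      entity_ids = d$entity_ids[rows])
  expect_equal(log_likelihood_mixture(m, d2), log_likelihood_mixture(m, d))
})

test_that("fit_component_mle applies clamping, floors and population SD", {
  d <- mixed_dataset(R = matrix(c(1, 1, 1), 3, 1),
                     E = matrix(c(1, 3, 2), 3, 1))
  # pure binary column is clamped
  comp <- fit_component_mle(d, 1:3)
  expect_equal(comp$p, 1 - 0.001)
  # singleton: population SD of one point is 0, floored
  comp1 <- fit_component_mle(d, 2)
  expect_equal(comp1$sigma, 0.005)
  expect_equal(comp1$mu, 3)
  # two-point population SD: members {1, 3} -> mu 2, sigma 1
  comp2 <- fit_component_mle(d, c(1, 2))
  expect_equal(comp2$mu, 2)
  expect_equal(comp2$sigma, 1)
  expect_error(fit_component_mle(d, integer(0)), "non-empty")
})

test_that("classification log-likelihood matches naive recomputation", {
  set.seed(5)
  d <- mixed_dataset(R = matrix(rbinom(12, 1, 0.5), 4, 3),
                     E = matrix(rnorm(8), 4, 2))
  z <- c(1L, 1L, 2L, 2L)
  L <- classification_log_likelihood(d, z)
  k <- count_parameters(2, 3, 2)
  expect_equal(-2 * L + k * 2, naive_hard_objective(d, z, 2))
  # one cluster: the n * log(n/N) mixing term vanishes (ln 1 = 0)
  L1 <- classification_log_likelihood(d, rep(1L, 4))
  expect_equal(-2 * L1 + count_parameters(1, 3, 2) * 2,
               naive_hard_objective(d, rep(1L, 4), 2))
})

test_that("hard assignment never beats the mixture likelihood it induces", {
  set.seed(13)
  for (rep in 1:5) {
    d <- mixed_dataset(R = matrix(rbinom(24, 1, 0.5), 8, 3),
                       E = matrix(rnorm(24), 8, 3))
    z <- sample(1:3, 8, replace = TRUE)
    z <- as.integer(factor(z, levels = unique(z)))
    cl <- classification_log_likelihood(d, z)
    mix <- log_likelihood_mixture(hard_mle_model(d, z), d)
    expect_lte(cl, mix + 1e-10)
  }
})

test_that("parameter counting follows the free-parameter convention", {
  expect_identical(count_parameters(1, 0, 1), 2L)
  expect_identical(count_parameters(25, 20, 20), 1524L)
  expect_identical(count_parameters(2, 1, 0), 3L)
})

test_that("penalty families evaluate to their closed forms", {
  expect_equal(penalty_value(penalty_spec("constant", 2), 500), 2)
  expect_equal(penalty_value(penalty_spec("bic"), 100), log(100))
  expect_equal(penalty_value(penalty_spec("hannan_quinn"), 100),
               2 * log(log(100)))
  expect_equal(penalty_value(penalty_spec("caic"), 100), 1 + log(100))
  # shorthands
  expect_equal(penalty_value(penalty_spec("aic"), 10), 2)
  expect_equal(penalty_value(penalty_spec("const:3.5"), 10), 3.5)
  expect_equal(penalty_value(penalty_spec("hq"), 100), 2 * log(log(100)))
  expect_error(penalty_value(penalty_spec("hannan_quinn"), 2), "N >= 3")
  expect_error(penalty_value(penalty_spec("bic"), 1), "N >= 2")
})

test_that("the penalised objective is -2L + k lambda and monotone in lambda", {
  expect_equal(penalized_objective(0, 0, penalty_spec("constant", 2), 10), 0)
  expect_equal(penalized_objective(-100, 10, penalty_spec("constant", 2), 10),
               220)
  expect_equal(penalized_objective(-100, 10, penalty_spec("bic"), 100),
               200 + 10 * log(100))
  lams <- c(1, 2, 3, 4, 5)
  objs <- vapply(lams, function(l) {
    penalized_objective(-50, 7, penalty_spec("constant", l), 100)
  }, numeric(1))
  expect_true(all(diff(objs) > 0))
})

test_that("datasets validate their block contents", {
  expect_error(mixed_dataset(R = matrix(c(0, 2), 1, 2)), "0 or 1")
  expect_error(mixed_dataset(E = matrix(c(1, NA), 1, 2)), "missing")
  expect_error(mixed_dataset(), "at least one")
  # empty binary block supports expression-only clustering
  d <- mixed_dataset(E = matrix(rnorm(6), 3, 2))
  expect_identical(d$n_r, 0L)
  expect_equal(classification_log_likelihood(d, c(1L, 1L, 2L)),
               classification_log_likelihood(d, c(1L, 1L, 2L)))
})
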