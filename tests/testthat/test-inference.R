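test_that("with no data the posterior equals the Dirichlet(1,1,1) prior", {
  f <- quick_fit(c(0, 0, 0), seed = 3)
  # within 3 Monte-Carlo SE componentwise
  expect_true(all(abs(f$mean - 1 / 3) < 3 * mcse_mean(f)))
  # prior SD of Dirichlet(1,1,1): sqrt(2/9/4) = sqrt(1/18)
  expect_true(all(abs(f$sd - sqrt(1 / 18)) < 3 * mcse_sd(f)))
})

test_that("at r = 1 the sampler reproduces the conjugate closed form", {
  n <- c(10, 0, 0)
  f <- quick_fit(n, r = 1, seed = 5)
  a <- 1 + n
  a0 <- sum(a)
  expect_true(all(abs(f$mean - a / a0) < 3 * mcse_mean(f)))
  expect_true(all(abs(f$sd - sqrt(a * (a0 - a) / (a0^2 * (a0 + 1)))) <
                    3 * mcse_sd(f)))
})

test_that("sampler agrees with the simplex quadrature oracle", {
  f <- quick_fit(c(90, 10, 0), r = 0.7, seed = 9, iterations = 12000,
                 burn_in = 2000)
  g <- exact_posterior(c(90, 10, 0), r = 0.7)
  expect_true(all(abs(f$mean - g$mean) < 0.01))
  expect_true(all(abs(f$sd - g$sd) < 0.01))
})

test_that("sampling is deterministic given data, config, and seed", {
  f1 <- quick_fit(c(30, 20, 10), seed = 77, iterations = 2000,
                  burn_in = 500)
  f2 <- quick_fit(c(30, 20, 10), seed = 77, iterations = 2000,
                  burn_in = 500)
  expect_identical(f1$samples, f2$samples)
  f3 <- quick_fit(c(30, 20, 10), seed = 78, iterations = 2000,
                  burn_in = 500)
  expect_false(identical(f1$samples, f3$samples))
  # the caller's RNG stream is not disturbed
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(quick_fit(c(5, 5, 5), seed = 1, iterations = 1000,
                      burn_in = 100))
  expect_identical(runif(1), before)
})

test_that("retained sample count follows iterations, burn-in, and thinning", {
  f <- oligo_fit(c(5, 5, 5), iterations = 1007, burn_in = 100, thin = 7,
                 seed = 1)
  expect_identical(nrow(f$samples), (1007L - 100L) %/% 7L)
  expect_true(all(f$samples >= 0))
  expect_equal(unname(rowSums(f$samples)), rep(1, nrow(f$samples)),
               tolerance = 1e-12)
})

test_that("fit inputs are validated", {
  expect_error(oligo_fit(c(-1, 0, 0)), "non-negative")
  expect_error(oligo_fit(c(1.5, 0, 0)), "whole numbers")
  expect_error(oligo_fit(c(1, 2)), "three numbers")
  expect_error(oligo_fit(c(5, 5, 5), r = 0), "must be > 0")
  expect_error(oligo_fit(c(5, 5, 5), burn_in = 100, iterations = 100),
               "burn_in")
  expect_error(oligo_fit(c(5, 5, 5), prior = c(1, 0, 1)), "positive")
})

test_that("quadrature oracle is self-consistent and validates input", {
  expect_equal(unname(exact_posterior(c(0, 0, 0))$mean), rep(1 / 3, 3),
               tolerance = 1e-6)
  g <- exact_posterior(c(10, 0, 0), r = 1)
  a <- c(11, 1, 1)
  expect_equal(unname(g$mean), a / 13, tolerance = 1e-4)
  expect_equal(unname(g$sd), sqrt(a * (13 - a) / (13^2 * 14)),
               tolerance = 1e-3)
  # doubling the resolution barely moves the answer
  m1 <- exact_posterior(c(90, 10, 0), r = 0.7, resolution = 200)$mean
  m2 <- exact_posterior(c(90, 10, 0), r = 0.7, resolution = 400)$mean
  expect_true(max(abs(m1 - m2)) < 1e-3)
  expect_error(exact_posterior(c(1, 1, 1), resolution = 50), ">= 100")
})

test_that("posterior-predictive check reports predicted vs empirical", {
  sim <- simulate_counts(c(0.3, 0.4, 0.3), r = 0.7, n_traces = 5000,
                         seed = 21)
  f <- quick_fit(sim$counts, r = 0.7, seed = 22)
  ppc <- posterior_predictive_check(f)
  expect_equal(sum(ppc$predicted), 1, tolerance = 1e-9)
  # data generated from the model itself: discrepancy within binomial noise
  expect_lt(ppc$max_discrepancy, 3 * sqrt(0.25 / 5000))
  # at r = 1 predicted fractions equal the posterior mean exactly
  f1 <- quick_fit(c(20, 30, 10), r = 1, seed = 23)
  expect_equal(unname(posterior_predictive_check(f1)$predicted),
               unname(f1$mean), tolerance = 1e-12)
  # prior leakage is reported, not hidden
  f2 <- quick_fit(c(100, 0, 0), r = 0.7, seed = 24)
  expect_gt(posterior_predictive_check(f2)$predicted[["w2"]], 0)
})

test_that("permuting counts and prior at r = 1 permutes the posterior", {
  perm <- c(3, 1, 2)
  n <- c(12, 4, 30)
  f <- quick_fit(n, r = 1, seed = 31)
  fp <- quick_fit(n[perm], r = 1, seed = 32, prior = c(1, 1, 1)[perm])
  tol <- 3 * (mcse_mean(f) + mcse_mean(fp)[order(perm)])
  expect_true(all(abs(f$mean[perm] - fp$mean) < tol[perm]))
})
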