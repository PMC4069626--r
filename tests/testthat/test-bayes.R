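test_that("posterior kernel equals likelihood plus gamma log-densities", {
  aln <- simulate_pair(60, 0.5, 0.5, seed = 51)
  f <- codon_frequencies()
  pr <- gamma_prior()
  k <- log_posterior_kernel(aln, f, 2, pr, 0.5, 0.5)
  m <- codon_model(f, 2, 0.5)
  expect_equal(k, log_likelihood(aln, m, 0.5) +
                 dgamma(0.5, 1.1, rate = 1.1, log = TRUE) +
                 dgamma(0.5, 1.1, rate = 2.2, log = TRUE),
               tolerance = 1e-10)
  # empty alignment: kernel reduces to the log prior exactly
  empty <- suppressWarnings(pair_alignment("NNN", "NNN"))
  expect_equal(log_posterior_kernel(empty, f, 2, pr, 0.7, 0.3),
               dgamma(0.7, 1.1, rate = 1.1, log = TRUE) +
                 dgamma(0.3, 1.1, rate = 2.2, log = TRUE),
               tolerance = 1e-12)
  # prior penalisation: kernel decays as omega grows at fixed t
  ks <- vapply(c(5, 20, 80), function(w)
    log_posterior_kernel(aln, f, 2, pr, 0.5, w), 0)
  expect_true(all(diff(ks) < 0))
  expect_error(log_posterior_kernel(aln, f, 2, pr, -1, 0.5), "positive")
})

test_that("Gauss-Legendre rule integrates low-degree polynomials exactly", {
  tr <- structure(list(mu1 = 0, sigma1 = 1, mu2 = 0, sigma2 = 1,
                       source = "ng_branch", mode_logg = NA_real_),
                  class = "logistic_transform")
  g <- quadrature_grid(tr, 12)
  for (k in 0:5) {
    exact <- if (k %% 2 == 0) 2 / (k + 1) else 0
    expect_equal(sum(g$weights * g$nodes^k), exact, tolerance = 1e-12)
  }
  expect_error(quadrature_grid(tr, 4), "n >= 8")
})

test_that("transform branch follows the data regime", {
  f <- codon_frequencies()
  pr <- gamma_prior()
  # case I: interior MLEs, moderate divergence -> counting branch
  a1 <- simulate_pair(200, 0.5, 0.5, seed = 52)
  ml1 <- mle_pairwise(a1, se = FALSE, lrt = FALSE)
  tr1 <- choose_transform(ml1, ng_counts(a1), a1, f, pr)
  expect_identical(tr1$source, "ng_branch")
  expect_true(tr1$sigma1 > 0 && tr1$sigma2 > 0)
  # identical sequences: boundary MLE -> Hessian branch
  a2 <- fixture_identical(100, seed = 53)
  ml2 <- mle_pairwise(a2)
  tr2 <- choose_transform(ml2, suppressWarnings(ng_counts(a2)), a2, f, pr)
  expect_identical(tr2$source, "hessian_branch")
  # saturated random pair -> Hessian branch
  a3 <- fixture_random(100, seed = 54)
  ng3 <- suppressWarnings(ng_counts(a3))
  ml3 <- mle_pairwise(a3, se = FALSE, lrt = FALSE)
  tr3 <- choose_transform(ml3, ng3, a3, f, pr)
  if (ng3$saturated) expect_identical(tr3$source, "hessian_branch")
  expect_true(tr3$sigma1 > 0 && tr3$sigma2 > 0)
})

test_that("no-data posterior equals the prior (analytic oracle)", {
  empty <- suppressWarnings(pair_alignment("NNN", "NNN"))
  b <- suppressWarnings(bayes_pairwise(empty))
  expect_equal(b$mean_t, 1, tolerance = 1e-3)
  expect_equal(b$mean_omega, 0.5, tolerance = 1e-3)
  # analytic gamma moments: var = alpha / beta^2
  expect_equal(b$var_t, 1.1 / 1.1^2, tolerance = 1e-2)
  expect_equal(b$var_omega, 1.1 / 2.2^2, tolerance = 1e-2)
  expect_lt(abs(b$cov_t_omega), 1e-3)
  expect_equal(b$prob_omega_gt1, 1 - pgamma(1, 1.1, rate = 2.2),
               tolerance = 1e-3)
})

test_that("quadrature matches dense-grid integration on a case-I fixture", {
  aln <- simulate_pair(100, 0.4, 0.4, seed = 55)
  ml <- mle_pairwise(aln, se = FALSE, lrt = FALSE)
  b <- bayes_pairwise(aln, ml = ml)
  o <- riemann_posterior(aln, codon_frequencies(), ml$kappa_hat,
                         gamma_prior())
  expect_lt(rel_diff(b$mean_t, o$mean_t), 1e-4)
  expect_lt(rel_diff(b$mean_omega, o$mean_omega), 1e-4)
  expect_lt(rel_diff(b$var_t, o$var_t), 1e-4)
  expect_lt(rel_diff(b$var_omega, o$var_omega), 1e-4)
  expect_lt(rel_diff(b$cov_t_omega, o$cov_t_omega), 1e-4)
  # P(omega > 1 | x) + P(omega <= 1 | x) = 1 via the oracle's restriction
  expect_lt(abs(b$prob_omega_gt1 - o$prob), 1e-6)
})

test_that("posterior summaries are valid for boundary-case alignments", {
  cases <- list(identical = fixture_identical(100, seed = 56),
                syn_only = fixture_one_class(100, 18, TRUE, seed = 57),
                nonsyn_only = fixture_one_class(100, 22, FALSE, seed = 58),
                random = fixture_random(100, seed = 59))
  for (nm in names(cases)) {
    b <- bayes_pairwise(cases[[nm]])
    vals <- c(b$mean_t, b$mean_omega, b$var_t, b$var_omega, b$cov_t_omega,
              b$prob_omega_gt1)
    expect_true(all(is.finite(vals)), label = nm)
    expect_gte(b$var_t, 0)
    expect_gte(b$var_omega, 0)
    expect_lte(abs(b$cov_t_omega), sqrt(b$var_t * b$var_omega) + 1e-12)
    expect_true(b$prob_omega_gt1 >= 0 && b$prob_omega_gt1 <= 1)
  }
})

test_that("n = 32 and n = 64 quadrature agree on the five case fixtures", {
  cases <- list(simulate_pair(100, 0.3, 0.3, seed = 60),
                fixture_identical(100, seed = 61),
                fixture_one_class(100, 20, TRUE, seed = 62),
                fixture_one_class(100, 20, FALSE, seed = 63),
                fixture_random(100, seed = 64))
  for (aln in cases) {
    ml <- mle_pairwise(aln, se = FALSE, lrt = FALSE)
    b32 <- bayes_pairwise(aln, ml = ml, n = 32)
    b64 <- bayes_pairwise(aln, ml = ml, n = 64)
    for (nm in c("mean_t", "mean_omega", "var_t", "var_omega"))
      expect_lt(rel_diff(b32[[nm]], b64[[nm]]), 1e-4)
  }
})

test_that("likelihood dominates the prior for long informative genes", {
  aln <- simulate_pair(5000, 1, 0.5, seed = 65)
  ml <- mle_pairwise(aln, se = FALSE, lrt = FALSE)
  b <- bayes_pairwise(aln, ml = ml)
  expect_lt(abs(b$mean_t - ml$t_hat), 0.02)
  expect_lt(abs(b$mean_omega - ml$omega_hat), 0.02)
})

test_that("a more informative prior pulls omega towards its prior mean", {
  # fixture with MLE far below 0.5: AP1 (alpha = 2, same means) should
  # move the posterior mean of omega towards 0.5
  aln <- simulate_pair(200, 0.3, 0.05, seed = 66)
  ml <- mle_pairwise(aln, se = FALSE, lrt = FALSE)
  b_def <- bayes_pairwise(aln, ml = ml)
  b_ap1 <- bayes_pairwise(aln, ml = ml, prior = gamma_prior(2, 2, 2, 4))
  expect_gt(b_ap1$mean_omega, b_def$mean_omega)
})

test_that("identical sequences reproduce the known posterior means", {
  aln <- fixture_identical(100, seed = 67)
  b <- bayes_pairwise(aln)
  expect_lt(abs(b$mean_t - 0.011), 0.005)
  expect_lt(abs(b$mean_omega - 0.496), 0.02)
  expect_identical(b$kappa, 2)
  expect_identical(b$transform$source, "hessian_branch")
})
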