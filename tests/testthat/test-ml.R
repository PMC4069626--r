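test_that("log-likelihood matches a per-site brute-force computation", {
  aln <- pair_alignment("TTTAAAGGG", "TTCAAAGGC")
  f <- codon_frequencies()
  m <- codon_model(f, 2, 0.5)
  gc <- genetic_code()
  P <- oracle_expm(m$Q, 0.37)
  i <- match(aln$codons1, gc$sense_codons)
  j <- match(aln$codons2, gc$sense_codons)
  expect_equal(log_likelihood(aln, m, 0.37),
               sum(log(f$pi[i] * P[cbind(i, j)])), tolerance = 1e-10)
})

test_that("likelihood is symmetric in sequence order (reversibility)", {
  aln <- simulate_pair(120, 0.7, 0.4, seed = 41)
  rev <- pair_alignment(aln$codons2, aln$codons1)
  m <- codon_model(codon_frequencies(), 2.3, 0.4)
  expect_lt(abs(log_likelihood(aln, m, 0.7) - log_likelihood(rev, m, 0.7)),
            1e-9)
})

test_that("identical sequences: t_zero boundary, kappa fixed at 2", {
  aln <- fixture_identical(100, seed = 5)
  fit <- mle_pairwise(aln)
  expect_identical(fit$boundary, "t_zero")
  expect_identical(fit$t_hat, 0)
  expect_identical(fit$kappa_hat, 2)
  expect_true(is.na(fit$omega_hat))  # not unique
  expect_equal(fit$logL, sum(aln$patterns$n * log(1 / 61)),
               tolerance = 1e-10)
  expect_false(fit$significant_5pct)
})

test_that("one-class differences drive omega to its 0 / Inf sentinels", {
  syn <- fixture_one_class(100, 20, synonymous = TRUE, seed = 6)
  fit_s <- mle_pairwise(syn, se = FALSE, lrt = FALSE)
  expect_identical(fit_s$boundary, "omega_zero")
  expect_identical(fit_s$omega_hat, 0)

  nonsyn <- fixture_one_class(100, 25, synonymous = FALSE, seed = 7)
  fit_n <- mle_pairwise(nonsyn, se = FALSE, lrt = FALSE)
  expect_identical(fit_n$boundary, "omega_inf")
  expect_identical(fit_n$omega_hat, Inf)
})

test_that("MLE agrees with a nested grid-refinement oracle", {
  aln <- simulate_pair(500, 1, 0.5, seed = 8)
  fit <- mle_pairwise(aln, se = FALSE, lrt = FALSE)
  # independent oracle: iterative 3-D grid refinement of the
  # log-likelihood over (t, omega, kappa)
  f <- codon_frequencies()
  centre <- log(c(1, 0.5, 2)); width <- c(1.5, 1.5, 1.5)
  for (it in 1:8) {
    gr <- lapply(1:3, function(d)
      seq(centre[d] - width[d], centre[d] + width[d], length.out = 7))
    best <- c(-Inf, NA, NA, NA)
    for (lw in gr[[2]]) for (lk in gr[[3]]) {
      m <- codon_model(f, exp(lk), exp(lw))
      ll <- log_likelihood(aln, m, exp(gr[[1]]))
      b <- which.max(ll)
      if (ll[b] > best[1]) best <- c(ll[b], gr[[1]][b], lw, lk)
    }
    centre <- best[2:4]; width <- width / 2.5
  }
  expect_lt(abs(fit$t_hat - exp(centre[1])), 1e-3)
  expect_lt(abs(fit$omega_hat - exp(centre[2])), 1e-3)
  expect_lt(abs(fit$kappa_hat - exp(centre[3])), 2e-3)
  expect_gte(fit$logL + 1e-6, best[1])
})

test_that("profile likelihood in t is unimodal for case-I data", {
  aln <- simulate_pair(300, 0.6, 0.4, seed = 9)
  fit <- mle_pairwise(aln, se = FALSE, lrt = FALSE)
  m <- codon_model(codon_frequencies(), fit$kappa_hat, fit$omega_hat)
  tg <- exp(seq(log(0.01), log(10), length.out = 80))
  ll <- log_likelihood(aln, m, tg)
  signs <- sign(diff(ll))
  expect_lte(sum(diff(signs) != 0), 1)  # one sign change: unimodal
})

test_that("LRT is one-sided with critical value 2.71", {
  # omega_hat < 1: never significant regardless of the statistic
  aln <- simulate_pair(500, 1, 0.2, seed = 10)
  fit <- mle_pairwise(aln)
  expect_gte(fit$lrt_stat, -1e-6)
  expect_lt(fit$omega_hat, 1)
  expect_false(fit$significant_5pct)
  # strong positive selection: significant with a large statistic
  aln2 <- simulate_pair(500, 1, 2, seed = 11)
  fit2 <- mle_pairwise(aln2)
  expect_gt(fit2$omega_hat, 1)
  expect_gt(fit2$lrt_stat, 2.71)
  expect_true(fit2$significant_5pct)
  res <- lrt_positive_selection(aln2)
  expect_identical(res$significant_5pct, fit2$significant_5pct)
})

test_that("interior standard errors are positive and scale with information", {
  a_short <- simulate_pair(150, 0.5, 0.5, seed = 12)
  a_long <- simulate_pair(1500, 0.5, 0.5, seed = 12)
  f_short <- mle_pairwise(a_short, lrt = FALSE)
  f_long <- mle_pairwise(a_long, lrt = FALSE)
  expect_true(f_short$se_t > 0 && f_short$se_omega > 0)
  expect_lt(f_long$se_omega, f_short$se_omega)
  expect_lt(f_long$se_t, f_short$se_t)
})

test_that("model-based dN/dS reproduces omega and is linear in t", {
  f <- codon_frequencies()
  m1 <- codon_model(f, 2, 1)
  d1 <- dnds_from_mle(m1, 0.8)
  expect_equal(d1[["dN"]], d1[["dS"]], tolerance = 1e-9)
  m2 <- codon_model(f, 2, 0.37)
  d2 <- dnds_from_mle(m2, 0.8)
  expect_equal(d2[["dN"]] / d2[["dS"]], 0.37, tolerance = 1e-9)
  d3 <- dnds_from_mle(m2, 1.6)
  expect_equal(unname(d3), unname(2 * d2), tolerance = 1e-9)
})

test_that("mean MLE of omega matches the simulation study at (t=0.5, omega=0.1)", {
  R <- 500
  w <- vapply(1:R, function(k) {
    aln <- simulate_pair(500, 0.5, 0.1, seed = 40000 + k)
    mle_pairwise(aln, se = FALSE, lrt = FALSE)$omega_hat
  }, 0)
  w <- w[is.finite(w)]
  # reference mean 0.101 with sqrt(MSE) = 0.018 over replicates
  expect_lt(abs(mean(w) - 0.101), 3 * 0.018 / sqrt(R) + 5e-4)
})
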