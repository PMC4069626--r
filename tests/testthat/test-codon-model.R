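test_that("genetic code has 61 sense codons and excludes the three stops", {
  gc <- genetic_code()
  expect_length(gc$sense_codons, 61)
  expect_false(any(c("TAA", "TAG", "TGA") %in% gc$sense_codons))
  expect_true(all(grepl("^[TCAG]{3}$", gc$sense_codons)))
  skip_if_not_installed("Biostrings")
  expect_equal(unname(gc$aa),
               unname(as.character(Biostrings::GENETIC_CODE[gc$sense_codons])))
})

test_that("rate matrix matches a brute-force construction", {
  for (par in list(list(f = codon_frequencies(), k = 2, w = 0.5),
                   list(f = codon_frequencies(), k = 1, w = 1))) {
    m <- codon_model(par$f, par$k, par$w)
    Qo <- oracle_rate_matrix(par$f$pi, par$k, par$w)
    expect_lt(max(abs(unname(m$Q) - Qo)), 1e-12)
  }
  # F61 with uneven frequencies
  set.seed(4)
  pi <- rgamma(61, 1); pi <- pi / sum(pi)
  f61 <- codon_frequencies("F61", pi)
  m <- codon_model(f61, 3.7, 1.8)
  expect_lt(max(abs(unname(m$Q) - oracle_rate_matrix(pi, 3.7, 1.8))), 1e-12)
})

test_that("rate matrix structure: multi-hit zeros and kappa/omega ratios", {
  m <- codon_model(codon_frequencies(), 2, 0.5)
  gc <- genetic_code()
  idx <- function(cd) match(cd, gc$sense_codons)
  expect_identical(m$Q[idx("TTT"), idx("GGG")], 0)  # three differences
  # synonymous transition vs nonsynonymous transversion: kappa / omega = 4
  expect_equal(m$Q[idx("TTT"), idx("TTC")] / m$Q[idx("TTT"), idx("TTA")],
               2 / 0.5)
  expect_lt(max(abs(rowSums(m$Q))), 1e-10)
  expect_equal(-sum(m$freqs$pi * diag(m$Q)), 1, tolerance = 1e-10)
  # detailed balance
  F <- m$freqs$pi * m$Q
  expect_lt(max(abs(F - t(F))), 1e-12)
})

test_that("invalid model parameters are rejected", {
  f <- codon_frequencies()
  expect_error(codon_model(f, -1, 0.5), "nonnegative")
  expect_error(codon_model(f, 2, NaN), "nonnegative")
  expect_error(codon_frequencies("F61", rep(1, 61)), "sum to 1")
  expect_error(transition_probabilities(codon_model(f, 2, 1), -0.1))
})

test_that("transition probabilities match the matrix-exponential oracle", {
  m <- codon_model(codon_frequencies(), 2, 0.3)
  expect_equal(transition_probabilities(m, 0), diag(61),
               ignore_attr = TRUE)
  P <- transition_probabilities(m, 0.5)
  expect_lt(max(abs(P - oracle_expm(m$Q, 0.5))), 1e-8)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_true(all(P >= 0 & P <= 1))
  # ergodic limit: rows converge to pi
  Pinf <- transition_probabilities(m, 500)
  expect_lt(max(abs(sweep(Pinf, 2, m$freqs$pi))), 1e-6)
})

test_that("reversibility, Chapman-Kolmogorov and rate scaling hold", {
  m <- codon_model(codon_frequencies(), 2.5, 0.7)
  dec <- spectral_decompose(m)
  for (tt in c(0.1, 0.7)) {
    P <- transition_probabilities(m, tt, dec)
    D <- m$freqs$pi * P
    expect_lt(max(abs(D - t(D))), 1e-9)
  }
  P1 <- transition_probabilities(m, 0.1, dec)
  P2 <- transition_probabilities(m, 0.7, dec)
  expect_lt(max(abs(P1 %*% P2 - transition_probabilities(m, 0.8, dec))),
            1e-8)
  tt <- 1e-4
  P <- transition_probabilities(m, tt, dec)
  expect_equal(sum(m$freqs$pi * (1 - diag(P))) / tt, 1, tolerance = 1e-3)
})

test_that("spectral decomposition is valid and matches direct exponentiation", {
  m <- codon_model(codon_frequencies(), 2, 0.5)
  dec <- spectral_decompose(m)
  expect_false(dec$defective)
  expect_lt(max(dec$lambda), 1e-9)
  expect_equal(max(dec$lambda), 0, tolerance = 1e-9)
  rebuild <- dec$U %*% (dec$lambda * dec$Uinv)
  expect_lt(max(abs(rebuild - m$Q)), 1e-8)
  # stationary left eigenvector equals pi
  k0 <- which.max(dec$lambda)
  v <- dec$Uinv[k0, ] * dec$U[1, k0]  # pi_j * (U row constant for lambda=0)
  expect_lt(max(abs(v / sum(v) - m$freqs$pi)), 1e-8)
  for (tt in c(0.01, 0.1, 1, 10)) {
    expect_lt(max(abs(transition_probabilities(m, tt, dec) -
                        oracle_expm(m$Q, tt))), 1e-8)
  }
})

test_that("zero-frequency codons under F61 are handled by support restriction", {
  set.seed(9)
  pi <- rgamma(61, 1); pi[c(3, 17, 44)] <- 0; pi <- pi / sum(pi)
  f <- codon_frequencies("F61", pi)
  m <- codon_model(f, 2, 0.5)
  dec <- spectral_decompose(m)
  expect_identical(length(dec$support), 58L)
  P <- transition_probabilities(m, 0.4, dec)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  # the support block matches direct exponentiation of the restricted Q
  s <- dec$support
  expect_lt(max(abs(P[s, s] - oracle_expm(m$Q[s, s], 0.4))), 1e-8)
})
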