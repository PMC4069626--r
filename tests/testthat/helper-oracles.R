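# Independent oracles used across the suite.  Each reimplements the
# quantity it checks by a different route than the package: brute-force
# enumeration over the genetic code, Matrix::expm, recursive pathway
# enumeration, and Simpson integration on a dense grid.

# amino acid of a codon via Biostrings (independent of the package's
# hardcoded table); returns "*" for stops
oracle_aa <- function(codon) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    as.character(Biostrings::GENETIC_CODE[codon])
  } else {
    # fall back to translating via ape's trans() through seqinr-free route
    gc <- genetic_code()
    ifelse(codon %in% gc$stop_codons, "*", unname(gc$aa[codon]))
  }
}

# brute-force scaled rate matrix: nested loops over all codon pairs,
# comparing strings position by position
oracle_rate_matrix <- function(pi, kappa, omega) {
  gc <- genetic_code()
  codons <- gc$sense_codons
  aa <- oracle_aa(codons)
  Q <- matrix(0, 61, 61)
  purine <- c("A", "G")
  for (i in 1:61) for (j in 1:61) {
    if (i == j) next
    a <- strsplit(codons[i], "")[[1]]
    b <- strsplit(codons[j], "")[[1]]
    d <- which(a != b)
    if (length(d) != 1) next
    rate <- pi[j]
    if ((a[d] %in% purine) == (b[d] %in% purine)) rate <- rate * kappa
    if (aa[i] != aa[j]) rate <- rate * omega
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

# scaling-and-squaring matrix exponential (Matrix::expm)
oracle_expm <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# recursive Nei-Gojobori pathway enumeration for one codon pair:
# depth-first over the remaining differing positions, skipping stops
oracle_ng_pathways <- function(c1, c2) {
  gc <- genetic_code()
  stops <- gc$stop_codons
  recurse <- function(cur, target) {
    d <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(d) == 0) return(list(c(0, 0, 0)))  # (s, n, npaths marker)
    out <- list()
    for (p in d) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      if (nxt %in% stops && nxt != target) next
      step_syn <- oracle_aa(cur) == oracle_aa(nxt)
      for (rest in recurse(nxt, target))
        out[[length(out) + 1]] <- rest + c(step_syn, !step_syn, 0)
    }
    out
  }
  paths <- recurse(c1, c2)
  if (length(paths) == 0) return(NULL)  # fully blocked
  m <- do.call(rbind, paths)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

# dense-grid Simpson integration of the posterior on (log t, log omega);
# independent of the quadrature + logistic transform under test
riemann_posterior <- function(aln, freqs, kappa, prior, ngrid = 601,
                              ylim = c(-8, 4)) {
  stopifnot(ngrid %% 2 == 1)
  y <- seq(ylim[1], ylim[2], length.out = ngrid)
  tv <- exp(y); wv <- exp(y)
  logg <- matrix(NA_real_, ngrid, ngrid)
  for (j in seq_len(ngrid)) {
    m <- codon_model(freqs, kappa, wv[j])
    logg[, j] <- log_likelihood(aln, m, tv) +
      dgamma(tv, prior$alpha_t, rate = prior$beta_t, log = TRUE) +
      dgamma(wv[j], prior$alpha_omega, rate = prior$beta_omega, log = TRUE)
  }
  lmax <- max(logg)
  G <- exp(sweep(sweep(logg - lmax, 1, y, "+"), 2, y, "+"))
  h <- y[2] - y[1]
  simp <- rep(c(2, 4), length.out = ngrid); simp[c(1, ngrid)] <- 1
  wt <- simp * h / 3
  I <- function(M) as.numeric(t(wt) %*% M %*% wt)
  A <- I(G)
  # restriction to omega > 1: Simpson restarted at the grid point y = 0
  i0 <- which(abs(y) < 1e-12)
  wt2 <- numeric(ngrid)
  wt2[i0] <- h / 3
  simr <- rep(c(4, 2), length.out = ngrid - i0); simr[length(simr)] <- 1
  wt2[(i0 + 1):ngrid] <- simr * h / 3
  Et <- I(tv * G) / A; Ew <- I(t(t(G) * wv)) / A
  list(mean_t = Et, mean_omega = Ew,
       var_t = I(tv^2 * G) / A - Et^2,
       var_omega = I(t(t(G) * wv^2)) / A - Ew^2,
       cov_t_omega = I(tv * t(t(G) * wv)) / A - Et * Ew,
       prob = as.numeric(t(wt) %*% G %*% wt2) / A)
}

rel_diff <- function(a, b) abs(a - b) / max(abs(b), 1e-6)
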