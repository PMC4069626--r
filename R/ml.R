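# Likelihood of a pairwise codon alignment and maximum-likelihood
# estimation of (t, omega, kappa), with boundary-case classification and
# the one-sided LRT for positive selection.

.T_LO <- 1e-6; .T_HI <- 50
.W_LO <- 1e-6; .W_HI <- 99
.K_LO <- 0.01; .K_HI <- 99
.BOUND_EPS <- 1e-4   # proximity to lower bound -> 0 sentinel
.BOUND_FRAC <- 0.98  # fraction of upper bound -> Inf sentinel

# precomputed likelihood machinery for one (alignment, frequency) pair:
# support-restricted state space, pattern indices, and evaluators.
# loglik(dec, tvec) returns sum_h log(pi_i P_ij(t)) for each t.
.lik_machine <- function(aln, freqs) {
  stopifnot(inherits(aln, "pair_alignment"),
            inherits(freqs, "codon_frequencies"))
  ss <- .support_structure(freqs$pi)
  p <- aln$patterns
  if (nrow(p) > 0 && any(ss$map[p$i] == 0 | ss$map[p$j] == 0))
    stop("observed codon has zero frequency under the supplied model")
  ii <- ss$map[p$i]; jj <- ss$map[p$j]; nn <- p$n
  logpi_sum <- if (nrow(p) > 0) sum(nn * log(ss$pi[ii])) else 0
  identical_seqs <- nrow(p) == 0 || all(ii == jj)
  # mkll folds the pattern-weight matrix W (depends on the decomposition,
  # not on t) so repeated evaluations over t are a single mat-vec each
  mkll <- function(dec) {
    if (length(ii) == 0) return(function(tvec) rep(0, length(tvec)))
    W <- dec$U[ii, , drop = FALSE] * t(dec$Uinv)[jj, , drop = FALSE]
    function(tvec) {
      P <- W %*% exp(outer(dec$lambda, tvec))
      as.numeric(colSums(nn * log(pmax(P, 1e-300)))) + logpi_sum
    }
  }
  list(
    pi = ss$pi, pairs = ss$pairs, support = ss$support,
    ii = ii, jj = jj, nn = nn, logpi_sum = logpi_sum,
    L_c = aln$L_c, identical = identical_seqs,
    decomp = function(kappa, omega)
      .decomp_support(ss$pi, kappa, omega, ss$pairs),
    mkll = mkll,
    loglik = function(dec, tvec) mkll(dec)(tvec))
}

#' Log-likelihood of a pairwise alignment under a codon model
#'
#' The likelihood is the product over codon sites of `pi_i P_ij(t)`, where
#' i and j are the codons observed in the two sequences; by reversibility
#' it is symmetric in sequence order.
#'
#' @param aln a `pair_alignment`.
#' @param model a [codon_model()] object.
#' @param t nonnegative distance(s), expected substitutions per codon.
#' @return Numeric vector of log-likelihood values, one per element of `t`.
#' @export
log_likelihood <- function(aln, model, t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and nonnegative")
  mach <- .lik_machine(aln, model$freqs)
  dec <- mach$decomp(model$kappa, model$omega)
  mach$loglik(dec, t)
}

# profile the likelihood over t at fixed (kappa, omega)
.profile_t <- function(mach, kappa, omega) {
  dec <- mach$decomp(kappa, omega)
  ll <- mach$mkll(dec)
  f <- function(lt) -ll(exp(lt))
  opt <- optimize(f, c(log(.T_LO), log(.T_HI)), tol = 1e-7)
  # a monotone profile pushes the optimum to a bound; check the ends
  ends <- c(log(.T_LO), log(.T_HI))
  fe <- vapply(ends, f, 0)
  if (min(fe) < opt$objective) {
    k <- which.min(fe)
    opt <- list(minimum = ends[k], objective = fe[k])
  }
  list(t = exp(opt$minimum), logL = -opt$objective)
}

.classify_boundary <- function(t, omega) {
  t_zero <- t <= .T_LO + .BOUND_EPS
  t_inf <- t >= .BOUND_FRAC * .T_HI
  w_zero <- !is.na(omega) && omega <= .W_LO + .BOUND_EPS
  w_inf <- !is.na(omega) && omega >= .BOUND_FRAC * .W_HI
  if (t_zero) "t_zero"
  else if (w_zero) "omega_zero"
  else if (t_inf) "t_inf"
  else if (w_inf) "omega_inf"
  else "interior"
}

# finite-difference Hessian of f at x (central second differences)
.fd_hessian <- function(f, x, h = 1e-3) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (a in 1:k) {
    ea <- replace(numeric(k), a, h)
    H[a, a] <- (f(x + ea) - 2 * f0 + f(x - ea)) / h^2
    if (a < k) for (b in (a + 1):k) {
      eb <- replace(numeric(k), b, h)
      H[a, b] <- H[b, a] <-
        (f(x + ea + eb) - f(x + ea - eb) -
           f(x - ea + eb) + f(x - ea - eb)) / (4 * h^2)
    }
  }
  H
}

#' Maximum-likelihood estimation for a pairwise codon alignment
#'
#' Maximises the likelihood over (t, omega, kappa) on the log scale within
#' wide bounds (t in \[1e-6, 50\], omega in \[1e-6, 99\], kappa in
#' \[0.01, 99\]), using a Nei-Gojobori-based start plus two perturbations.
#' Estimates hitting the bounds are reported as 0 / `Inf` sentinels with a
#' boundary flag: identical sequences give `t_zero` (kappa is then fixed at
#' 2 and omega is not unique), synonymous-only differences give
#' `omega_zero`, nonsynonymous-only `omega_inf`, and saturated sequences
#' `t_inf`.
#'
#' @param aln a `pair_alignment`.
#' @param freqs a [codon_frequencies()] object (default Fequal).
#' @param fix_omega optional value at which to fix omega (e.g. 1 for the
#'   null model of the LRT).
#' @param fix_kappa optional value at which to fix kappa.
#' @param se compute asymptotic standard errors from the finite-difference
#'   observed information at an interior MLE (default TRUE).
#' @param lrt also fit the omega = 1 null and report the one-sided
#'   likelihood ratio statistic (default TRUE; ignored when `fix_omega`
#'   is given).
#' @return An object of class `ml_result` with elements `t_hat`,
#'   `omega_hat`, `kappa_hat`, `logL`, `boundary`, `se_t`, `se_omega`,
#'   `sd_log_t`, `sd_log_omega`, `logL0`, `lrt_stat`, `significant_5pct`.
#' @export
mle_pairwise <- function(aln, freqs = codon_frequencies(), fix_omega = NULL,
                         fix_kappa = NULL, se = TRUE, lrt = TRUE) {
  mach <- .lik_machine(aln, freqs)

  if (mach$identical) {
    logL <- mach$logpi_sum  # P(0) = I
    return(structure(list(
      t_hat = 0, omega_hat = NA_real_,
      kappa_hat = if (is.null(fix_kappa)) 2 else fix_kappa,
      logL = logL, boundary = "t_zero",
      se_t = NA_real_, se_omega = NA_real_,
      sd_log_t = NA_real_, sd_log_omega = NA_real_,
      logL0 = logL, lrt_stat = 0, significant_5pct = FALSE,
      convergence = 0L), class = "ml_result"))
  }

  ng <- suppressWarnings(ng_counts(aln))
  w_start <- if (!is.na(ng$omega_hat) && ng$omega_hat > 0) ng$omega_hat
  else if (ng$Nd == 0) 0.02
  else if (ng$Sd == 0 || (!is.na(ng$dS) && ng$dS == 0)) 5
  else 1
  w_start <- min(max(w_start, 1e-3), 50)
  k_start <- if (is.null(fix_kappa)) 2 else fix_kappa

  free <- c(kappa = is.null(fix_kappa), omega = is.null(fix_omega))
  lower <- log(c(.K_LO, .W_LO))[free]
  upper <- log(c(.K_HI, .W_HI))[free]

  make_par <- function(kappa, omega) log(c(kappa, omega))[free]
  unpack <- function(par) {
    full <- c(if (is.null(fix_kappa)) NA else fix_kappa,
              if (is.null(fix_omega)) NA else fix_omega)
    full[free] <- exp(par)
    list(kappa = full[1], omega = full[2])
  }
  obj <- function(par) {
    pp <- unpack(par)
    -.profile_t(mach, pp$kappa, pp$omega)$logL
  }

  starts <- list(make_par(k_start, w_start))
  if (any(free))
    starts <- c(starts, list(make_par(k_start * 1.5, w_start * 3),
                             make_par(k_start / 1.5, w_start / 3)))
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))

  best <- NULL
  for (s in starts) {
    fit <- if (length(s) == 0) {
      list(par = s, value = obj(s), convergence = 0L)
    } else if (length(s) == 1) {
      o <- optimize(function(x) obj(x), c(lower, upper), tol = 1e-7)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e9))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pp <- unpack(best$par)
  prof <- .profile_t(mach, pp$kappa, pp$omega)
  t_hat <- prof$t; logL <- prof$logL
  boundary <- .classify_boundary(t_hat, pp$omega)

  out <- list(t_hat = t_hat, omega_hat = pp$omega, kappa_hat = pp$kappa,
              logL = logL, boundary = boundary,
              se_t = NA_real_, se_omega = NA_real_,
              sd_log_t = NA_real_, sd_log_omega = NA_real_,
              logL0 = NA_real_, lrt_stat = NA_real_,
              significant_5pct = NA, convergence = best$convergence)

  # sentinel encoding of boundary estimates
  if (boundary == "t_zero") out$t_hat <- 0
  if (boundary == "t_inf") { out$t_hat <- Inf; out$omega_hat <- pp$omega }
  if (boundary == "omega_zero") out$omega_hat <- 0
  if (boundary == "omega_inf") out$omega_hat <- Inf
  if (boundary == "t_inf" && !is.na(pp$omega) &&
      pp$omega >= .BOUND_FRAC * .W_HI) out$omega_hat <- Inf

  if (se && boundary == "interior" && is.null(fix_omega)) {
    pars <- c(log(t_hat), log(pp$omega),
              if (is.null(fix_kappa)) log(pp$kappa))
    nll <- function(x) {
      kap <- if (is.null(fix_kappa)) exp(x[3]) else fix_kappa
      dec <- mach$decomp(kap, exp(x[2]))
      -mach$loglik(dec, exp(x[1]))
    }
    H <- .fd_hessian(nll, pars)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V)[1:2] > 0)) {
      out$sd_log_t <- sqrt(V[1, 1]); out$sd_log_omega <- sqrt(V[2, 2])
      out$se_t <- t_hat * out$sd_log_t
      out$se_omega <- pp$omega * out$sd_log_omega
    }
  }

  if (is.null(fix_omega) && lrt) {
    null_fit <- mle_pairwise(aln, freqs, fix_omega = 1,
                             fix_kappa = fix_kappa, se = FALSE, lrt = FALSE)
    out$logL0 <- null_fit$logL
    out$lrt_stat <- max(0, 2 * (logL - out$logL0))
    out$significant_5pct <- isTRUE(out$lrt_stat > 2.71 &&
                                     !is.na(out$omega_hat) &&
                                     out$omega_hat > 1)
  }
  structure(out, class = "ml_result")
}

#' @export
print.ml_result <- function(x, ...) {
  cat("ML estimates: t =", format(x$t_hat, digits = 4),
      " omega =", format(x$omega_hat, digits = 4),
      " kappa =", format(x$kappa_hat, digits = 4),
      " [", x$boundary, "]\n")
  cat("  logL =", format(x$logL, digits = 8))
  if (!is.na(x$lrt_stat))
    cat("  LRT =", format(x$lrt_stat, digits = 4),
        if (isTRUE(x$significant_5pct)) "(significant at 5%)" else "")
  cat("\n")
  invisible(x)
}

#' One-sided likelihood ratio test for positive selection
#'
#' Compares the unconstrained fit with the omega = 1 null; the test is
#' one-sided with critical value 2.71 at the 5% level, and is significant
#' only when the MLE of omega exceeds 1.
#'
#' @param aln a `pair_alignment`.
#' @param freqs a [codon_frequencies()] object.
#' @return List with `lrt_stat`, `significant_5pct` and the full `fit`.
#' @export
lrt_positive_selection <- function(aln, freqs = codon_frequencies()) {
  fit <- mle_pairwise(aln, freqs, se = FALSE)
  list(lrt_stat = fit$lrt_stat, significant_5pct = fit$significant_5pct,
       fit = fit)
}

#' Model-based dN and dS at a fitted distance
#'
#' Partitions the substitution flow of the scaled rate matrix into
#' synonymous and nonsynonymous classes and divides by the corresponding
#' model site proportions (computed from the same matrix at omega = 1), so
#' that dN/dS equals the model omega exactly.
#'
#' @param model a [codon_model()] object (at the MLEs of kappa and omega).
#' @param t distance (interior MLE).
#' @return Named numeric `c(dN = , dS = )` (per-site distances).
#' @export
dnds_from_mle <- function(model, t) {
  stopifnot(inherits(model, "codon_model"), is.finite(t), t >= 0)
  pairs <- .codon_pair_structure()
  pi <- model$freqs$pi
  flow <- function(Q) {
    f <- pi[pairs$from] * Q[cbind(pairs$from, pairs$to)]
    c(S = sum(f[pairs$synonymous]), N = sum(f[!pairs$synonymous]))
  }
  fl <- flow(model$Q)                                     # sums to 1
  fl1 <- flow(.build_Q(pi, model$kappa, 1)$Q)             # site proportions
  c(dN = t * fl[["N"]] / (3 * fl1[["N"]]),
    dS = t * fl[["S"]] / (3 * fl1[["S"]]))
}
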