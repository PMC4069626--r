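#' Codon frequency models
#'
#' Constructs the equilibrium codon frequencies used by [codon_model()].
#' Under `Fequal` every sense codon has frequency 1/61; under `F61` the
#' frequencies are supplied (typically from [observed_codon_frequencies()]).
#'
#' @param model `"Fequal"` or `"F61"`.
#' @param pi numeric vector of 61 nonnegative frequencies summing to 1
#'   (required for `F61`, ignored for `Fequal`); may be named by codon.
#' @return An object of class `codon_frequencies`: list with `pi` (named
#'   numeric of length 61) and `model_tag`.
#' @examples
#' codon_frequencies()$pi[1:3]
#' @export
codon_frequencies <- function(model = c("Fequal", "F61"), pi = NULL) {
  model <- match.arg(model)
  gc <- genetic_code()
  if (model == "Fequal") {
    pi <- rep(1 / 61, 61)
  } else {
    if (is.null(pi) || length(pi) != 61)
      stop("F61 requires a vector of 61 codon frequencies")
    if (any(!is.finite(pi)) || any(pi < 0))
      stop("codon frequencies must be finite and nonnegative")
    if (abs(sum(pi) - 1) > 1e-12) stop("codon frequencies must sum to 1")
  }
  names(pi) <- gc$sense_codons
  structure(list(pi = pi, model_tag = model), class = "codon_frequencies")
}

#' @export
print.codon_frequencies <- function(x, ...) {
  cat("Codon frequencies (", x$model_tag, "), ",
      sum(x$pi > 0), " codons with positive frequency\n", sep = "")
  invisible(x)
}

# unscaled rate assembly shared by codon_model() and the internal fast path;
# returns list(Q, scale) with Q already divided by scale
.build_Q <- function(pi, kappa, omega, pairs = .codon_pair_structure()) {
  k <- length(pi)
  rate <- pi[pairs$to]
  rate[pairs$transition] <- rate[pairs$transition] * kappa
  rate[!pairs$synonymous] <- rate[!pairs$synonymous] * omega
  Q <- matrix(0, k, k)
  Q[cbind(pairs$from, pairs$to)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix: total substitution rate is 0")
  list(Q = Q / scale, scale = scale)
}

#' Codon substitution model
#'
#' Builds the 61x61 instantaneous rate matrix of the (simplified
#' Goldman-Yang) codon substitution model.  The rate from codon i to codon
#' j is 0 when they differ at more than one position, and otherwise
#' proportional to `pi_j`, multiplied by `kappa` for a transition and by
#' `omega` for a nonsynonymous change.  The matrix is scaled so that the
#' mean substitution rate at equilibrium is 1, i.e. time t is measured in
#' expected nucleotide substitutions per codon.
#'
#' @param freqs a [codon_frequencies()] object.
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param omega nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @return An object of class `codon_model`: list with `code`, `freqs`,
#'   `kappa`, `omega`, `Q` (scaled 61x61 generator) and `scale` (the raw
#'   total rate used as the normalising divisor).
#' @examples
#' m <- codon_model(codon_frequencies(), kappa = 2, omega = 0.5)
#' max(abs(rowSums(m$Q)))        # rows sum to 0
#' -sum(m$freqs$pi * diag(m$Q))  # mean rate 1
#' @export
codon_model <- function(freqs, kappa, omega) {
  if (!inherits(freqs, "codon_frequencies"))
    stop("freqs must be a codon_frequencies object")
  for (v in c(kappa = kappa, omega = omega))
    if (!is.finite(v) || v < 0)
      stop("kappa and omega must be finite and nonnegative")
  b <- .build_Q(freqs$pi, kappa, omega)
  structure(list(code = genetic_code(), freqs = freqs,
                 kappa = kappa, omega = omega,
                 Q = b$Q, scale = b$scale),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat("Codon substitution model (", x$freqs$model_tag, "): kappa = ",
      format(x$kappa), ", omega = ", format(x$omega), "\n", sep = "")
  invisible(x)
}

# internal fast decomposition on the support of pi (all pi > 0 assumed)
.decomp_support <- function(pi, kappa, omega, pairs) {
  Q <- .build_Q(pi, kappa, omega, pairs)$Q
  d <- .eig_rev_cpp(Q, pi)
  if (!isTRUE(d$ok)) stop("eigendecomposition of the rate matrix failed")
  d$lambda <- as.numeric(d$lambda)
  d
}

# restrict the pair structure (and renumber states) to codons with pi > 0
.support_structure <- function(pi) {
  supp <- which(pi > 0)
  map <- integer(length(pi)); map[supp] <- seq_along(supp)
  pairs <- .codon_pair_structure()
  keep <- pairs$from %in% supp & pairs$to %in% supp
  pr <- pairs[keep, ]
  pr$from <- map[pr$from]; pr$to <- map[pr$to]
  list(support = supp, map = map, pairs = pr,
       pi = pi[supp] / sum(pi[supp]))
}

#' Spectral decomposition of a codon model
#'
#' Decomposes the (reversible) generator as Q = U diag(lambda) U^-1 via
#' similarity to a symmetric matrix, enabling fast evaluation of
#' P(t) = exp(Qt) for many t.  When some codon frequencies are 0 (possible
#' under F61) the decomposition is restricted to the support of pi; those
#' codons never occur in the data, so the likelihood is unaffected.
#'
#' @param model a [codon_model()] object.
#' @return An object of class `spectral_decomposition`: list with
#'   `lambda`, `U`, `Uinv`, `support` (indices of codons with pi > 0) and
#'   `defective` (TRUE if the decomposition failed validation and direct
#'   exponentiation must be used instead).
#' @export
spectral_decompose <- function(model) {
  stopifnot(inherits(model, "codon_model"))
  ss <- .support_structure(model$freqs$pi)
  d <- tryCatch(.decomp_support(ss$pi, model$kappa, model$omega, ss$pairs),
                error = function(e) NULL)
  defective <- TRUE
  if (!is.null(d)) {
    Qs <- model$Q[ss$support, ss$support, drop = FALSE]
    rebuild <- d$U %*% (d$lambda * d$Uinv)
    defective <- max(abs(rebuild - Qs)) > 1e-8
  }
  if (defective)
    warning("spectral decomposition numerically defective; ",
            "transition probabilities will use direct exponentiation")
  structure(list(lambda = if (defective) NULL else d$lambda,
                 U = if (defective) NULL else d$U,
                 Uinv = if (defective) NULL else d$Uinv,
                 support = ss$support, defective = defective),
            class = "spectral_decomposition")
}

# P(t) on the support from a decomposition; clamps round-off negatives
.ptrans <- function(dec, t) {
  P <- dec$U %*% (exp(dec$lambda * t) * dec$Uinv)
  P[P < 0 & P > -1e-12] <- 0
  P
}

#' Transition probabilities P(t) = exp(Qt)
#'
#' @param model a [codon_model()] object.
#' @param t nonnegative time (expected substitutions per codon).
#' @param decomposition optional precomputed [spectral_decompose()] result.
#' @return 61x61 row-stochastic matrix of codon transition probabilities.
#'   Rows/columns for codons with zero frequency (F61) are identity rows:
#'   such codons never occur in data under the model.
#' @examples
#' m <- codon_model(codon_frequencies(), 2, 0.3)
#' P <- transition_probabilities(m, 0.5)
#' range(rowSums(P))
#' @export
transition_probabilities <- function(model, t, decomposition = NULL) {
  stopifnot(inherits(model, "codon_model"))
  if (!is.finite(t) || t < 0) stop("t must be finite and nonnegative")
  if (is.null(decomposition)) decomposition <- spectral_decompose(model)
  k <- length(model$freqs$pi)
  P <- diag(k)
  supp <- decomposition$support
  if (decomposition$defective) {
    Qs <- model$Q[supp, supp, drop = FALSE]
    Ps <- as.matrix(Matrix::expm(Qs * t))
  } else {
    Ps <- .ptrans(decomposition, t)
  }
  P[supp, supp] <- Ps
  dimnames(P) <- list(names(model$freqs$pi), names(model$freqs$pi))
  P
}
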