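Package: pairomega
Title: Bayesian and Maximum-Likelihood Estimation of dN/dS from Pairwise
    Codon Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the nonsynonymous/synonymous rate ratio (omega =
    dN/dS) and the evolutionary distance t between two protein-coding
    sequences under a codon substitution model.  Provides maximum-likelihood
    estimation with boundary-case classification and a one-sided likelihood
    ratio test for positive selection, and Bayesian posterior means,
    variances and the posterior probability P(omega > 1 | x) computed by
    Gauss-Legendre quadrature after a logistic change of variables, so that
    estimates remain finite even for identical, saturated or
    single-class-difference alignments.  Includes Nei-Gojobori counting, a
    pairwise codon-sequence simulator, and a batch driver for genome-scale
    screens.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Matrix,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
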