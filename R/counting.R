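# Nei-Gojobori (1986) counting: synonymous/nonsynonymous site and
# difference counts, JC69 distance correction and sampling variances.
# These parameterise the logistic change of variables used by the Bayesian
# quadrature, and are reported alongside the model-based estimates.

# per-codon synonymous site counts: each position contributes
# (number of synonymous single-nucleotide changes) / 3; changes into stop
# codons are never synonymous, so each position is one full site and
# S + N = 3 L_c (this reproduces the standard S of ~73-74 per 100 codons
# under uniform usage)
.ng_site_table <- function() {
  cache <- .pkg_cache
  if (!is.null(cache$ng_sites)) return(cache$ng_sites)
  gc <- genetic_code()
  mat <- do.call(rbind, strsplit(gc$sense_codons, ""))
  s <- numeric(61)
  for (ci in 1:61) {
    for (p in 1:3) {
      alt <- setdiff(.NUC, mat[ci, p])
      neigh <- vapply(alt, function(nt) {
        cd <- mat[ci, ]; cd[p] <- nt; paste(cd, collapse = "")
      }, "")
      sense <- neigh[!(neigh %in% gc$stop_codons)]
      if (length(sense) > 0)
        s[ci] <- s[ci] + sum(gc$aa[sense] == gc$aa[ci]) / 3
    }
  }
  cache$ng_sites <- s
  s
}

# pathway-averaged (Sd, Nd) contributions for every ordered codon pair:
# orderings of the single changes are enumerated, pathways through stop
# codons are skipped, and the remainder averaged.  If every pathway is
# blocked (cannot happen for 1-2 differences under the standard code) all
# orderings are used with stop-involving steps counted as nonsynonymous.
.ng_path_tables <- function() {
  cache <- .pkg_cache
  if (!is.null(cache$ng_paths)) return(cache$ng_paths)
  gc <- genetic_code()
  codons64 <- .all_codons()
  aa64 <- .AA64
  names(aa64) <- codons64
  mat <- do.call(rbind, strsplit(gc$sense_codons, ""))
  Sd <- matrix(0, 61, 61); Nd <- matrix(0, 61, 61)
  perms <- list(`1` = list(1L),
                `2` = list(1:2, 2:1),
                `3` = list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                           c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  for (a in 1:61) for (b in 1:61) {
    if (a == b) next
    diffpos <- which(mat[a, ] != mat[b, ])
    k <- length(diffpos)
    walk <- function(order, allow_stop) {
      cur <- mat[a, ]; s <- 0; n <- 0
      for (p in diffpos[order]) {
        nxt <- cur; nxt[p] <- mat[b, p]
        cfrom <- paste(cur, collapse = ""); cto <- paste(nxt, collapse = "")
        if (aa64[cto] == "*" && cto != paste(mat[b, ], collapse = "")) {
          if (!allow_stop) return(NULL)
          n <- n + 1                       # blocked-step fallback
        } else if (aa64[cfrom] == "*" || aa64[cto] == "*") {
          n <- n + 1
        } else if (aa64[cfrom] == aa64[cto]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    }
    res <- Filter(Negate(is.null), lapply(perms[[k]], walk, allow_stop = FALSE))
    if (length(res) == 0)
      res <- lapply(perms[[k]], walk, allow_stop = TRUE)
    m <- colMeans(do.call(rbind, res))
    Sd[a, b] <- m[1]; Nd[a, b] <- m[2]
  }
  cache$ng_paths <- list(Sd = Sd, Nd = Nd)
  cache$ng_paths
}

#' Nei-Gojobori synonymous/nonsynonymous site counts
#'
#' Each codon position contributes one site, split as the fraction of its
#' three possible single-nucleotide changes that are synonymous (changes
#' into stop codons are never synonymous); `S` averages the two sequences
#' and `N = 3 L_c - S`.
#'
#' @param aln a `pair_alignment`.
#' @return Named numeric `c(S = , N = )`.
#' @export
ng_site_counts <- function(aln) {
  stopifnot(inherits(aln, "pair_alignment"), aln$L_c >= 1)
  s_tab <- .ng_site_table()
  gc <- genetic_code()
  i <- match(aln$codons1, gc$sense_codons)
  j <- match(aln$codons2, gc$sense_codons)
  S <- (sum(s_tab[i]) + sum(s_tab[j])) / 2
  c(S = S, N = 3 * aln$L_c - S)
}

#' Nei-Gojobori synonymous/nonsynonymous difference counts
#'
#' Codon pairs differing at k positions contribute counts averaged over the
#' k! orderings of the single changes, skipping pathways through stop
#' codons.
#'
#' @param aln a `pair_alignment`.
#' @return Named numeric `c(Sd = , Nd = )`.
#' @export
ng_difference_counts <- function(aln) {
  stopifnot(inherits(aln, "pair_alignment"), aln$L_c >= 1)
  tabs <- .ng_path_tables()
  p <- aln$patterns
  c(Sd = sum(p$n * tabs$Sd[cbind(p$i, p$j)]),
    Nd = sum(p$n * tabs$Nd[cbind(p$i, p$j)]))
}

#' Jukes-Cantor multiple-hit correction
#'
#' d = -(3/4) log(1 - 4p/3); undefined (NA, with the saturation flag set by
#' callers) for p >= 3/4.
#'
#' @param p proportion of differences per site, in `[0, 3/4)`.
#' @return Corrected distance; `NA` when saturated.
#' @examples
#' jc69_distance(0.3)  # 0.3831...
#' @export
jc69_distance <- function(p) {
  d <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
  if (anyNA(d)) warning("p >= 3/4: JC69 correction undefined (saturation)")
  d
}

# JC69 large-sample variance of the corrected distance
.jc69_var <- function(p, sites) 9 * p * (1 - p) / ((3 - 4 * p)^2 * sites)

#' Nei-Gojobori counting estimates for a pairwise alignment
#'
#' Computes S, N, Sd, Nd, the proportions pS and pN, JC69-corrected dS and
#' dN with their variances, and delta-method variances of the composite
#' estimators `omega_hat = dN/dS` and `t_hat = (S dS + N dN)/L_c` (the
#' per-codon expected number of nucleotide substitutions implied by dS and
#' dN), treating dS and dN as independent.
#'
#' @param aln a `pair_alignment`.
#' @return An object of class `ng_result`.
#' @export
ng_counts <- function(aln) {
  stopifnot(inherits(aln, "pair_alignment"), aln$L_c >= 1)
  sn <- ng_site_counts(aln)
  dd <- ng_difference_counts(aln)
  S <- sn[["S"]]; N <- sn[["N"]]
  Sd <- dd[["Sd"]]; Nd <- dd[["Nd"]]
  pS <- Sd / S; pN <- Nd / N
  saturated <- pS >= 0.74 || pN >= 0.74
  dS <- suppressWarnings(jc69_distance(pS))
  dN <- suppressWarnings(jc69_distance(pN))
  var_dS <- if (is.na(dS)) NA_real_ else .jc69_var(pS, S)
  var_dN <- if (is.na(dN)) NA_real_ else .jc69_var(pN, N)
  L_c <- aln$L_c
  if (!is.na(dS) && !is.na(dN)) {
    t_hat <- (S * dS + N * dN) / L_c
    var_t_hat <- (S / L_c)^2 * var_dS + (N / L_c)^2 * var_dN
    omega_hat <- if (dS > 0) dN / dS else NA_real_
    var_omega_hat <- if (!is.na(omega_hat) && dN > 0)
      omega_hat^2 * (var_dN / dN^2 + var_dS / dS^2) else NA_real_
  } else {
    t_hat <- NA_real_; var_t_hat <- NA_real_
    omega_hat <- NA_real_; var_omega_hat <- NA_real_
  }
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, var_dS = var_dS, var_dN = var_dN,
                 t_hat = t_hat, omega_hat = omega_hat,
                 var_t_hat = var_t_hat, var_omega_hat = var_omega_hat,
                 saturated = saturated, L_c = L_c),
            class = "ng_result")
}

#' @export
print.ng_result <- function(x, ...) {
  cat("Nei-Gojobori counts: S =", format(x$S, digits = 4),
      "N =", format(x$N, digits = 4),
      "Sd =", format(x$Sd, digits = 4),
      "Nd =", format(x$Nd, digits = 4), "\n")
  cat("  dS =", format(x$dS, digits = 4), " dN =", format(x$dN, digits = 4),
      " dN/dS =", format(x$omega_hat, digits = 4),
      if (x$saturated) " [saturated]" else "", "\n")
  invisible(x)
}
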