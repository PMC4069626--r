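# Standard nuclear genetic code in the T, C, A, G codon order used by most
# codon-model software; the 61 sense codons index the state space throughout.

.NUC <- c("T", "C", "A", "G")

# amino acids for the 64 codons TTT, TTC, TTA, TTG, TCT, ... (3rd position
# fastest), '*' marking stops
.AA64 <- strsplit(paste0(
  "FFLLSSSSYY**CC*W",
  "LLLLPPPPHHQQRRRR",
  "IIIMTTTTNNKKSSRR",
  "VVVVAAAADDEEGGGG"), "")[[1]]

.all_codons <- function() {
  g <- expand.grid(n3 = .NUC, n2 = .NUC, n1 = .NUC, stringsAsFactors = FALSE)
  paste0(g$n1, g$n2, g$n3)
}

#' Standard genetic code tables
#'
#' Returns the standard nuclear genetic code restricted to its 61 sense
#' codons (stop codons TAA, TAG and TGA are excluded, as the codon
#' substitution model assumes stops do not occur within reading frames).
#'
#' @return An object of class `genetic_code`: a list with `sense_codons`
#'   (character vector of length 61, in T/C/A/G codon order), `aa` (named
#'   character vector mapping each sense codon to its one-letter amino
#'   acid), and `stop_codons`.
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons)  # 61
#' gc$aa["ATG"]             # "M"
#' @export
genetic_code <- function() {
  cache <- .pkg_cache
  if (is.null(cache$code)) {
    codons <- .all_codons()
    names(.AA64) <- codons
    sense <- codons[.AA64 != "*"]
    cache$code <- structure(
      list(sense_codons = sense,
           aa = .AA64[sense],
           stop_codons = codons[.AA64 == "*"]),
      class = "genetic_code")
  }
  cache$code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$sense_codons), "sense codons,",
      "stops", paste(x$stop_codons, collapse = ", "), "\n")
  invisible(x)
}

# TRUE when the single-nucleotide change a -> b is a transition
is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

# Table of all ordered sense-codon pairs differing at exactly one position,
# with transition and synonymy flags.  Drives rate-matrix construction.
.codon_pair_structure <- function() {
  cache <- .pkg_cache
  if (!is.null(cache$pairs)) return(cache$pairs)
  gc <- genetic_code()
  codons <- gc$sense_codons
  mat <- do.call(rbind, strsplit(codons, ""))
  from <- integer(0); to <- integer(0); pos <- integer(0)
  for (p in 1:3) {
    same_other <- apply(mat[, -p, drop = FALSE], 1, paste, collapse = "")
    grp <- split(seq_along(codons), same_other)
    for (idx in grp) {
      if (length(idx) < 2) next
      pr <- expand.grid(i = idx, j = idx)
      pr <- pr[pr$i != pr$j, ]
      from <- c(from, pr$i); to <- c(to, pr$j); pos <- c(pos, rep(p, nrow(pr)))
    }
  }
  ts <- is_transition(mat[cbind(from, pos)], mat[cbind(to, pos)])
  syn <- gc$aa[from] == gc$aa[to]
  cache$pairs <- data.frame(from = from, to = to, pos = pos,
                            transition = ts, synonymous = unname(syn))
  cache$pairs
}
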