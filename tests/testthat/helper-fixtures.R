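# Fixture generators for the five boundary scenarios: normal (case I),
# identical (II), synonymous-only (III), nonsynonymous-only (IV) and
# random (V) sequence pairs.  All are built in code, seeded.

# codons that have at least one synonymous / nonsynonymous single-nt
# sense neighbour, with one such neighbour picked at random
.neighbours <- function(codon, synonymous) {
  gc <- genetic_code()
  a <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) for (nt in setdiff(c("T", "C", "A", "G"), a[p])) {
    b <- a; b[p] <- nt
    cd <- paste(b, collapse = "")
    if (!(cd %in% gc$sense_codons)) next
    same_aa <- gc$aa[cd] == gc$aa[codon]
    if (same_aa == synonymous) out <- c(out, cd)
  }
  out
}

fixture_identical <- function(L = 100, seed = 1)
  simulate_pair(L, t = 0, omega = 0.5, seed = seed)

# pair whose differences are exclusively synonymous (case III) or
# exclusively nonsynonymous (case IV) single-nucleotide changes
fixture_one_class <- function(L = 100, n_changes = 15, synonymous = TRUE,
                              seed = 1) {
  gc <- genetic_code()
  set.seed(seed)
  c1 <- sample(gc$sense_codons, L, replace = TRUE)
  c2 <- c1
  eligible <- which(vapply(c1, function(cd)
    length(.neighbours(cd, synonymous)) > 0, TRUE))
  sites <- sample(eligible, min(n_changes, length(eligible)))
  for (s in sites) {
    nb <- .neighbours(c1[s], synonymous)
    c2[s] <- nb[sample.int(length(nb), 1)]
  }
  pair_alignment(c1, c2)
}

fixture_random <- function(L = 100, seed = 1) {
  gc <- genetic_code()
  set.seed(seed)
  pair_alignment(sample(gc$sense_codons, L, replace = TRUE),
                 sample(gc$sense_codons, L, replace = TRUE))
}
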