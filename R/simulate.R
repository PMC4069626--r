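# Pairwise codon-alignment simulator.  Sites are i.i.d.: the codon in
# sequence 1 is drawn from the equilibrium frequencies and the codon in
# sequence 2 from the corresponding row of P(t); by reversibility this is
# equivalent to evolving both sequences from a common ancestor with total
# path length t.  No indels are simulated.

#' Simulate a pairwise codon alignment
#'
#' @param L_c number of codon sites (>= 1).
#' @param t evolutionary distance between the two sequences, in expected
#'   nucleotide substitutions per codon (>= 0).
#' @param omega dN/dS ratio.
#' @param kappa transition/transversion rate ratio (default 2).
#' @param freqs a [codon_frequencies()] object (default Fequal).
#' @param seed optional integer seed; when given the draw is reproducible
#'   and the global RNG state is left untouched.
#' @param names sequence identifiers.
#' @return A `pair_alignment`.
#' @examples
#' aln <- simulate_pair(100, t = 0.5, omega = 0.5, seed = 1)
#' aln$L_c
#' @export
simulate_pair <- function(L_c, t, omega, kappa = 2,
                          freqs = codon_frequencies(), seed = NULL,
                          names = c("seq1", "seq2")) {
  stopifnot(L_c >= 1, t >= 0, omega >= 0, kappa >= 0)
  gc <- genetic_code()
  pi <- freqs$pi
  .with_seed(seed, {
    i <- sample.int(61, L_c, replace = TRUE, prob = pi)
    if (t == 0) {
      j <- i
    } else {
      model <- codon_model(freqs, kappa, omega)
      P <- transition_probabilities(model, t)
      j <- integer(L_c)
      for (ci in unique(i)) {
        sel <- i == ci
        j[sel] <- sample.int(61, sum(sel), replace = TRUE, prob = P[ci, ])
      }
    }
    pair_alignment(gc$sense_codons[i], gc$sense_codons[j], names = names)
  })
}

#' Replicate manifest for a simulation study
#'
#' Builds the full factorial grid of (t, omega) cells with `replicates`
#' replicates per cell and a deterministic per-replicate seed derived from
#' the study seed, so any replicate is reproducible in isolation; the same
#' study seed yields bitwise-identical sequences.
#'
#' @param t_values,omega_values numeric vectors defining the grid.
#' @param L_c codons per sequence (default 500).
#' @param replicates replicates per cell.
#' @param kappa transition/transversion ratio (default 2).
#' @param seed study seed (integer).
#' @param dir optional directory: when given, each replicate is written as
#'   a FASTA file and a `manifest.tsv` is written alongside.
#' @param freqs a [codon_frequencies()] object (default Fequal).
#' @return Data frame with columns `cell`, `t`, `omega`, `replicate`,
#'   `seed` and (when `dir` is given) `file`.
#' @export
simulate_study <- function(t_values, omega_values, L_c = 500, replicates,
                           kappa = 2, seed = 1, dir = NULL,
                           freqs = codon_frequencies()) {
  stopifnot(replicates >= 1)
  grid <- expand.grid(t = t_values, omega = omega_values,
                      KEEP.OUT.ATTRS = FALSE)
  cells <- nrow(grid)
  man <- data.frame(
    cell = rep(seq_len(cells), each = replicates),
    t = rep(grid$t, each = replicates),
    omega = rep(grid$omega, each = replicates),
    replicate = rep(seq_len(replicates), cells))
  # per-replicate substream seeds, kept within 32-bit integer range
  man$seed <- as.integer((as.numeric(seed) * 7919 +
                            (man$cell - 1) * 1e5 + man$replicate) %%
                           .Machine$integer.max)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    man$file <- file.path(dir, sprintf("cell%02d_rep%05d.fasta",
                                       man$cell, man$replicate))
    for (k in seq_len(nrow(man))) {
      aln <- simulate_pair(L_c, man$t[k], man$omega[k], kappa,
                           freqs = freqs, seed = man$seed[k])
      write_pair_fasta(aln, man$file[k])
    }
    write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  attr(man, "L_c") <- L_c
  attr(man, "kappa") <- kappa
  man
}
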