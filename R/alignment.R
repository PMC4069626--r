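#' Read a pairwise codon alignment
#'
#' Reads an in-frame alignment of exactly two equal-length sequences from a
#' FASTA or sequential PHYLIP file.  Sequences are uppercased and RNA 'U'
#' is mapped to 'T'; no cleaning is performed at this stage (see
#' [clean_and_compress()]).
#'
#' @param file path to the alignment file.
#' @param format `"auto"` (default; FASTA if the first non-blank character
#'   is '>'), `"fasta"` or `"phylip"`.
#' @return An object of class `raw_pair_alignment`: list with `names`
#'   (two identifiers) and `seqs` (two nucleotide strings).
#' @export
read_pair_alignment <- function(file, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L)
    format <- if (grepl("^\\s*>", first)) "fasta" else "phylip"
  }
  if (format == "fasta") {
    # BStringSet keeps gaps, ambiguity codes and RNA 'U' verbatim
    dna <- Biostrings::readBStringSet(file)
    seqs <- as.character(dna)
    nms <- sub("\\s.*$", "", names(dna))  # identifier = first header token
  } else {
    dna <- ape::read.dna(file, format = "sequential", as.character = TRUE)
    seqs <- apply(dna, 1, paste, collapse = "")
    nms <- rownames(dna)
  }
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (length(seqs) != 2)
    stop("expected exactly 2 sequences in '", file, "', found ",
         length(seqs))
  if (nchar(seqs[1]) != nchar(seqs[2]))
    stop("sequences '", nms[1], "' (", nchar(seqs[1]), " nt) and '", nms[2],
         "' (", nchar(seqs[2]), " nt) have unequal lengths")
  if (nchar(seqs[1]) %% 3 != 0)
    stop("alignment length ", nchar(seqs[1]), " of '", nms[1],
         "' is not a multiple of 3")
  structure(list(names = nms, seqs = unname(seqs)),
            class = "raw_pair_alignment")
}

.split_codons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

#' Clean and compress a pairwise alignment
#'
#' Removes every codon site at which either sequence contains a non-ACGT
#' character (gap or ambiguity) or a stop codon, then compresses the
#' remaining sites into site-pattern counts.  Pattern compression is
#' lossless for the likelihood, which only depends on how many times each
#' ordered codon pair occurs.
#'
#' @param raw a `raw_pair_alignment` from [read_pair_alignment()], or a
#'   character vector of two nucleotide strings.
#' @param max_short genes with `L_c <= max_short` retained codons are
#'   flagged `excluded_short` (the genome-screen length filter); default 50.
#' @return A list with `aln` (class `pair_alignment`: `names`, `codons1`,
#'   `codons2`, `L_c`, and `patterns`, a data frame of codon-state indices
#'   `i`, `j` with counts `n`) and `report` (class `cleaning_report`:
#'   `sites_removed_gap_ambiguity`, `sites_removed_stop`, `excluded_short`).
#' @export
clean_and_compress <- function(raw, max_short = 50) {
  if (is.character(raw) && length(raw) == 2)
    raw <- structure(list(names = c("seq1", "seq2"),
                          seqs = gsub("U", "T", toupper(raw), fixed = TRUE)),
                     class = "raw_pair_alignment")
  stopifnot(inherits(raw, "raw_pair_alignment"))
  gc <- genetic_code()
  c1 <- .split_codons(raw$seqs[1])
  c2 <- .split_codons(raw$seqs[2])
  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  is_stop <- (c1 %in% gc$stop_codons) | (c2 %in% gc$stop_codons)
  keep <- clean & !is_stop
  n_stop <- sum(clean & is_stop)
  if (n_stop > 0)
    warning(n_stop, " codon site(s) containing stop codons removed")
  c1 <- c1[keep]; c2 <- c2[keep]
  i <- match(c1, gc$sense_codons)
  j <- match(c2, gc$sense_codons)
  L_c <- length(i)
  if (L_c == 0) {
    warning("no codon sites retained after cleaning; ",
            "likelihood is constant and the posterior equals the prior")
    patterns <- data.frame(i = integer(0), j = integer(0), n = integer(0))
  } else {
    tab <- table(i * 64L + j)
    key <- as.integer(names(tab))
    patterns <- data.frame(i = key %/% 64L, j = key %% 64L,
                           n = as.integer(tab))
  }
  aln <- structure(list(names = raw$names, codons1 = c1, codons2 = c2,
                        L_c = L_c, patterns = patterns),
                   class = "pair_alignment")
  report <- structure(
    list(sites_removed_gap_ambiguity = sum(!clean),
         sites_removed_stop = n_stop,
         excluded_short = L_c <= max_short),
    class = "cleaning_report")
  list(aln = aln, report = report)
}

#' Construct a cleaned pairwise alignment from two sequences
#'
#' Convenience wrapper around [clean_and_compress()] returning the
#' `pair_alignment` only (the cleaning report is attached as attribute
#' `"report"`).
#'
#' @param seq1,seq2 nucleotide strings (equal length, multiple of 3), or
#'   character vectors of codons.
#' @param names two sequence identifiers.
#' @return A `pair_alignment` object.
#' @examples
#' a <- pair_alignment("TTTTTCAAA", "TTCTTCAAG")
#' a$patterns
#' @export
pair_alignment <- function(seq1, seq2, names = c("seq1", "seq2")) {
  if (length(seq1) > 1) seq1 <- paste(seq1, collapse = "")
  if (length(seq2) > 1) seq2 <- paste(seq2, collapse = "")
  if (nchar(seq1) != nchar(seq2)) stop("sequences have unequal lengths")
  if (nchar(seq1) %% 3 != 0) stop("length is not a multiple of 3")
  raw <- structure(list(names = names,
                        seqs = gsub("U", "T", toupper(c(seq1, seq2)),
                                    fixed = TRUE)),
                   class = "raw_pair_alignment")
  cc <- clean_and_compress(raw)
  structure(cc$aln, report = cc$report)
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat("Pairwise codon alignment: ", x$names[1], " vs ", x$names[2], ", ",
      x$L_c, " codon sites (", nrow(x$patterns), " distinct patterns)\n",
      sep = "")
  invisible(x)
}

#' Observed codon frequencies (F61)
#'
#' Codon frequencies estimated as the observed proportions across both
#' sequences of a cleaned alignment.
#'
#' @param aln a `pair_alignment`.
#' @return A [codon_frequencies()] object with `model_tag = "F61"`; falls
#'   back to `Fequal` with a warning when the alignment has no sites.
#' @export
observed_codon_frequencies <- function(aln) {
  stopifnot(inherits(aln, "pair_alignment"))
  if (aln$L_c == 0) {
    warning("empty alignment: falling back to Fequal frequencies")
    return(codon_frequencies("Fequal"))
  }
  gc <- genetic_code()
  counts <- table(factor(c(aln$codons1, aln$codons2),
                         levels = gc$sense_codons))
  codon_frequencies("F61", pi = as.numeric(counts) / (2 * aln$L_c))
}

#' Write a pairwise alignment to FASTA
#'
#' @param aln a `pair_alignment` (cleaned codons are written) or
#'   `raw_pair_alignment`.
#' @param file output path.
#' @export
write_pair_fasta <- function(aln, file) {
  if (inherits(aln, "pair_alignment")) {
    seqs <- c(paste(aln$codons1, collapse = ""),
              paste(aln$codons2, collapse = ""))
    nms <- aln$names
  } else {
    seqs <- aln$seqs; nms <- aln$names
  }
  dna <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  names(dna) <- nms
  ape::write.FASTA(dna, file)
  invisible(file)
}
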