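# Genome-scale driver: counting + ML + Bayesian estimation over many gene
# alignments, with the N_0 / N_inf / N_L / N_B bookkeeping used in
# genome-screen summary tables.

#' Full estimation for one gene pair
#'
#' Runs Nei-Gojobori counting, maximum-likelihood and Bayesian estimation
#' on one pairwise alignment and returns a one-row data frame.
#'
#' @param x a `pair_alignment`, a `raw_pair_alignment`, or a file path.
#' @param freq_model `"Fequal"` or `"F61"` (observed frequencies of this
#'   gene).
#' @param prior a [gamma_prior()].
#' @param n quadrature points per dimension.
#' @param gene gene identifier for the output row.
#' @return A one-row data frame (see [run_batch()] for columns).
#' @export
estimate_pair <- function(x, freq_model = c("F61", "Fequal"),
                          prior = gamma_prior(), n = 32, gene = NULL) {
  freq_model <- match.arg(freq_model)
  if (is.character(x) && length(x) == 1) {
    if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(x))
    x <- read_pair_alignment(x)
  }
  if (inherits(x, "raw_pair_alignment")) x <- clean_and_compress(x)$aln
  stopifnot(inherits(x, "pair_alignment"))
  if (is.null(gene)) gene <- paste(x$names, collapse = "_")

  freqs <- if (freq_model == "F61" && x$L_c > 0)
    suppressWarnings(observed_codon_frequencies(x))
  else codon_frequencies("Fequal")

  ng <- if (x$L_c >= 1) suppressWarnings(ng_counts(x)) else NULL
  ml <- if (x$L_c >= 1) mle_pairwise(x, freqs, se = FALSE) else NULL
  bb <- bayes_pairwise(x, freqs, prior = prior, n = n, ml = ml)

  data.frame(
    gene = gene, L_c = x$L_c,
    S = if (is.null(ng)) NA_real_ else ng$S,
    N = if (is.null(ng)) NA_real_ else ng$N,
    Sd = if (is.null(ng)) NA_real_ else ng$Sd,
    Nd = if (is.null(ng)) NA_real_ else ng$Nd,
    dS_ng = if (is.null(ng)) NA_real_ else ng$dS,
    dN_ng = if (is.null(ng)) NA_real_ else ng$dN,
    kappa_hat = bb$kappa,
    t_ml = if (is.null(ml)) NA_real_ else ml$t_hat,
    omega_ml = if (is.null(ml)) NA_real_ else ml$omega_hat,
    boundary = if (is.null(ml)) "no_data" else ml$boundary,
    logL = if (is.null(ml)) NA_real_ else ml$logL,
    lrt_stat = if (is.null(ml)) NA_real_ else ml$lrt_stat,
    lrt_sig = if (is.null(ml)) FALSE else isTRUE(ml$significant_5pct),
    t_bayes = bb$mean_t, omega_bayes = bb$mean_omega,
    var_t = bb$var_t, var_omega = bb$var_omega,
    cov_t_omega = bb$cov_t_omega,
    prob_pos = bb$prob_omega_gt1,
    bayes_sig = bb$prob_omega_gt1 > 0.95,
    branch = bb$transform$source,
    stringsAsFactors = FALSE)
}

#' Batch estimation over many gene alignments
#'
#' Applies cleaning and the short-gene filter, then runs counting, ML and
#' Bayesian estimation on every retained gene.  Every retained gene gets
#' finite Bayesian summaries even when the ML estimates carry 0/Inf
#' sentinels.  Output is deterministic given inputs and configuration.
#'
#' @param files character vector of alignment file paths, a directory, or
#'   a manifest data frame with a `file` column (e.g. from
#'   [simulate_study()]).
#' @param freq_model `"F61"` (per-gene observed frequencies, the default)
#'   or `"Fequal"`.
#' @param prior a [gamma_prior()].
#' @param n quadrature points per dimension.
#' @param min_codons genes with `L_c <= min_codons` are excluded
#'   (default 50; set to 0 to keep everything).
#' @param out_prefix optional path prefix: writes `<prefix>_genes.tsv` and
#'   `<prefix>_summary.tsv`.
#' @return List with `genes` (per-gene data frame), `summary` (from
#'   [batch_summary()]), `excluded_short` and `failed` gene counts.
#' @export
run_batch <- function(files, freq_model = c("F61", "Fequal"),
                      prior = gamma_prior(), n = 32, min_codons = 50,
                      out_prefix = NULL) {
  freq_model <- match.arg(freq_model)
  if (is.data.frame(files)) files <- files$file
  if (length(files) == 1 && dir.exists(files))
    files <- list.files(files, pattern = "\\.(fa|fasta|fas|phy|phylip)$",
                        full.names = TRUE)
  rows <- list(); excluded <- 0L; failed <- 0L
  for (f in files) {
    row <- tryCatch({
      raw <- read_pair_alignment(f)
      cc <- suppressWarnings(clean_and_compress(raw, max_short = min_codons))
      if (cc$report$excluded_short && min_codons > 0) {
        excluded <- excluded + 1L
        NULL
      } else {
        estimate_pair(cc$aln, freq_model = freq_model, prior = prior,
                      n = n, gene = sub("\\.[^.]*$", "", basename(f)))
      }
    }, error = function(e) {
      message("skipping '", f, "': ", conditionMessage(e))
      failed <<- failed + 1L
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  genes <- if (length(rows)) do.call(rbind, rows) else NULL
  summ <- if (!is.null(genes)) batch_summary(genes) else NULL
  if (!is.null(out_prefix) && !is.null(genes)) {
    gtab <- genes
    # human-readable sentinels alongside the machine-readable boundary flag
    gtab$t_ml <- ifelse(is.infinite(gtab$t_ml), "inf",
                        format(gtab$t_ml, digits = 6))
    gtab$omega_ml <- ifelse(is.infinite(gtab$omega_ml), "inf",
                            format(gtab$omega_ml, digits = 6))
    write.table(gtab, paste0(out_prefix, "_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summ, paste0(out_prefix, "_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(genes = genes, summary = summ,
       excluded_short = excluded, failed = failed)
}

#' Summary statistics over a batch of genes
#'
#' Mean, SD and quartiles per statistic, with the genome-screen
#' conventions: ML summaries are computed after removing infinite
#' estimates (zeros are kept), Bayesian summaries include all genes, and
#' the counts N_0 and N_inf (boundary MLEs of t and omega), N_L
#' (significant one-sided LRTs) and N_B (genes with
#' P(omega > 1 | x) > 0.95) are reported.
#'
#' @param genes per-gene data frame from [run_batch()].
#' @return Data frame with one row per (statistic, method).
#' @export
batch_summary <- function(genes) {
  qstats <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(rep(NA_real_, 6))
    c(mean(v), stats::sd(v), stats::quantile(v, c(0.25, 0.5, 0.75)),
      length(v))
  }
  rows <- rbind(
    t_bayes = qstats(genes$t_bayes),
    omega_bayes = qstats(genes$omega_bayes),
    t_ml = qstats(genes$t_ml),
    omega_ml = qstats(genes$omega_ml))
  out <- data.frame(statistic = rownames(rows),
                    mean = rows[, 1], sd = rows[, 2],
                    q25 = rows[, 3], median = rows[, 4], q75 = rows[, 5],
                    n_used = rows[, 6], row.names = NULL)
  counts <- data.frame(
    n_genes = nrow(genes),
    N0_t = sum(genes$t_ml == 0, na.rm = TRUE),
    Ninf_t = sum(is.infinite(genes$t_ml), na.rm = TRUE),
    N0_omega = sum(genes$omega_ml == 0, na.rm = TRUE),
    Ninf_omega = sum(is.infinite(genes$omega_ml), na.rm = TRUE),
    n_omega_ml_gt1 = sum(genes$omega_ml > 1, na.rm = TRUE),
    n_omega_bayes_gt1 = sum(genes$omega_bayes > 1, na.rm = TRUE),
    N_L = sum(genes$lrt_sig, na.rm = TRUE),
    N_B = sum(genes$bayes_sig, na.rm = TRUE))
  merge(out, counts)
}
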