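## Accuracy metrics and the deconvolved-vs-naive benchmark: estimated
## counts, RPKM, the Error Fraction (fraction of transcripts whose
## estimate deviates from truth by more than a percent-error threshold),
## and the mixing-proportion grid experiment.

#' Expected read counts per transcript and cell type
#'
#' Cell a counts combine the pure sample and the a-attributed share of
#' the mixed sample: N_p q_p + N_m q_ma; cell b counts are N_m q_mb.
#' Column sums equal N_p + N_m tau_a and N_m tau_b respectively.
#'
#' @param stats a \code{sufficient_stats} (or a \code{demix_fit}, whose
#'   stats and read counts are then used).
#' @param N_p,N_m read counts of the pure and mixed samples.
#' @return list with numeric vectors \code{counts_a}, \code{counts_b}.
#' @export
estimated_counts <- function(stats, N_p = NULL, N_m = NULL) {
  if (inherits(stats, "demix_fit")) {
    N_p <- stats$N_p; N_m <- stats$N_m; stats <- stats$stats
  }
  stopifnot(inherits(stats, "sufficient_stats"),
            !is.null(N_p), !is.null(N_m))
  list(counts_a = N_p * stats$q_p + N_m * stats$q_ma,
       counts_b = N_m * stats$q_mb)
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts per-transcript read counts.
#' @param lengths transcript lengths in nt (raw, not effective).
#' @param total_mapped total mapped reads of the library.
#' @return numeric vector of RPKM values.
#' @export
rpkm <- function(counts, lengths, total_mapped) {
  stopifnot(length(counts) == length(lengths), total_mapped >= 1)
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  counts / (lengths / 1e3) / (total_mapped / 1e6)
}

#' Error Fraction of an estimate against ground truth
#'
#' Percent error is |est - truth| / truth * 100 per transcript;
#' transcripts whose truth is zero are excluded from the denominator and
#' reported as \code{n_excluded}.  The Error Fraction is the fraction of
#' compared transcripts with percent error above \code{threshold}
#' (default 10).
#'
#' @param estimate,truth aligned per-transcript value vectors (counts,
#'   RPKM, or sampling probabilities).
#' @param threshold percent-error threshold, default 10.
#' @return object of class \code{eval_report}: list with
#'   \code{error_fraction}, \code{percent_error} (NA where excluded),
#'   \code{flagged}, \code{n_compared}, \code{n_excluded},
#'   \code{threshold}.
#' @export
error_fraction <- function(estimate, truth, threshold = 10) {
  if (length(estimate) != length(truth))
    stop("estimate and truth must have equal length")
  pe <- rep(NA_real_, length(truth))
  cmp <- truth > 0
  pe[cmp] <- abs(estimate[cmp] - truth[cmp]) / truth[cmp] * 100
  flagged <- !is.na(pe) & pe > threshold
  structure(list(error_fraction = if (any(cmp)) sum(flagged) / sum(cmp) else NA_real_,
                 percent_error = pe, flagged = flagged,
                 n_compared = sum(cmp), n_excluded = sum(!cmp),
                 threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: EF = %.3f (threshold %g%%), %d compared, %d excluded\n",
              x$error_fraction, x$threshold, x$n_compared, x$n_excluded))
  invisible(x)
}

## EF between two count vectors after within-library RPKM normalisation.
ef_rpkm <- function(est_counts, true_counts, lengths, threshold = 10) {
  est_r <- rpkm(est_counts, lengths, max(sum(est_counts), 1))
  tru_r <- rpkm(true_counts, lengths, max(sum(true_counts), 1))
  error_fraction(est_r, tru_r, threshold)
}

#' Deconvolved-versus-naive benchmark over a mixing-proportion grid
#'
#' For each cell type b proportion: simulates a pure and a mixed read
#' set from one fixed pair of abundance profiles, fits (i) the full
#' deconvolution model with the prior at the true proportion and (ii)
#' the naive mode that treats the mixed sample as pure, then scores the
#' Error Fraction of estimated abundances against the ground-truth
#' ledger.  Comparisons use RPKM-normalised counts so libraries of
#' different effective sizes (the naive fit spans the whole mixed
#' library; the truth for cell b is only its b-read subset) are
#' comparable.
#'
#' @param tau_grid mixing proportions to scan (default 0.4-0.9 in steps
#'   of 0.1).
#' @param config a \code{\link{sim_config}} describing the simulated
#'   world (catalog size, read numbers, fragment model, seed).
#' @param em an \code{\link{em_config}} for the fits.
#' @param threshold Error Fraction percent threshold (default 10).
#' @param bias enable bias correction in the deconvolution fits.
#' @return data.frame with one row per (proportion, method, cell_type):
#'   columns proportion, method ("deconvolved"/"naive"), cell_type,
#'   error_fraction, n_compared, n_excluded.
#' @export
run_benchmark <- function(tau_grid = seq(0.4, 0.9, by = 0.1),
                          config = sim_config(), em = em_config(),
                          threshold = 10, bias = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  catalog <- generate_catalog(config)
  T <- length(catalog$ids)
  ab <- generate_abundances(catalog, seed = config$seed + 1L,
                            concentration = config$concentration)
  rows <- list()
  for (k in seq_along(tau_grid)) {
    tb <- tau_grid[k]
    pure <- generate_reads(catalog, ab$rho_a, config$n_reads_pure,
                           frag = config$frag,
                           read_length = config$read_length,
                           bias_spec = config$bias_spec,
                           seed = config$seed + 100L + k,
                           sample_tag = "pure", with_seqs = FALSE)
    mixed <- generate_mixture(catalog, ab$rho_a, ab$rho_b, tb,
                              config$n_reads_mixed, frag = config$frag,
                              read_length = config$read_length,
                              bias_spec = config$bias_spec,
                              seed = config$seed + 200L + k,
                              with_seqs = FALSE)
    em_k <- em_config(forget_sigma = em$forget_sigma, epochs = em$epochs,
                      tol = em$tol, seed = em$seed + k,
                      minibatch = em$minibatch)
    fit <- fit_demix(catalog, pure$aln, mixed$aln, prior_b = tb,
                     frag = config$frag, config = em_k, bias = bias)
    naive <- fit_single(catalog, mixed$aln, frag = config$frag,
                        config = em_k)

    truth_a <- true_counts(pure$truth, T) +
      true_counts(mixed$truth, T, cell = "a")
    truth_b <- true_counts(mixed$truth, T, cell = "b")

    ef_da <- ef_rpkm(fit$counts$counts_a, truth_a, catalog$lengths, threshold)
    ef_db <- ef_rpkm(fit$counts$counts_b, truth_b, catalog$lengths, threshold)
    ef_nb <- ef_rpkm(naive$counts$counts_a, truth_b, catalog$lengths, threshold)

    add <- function(method, cell, ef)
      data.frame(proportion = tb, method = method, cell_type = cell,
                 error_fraction = ef$error_fraction,
                 n_compared = ef$n_compared, n_excluded = ef$n_excluded)
    rows[[length(rows) + 1L]] <- rbind(add("deconvolved", "a", ef_da),
                                       add("deconvolved", "b", ef_db),
                                       add("naive", "b", ef_nb))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
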