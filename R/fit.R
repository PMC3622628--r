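## High-level fitting front ends: the full two-sample deconvolution
## (optionally with bias correction) and the single-sample "naive" mode
## that treats one read set as a pure sample — the baseline the
## deconvolution is benchmarked against.

#' Fit the deconvolution model to a pure and a mixed sample
#'
#' Computes effective lengths, optionally runs a bias-free warm-up epoch
#' to train the bias models (which are then frozen), and fits the full
#' model by online EM.
#'
#' @param catalog a \code{transcript_catalog}.
#' @param pure_aln,mixed_aln \code{alignment_set}s of the two samples.
#' @param prior_b prior proportion of cell type b in the mixed sample.
#' @param beta_scale Beta prior strength multiplier (default 10; the
#'   pseudo-counts total about \code{beta_scale} times the mixed read
#'   count).
#' @param frag a \code{fragment_model} (defaults mu = 200, sigma = 80).
#' @param config an \code{\link{em_config}}.
#' @param bias enable positional/sequence bias correction (requires
#'   catalog sequences).
#' @param bias_cfg a \code{\link{bias_config}}.
#' @return a \code{demix_fit} augmented with \code{catalog_ids},
#'   \code{l_eff}, \code{counts} (per-transcript estimated counts per
#'   cell type) and, when bias is enabled, \code{bias_model}.
#' @export
fit_demix <- function(catalog, pure_aln, mixed_aln, prior_b,
                      beta_scale = 10, frag = fragment_model(),
                      config = em_config(), bias = FALSE,
                      bias_cfg = bias_config()) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  l_eff <- effective_lengths(catalog, frag)
  wp <- wm <- NULL
  bias_model <- NULL
  if (bias) {
    warm_cfg <- em_config(forget_sigma = config$forget_sigma, epochs = 1L,
                          tol = config$tol, seed = config$seed,
                          minibatch = config$minibatch)
    warm <- run_online_em(pure_aln, mixed_aln, l_eff, prior_b, beta_scale,
                          config = warm_cfg)
    alpha_m <- mixed_alpha_linear(warm$params$alpha_a, warm$params$alpha_b,
                                  warm$params$tau_a, warm$params$tau_b)
    bias_model <- train_bias(list(pure_aln, mixed_aln), catalog, l_eff,
                             list(warm$params$alpha_a, alpha_m),
                             config = bias_cfg)
    wp <- apply_bias(pure_aln, bias_model, catalog, l_eff)
    wm <- apply_bias(mixed_aln, bias_model, catalog, l_eff)
  }
  fit <- run_online_em(pure_aln, mixed_aln, l_eff, prior_b, beta_scale,
                       config = config, weights_pure = wp,
                       weights_mixed = wm)
  fit$catalog_ids <- catalog$ids
  fit$lengths <- catalog$lengths
  fit$l_eff <- l_eff
  fit$bias_model <- bias_model
  fit$counts <- estimated_counts(fit$stats, fit$N_p, fit$N_m)
  fit
}

#' Naive single-sample fit
#'
#' Treats one read set as a pure sample and estimates a single abundance
#' profile — the conventional analysis that ignores tissue heterogeneity.
#' Used as the comparison baseline for the mixed sample.
#'
#' @param catalog a \code{transcript_catalog}.
#' @param aln the read set to fit.
#' @param frag a \code{fragment_model}.
#' @param config an \code{\link{em_config}}.
#' @return a \code{demix_fit} with \code{N_m = 0}; \code{counts$counts_a}
#'   holds the estimated counts of the single profile.
#' @export
fit_single <- function(catalog, aln, frag = fragment_model(),
                       config = em_config()) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  l_eff <- effective_lengths(catalog, frag)
  fit <- run_online_em(aln, NULL, l_eff, prior_b = 0, config = config)
  fit$catalog_ids <- catalog$ids
  fit$lengths <- catalog$lengths
  fit$l_eff <- l_eff
  fit$counts <- list(counts_a = fit$N_p * fit$stats$q_p,
                     counts_b = rep(0, length(l_eff)))
  fit
}
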