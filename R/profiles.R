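## Relative abundance (rho) and read sampling probability (alpha) profiles,
## the linear mixed-sample composition and its nonlinearity diagnostics,
## and the model log-posterior.

check_profile <- function(x, what = "profile", tol = 1e-9) {
  if (!is.numeric(x) || length(x) < 1L)
    stop(what, " must be a nonempty numeric vector")
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " entries must be finite and nonnegative")
  if (abs(sum(x) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(x)), ")")
  invisible(x)
}

#' Convert relative abundances to read sampling probabilities
#'
#' A read is drawn from transcript t with probability proportional to
#' rho_t * l_eff_t: longer transcripts contribute proportionally more reads
#' at equal molar abundance.
#'
#' @param rho relative abundance vector (nonnegative, sums to 1).
#' @param l_eff effective lengths aligned to the same catalog.
#' @return sampling probability vector alpha summing to 1.
#' @export
rho_to_alpha <- function(rho, l_eff) {
  check_profile(rho, "rho")
  stopifnot(length(rho) == length(l_eff), all(l_eff > 0))
  num <- rho * l_eff
  s <- sum(num)
  if (s <= 0) stop("degenerate profile: all rho * l_eff are zero")
  num / s
}

#' Convert read sampling probabilities back to relative abundances
#'
#' Inverse of \code{\link{rho_to_alpha}}: rho_t proportional to
#' alpha_t / l_eff_t.
#'
#' @inheritParams rho_to_alpha
#' @param alpha sampling probability vector (nonnegative, sums to 1).
#' @return relative abundance vector summing to 1.
#' @export
alpha_to_rho <- function(alpha, l_eff) {
  check_profile(alpha, "alpha")
  stopifnot(length(alpha) == length(l_eff), all(l_eff > 0))
  num <- alpha / l_eff
  s <- sum(num)
  if (s <= 0) stop("degenerate profile: all alpha / l_eff are zero")
  num / s
}

#' Linear approximation of the mixed-sample sampling probabilities
#'
#' The exact mixed-sample alpha is a nonlinear combination of the two
#' cell-type profiles (see \code{\link{mixing_factors}}); estimation uses
#' the linear form tau_a * alpha_a + tau_b * alpha_b, which is accurate
#' when the nonlinearity factors are close to 1.
#'
#' @param alpha_a,alpha_b per-cell-type sampling probability vectors.
#' @param tau_a,tau_b mixing proportions, summing to 1.
#' @return mixed sampling probability vector.
#' @export
mixed_alpha_linear <- function(alpha_a, alpha_b, tau_a, tau_b) {
  check_profile(alpha_a, "alpha_a")
  check_profile(alpha_b, "alpha_b")
  if (abs(tau_a + tau_b - 1) > 1e-9) stop("tau_a + tau_b must equal 1")
  tau_a * alpha_a + tau_b * alpha_b
}

#' Nonlinearity factors of the mixed-sample composition
#'
#' The exact mixed-sample sampling probabilities satisfy
#' alpha_m = Lambda_a tau_a alpha_a + Lambda_b tau_b alpha_b with
#' Lambda_s = sum_k rho^s_k l_eff_k / sum_k rho^m_k l_eff_k.  With many
#' transcripts both factors concentrate near 1, which justifies the linear
#' approximation actually used in fitting.  This function is a diagnostic
#' only; the factors are never applied during estimation.
#'
#' @param rho_a,rho_b per-cell-type relative abundance vectors.
#' @param tau_a,tau_b mixing proportions summing to 1.
#' @param l_eff effective lengths.
#' @return named numeric vector \code{c(lambda_a =, lambda_b =)}.
#' @export
mixing_factors <- function(rho_a, rho_b, tau_a, tau_b, l_eff) {
  check_profile(rho_a, "rho_a")
  check_profile(rho_b, "rho_b")
  if (abs(tau_a + tau_b - 1) > 1e-9) stop("tau_a + tau_b must equal 1")
  rho_m <- tau_a * rho_a + tau_b * rho_b
  denom <- sum(rho_m * l_eff)
  c(lambda_a = sum(rho_a * l_eff) / denom,
    lambda_b = sum(rho_b * l_eff) / denom)
}

#' Model parameter bundle
#'
#' @param alpha_a,alpha_b per-transcript read sampling probabilities for
#'   cell types a and b (each sums to 1).
#' @param tau_a,tau_b mixing proportions of the mixed sample (sum to 1).
#' @param beta_a,beta_b Beta prior pseudo-counts on (tau_a, tau_b),
#'   each >= 1.
#' @return an object of class \code{model_params}.
#' @export
model_params <- function(alpha_a, alpha_b, tau_a, tau_b,
                         beta_a = 1, beta_b = 1) {
  check_profile(alpha_a, "alpha_a")
  check_profile(alpha_b, "alpha_b")
  if (abs(tau_a + tau_b - 1) > 1e-9) stop("tau_a + tau_b must equal 1")
  if (tau_a < 0 || tau_a > 1) stop("tau_a must lie in [0,1]")
  if (beta_a < 1 || beta_b < 1) stop("beta pseudo-counts must be >= 1")
  structure(list(alpha_a = alpha_a, alpha_b = alpha_b,
                 tau_a = tau_a, tau_b = tau_b,
                 beta_a = beta_a, beta_b = beta_b),
            class = "model_params")
}

## Per-read log sum of candidate terms; zero-sum reads are dropped with a
## warning and their count returned as an attribute.
read_log_terms <- function(aln, per_aln_value) {
  grp <- rep.int(seq_len(aln$n_reads), diff(aln$offsets))
  sums <- as.vector(rowsum(per_aln_value, grp, reorder = TRUE))
  bad <- sums <= 0 | !is.finite(sums)
  if (any(bad))
    warning(sum(bad), " read(s) with zero total weight excluded from log-posterior")
  structure(sum(log(sums[!bad])), n_excluded = sum(bad))
}

#' Unnormalised log-posterior of the model
#'
#' Evaluates the read-level mixture log-likelihood of the pure and mixed
#' samples plus the Beta prior term on the mixing proportions (up to an
#' additive constant).  Used for convergence monitoring and for the EM
#' monotonicity checks.
#'
#' @param params a \code{model_params}.
#' @param pure_aln,mixed_aln \code{alignment_set} objects (see
#'   \code{\link{parse_sam}}); either may be NULL.
#' @param l_eff effective length vector over the catalog.
#' @param weights_pure,weights_mixed optional per-alignment bias weights
#'   (default 1).
#' @return scalar log-posterior (unnormalised); attribute
#'   \code{n_excluded} counts reads dropped for zero total weight.
#' @export
log_posterior <- function(params, pure_aln, mixed_aln, l_eff,
                          weights_pure = NULL, weights_mixed = NULL) {
  stopifnot(inherits(params, "model_params"))
  lp <- 0
  n_exc <- 0L
  if (!is.null(pure_aln) && pure_aln$n_reads > 0L) {
    w <- if (is.null(weights_pure)) 1 else weights_pure
    v <- params$alpha_a[pure_aln$tx] / l_eff[pure_aln$tx] * w
    t1 <- read_log_terms(pure_aln, v)
    lp <- lp + as.numeric(t1)
    n_exc <- n_exc + attr(t1, "n_excluded")
  }
  if (!is.null(mixed_aln) && mixed_aln$n_reads > 0L) {
    w <- if (is.null(weights_mixed)) 1 else weights_mixed
    am <- params$tau_a * params$alpha_a + params$tau_b * params$alpha_b
    v <- am[mixed_aln$tx] / l_eff[mixed_aln$tx] * w
    t2 <- read_log_terms(mixed_aln, v)
    lp <- lp + as.numeric(t2)
    n_exc <- n_exc + attr(t2, "n_excluded")
  }
  if (params$beta_a > 1) lp <- lp + (params$beta_a - 1) * log(params$tau_a)
  if (params$beta_b > 1) lp <- lp + (params$beta_b - 1) * log(params$tau_b)
  structure(lp, n_excluded = n_exc)
}
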