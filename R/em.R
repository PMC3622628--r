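## Estimation engine: online E-step, MAP M-step, batch-EM reference, and
## the streaming driver.  The per-read operations (e_step_*,
## interpolate_stats, m_step) are the unit-testable contracts; large runs
## go through the compiled streaming engine, whose output is checked
## against the R reference implementation and the batch-EM fixed point in
## the test suite.

#' Online EM configuration
#'
#' @param forget_sigma forgetting factor controlling the step size
#'   1/(n+2)^sigma; must satisfy 0.5 < sigma <= 1 for the stochastic
#'   approximation to converge.  Default 0.85.
#' @param epochs maximum passes over the data (the step counter continues
#'   across epochs).  Default 2.
#' @param tol relative log-posterior change between epochs below which the
#'   run stops early.  Default 1e-6.
#' @param seed RNG seed for the per-epoch shuffle of the merged
#'   pure+mixed read stream.
#' @param minibatch reads per M-step.  Default 1 (fully online; this is
#'   the path served by the compiled engine — larger values fall back to
#'   the R reference loop).
#' @return an \code{em_config} object.
#' @export
em_config <- function(forget_sigma = 0.85, epochs = 2L, tol = 1e-6,
                      seed = 1L, minibatch = 1L) {
  if (!(forget_sigma > 0.5 && forget_sigma <= 1))
    stop("forget_sigma must lie in (0.5, 1]")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  structure(list(forget_sigma = forget_sigma, epochs = as.integer(epochs),
                 tol = tol, seed = as.integer(seed),
                 minibatch = as.integer(minibatch)),
            class = "em_config")
}

#' Sufficient statistics of the online EM
#'
#' Running averages of per-read posterior assignments: \code{q_p} over
#' pure-sample reads (sums to 1) and \code{q_ma}, \code{q_mb} over
#' mixed-sample reads attributed to cell types a and b (jointly sum to 1).
#'
#' @param q_p,q_ma,q_mb numeric vectors over the catalog.
#' @return a \code{sufficient_stats} object.
#' @export
sufficient_stats <- function(q_p, q_ma, q_mb) {
  stopifnot(length(q_p) == length(q_ma), length(q_ma) == length(q_mb))
  if (any(q_p < 0) || any(q_ma < 0) || any(q_mb < 0))
    stop("sufficient statistics must be nonnegative")
  if (abs(sum(q_p) - 1) > 1e-9)
    stop("q_p must sum to 1")
  if (abs(sum(q_ma) + sum(q_mb) - 1) > 1e-9)
    stop("q_ma + q_mb must jointly sum to 1")
  structure(list(q_p = q_p, q_ma = q_ma, q_mb = q_mb),
            class = "sufficient_stats")
}

#' E-step for one pure-sample read
#'
#' Posterior probability that the read originated from each of its
#' candidate transcripts: proportional to alpha_a / l_eff * w over the
#' candidates.
#'
#' @param group one read's alignment group (see
#'   \code{\link{alignment_group}}), or a list with a \code{candidates}
#'   data.frame holding column \code{tx}.
#' @param params a \code{model_params}.
#' @param l_eff effective lengths.
#' @param weights per-candidate bias weights (default 1).
#' @return object of class \code{latent_posterior} with fields
#'   \code{sample = "pure"}, \code{tx}, \code{q}; or NULL (with a
#'   warning) if every numerator is zero.
#' @export
e_step_pure <- function(group, params, l_eff, weights = NULL) {
  tx <- group$candidates$tx
  w <- if (is.null(weights)) rep(1, length(tx)) else weights
  num <- params$alpha_a[tx] / l_eff[tx] * w
  z <- sum(num)
  if (!(z > 0) || !is.finite(z)) {
    warning("pure read with all-zero posterior numerators skipped")
    return(NULL)
  }
  structure(list(sample = "pure", tx = tx, q = num / z),
            class = "latent_posterior")
}

#' E-step for one mixed-sample read
#'
#' Joint posterior over (candidate transcript, cell type): q_ma
#' proportional to tau_a * alpha_a / l_eff * w and q_mb proportional to
#' tau_b * alpha_b / l_eff * w, normalised so the two blocks jointly sum
#' to 1.
#'
#' @inheritParams e_step_pure
#' @return \code{latent_posterior} with \code{sample = "mixed"},
#'   \code{tx}, \code{q_ma}, \code{q_mb}; or NULL on an all-zero read.
#' @export
e_step_mixed <- function(group, params, l_eff, weights = NULL) {
  tx <- group$candidates$tx
  w <- if (is.null(weights)) rep(1, length(tx)) else weights
  base <- w / l_eff[tx]
  num_a <- params$tau_a * params$alpha_a[tx] * base
  num_b <- params$tau_b * params$alpha_b[tx] * base
  z <- sum(num_a) + sum(num_b)
  if (!(z > 0) || !is.finite(z)) {
    warning("mixed read with all-zero posterior numerators skipped")
    return(NULL)
  }
  structure(list(sample = "mixed", tx = tx,
                 q_ma = num_a / z, q_mb = num_b / z),
            class = "latent_posterior")
}

#' Fold one read's posterior into the running averages
#'
#' Stepwise-EM interpolation: q*(n+1) = (1 - gamma) q*(n) + gamma q_new
#' with gamma = 1/(n+2)^sigma.  A pure read updates only \code{q_p}; a
#' mixed read updates only \code{q_ma}/\code{q_mb}, so the normalisation
#' invariants are preserved exactly.
#'
#' @param stats a \code{sufficient_stats}.
#' @param posterior a \code{latent_posterior} from
#'   \code{\link{e_step_pure}} or \code{\link{e_step_mixed}}.
#' @param n step index of the corresponding sample (0 for its first
#'   read).
#' @param forget_sigma forgetting factor in (0.5, 1].
#' @return updated \code{sufficient_stats}.
#' @export
interpolate_stats <- function(stats, posterior, n, forget_sigma) {
  stopifnot(inherits(stats, "sufficient_stats"),
            inherits(posterior, "latent_posterior"))
  gamma <- (n + 2)^(-forget_sigma)
  if (posterior$sample == "pure") {
    q <- stats$q_p * (1 - gamma)
    q[posterior$tx] <- q[posterior$tx] + gamma * posterior$q
    stats$q_p <- q
  } else {
    qa <- stats$q_ma * (1 - gamma)
    qb <- stats$q_mb * (1 - gamma)
    qa[posterior$tx] <- qa[posterior$tx] + gamma * posterior$q_ma
    qb[posterior$tx] <- qb[posterior$tx] + gamma * posterior$q_mb
    stats$q_ma <- qa
    stats$q_mb <- qb
  }
  stats
}

#' MAP M-step
#'
#' Updates the mixing proportions from the mixed-sample averages and the
#' Beta prior pseudo-counts, then the per-transcript sampling
#' probabilities:
#' tau_a = (sum(q_ma) + (beta_a - 1)/N_m) / (1 + (beta_a + beta_b - 2)/N_m),
#' alpha_a = (q_p + q_ma) / (1 + tau_a), alpha_b = q_mb / tau_b.
#'
#' @param stats a \code{sufficient_stats}.
#' @param beta_a,beta_b Beta prior pseudo-counts (>= 1).
#' @param N_m number of mixed-sample reads (>= 1).
#' @param prev_alpha_b fallback for alpha_b when tau_b falls below
#'   \code{tau_floor} (division guard); default uniform.
#' @param tau_floor threshold for the guard, default 1e-8.
#' @return a \code{model_params}.
#' @export
m_step <- function(stats, beta_a, beta_b, N_m, prev_alpha_b = NULL,
                   tau_floor = 1e-8) {
  stopifnot(inherits(stats, "sufficient_stats"), N_m >= 1)
  shift <- (beta_a + beta_b - 2) / N_m
  tau_a <- (sum(stats$q_ma) + (beta_a - 1) / N_m) / (1 + shift)
  tau_b <- 1 - tau_a
  ## alpha updates renormalised onto the simplex: with an informative
  ## prior tau differs from sum(q_ma), so dividing by (1 + tau_a) alone
  ## would leave sum(alpha) != 1; the exact constrained maximiser is
  ## alpha_a proportional to q_p + q_ma and alpha_b proportional to q_mb.
  alpha_a <- (stats$q_p + stats$q_ma) / (1 + tau_a)
  alpha_a <- alpha_a / sum(alpha_a)
  if (tau_b < tau_floor || sum(stats$q_mb) <= 0) {
    warning("tau_b below floor; alpha_b held at previous value")
    alpha_b <- if (is.null(prev_alpha_b))
      rep(1 / length(stats$q_p), length(stats$q_p)) else prev_alpha_b
  } else {
    alpha_b <- stats$q_mb / tau_b
    alpha_b <- alpha_b / sum(alpha_b)
  }
  model_params(alpha_a, alpha_b, tau_a, tau_b, beta_a, beta_b)
}

## Beta pseudo-counts from a prior proportion and strength.  The +1 keeps
## both pseudo-counts >= 1 (well-defined log-prior) and places the Beta
## mode exactly at the prior proportion.
beta_from_prior <- function(prior_b, beta_scale, N_m) {
  stopifnot(prior_b >= 0, prior_b <= 1, beta_scale >= 0)
  c(beta_a = 1 + (1 - prior_b) * beta_scale * N_m,
    beta_b = 1 + prior_b * beta_scale * N_m)
}

## Sum per-alignment values into a length-T per-transcript vector.
accum_tx <- function(vals, tx, T) {
  out <- numeric(T)
  if (length(vals)) {
    s <- rowsum(vals, tx, reorder = FALSE)
    out[as.integer(rownames(s))] <- s
  }
  out
}

#' Batch EM reference implementation
#'
#' Classic full-data EM on the complete posterior, used as the testing
#' oracle for the streaming engine.  Holds all per-read posteriors in
#' vectorised form; only suitable for instances that fit in memory.  The
#' log-posterior is recomputed inline each iteration and asserted
#' nondecreasing.
#'
#' @param pure_aln,mixed_aln \code{alignment_set}s.
#' @param l_eff effective lengths.
#' @param prior_b prior proportion of cell type b.
#' @param beta_scale prior strength multiplier (pseudo-counts are
#'   \code{1 + prior * beta_scale * N_m}); default 10.
#' @param n_iter iterations to run.
#' @param weights_pure,weights_mixed optional per-alignment bias weights.
#' @param check_monotone assert the log-posterior never decreases
#'   (relative tolerance 1e-8).
#' @return list with \code{params}, \code{stats}, \code{trace} (the
#'   per-iteration log-posterior).
#' @export
batch_em <- function(pure_aln, mixed_aln, l_eff, prior_b,
                     beta_scale = 10, n_iter = 100,
                     weights_pure = NULL, weights_mixed = NULL,
                     check_monotone = TRUE) {
  T <- length(l_eff)
  Np <- pure_aln$n_reads
  Nm <- mixed_aln$n_reads
  stopifnot(Np >= 1, Nm >= 1)
  bb <- beta_from_prior(prior_b, beta_scale, Nm)
  beta_a <- bb[["beta_a"]]; beta_b <- bb[["beta_b"]]

  gp <- aln_group_index(pure_aln)
  gm <- aln_group_index(mixed_aln)
  wp <- if (is.null(weights_pure)) rep(1, pure_aln$n_alignments) else weights_pure
  wm <- if (is.null(weights_mixed)) rep(1, mixed_aln$n_alignments) else weights_mixed
  base_p <- wp / l_eff[pure_aln$tx]
  base_m <- wm / l_eff[mixed_aln$tx]

  alpha_a <- rep(1 / T, T)
  alpha_b <- rep(1 / T, T)
  tau_a <- 1 - prior_b
  tau_b <- prior_b
  trace <- numeric(n_iter)

  for (it in seq_len(n_iter)) {
    ## E-step, pure sample
    vp <- alpha_a[pure_aln$tx] * base_p
    zp <- as.vector(rowsum(vp, gp, reorder = TRUE))
    okp <- zp > 0
    qp_aln <- ifelse(okp[gp], vp / zp[gp], 0)
    q_p <- accum_tx(qp_aln, pure_aln$tx, T) / sum(okp)

    ## E-step, mixed sample
    va <- tau_a * alpha_a[mixed_aln$tx] * base_m
    vb <- tau_b * alpha_b[mixed_aln$tx] * base_m
    zm <- as.vector(rowsum(va + vb, gm, reorder = TRUE))
    okm <- zm > 0
    qa_aln <- ifelse(okm[gm], va / zm[gm], 0)
    qb_aln <- ifelse(okm[gm], vb / zm[gm], 0)
    nm_eff <- sum(okm)
    q_ma <- accum_tx(qa_aln, mixed_aln$tx, T) / nm_eff
    q_mb <- accum_tx(qb_aln, mixed_aln$tx, T) / nm_eff

    ## log-posterior at the pre-update parameters (inline, for the
    ## monotonicity assertion)
    lp <- sum(log(zp[okp])) + sum(log(zm[okm]))
    if (beta_a > 1) lp <- lp + (beta_a - 1) * log(tau_a)
    if (beta_b > 1) lp <- lp + (beta_b - 1) * log(tau_b)
    trace[it] <- lp
    if (check_monotone && it > 1 &&
        lp < trace[it - 1] - 1e-8 * (abs(trace[it - 1]) + 1))
      stop("batch EM log-posterior decreased at iteration ", it)

    ## M-step
    stats <- sufficient_stats(q_p, q_ma, q_mb)
    prev_ab <- alpha_b
    pr <- m_step(stats, beta_a, beta_b, Nm, prev_alpha_b = prev_ab)
    alpha_a <- pr$alpha_a; alpha_b <- pr$alpha_b
    tau_a <- pr$tau_a; tau_b <- pr$tau_b
  }
  list(params = model_params(alpha_a, alpha_b, tau_a, tau_b, beta_a, beta_b),
       stats = sufficient_stats(q_p, q_ma, q_mb),
       trace = trace)
}

## R reference implementation of the streaming loop; exact semantics of
## the compiled engine (minibatch = 1) plus the general minibatch path.
## Slow; used in tests and for minibatch > 1.
r_online_em <- function(pure_aln, mixed_aln, l_eff, prior_b, beta_scale,
                        config, weights_pure = NULL, weights_mixed = NULL) {
  T <- length(l_eff)
  Np <- pure_aln$n_reads
  Nm <- if (is.null(mixed_aln)) 0L else mixed_aln$n_reads
  bb <- if (Nm) beta_from_prior(prior_b, beta_scale, Nm)
        else c(beta_a = 1, beta_b = 1)
  beta_a <- bb[["beta_a"]]; beta_b <- bb[["beta_b"]]
  wp <- if (is.null(weights_pure)) rep(1, pure_aln$n_alignments) else weights_pure
  wm <- if (Nm && is.null(weights_mixed)) rep(1, mixed_aln$n_alignments) else weights_mixed

  stats <- sufficient_stats(rep(1 / T, T), rep((1 - prior_b) / T, T),
                            rep(prior_b / T, T))
  params <- if (Nm) m_step(stats, beta_a, beta_b, Nm)
            else model_params(stats$q_p, rep(1 / T, T), 1 - prior_b, prior_b)
  n_p <- 0L; n_m <- 0L
  trace <- numeric(0)
  withr_seed <- config$seed

  set.seed(withr_seed)
  for (ep in seq_len(config$epochs)) {
    sched <- sample.int(Np + Nm)
    batch_count <- 0L
    for (s in sched) {
      if (s <= Np) {
        grp <- alignment_group(pure_aln, s)
        idx <- pure_aln$offsets[s]:(pure_aln$offsets[s + 1L] - 1L)
        post <- e_step_pure(grp, params, l_eff, weights = wp[idx])
        if (is.null(post)) next
        stats <- interpolate_stats(stats, post, n_p, config$forget_sigma)
        n_p <- n_p + 1L
      } else {
        i <- s - Np
        grp <- alignment_group(mixed_aln, i)
        idx <- mixed_aln$offsets[i]:(mixed_aln$offsets[i + 1L] - 1L)
        post <- e_step_mixed(grp, params, l_eff, weights = wm[idx])
        if (is.null(post)) next
        stats <- interpolate_stats(stats, post, n_m, config$forget_sigma)
        n_m <- n_m + 1L
      }
      batch_count <- batch_count + 1L
      if (batch_count >= config$minibatch) {
        params <- if (Nm)
          m_step(stats, beta_a, beta_b, Nm, prev_alpha_b = params$alpha_b)
        else model_params(stats$q_p, params$alpha_b, params$tau_a,
                          params$tau_b, beta_a, beta_b)
        batch_count <- 0L
      }
    }
    if (batch_count > 0L) {
      params <- if (Nm)
        m_step(stats, beta_a, beta_b, Nm, prev_alpha_b = params$alpha_b)
      else model_params(stats$q_p, params$alpha_b, params$tau_a,
                        params$tau_b, beta_a, beta_b)
    }
    lp <- as.numeric(log_posterior(params, pure_aln, mixed_aln, l_eff,
                                   weights_pure = wp, weights_mixed = wm))
    trace <- c(trace, lp)
    if (ep > 1 && abs(lp - trace[ep - 1]) <
          config$tol * (abs(trace[ep - 1]) + 1e-12)) break
  }
  list(params = params, stats = stats, trace = trace,
       epochs_run = length(trace), N_p = Np, N_m = Nm)
}

#' Fit the mixture model by online EM
#'
#' Streams a seeded, shuffled interleave of the pure and mixed read sets,
#' performing one E-step, interpolation and (implicit) M-step per read.
#' Initialisation is uniform alpha with tau at the prior mean; the Beta
#' prior pseudo-counts are \code{1 + prior * beta_scale * N_m}, placing
#' the prior mode exactly at the supplied proportion with the requested
#' total strength.
#'
#' @param pure_aln \code{alignment_set} of the pure (cell type a) sample.
#' @param mixed_aln \code{alignment_set} of the mixed sample, or NULL for
#'   a single-sample ("naive") fit of the pure stream alone.
#' @param l_eff effective length vector over the catalog.
#' @param prior_b prior proportion of cell type b in the mixed sample.
#' @param beta_scale prior strength multiplier (default 10).
#' @param config an \code{\link{em_config}}.
#' @param weights_pure,weights_mixed optional per-alignment bias weights.
#' @param engine "cpp" (default) or "r" (reference loop; required for
#'   \code{minibatch > 1}).
#' @return list of class \code{demix_fit}: \code{params}
#'   (\code{model_params}), \code{stats} (\code{sufficient_stats}),
#'   \code{trace} (per-epoch log-posterior), \code{N_p}, \code{N_m},
#'   \code{epochs_run}, \code{config}.
#' @export
run_online_em <- function(pure_aln, mixed_aln, l_eff, prior_b,
                          beta_scale = 10, config = em_config(),
                          weights_pure = NULL, weights_mixed = NULL,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(pure_aln, "alignment_set"))
  if (pure_aln$n_reads < 1L) stop("pure read stream is empty")
  if (!is.null(mixed_aln) && mixed_aln$n_reads < 1L)
    stop("mixed read stream is empty")
  if (config$minibatch > 1L) engine <- "r"
  if (engine == "r") {
    res <- r_online_em(pure_aln, mixed_aln, l_eff, prior_b, beta_scale,
                       config, weights_pure, weights_mixed)
    out <- list(params = res$params, stats = res$stats, trace = res$trace,
                N_p = res$N_p, N_m = res$N_m,
                epochs_run = res$epochs_run, config = config)
    class(out) <- "demix_fit"
    return(out)
  }

  Np <- pure_aln$n_reads
  Nm <- if (is.null(mixed_aln)) 0L else mixed_aln$n_reads
  wp <- if (is.null(weights_pure)) rep(1, pure_aln$n_alignments) else as.numeric(weights_pure)
  if (Nm) {
    wm <- if (is.null(weights_mixed)) rep(1, mixed_aln$n_alignments) else as.numeric(weights_mixed)
    m_off <- mixed_aln$offsets; m_tx <- mixed_aln$tx
  } else {
    wm <- numeric(0); m_off <- 1L; m_tx <- integer(0)
  }
  bb <- if (Nm) beta_from_prior(prior_b, beta_scale, Nm)
        else c(beta_a = 1, beta_b = 1)

  set.seed(config$seed)
  sched <- unlist(lapply(seq_len(config$epochs),
                         function(e) sample.int(Np + Nm)))
  sched_sample <- as.integer(sched > Np)
  sched_read <- ifelse(sched > Np, sched - Np, sched)
  epoch_len <- rep.int(Np + Nm, config$epochs)

  res <- cpp_online_em(pure_aln$offsets, pure_aln$tx, wp,
                       m_off, m_tx, wm, as.numeric(l_eff),
                       sched_sample, as.integer(sched_read),
                       as.integer(epoch_len),
                       1 - prior_b, bb[["beta_a"]], bb[["beta_b"]],
                       config$forget_sigma, config$tol, 1e-8)
  if (res$tau_b_floored)
    warning("tau_b below floor at the solution; alpha_b reported as uniform")
  params <- model_params(res$alpha_a / sum(res$alpha_a),
                         res$alpha_b / sum(res$alpha_b),
                         res$tau_a, res$tau_b,
                         bb[["beta_a"]], bb[["beta_b"]])
  stats <- sufficient_stats(res$q_p / sum(res$q_p),
                            res$q_ma / (sum(res$q_ma) + sum(res$q_mb)),
                            res$q_mb / (sum(res$q_ma) + sum(res$q_mb)))
  out <- list(params = params, stats = stats, trace = res$trace,
              N_p = Np, N_m = Nm, epochs_run = res$epochs_run,
              n_skipped = res$n_skipped, config = config)
  class(out) <- "demix_fit"
  out
}

#' @export
print.demix_fit <- function(x, ...) {
  cat(sprintf("demix_fit: %d pure + %d mixed reads, tau_b = %.4f, %d epoch(s), log-posterior %.2f\n",
              x$N_p, x$N_m, x$params$tau_b, x$epochs_run,
              utils::tail(x$trace, 1)))
  invisible(x)
}
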