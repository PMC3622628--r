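# E-step / interpolation / M-step contracts, batch-EM monotonicity, and
# equivalence of the streaming engine with its R reference and the
# batch-EM fixed point.

test_that("pure E-step matches hand evaluations", {
  p <- model_params(c(0.5, 0.5), c(0.5, 0.5), 0.5, 0.5)
  g1 <- list(candidates = data.frame(tx = 2L))
  expect_equal(e_step_pure(g1, p, c(100, 200))$q, 1)

  g2 <- list(candidates = data.frame(tx = c(1L, 2L)))
  post <- e_step_pure(g2, p, c(100, 200))
  expect_equal(post$q, c(2 / 3, 1 / 3))   # 0.005 : 0.0025

  # an all-zero read is skipped with a warning
  p0 <- model_params(c(0, 1), c(0.5, 0.5), 0.5, 0.5)
  expect_warning(out <- e_step_pure(g1 <- list(candidates = data.frame(tx = 1L)),
                                    p0, c(1, 1)), "skipped")
  expect_null(out)
})

test_that("mixed E-step matches hand evaluations and joint normalisation", {
  # tau split example: alpha_a = (.8,.2), alpha_b = (.2,.8), equal l_eff
  p <- model_params(c(0.8, 0.2), c(0.2, 0.8), 0.5, 0.5)
  g <- list(candidates = data.frame(tx = c(1L, 2L)))
  post <- e_step_mixed(g, p, c(1, 1))
  expect_equal(post$q_ma, c(0.4, 0.1), tolerance = 1e-12)
  expect_equal(post$q_mb, c(0.1, 0.4), tolerance = 1e-12)
  expect_equal(sum(post$q_ma) + sum(post$q_mb), 1, tolerance = 1e-12)

  # tau_b = 0 kills the b block
  p0 <- model_params(c(0.5, 0.5), c(0.5, 0.5), 1, 0)
  post0 <- e_step_mixed(g, p0, c(1, 1))
  expect_equal(post0$q_mb, c(0, 0))

  # alpha_a == alpha_b: per-transcript split is exactly tau_a : tau_b
  pe <- model_params(c(0.3, 0.7), c(0.3, 0.7), 0.25, 0.75)
  pq <- e_step_mixed(g, pe, c(50, 50))
  expect_equal(pq$q_ma / (pq$q_ma + pq$q_mb), rep(0.25, 2), tolerance = 1e-12)
})

test_that("interpolation follows the closed forms and preserves sums", {
  T <- 4L
  stats <- sufficient_stats(rep(0.25, T), rep(0.1, T), rep(0.15, T))
  post <- structure(list(sample = "pure", tx = c(1L, 3L), q = c(0.6, 0.4)),
                    class = "latent_posterior")
  # sigma = 1, n = 0: gamma = 1/2, arithmetic mean of old and dense-new
  s1 <- interpolate_stats(stats, post, 0, 1)
  dense_new <- c(0.6, 0, 0.4, 0)
  expect_equal(s1$q_p, (rep(0.25, T) + dense_new) / 2, tolerance = 1e-15)
  expect_equal(sum(s1$q_p), 1, tolerance = 1e-12)

  # fixed point: q_new equal to current stats leaves them unchanged
  postfix <- structure(list(sample = "pure", tx = 1:4, q = rep(0.25, 4)),
                       class = "latent_posterior")
  sfix <- interpolate_stats(stats, postfix, 9, 0.7)
  expect_equal(sfix$q_p, stats$q_p, tolerance = 1e-15)

  # sigma = 0.85, n = 3: gamma = 5^-0.85 (scalar oracle)
  g <- 5^(-0.85)
  s2 <- interpolate_stats(stats, post, 3, 0.85)
  expect_equal(s2$q_p, (1 - g) * rep(0.25, T) + g * dense_new,
               tolerance = 1e-14)

  # mixed update preserves the joint sum exactly
  postm <- structure(list(sample = "mixed", tx = 2L, q_ma = 0.7, q_mb = 0.3),
                     class = "latent_posterior")
  sm <- interpolate_stats(stats, postm, 5, 0.85)
  expect_equal(sum(sm$q_ma) + sum(sm$q_mb), 1, tolerance = 1e-12)
  expect_equal(sm$q_p, stats$q_p)   # untouched
})

test_that("M-step matches hand evaluations and conserves normalisation", {
  # flat prior: tau_a = sum(q_ma)
  T <- 5L
  q_p <- rep(0.2, T)
  q_ma <- rep(0.3 / T, T)
  q_mb <- rep(0.7 / T, T)
  st <- sufficient_stats(q_p, q_ma, q_mb)
  pr <- m_step(st, 1, 1, 100)
  expect_equal(pr$tau_a, 0.3, tolerance = 1e-12)
  expect_equal(sum(pr$alpha_a), 1, tolerance = 1e-12)
  expect_equal(sum(pr$alpha_b), 1, tolerance = 1e-12)
  expect_equal(pr$tau_a + pr$tau_b, 1)

  # hand case: beta = (5,5), N_m = 100, sum(q_ma) = 0.3
  pr2 <- m_step(st, 5, 5, 100)
  expect_equal(pr2$tau_a, 0.34 / 1.08, tolerance = 1e-12)

  # tau_b floor guard holds alpha_b at the supplied previous value
  st0 <- sufficient_stats(q_p, rep(1 / T, T), rep(0, T))
  prev <- c(0.5, 0.2, 0.1, 0.1, 0.1)
  expect_warning(pr3 <- m_step(st0, 1, 1, 100, prev_alpha_b = prev), "floor")
  expect_equal(pr3$alpha_b, prev)
})

test_that("batch EM log-posterior is monotone and handles degenerate cases", {
  set.seed(11)
  for (rep_i in 1:5) {
    T <- sample(2:5, 1)
    n <- sample(10:20, 1)
    pure <- random_aln(n, T)
    mixed <- random_aln(n, T, sample_tag = "mixed")
    l_eff <- runif(T, 100, 1000)
    # check_monotone = TRUE raises on any decrease
    res <- batch_em(pure, mixed, l_eff, prior_b = runif(1, 0.1, 0.9),
                    n_iter = 100)
    expect_true(all(diff(res$trace) >= -1e-8 * (abs(res$trace[-1]) + 1)))
    expect_equal(sum(res$params$alpha_a), 1, tolerance = 1e-9)
    expect_equal(sum(res$params$alpha_b), 1, tolerance = 1e-9)
  }

  # single-transcript catalog: alpha = 1, tau pulled to the prior mode
  pure1 <- unique_reads_aln(rep(1L, 10))
  mixed1 <- unique_reads_aln(rep(1L, 10), sample_tag = "mixed")
  r1 <- batch_em(pure1, mixed1, l_eff = 500, prior_b = 0.6,
                 beta_scale = 10, n_iter = 50)
  expect_equal(r1$params$alpha_a, 1)
  expect_equal(r1$params$tau_b, 0.6, tolerance = 1e-3)
})

test_that("streaming engine matches the R reference loop", {
  set.seed(21)
  T <- 6L
  pure <- random_aln(25, T)
  mixed <- random_aln(30, T, sample_tag = "mixed")
  l_eff <- runif(T, 100, 2000)
  cfg <- em_config(forget_sigma = 0.85, epochs = 3, tol = 1e-15, seed = 5)
  fr <- run_online_em(pure, mixed, l_eff, prior_b = 0.3, config = cfg,
                      engine = "r")
  fc <- run_online_em(pure, mixed, l_eff, prior_b = 0.3, config = cfg,
                      engine = "cpp")
  expect_equal(fc$params$tau_b, fr$params$tau_b, tolerance = 1e-10)
  expect_equal(fc$params$alpha_a, fr$params$alpha_a, tolerance = 1e-10)
  expect_equal(fc$params$alpha_b, fr$params$alpha_b, tolerance = 1e-10)
  expect_equal(fc$stats$q_p, fr$stats$q_p, tolerance = 1e-10)
})

test_that("online EM converges to the batch-EM fixed point", {
  # instance with an interior fixed point: every transcript carries
  # unique reads in both samples, plus ambiguous reads on top.  The
  # stepwise scheme approaches the fixed point at roughly
  # (initial distance)/steps, so the budget here is chosen to bring it
  # within 1e-3 (see the methods vignette on convergence).
  set.seed(33)
  T <- 5L
  mk <- function(tag) {
    uni <- lapply(rep(1:T, each = 8), function(t) list(tx = t))
    amb <- lapply(1:10, function(i) list(tx = sort(sample.int(T, 2))))
    make_aln(c(uni, amb), sample_tag = tag)
  }
  pure <- mk("pure")
  mixed <- mk("mixed")
  l_eff <- runif(T, 200, 2000)
  batch <- batch_em(pure, mixed, l_eff, prior_b = 0.5, n_iter = 5000)
  onl <- run_online_em(pure, mixed, l_eff, prior_b = 0.5,
                       config = em_config(forget_sigma = 0.6, epochs = 2000,
                                          tol = 1e-300, seed = 2))
  expect_equal(onl$params$tau_b, batch$params$tau_b, tolerance = 1e-3)
  expect_equal(onl$params$alpha_a, batch$params$alpha_a, tolerance = 1e-3)
  expect_equal(onl$params$alpha_b, batch$params$alpha_b, tolerance = 1e-3)
})

test_that("degenerate mixture (prior_b = 0) reduces to the pure-only fit", {
  set.seed(44)
  T <- 5L
  pure <- random_aln(40, T)
  # feed the same read set as the mixed sample with tau_b prior 0
  mixed <- pure; mixed$sample_tag <- "mixed"
  l_eff <- rep(500, T)
  both <- suppressWarnings(
    batch_em(pure, mixed, l_eff, prior_b = 0, beta_scale = 10,
             n_iter = 300))
  expect_equal(both$params$tau_b, 0)

  # independent pure-only batch EM coded inline
  grp <- rep.int(seq_len(pure$n_reads), diff(pure$offsets))
  alpha <- rep(1 / T, T)
  for (it in 1:300) {
    v <- alpha[pure$tx] / l_eff[pure$tx]
    z <- as.vector(rowsum(v, grp))
    q <- v / z[grp]
    alpha <- as.vector(rowsum(q, pure$tx)) / pure$n_reads
  }
  expect_equal(both$params$alpha_a, alpha, tolerance = 1e-6)
})

test_that("normalisation invariants hold after every online update", {
  # property suite: run the R reference loop step by step and check the
  # invariants after each M-step
  set.seed(55)
  T <- 4L
  pure <- random_aln(15, T)
  mixed <- random_aln(15, T, sample_tag = "mixed")
  l_eff <- runif(T, 100, 1000)
  stats <- sufficient_stats(rep(1 / T, T), rep(0.5 / T, T), rep(0.5 / T, T))
  params <- m_step(stats, 2, 2, 15)
  n_p <- 0; n_m <- 0
  for (i in 1:15) {
    post <- e_step_pure(alignment_group(pure, i), params, l_eff)
    stats <- interpolate_stats(stats, post, n_p, 0.85); n_p <- n_p + 1
    postm <- e_step_mixed(alignment_group(mixed, i), params, l_eff)
    stats <- interpolate_stats(stats, postm, n_m, 0.85); n_m <- n_m + 1
    params <- m_step(stats, 2, 2, 15, prev_alpha_b = params$alpha_b)
    expect_identical(params$tau_a + params$tau_b, 1)
    expect_equal(sum(params$alpha_a), 1, tolerance = 1e-9)
    expect_equal(sum(params$alpha_b), 1, tolerance = 1e-9)
    expect_equal(sum(stats$q_p), 1, tolerance = 1e-9)
    expect_equal(sum(stats$q_ma) + sum(stats$q_mb), 1, tolerance = 1e-9)
  }
})

test_that("parameter recovery with unique alignments matches count fractions", {
  # with unique alignments and no bias, the pure-sample alpha estimate
  # converges to the empirical read-count fractions (closed form)
  set.seed(66)
  T <- 20L
  probs <- rgamma(T, 1); probs <- probs / sum(probs)
  tx <- sample.int(T, 1e4, replace = TRUE, prob = probs)
  aln <- unique_reads_aln(tx)
  cat_ <- transcript_catalog(paste0("t", 1:T), rep(1000L, T))
  fit <- fit_single(cat_, aln, config = em_config(forget_sigma = 1,
                                                  epochs = 3, tol = 1e-15))
  emp <- tabulate(tx, T) / length(tx)
  expect_equal(fit$params$alpha_a, emp, tolerance = 1e-3)
})

test_that("em_config validates the forgetting factor constraint", {
  expect_error(em_config(forget_sigma = 0.5), "0.5")
  expect_error(em_config(forget_sigma = 1.2), "0.5")
  expect_silent(em_config(forget_sigma = 1))
  expect_error(em_config(epochs = 0), "epochs")
})
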