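# Generator contracts: determinism, ledger consistency, k-mer
# uniqueness, multinomial agreement, mixing proportions.

test_that("catalog generation is deterministic and honours ambiguity", {
  cfg <- sim_config(n_transcripts = 10L, length_range = c(200L, 400L),
                    read_length = 50L, ambiguity_spec = 0.4, seed = 101L)
  c1 <- generate_catalog(cfg)
  c2 <- generate_catalog(cfg)
  expect_identical(c1$sequences, c2$sequences)
  hom <- attr(c1, "homology")
  expect_equal(nrow(hom), 2L)   # floor(0.4 * 10 / 2)
  # the shared blocks really are identical sequence
  for (i in seq_len(nrow(hom))) {
    b1 <- substr(c1$sequences[hom$tx1[i]], hom$pos1[i] + 1,
                 hom$pos1[i] + hom$len[i])
    b2 <- substr(c1$sequences[hom$tx2[i]], hom$pos2[i] + 1,
                 hom$pos2[i] + hom$len[i])
    expect_identical(b1, b2)
  }
  # single-transcript degenerate case
  c3 <- generate_catalog(sim_config(n_transcripts = 1L,
                                    length_range = c(100L, 100L),
                                    read_length = 50L, seed = 3L))
  expect_equal(length(c3$ids), 1L)
  # FASTA written twice is byte-identical
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_catalog_fasta(c1, f1); write_catalog_fasta(generate_catalog(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ambiguity 0 yields no shared read-length k-mer across transcripts", {
  cfg <- sim_config(n_transcripts = 8L, length_range = c(150L, 250L),
                    read_length = 30L, ambiguity_spec = 0, seed = 11L)
  cat_ <- generate_catalog(cfg)
  # exhaustive k-mer scan oracle
  kmers <- lapply(cat_$sequences, function(s) {
    n <- nchar(s) - 30L + 1L
    unique(substring(s, 1:n, 30:(n + 29L)))
  })
  for (i in 1:7) for (j in (i + 1):8)
    expect_length(intersect(kmers[[i]], kmers[[j]]), 0)
})

test_that("abundance profiles are normalised Dirichlet draws", {
  cat_ <- generate_catalog(sim_config(n_transcripts = 50L,
                                      length_range = c(100L, 200L),
                                      read_length = 50L, seed = 5L))
  ab <- generate_abundances(cat_, seed = 6L)
  expect_equal(sum(ab$rho_a), 1, tolerance = 1e-12)
  expect_equal(sum(ab$rho_b), 1, tolerance = 1e-12)
  expect_gt(sum(abs(ab$rho_a - ab$rho_b)), 0)   # two distinct draws
  # large concentration approaches uniformity
  abu <- generate_abundances(cat_, seed = 7L, concentration = 1e6)
  expect_lt(max(abs(abu$rho_a - 1 / 50)), 0.1 / 50)
})

test_that("read generation matches the sampling model and its ledger", {
  cfg <- sim_config(n_transcripts = 25L, length_range = c(400L, 2000L),
                    read_length = 75L, seed = 21L)
  cat_ <- generate_catalog(cfg)
  ab <- generate_abundances(cat_, seed = 22L)
  gen <- generate_reads(cat_, ab$rho_a, 100000L, frag = cfg$frag,
                        seed = 23L, with_seqs = FALSE)
  # empirical transcript counts within 3-sigma multinomial bounds of alpha
  l_eff <- effective_lengths(cat_, cfg$frag)
  alpha <- rho_to_alpha(ab$rho_a, l_eff)
  counts <- true_counts(gen$truth, 25L)
  expect_equal(sum(counts), 100000L)
  # counts are exactly Multinomial(n, alpha): chi-square goodness of fit
  # plus a 4-sigma per-bin guard (3-sigma across 25 bins false-alarms)
  expect_gt(suppressWarnings(chisq.test(counts, p = alpha)$p.value), 1e-4)
  sd4 <- 4 * sqrt(100000 * alpha * (1 - alpha))
  expect_true(all(abs(counts - 100000 * alpha) <= pmax(sd4, 12)))
  # all ledger positions are valid starts
  expect_true(all(gen$truth$pos >= 0L))
  expect_true(all(gen$truth$pos + 75L <= cat_$lengths[gen$truth$tx]))

  # point-mass abundance puts every read on that transcript
  rho1 <- c(1, rep(0, 24))
  g1 <- generate_reads(cat_, rho1, 500L, frag = cfg$frag, seed = 24L,
                       with_seqs = FALSE)
  expect_true(all(g1$truth$tx == 1L))
})

test_that("ledger and SAM record counts agree with homologous placements", {
  cfg <- sim_config(n_transcripts = 10L, length_range = c(300L, 600L),
                    read_length = 50L, ambiguity_spec = 1, seed = 31L)
  cat_ <- generate_catalog(cfg)
  ab <- generate_abundances(cat_, seed = 32L)
  gen <- generate_reads(cat_, ab$rho_a, 2000L, frag = cfg$frag,
                        read_length = 50L, seed = 33L, with_seqs = FALSE)
  hom <- attr(cat_, "homology")
  both <- rbind(data.frame(tx = hom$tx1, p = hom$pos1, len = hom$len),
                data.frame(tx = hom$tx2, p = hom$pos2, len = hom$len))
  j <- match(gen$truth$tx, both$tx)
  inside <- !is.na(j) & gen$truth$pos >= both$p[j] &
    gen$truth$pos + 50L <= both$p[j] + both$len[j]
  # exactly the in-block reads have two candidates
  expect_equal(diff(gen$aln$offsets), 1L + as.integer(inside))
  expect_equal(gen$aln$stats$multimapped_reads, sum(inside))
})

test_that("mixture generation tags cells correctly", {
  cfg <- sim_config(n_transcripts = 15L, length_range = c(300L, 800L),
                    read_length = 50L, seed = 41L)
  cat_ <- generate_catalog(cfg)
  ab <- generate_abundances(cat_, seed = 42L)
  # tau_b = 0: ledger has no b labels
  m0 <- generate_mixture(cat_, ab$rho_a, ab$rho_b, 0, 1000L,
                         frag = cfg$frag, read_length = 50L, seed = 43L,
                         with_seqs = FALSE)
  expect_true(all(m0$truth$cell_type == "a"))
  # tau_b = 0.6 at n = 1e5: b fraction within 3 sigma of 0.6
  m6 <- generate_mixture(cat_, ab$rho_a, ab$rho_b, 0.6, 100000L,
                         frag = cfg$frag, read_length = 50L, seed = 44L,
                         with_seqs = FALSE)
  nb <- sum(m6$truth$cell_type == "b")
  expect_lt(abs(nb / 1e5 - 0.6), 3 * sqrt(0.6 * 0.4 / 1e5))
  # extracted b-subset bookkeeping is exact
  expect_equal(sum(true_counts(m6$truth, 15L, cell = "b")), nb)
  expect_equal(true_counts(m6$truth, 15L, cell = "a") +
               true_counts(m6$truth, 15L, cell = "b"),
               true_counts(m6$truth, 15L))
})

test_that("generator output is byte-deterministic end to end", {
  cfg <- sim_config(n_transcripts = 8L, length_range = c(200L, 400L),
                    read_length = 40L, ambiguity_spec = 0.5,
                    n_reads_pure = 300L, n_reads_mixed = 300L, seed = 51L)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- cmd_simulate(d1, cfg)
  p2 <- cmd_simulate(d2, cfg)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = f)
})
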