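# Shared fixture builders: all fixtures are constructed in code.

# A tiny catalog with known sequences.
toy_catalog <- function() {
  transcript_catalog(
    ids = c("t1", "t2", "t3"),
    lengths = c(10L, 8L, 12L),
    sequences = c("ACGTACGTAC", "GGGGCCCC", "ATATATATATAT"))
}

# Build an alignment_set from a list of per-read candidate lists:
# list(list(read_id, tx = c(...), pos = c(...)), ...)
make_aln <- function(reads, sample_tag = "pure", qlen = 1L) {
  tx <- unlist(lapply(reads, `[[`, "tx"))
  pos <- unlist(lapply(reads, function(r)
    if (is.null(r$pos)) rep(0L, length(r$tx)) else r$pos))
  counts <- vapply(reads, function(r) length(r$tx), integer(1))
  strand <- unlist(lapply(reads, function(r)
    if (is.null(r$strand)) rep(0L, length(r$tx)) else r$strand))
  alignment_set(
    read_ids = vapply(seq_along(reads), function(i)
      if (is.null(reads[[i]]$read_id)) sprintf("r%03d", i)
      else reads[[i]]$read_id, character(1)),
    offsets = c(1L, cumsum(counts) + 1L),
    tx = tx, pos = pos, strand = strand,
    qlen = rep(as.integer(qlen), length(tx)),
    sample_tag = sample_tag)
}

# n unique single-candidate reads on the given transcripts.
unique_reads_aln <- function(tx_per_read, sample_tag = "pure") {
  make_aln(lapply(seq_along(tx_per_read),
                  function(i) list(tx = tx_per_read[i])),
           sample_tag = sample_tag)
}

# Random small alignment instance for property tests: every read gets
# 1-3 candidates among T transcripts.
random_aln <- function(n_reads, T, sample_tag = "pure", max_cand = 3L) {
  make_aln(lapply(seq_len(n_reads), function(i) {
    k <- sample.int(max_cand, 1)
    list(tx = sample.int(T, min(k, T)))
  }), sample_tag = sample_tag)
}

# Write SAM text lines (header + records) to a temp file.
write_sam_text <- function(records, sq = c("t1" = 10L, "t2" = 8L, "t3" = 12L)) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(header, records), path)
  path
}

# Independent brute-force evaluation of the model log-posterior on small
# instances (direct translation of the posterior formula, no shared code
# with log_posterior()).
brute_log_posterior <- function(alpha_a, alpha_b, tau_a, tau_b,
                                beta_a, beta_b, pure, mixed, l_eff,
                                wp = NULL, wm = NULL) {
  lp <- 0
  for (i in seq_len(pure$n_reads)) {
    idx <- pure$offsets[i]:(pure$offsets[i + 1] - 1)
    s <- 0
    for (k in seq_along(idx)) {
      j <- idx[k]
      t <- pure$tx[j]
      w <- if (is.null(wp)) 1 else wp[j]
      s <- s + alpha_a[t] / l_eff[t] * w
    }
    lp <- lp + log(s)
  }
  if (!is.null(mixed)) {
    for (i in seq_len(mixed$n_reads)) {
      idx <- mixed$offsets[i]:(mixed$offsets[i + 1] - 1)
      s <- 0
      for (k in seq_along(idx)) {
        j <- idx[k]
        t <- mixed$tx[j]
        w <- if (is.null(wm)) 1 else wm[j]
        s <- s + (tau_a * alpha_a[t] + tau_b * alpha_b[t]) / l_eff[t] * w
      }
      lp <- lp + log(s)
    }
  }
  lp + (beta_a - 1) * log(tau_a) + (beta_b - 1) * log(tau_b)
}
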