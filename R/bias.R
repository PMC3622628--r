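## Positional and sequence-specific read-start bias.
##
## The bias weight of an alignment is the likelihood ratio of its start
## position and local sequence under a trained "bias" model versus the
## uniform model:
##   w = [P(b | bias) / P(b | uniform)] * [P(pi | bias) / P(pi | uniform)]
## Positional bias uses the bin method: the start position relative to
## the effective length is discretised into n_bins bins; the foreground
## bin distribution is tallied from observed reads (multi-mapped reads
## contribute fractionally by their current posterior weight) and the
## background is uniform over bins by construction.  Sequence bias uses
## per-offset Markov chains over a window centred at the read's 5' end:
## the foreground chain is tallied from observed read windows, the
## background chain from transcript sequence content weighted by the
## current sampling probabilities.  Exact bin counts, window size and
## chain order follow the conventions of comparable bias models and are
## configurable.

BASES <- c("A", "C", "G", "T")

#' Bias module configuration
#'
#' @param n_bins relative-position bins (default 20).
#' @param window_L odd sequence-window length centred at the read start
#'   (default 21).
#' @param order Markov chain order cap (default 3; the chain at window
#'   offset j uses order \code{min(order, j-1)}).
#' @param pseudocount Laplace smoothing added to every count (default 1).
#' @param min_reads below this many training reads the trained model is
#'   replaced by the identity model with a warning (default 100).
#' @return a \code{bias_config} object.
#' @export
bias_config <- function(n_bins = 20L, window_L = 21L, order = 3L,
                        pseudocount = 1, min_reads = 100L) {
  stopifnot(n_bins >= 1L, window_L >= 1L, window_L %% 2L == 1L,
            order >= 0L, pseudocount > 0, min_reads >= 0L)
  structure(list(n_bins = as.integer(n_bins), window_L = as.integer(window_L),
                 order = as.integer(order), pseudocount = pseudocount,
                 min_reads = as.integer(min_reads)),
            class = "bias_config")
}

#' Identity (no-op) bias model
#'
#' Foreground equals background everywhere, so every weight is exactly 1.
#'
#' @param config a \code{\link{bias_config}}.
#' @return a \code{bias_model}.
#' @export
identity_bias_model <- function(config = bias_config()) {
  nb <- config$n_bins
  pos <- list(n_bins = nb,
              fg_bin_prob = rep(1 / nb, nb),
              bg_bin_prob = rep(1 / nb, nb))
  L <- config$window_L
  fg <- vector("list", L)
  for (j in seq_len(L)) {
    o <- min(config$order, j - 1L)
    fg[[j]] <- matrix(0.25, nrow = 4^o, ncol = 4,
                      dimnames = list(NULL, BASES))
  }
  bg <- lapply(0:config$order, function(o)
    matrix(0.25, nrow = 4^o, ncol = 4, dimnames = list(NULL, BASES)))
  structure(list(pos = pos,
                 seq = list(order = config$order, window_L = L,
                            fg_chain = fg, bg_chain = bg),
                 config = config, identity = TRUE),
            class = "bias_model")
}

## 5'-end position of each alignment (reverse strand reads start at the
## rightmost aligned base).
five_prime_pos <- function(pos, strand, qlen) {
  ifelse(strand == 1L, pos + pmax(qlen, 1L) - 1L, pos)
}

## Relative-position bin (1..n_bins) of start b within effective length.
position_bin <- function(b, l_eff_t, n_bins) {
  pmin(pmax(floor(b / l_eff_t * n_bins) + 1L, 1L), n_bins)
}

## Integer base codes for window strings: matrix n x L, NA for N.
window_codes <- function(windows, L) {
  codes <- match(unlist(strsplit(windows, "", fixed = TRUE)), BASES)
  matrix(codes, ncol = L, byrow = TRUE)
}

## Context index (1-based) from the o preceding base codes (most
## significant first); NA if any involved base is N.
context_index <- function(code_mat, j, o) {
  if (o == 0L) return(rep(1L, nrow(code_mat)))
  ctx <- rep(0L, nrow(code_mat))
  for (m in seq_len(o))
    ctx <- ctx * 4L + (code_mat[, j - o + m - 1L] - 1L)
  ctx + 1L
}

## Weighted transition tally for one offset: 4^o x 4 matrix.
tally_chain <- function(ctx, base, w, o, pseudocount) {
  tab <- matrix(pseudocount, nrow = 4^o, ncol = 4,
                dimnames = list(NULL, BASES))
  ok <- !is.na(ctx) & !is.na(base)
  if (any(ok)) {
    idx <- (base[ok] - 1L) * 4^o + ctx[ok]
    add <- rowsum(w[ok], idx, reorder = FALSE)
    tab[as.integer(rownames(add))] <- tab[as.integer(rownames(add))] + add
  }
  tab / rowSums(tab)
}

## Background conditional chains (orders 0..cap) from transcript k-mer
## content weighted by alpha_t (per-position weight alpha_t / #positions).
background_chains <- function(catalog, alpha, order_cap, pseudocount) {
  xs <- Biostrings::DNAStringSet(catalog$sequences)
  lapply(0:order_cap, function(o) {
    k <- o + 1L
    freq <- Biostrings::oligonucleotideFrequency(xs, width = k)
    npos <- pmax(catalog$lengths - k + 1L, 1L)
    wfreq <- colSums(freq * (alpha / npos))
    tab <- matrix(pseudocount, nrow = 4^o, ncol = 4,
                  dimnames = list(NULL, BASES))
    ## k-mer column order is lexicographic over A,C,G,T: first o bases are
    ## the context (most significant), last base the emission.
    kmers <- names(wfreq)
    base_code <- match(substr(kmers, k, k), BASES)
    if (o == 0L) {
      ctx <- rep(1L, length(kmers))
    } else {
      pre <- substr(kmers, 1L, o)
      ctx <- rep(0L, length(kmers))
      for (m in seq_len(o))
        ctx <- ctx * 4L + (match(substr(pre, m, m), BASES) - 1L)
      ctx <- ctx + 1L
    }
    idx <- (base_code - 1L) * 4^o + ctx
    tab[idx] <- tab[idx] + wfreq
    tab / rowSums(tab)
  })
}

#' Train the bias models
#'
#' Estimates the foreground positional-bin distribution and per-offset
#' sequence Markov chains from observed read starts, with multi-mapped
#' reads contributing fractionally by their current posterior weight
#' (computed from \code{current_alpha}); the background positional
#' distribution is uniform over bins, and the background chain reflects
#' transcript sequence content weighted by \code{current_alpha}.
#'
#' @param aln an \code{alignment_set}, or a list of them (pure and mixed
#'   tallied together).
#' @param catalog \code{transcript_catalog} with sequences.
#' @param l_eff effective lengths.
#' @param current_alpha sampling probabilities from a bias-free warm-up
#'   fit, used for posterior weighting and the sequence background.  May
#'   be a list parallel to \code{aln} (e.g. the pure-sample alpha for the
#'   pure stream and the mixture alpha for the mixed stream); the first
#'   entry then weights the sequence background.
#' @param config a \code{\link{bias_config}}.
#' @return a \code{bias_model} (identity if there are fewer than
#'   \code{config$min_reads} training reads).
#' @export
train_bias <- function(aln, catalog, l_eff, current_alpha,
                       config = bias_config()) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  if (is.null(catalog$sequences))
    stop("catalog has no sequences; bias training requires them")
  if (inherits(aln, "alignment_set")) aln <- list(aln)
  if (!is.list(current_alpha)) current_alpha <- list(current_alpha)
  if (length(current_alpha) == 1L)
    current_alpha <- rep(current_alpha, length(aln))
  stopifnot(length(current_alpha) == length(aln))
  n_train <- sum(vapply(aln, function(a) a$n_reads, numeric(1)))
  if (n_train < config$min_reads) {
    warning("fewer than ", config$min_reads,
            " training reads; returning identity bias model")
    return(identity_bias_model(config))
  }

  tx <- unlist(lapply(aln, `[[`, "tx"))
  pos <- unlist(lapply(aln, `[[`, "pos"))
  strand <- unlist(lapply(aln, `[[`, "strand"))
  qlen <- unlist(lapply(aln, `[[`, "qlen"))
  grp <- unlist(lapply(seq_along(aln), function(i)
    paste0(i, "_", aln_group_index(aln[[i]]))))
  alpha_per_aln <- unlist(lapply(seq_along(aln), function(i)
    current_alpha[[i]][aln[[i]]$tx]))

  ## fractional posterior weight of each candidate under current_alpha
  v <- alpha_per_aln / l_eff[tx]
  z <- rowsum(v, grp, reorder = FALSE)
  zi <- as.vector(z)[match(grp, rownames(z))]
  w <- ifelse(zi > 0, v / zi, 0)

  ## positional foreground
  nb <- config$n_bins
  b5 <- five_prime_pos(pos, strand, qlen)
  bin <- position_bin(b5, l_eff[tx], nb)
  fg_bin <- rep(config$pseudocount, nb)
  add <- rowsum(w, bin, reorder = FALSE)
  fg_bin[as.integer(rownames(add))] <-
    fg_bin[as.integer(rownames(add))] + add
  fg_bin <- fg_bin / sum(fg_bin)

  ## sequence foreground: per-offset chains from read windows
  L <- config$window_L
  windows <- local_sequences(catalog, tx, pos, strand, L, qlen)
  cm <- window_codes(windows, L)
  fg_chain <- vector("list", L)
  for (j in seq_len(L)) {
    o <- min(config$order, j - 1L)
    ctx <- context_index(cm, j, o)
    fg_chain[[j]] <- tally_chain(ctx, cm[, j], w, o, config$pseudocount)
  }

  bg_chain <- background_chains(catalog, current_alpha[[1]], config$order,
                                config$pseudocount)
  structure(list(pos = list(n_bins = nb, fg_bin_prob = fg_bin,
                            bg_bin_prob = rep(1 / nb, nb)),
                 seq = list(order = config$order, window_L = L,
                            fg_chain = fg_chain, bg_chain = bg_chain),
                 config = config, identity = FALSE),
            class = "bias_model")
}

## Per-alignment weights from raw vectors; core of bias_weight/apply_bias.
bias_weights_core <- function(model, tx, pos, strand, qlen, catalog, l_eff) {
  if (is.null(model)) return(rep(1, length(tx)))
  stopifnot(inherits(model, "bias_model"))
  nb <- model$pos$n_bins
  b5 <- five_prime_pos(pos, strand, qlen)
  bin <- position_bin(b5, l_eff[tx], nb)
  w <- model$pos$fg_bin_prob[bin] / model$pos$bg_bin_prob[bin]

  L <- model$seq$window_L
  windows <- local_sequences(catalog, tx, pos, strand, L, qlen)
  cm <- window_codes(windows, L)
  logr <- rep(0, length(tx))
  for (j in seq_len(L)) {
    o <- min(model$seq$order, j - 1L)
    ctx <- context_index(cm, j, o)
    base <- cm[, j]
    ok <- !is.na(ctx) & !is.na(base)
    if (any(ok)) {
      idx <- (base[ok] - 1L) * 4^o + ctx[ok]
      logr[ok] <- logr[ok] +
        log(model$seq$fg_chain[[j]][idx]) -
        log(model$seq$bg_chain[[o + 1L]][idx])
    }
  }
  w * exp(logr)
}

#' Bias weight of a single alignment
#'
#' @param model a \code{bias_model} (or NULL for the disabled module,
#'   giving weight exactly 1).
#' @param b 0-based 5' start position within the transcript.
#' @param l_eff_t effective length of the transcript.
#' @param window local sequence window of length \code{window_L} centred
#'   at \code{b} (5'->3' along the read).
#' @return a positive scalar weight.
#' @export
bias_weight <- function(model, b, l_eff_t, window) {
  if (is.null(model)) return(1)
  stopifnot(inherits(model, "bias_model"))
  nb <- model$pos$n_bins
  bin <- position_bin(b, l_eff_t, nb)
  w <- model$pos$fg_bin_prob[bin] / model$pos$bg_bin_prob[bin]
  L <- model$seq$window_L
  stopifnot(nchar(window) == L)
  cm <- window_codes(window, L)
  for (j in seq_len(L)) {
    o <- min(model$seq$order, j - 1L)
    ctx <- context_index(cm, j, o)
    base <- cm[, j]
    if (!is.na(ctx) && !is.na(base)) {
      idx <- (base - 1L) * 4^o + ctx
      w <- w * model$seq$fg_chain[[j]][idx] / model$seq$bg_chain[[o + 1L]][idx]
    }
  }
  unname(w)
}

#' Per-candidate bias weights for reads
#'
#' Computes the bias weight of every candidate alignment, for use as the
#' per-alignment weights of the estimation engine.  With a NULL model
#' (module disabled) the result is exactly 1 everywhere.
#'
#' @param aln an \code{alignment_set}, or a single read's group from
#'   \code{\link{alignment_group}}.
#' @param model a \code{bias_model} or NULL.
#' @param catalog \code{transcript_catalog} with sequences (not needed
#'   when \code{model} is NULL).
#' @param l_eff effective lengths.
#' @return numeric vector of weights, one per candidate alignment.
#' @export
apply_bias <- function(aln, model, catalog = NULL, l_eff = NULL) {
  if (inherits(aln, "alignment_set")) {
    if (is.null(model)) return(rep(1, aln$n_alignments))
    return(bias_weights_core(model, aln$tx, aln$pos, aln$strand, aln$qlen,
                             catalog, l_eff))
  }
  cand <- aln$candidates
  if (is.null(model)) return(rep(1, nrow(cand)))
  bias_weights_core(model, cand$tx, cand$pos, cand$strand, cand$qlen,
                    catalog, l_eff)
}

#' Dump trained bias tables as TSV (for inspection)
#'
#' @param model a \code{bias_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bias_tsv <- function(model, path) {
  stopifnot(inherits(model, "bias_model"))
  rows <- data.frame(component = "positional",
                     offset = seq_len(model$pos$n_bins),
                     context = NA_character_,
                     base = NA_character_,
                     fg = model$pos$fg_bin_prob,
                     bg = model$pos$bg_bin_prob)
  for (j in seq_len(model$seq$window_L)) {
    o <- min(model$seq$order, j - 1L)
    fg <- model$seq$fg_chain[[j]]
    bg <- model$seq$bg_chain[[o + 1L]]
    ctxs <- vapply(0:(4^o - 1L), function(i) {
      if (o == 0L) return("")
      d <- integer(o)
      for (m in o:1) { d[m] <- i %% 4L; i <- i %/% 4L }
      paste(BASES[d + 1L], collapse = "")
    }, character(1))
    grid <- expand.grid(ctx = seq_len(4^o), base = seq_len(4))
    rows <- rbind(rows, data.frame(
      component = "sequence", offset = j,
      context = ctxs[grid$ctx], base = BASES[grid$base],
      fg = fg[cbind(grid$ctx, grid$base)],
      bg = bg[cbind(grid$ctx, grid$base)]))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
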