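## Synthetic-data generator: random transcript catalogs (optionally with
## shared homologous blocks that induce multi-mapping), Dirichlet
## abundance profiles, and pure/mixed single-end read sets with
## ground-truth ledgers.  Reads are sampled exactly under the package's
## own generative model: transcript by rho weighted with effective
## length, fragment length from the (clamped) normal model, start
## position uniform over the fragment-compatible range — or positionally
## biased when a bias specification is injected.

#' Simulation configuration
#'
#' Defaults describe the desk-scale world the test-suite experiments run
#' in: a few hundred transcripts of 500-5000 nt, 75-bp single-end reads,
#' fragment length N(200, 80^2), flat Dirichlet abundance profiles, and
#' 100k reads per sample.
#'
#' @param n_transcripts catalog size (default 400).
#' @param length_range min/max transcript length in nt (default 500-5000).
#' @param read_length read length in nt (default 75).
#' @param n_reads_pure,n_reads_mixed reads per sample (default 1e5).
#' @param tau_b mixing proportion of cell type b in the mixed sample.
#' @param frag a \code{\link{fragment_model}}.
#' @param bias_spec optional positional bias to inject: a list with
#'   element \code{positional}, a vector of relative-position bin weights
#'   (e.g. \code{c(rep(0, 9), 1)} confines reads to the 3'-most decile).
#' @param ambiguity_spec fraction of transcripts paired up to share an
#'   exact homologous block (reads from the block multi-map); default 0.
#' @param ambig_block_len length of the shared block (default
#'   \code{2 * read_length}).
#' @param concentration symmetric Dirichlet concentration for abundance
#'   draws (default 1).
#' @param seed RNG seed; all generator output is byte-reproducible given
#'   the seed.
#' @return a \code{sim_config} object.
#' @export
sim_config <- function(n_transcripts = 400L, length_range = c(500L, 5000L),
                       read_length = 75L, n_reads_pure = 100000L,
                       n_reads_mixed = 100000L, tau_b = 0.6,
                       frag = fragment_model(200, 80), bias_spec = NULL,
                       ambiguity_spec = 0, ambig_block_len = NULL,
                       concentration = 1, seed = 1L) {
  stopifnot(n_transcripts >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            read_length >= 1L, read_length <= length_range[1],
            n_reads_pure >= 1L, n_reads_mixed >= 1L,
            tau_b >= 0, tau_b <= 1,
            inherits(frag, "fragment_model"),
            ambiguity_spec >= 0, ambiguity_spec <= 1,
            concentration > 0)
  if (is.null(ambig_block_len)) ambig_block_len <- 2L * read_length
  ambig_block_len <- min(as.integer(ambig_block_len), length_range[1])
  if (ambig_block_len < read_length) ambig_block_len <- read_length
  structure(list(n_transcripts = as.integer(n_transcripts),
                 length_range = as.integer(length_range),
                 read_length = as.integer(read_length),
                 n_reads_pure = as.integer(n_reads_pure),
                 n_reads_mixed = as.integer(n_reads_mixed),
                 tau_b = tau_b, frag = frag, bias_spec = bias_spec,
                 ambiguity_spec = ambiguity_spec,
                 ambig_block_len = ambig_block_len,
                 concentration = concentration, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random transcript catalog
#'
#' Sequences are i.i.d. uniform over A,C,G,T.  When
#' \code{ambiguity_spec > 0}, \code{floor(ambiguity_spec * n / 2)}
#' transcript pairs share an exact block of \code{ambig_block_len} nt at
#' random offsets, so reads fully inside the block align to both pair
#' members.  Block coordinates are recorded in the \code{"homology"}
#' attribute (data.frame tx1, pos1, tx2, pos2, len; 0-based positions).
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{transcript_catalog} with sequences.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  lens <- sample(config$length_range[1]:config$length_range[2], n,
                 replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  hom <- data.frame(tx1 = integer(0), pos1 = integer(0),
                    tx2 = integer(0), pos2 = integer(0), len = integer(0))
  n_pairs <- floor(config$ambiguity_spec * n / 2)
  if (n_pairs >= 1) {
    bl <- config$ambig_block_len
    for (p in seq_len(n_pairs)) {
      t1 <- 2L * p - 1L; t2 <- 2L * p
      p1 <- sample.int(lens[t1] - bl + 1L, 1L) - 1L
      p2 <- sample.int(lens[t2] - bl + 1L, 1L) - 1L
      block <- substr(seqs[t1], p1 + 1L, p1 + bl)
      substr(seqs[t2], p2 + 1L, p2 + bl) <- block
      hom <- rbind(hom, data.frame(tx1 = t1, pos1 = p1,
                                   tx2 = t2, pos2 = p2, len = bl))
    }
  }
  cat_ <- transcript_catalog(sprintf("tx%04d", seq_len(n)), lens, seqs)
  attr(cat_, "homology") <- hom
  cat_
}

#' Draw two cell-type abundance profiles
#'
#' Two independent symmetric Dirichlet draws over the catalog.
#'
#' @param catalog a \code{transcript_catalog}.
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration parameter (default 1).
#' @return list with normalised vectors \code{rho_a}, \code{rho_b}.
#' @export
generate_abundances <- function(catalog, seed = 1L, concentration = 1) {
  stopifnot(inherits(catalog, "transcript_catalog"), concentration > 0)
  set.seed(seed)
  T <- length(catalog$ids)
  draw <- function() {
    g <- stats::rgamma(T, shape = concentration, rate = 1)
    g / sum(g)
  }
  list(rho_a = draw(), rho_b = draw())
}

## Core sampler (does not seed): draws transcripts, fragment lengths,
## start positions for n reads under abundance profile rho.  Returns
## tx (index) and pos (0-based start).
sample_read_positions <- function(catalog, rho, n, frag, read_length,
                                  bias_spec = NULL) {
  l_eff <- effective_lengths(catalog, frag)
  alpha <- rho_to_alpha(rho, l_eff)
  tx <- sample.int(length(alpha), n, replace = TRUE, prob = alpha)
  l <- catalog$lengths[tx]
  x <- round(stats::rnorm(n, frag$mu, frag$sigma))
  x <- pmin(pmax(x, read_length), l)
  valid <- l - x + 1L          # number of admissible start positions
  if (is.null(bias_spec) || is.null(bias_spec$positional)) {
    pos <- floor(stats::runif(n) * valid)
  } else {
    wts <- bias_spec$positional
    nb <- length(wts)
    bin <- sample.int(nb, n, replace = TRUE, prob = wts)
    u <- stats::runif(n)
    pos <- floor(((bin - 1L) + u) / nb * valid)
  }
  pos <- pmin(as.integer(pos), valid - 1L)
  list(tx = tx, pos = pos, frag = as.integer(x))
}

## Add homologous-block placements: a read lying fully inside a shared
## block gains the mirrored placement on the partner transcript.
homolog_placements <- function(catalog, tx, pos, read_length) {
  hom <- attr(catalog, "homology")
  n <- length(tx)
  tx2 <- rep(NA_integer_, n)
  pos2 <- rep(NA_integer_, n)
  if (!is.null(hom) && nrow(hom) > 0) {
    both <- rbind(
      data.frame(tx = hom$tx1, p = hom$pos1, ptx = hom$tx2, pp = hom$pos2,
                 len = hom$len),
      data.frame(tx = hom$tx2, p = hom$pos2, ptx = hom$tx1, pp = hom$pos1,
                 len = hom$len))
    j <- match(tx, both$tx)
    hit <- !is.na(j) &
      pos >= both$p[j] &
      (pos + read_length) <= (both$p[j] + both$len[j])
    hit[is.na(hit)] <- FALSE
    tx2[hit] <- both$ptx[j[hit]]
    pos2[hit] <- both$pp[j[hit]] + (pos[hit] - both$p[j[hit]])
  }
  list(tx2 = tx2, pos2 = pos2)
}

## Assemble an alignment_set + ledger from sampled origins (and optional
## cell labels).
assemble_sim <- function(catalog, tx, pos, read_length, sample_tag,
                         read_prefix, cell = NULL, with_seqs = FALSE,
                         frag_len = NA_integer_) {
  n <- length(tx)
  hp <- homolog_placements(catalog, tx, pos, read_length)
  has2 <- !is.na(hp$tx2)
  counts <- 1L + has2
  offsets <- c(1L, cumsum(counts) + 1L)
  total <- offsets[n + 1L] - 1L
  atx <- integer(total); apos <- integer(total)
  first <- offsets[seq_len(n)]
  atx[first] <- tx; apos[first] <- pos
  if (any(has2)) {
    second <- first[has2] + 1L
    atx[second] <- hp$tx2[has2]
    apos[second] <- hp$pos2[has2]
  }
  ids <- sprintf("%s%07d", read_prefix, seq_len(n))
  truth <- data.frame(read_id = ids, tx = tx, pos = pos,
                      frag_len = frag_len,
                      cell_type = if (is.null(cell)) rep("a", n) else cell,
                      stringsAsFactors = FALSE)
  aln <- alignment_set(ids, offsets, atx, apos,
                       strand = integer(total),
                       qlen = rep.int(as.integer(read_length), total),
                       sample_tag = sample_tag,
                       stats = list(total_reads = n, aligned_reads = n,
                                    multimapped_reads = sum(has2),
                                    skipped_reads = 0L))
  seqs <- NULL
  if (with_seqs)
    seqs <- substr(catalog$sequences[tx], pos + 1L, pos + read_length)
  list(aln = aln, truth = truth, read_seqs = seqs)
}

#' Generate a pure-sample read set
#'
#' Reads are sampled under the package's generative model from one
#' abundance profile; reads falling inside a shared homologous block
#' receive both placements (multi-mapping).  Returns the in-memory
#' alignment set plus a ground-truth ledger; use \code{\link{write_sam}}
#' and \code{\link{write_catalog_fasta}} to materialise files.
#'
#' @param catalog a \code{transcript_catalog} from
#'   \code{\link{generate_catalog}}.
#' @param rho relative abundance vector.
#' @param n_reads number of reads.
#' @param frag a \code{fragment_model}.
#' @param read_length read length (nt).
#' @param bias_spec optional injected positional bias (see
#'   \code{\link{sim_config}}).
#' @param seed RNG seed.
#' @param sample_tag "pure" or "mixed" tag on the alignment set.
#' @param read_prefix prefix of generated read names.
#' @param with_seqs also return read sequences (needed to write SAM with
#'   SEQ fields); default TRUE.
#' @return list with \code{aln} (\code{alignment_set}), \code{truth}
#'   (data.frame read_id, tx, pos, cell_type), \code{read_seqs}.
#' @export
generate_reads <- function(catalog, rho, n_reads, frag = fragment_model(),
                           read_length = 75L, bias_spec = NULL, seed = 1L,
                           sample_tag = "pure", read_prefix = "rp",
                           with_seqs = TRUE) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  check_profile(rho, "rho")
  set.seed(seed)
  sp <- sample_read_positions(catalog, rho, n_reads, frag, read_length,
                              bias_spec)
  assemble_sim(catalog, sp$tx, sp$pos, read_length, sample_tag,
               read_prefix, with_seqs = with_seqs, frag_len = sp$frag)
}

#' Generate a mixed-sample read set
#'
#' Each read's cell type is drawn Bernoulli(tau_b); the read is then
#' sampled from that cell type's abundance profile.  The ledger retains
#' the cell-type label so the subset of reads originating purely from
#' cell type b can be extracted as a control.
#'
#' @inheritParams generate_reads
#' @param rho_a,rho_b cell-type abundance profiles.
#' @param tau_b mixing proportion of cell type b.
#' @return as \code{\link{generate_reads}}; \code{truth$cell_type} is
#'   "a" or "b".
#' @export
generate_mixture <- function(catalog, rho_a, rho_b, tau_b, n_reads,
                             frag = fragment_model(), read_length = 75L,
                             bias_spec = NULL, seed = 1L,
                             read_prefix = "rm", with_seqs = TRUE) {
  stopifnot(inherits(catalog, "transcript_catalog"),
            tau_b >= 0, tau_b <= 1)
  check_profile(rho_a, "rho_a")
  check_profile(rho_b, "rho_b")
  set.seed(seed)
  cell <- ifelse(stats::runif(n_reads) < tau_b, "b", "a")
  tx <- integer(n_reads); pos <- integer(n_reads)
  fl <- integer(n_reads)
  ia <- which(cell == "a"); ib <- which(cell == "b")
  if (length(ia)) {
    sa <- sample_read_positions(catalog, rho_a, length(ia), frag,
                                read_length, bias_spec)
    tx[ia] <- sa$tx; pos[ia] <- sa$pos; fl[ia] <- sa$frag
  }
  if (length(ib)) {
    sb <- sample_read_positions(catalog, rho_b, length(ib), frag,
                                read_length, bias_spec)
    tx[ib] <- sb$tx; pos[ib] <- sb$pos; fl[ib] <- sb$frag
  }
  assemble_sim(catalog, tx, pos, read_length, "mixed", read_prefix,
               cell = cell, with_seqs = with_seqs, frag_len = fl)
}

#' Per-transcript true read counts from a ledger
#'
#' @param truth a ledger data.frame from the generators.
#' @param T catalog size.
#' @param cell optionally restrict to one cell type ("a" or "b").
#' @return integer vector of length \code{T}.
#' @export
true_counts <- function(truth, T, cell = NULL) {
  if (!is.null(cell)) truth <- truth[truth$cell_type == cell, , drop = FALSE]
  tabulate(truth$tx, nbins = T)
}

#' Write a ground-truth ledger as TSV
#'
#' @param truth ledger data.frame.
#' @param catalog matching catalog (for transcript ids).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_tsv <- function(truth, catalog, path) {
  out <- data.frame(read_id = truth$read_id,
                    transcript_id = catalog$ids[truth$tx],
                    cell_type = truth$cell_type,
                    position = truth$pos)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
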