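#' Transcript catalog
#'
#' A reference set of transcripts: unique identifiers, lengths in
#' nucleotides, and (optionally) the nucleotide sequences themselves.
#' Sequences are only required by the bias-correction module and by the
#' read simulator; the core estimation engine works from lengths alone.
#'
#' @param ids character vector of unique transcript identifiers.
#' @param lengths integer vector of transcript lengths (nt), one per id.
#' @param sequences optional character vector of sequences over
#'   \code{A,C,G,T,N}; each must have \code{nchar} equal to the
#'   corresponding length.
#' @return An object of class \code{transcript_catalog}: a list with
#'   elements \code{ids}, \code{lengths}, \code{sequences}.
#' @export
transcript_catalog <- function(ids, lengths, sequences = NULL) {
  ids <- as.character(ids)
  lengths <- as.integer(lengths)
  if (length(ids) < 1L) stop("catalog must contain at least one transcript")
  if (length(ids) != length(lengths))
    stop("ids and lengths must have equal length")
  if (anyDuplicated(ids)) stop("transcript ids must be unique")
  if (any(is.na(lengths)) || any(lengths < 1L))
    stop("all transcript lengths must be >= 1")
  if (!is.null(sequences)) {
    sequences <- toupper(as.character(sequences))
    if (length(sequences) != length(ids))
      stop("sequences must match ids in length")
    if (any(nchar(sequences) != lengths))
      stop("sequence lengths must equal declared transcript lengths")
  }
  structure(list(ids = ids, lengths = lengths, sequences = sequences),
            class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf("transcript_catalog: %d transcripts, lengths %d-%d nt, sequences: %s\n",
              length(x$ids), min(x$lengths), max(x$lengths),
              if (is.null(x$sequences)) "absent" else "present"))
  invisible(x)
}

#' Fragment-length model
#'
#' The RNA-seq fragment length is modelled as a normal distribution with
#' mean \code{mu} and standard deviation \code{sigma}, discretised and
#' renormalised over the positions available within each transcript.
#' \code{sigma = 0} is allowed and treated as a point mass at
#' \code{round(mu)}, which makes short analytic test cases exact.
#'
#' @param mu mean fragment length (nt), > 0. Default 200.
#' @param sigma fragment length standard deviation (nt), >= 0. Default 80.
#' @return An object of class \code{fragment_model}.
#' @export
fragment_model <- function(mu = 200, sigma = 80) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("mu must be a single positive number")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single nonnegative number")
  structure(list(mu = mu, sigma = sigma), class = "fragment_model")
}

#' Effective transcript lengths
#'
#' The effective length of a transcript is the expected number of positions
#' at which a read can start, under the discretised fragment-length
#' distribution renormalised over fragment lengths x in 1..l_t:
#' \deqn{\tilde l_t = \sum_{x=1}^{l_t} p(x) (l_t - x + 1)}
#' where p(x) is the normal density at x renormalised over 1..l_t.
#' Results are clamped into [1, l_t].  For transcripts so short that the
#' whole renormalisation mass underflows, the fallback
#' \code{max(1, l_t - mu + 1)} is used.
#'
#' @param lengths integer vector of transcript lengths, or a
#'   \code{transcript_catalog}.
#' @param frag a \code{fragment_model}.
#' @return numeric vector of effective lengths, same order as input.
#' @export
effective_lengths <- function(lengths, frag) {
  if (inherits(lengths, "transcript_catalog")) lengths <- lengths$lengths
  lengths <- as.integer(lengths)
  if (any(is.na(lengths)) || any(lengths < 1L))
    stop("transcript lengths must be positive integers")
  stopifnot(inherits(frag, "fragment_model"))
  vapply(lengths, effective_length_one, numeric(1), frag = frag)
}

effective_length_one <- function(l, frag) {
  if (frag$sigma == 0) {
    x0 <- round(frag$mu)
    le <- if (x0 >= 1 && x0 <= l) l - x0 + 1 else max(1, l - frag$mu + 1)
    return(min(max(le, 1), l))
  }
  x <- seq_len(l)
  p <- stats::dnorm(x, mean = frag$mu, sd = frag$sigma)
  s <- sum(p)
  if (s <= 0 || !is.finite(s)) {
    le <- max(1, l - frag$mu + 1)
  } else {
    le <- sum(p * (l - x + 1)) / s
  }
  min(max(le, 1), l)
}

#' Read a transcript catalog from a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header line.
#'
#' @param path path to a (plain-text) FASTA file.
#' @param keep_sequences keep the sequences in the catalog (required for
#'   bias correction); default TRUE.
#' @return a \code{transcript_catalog}.
#' @export
read_catalog_fasta <- function(path, keep_sequences = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  transcript_catalog(ids, Biostrings::width(seqs),
                     sequences = if (keep_sequences) as.character(seqs) else NULL)
}

#' Write a transcript catalog to FASTA
#'
#' @param catalog a \code{transcript_catalog} with sequences present.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  if (is.null(catalog$sequences))
    stop("catalog has no sequences to write")
  xs <- Biostrings::DNAStringSet(catalog$sequences)
  names(xs) <- catalog$ids
  Biostrings::writeXStringSet(xs, filepath = path, width = 70L)
  invisible(path)
}
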