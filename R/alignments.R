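## SAM parsing into per-read alignment groups, and the compact in-memory
## alignment container shared by the estimation engine and the simulator.
##
## An alignment_set stores all candidate alignments of a read set in a
## "compressed row" layout: alignment-level vectors (tx, pos, strand, qlen)
## plus an offsets vector delimiting each read's block.  Positions are
## 0-based within the transcript (SAM POS is converted on read).

#' Construct an alignment set
#'
#' Usually produced by \code{\link{parse_sam}} or the simulator rather
#' than called directly.
#'
#' @param read_ids character, one per read.
#' @param offsets integer of length \code{n_reads + 1}; read i owns
#'   alignment rows \code{offsets[i] .. offsets[i+1]-1} (1-based).
#' @param tx integer catalog index per alignment.
#' @param pos integer 0-based start position per alignment.
#' @param strand integer per alignment: 0 forward, 1 reverse.
#' @param qlen integer read length per alignment.
#' @param sample_tag "pure" or "mixed".
#' @param stats optional list of stream statistics.
#' @return object of class \code{alignment_set}.
#' @export
alignment_set <- function(read_ids, offsets, tx, pos, strand, qlen,
                          sample_tag = "pure", stats = list()) {
  n_reads <- length(read_ids)
  offsets <- as.integer(offsets)
  stopifnot(length(offsets) == n_reads + 1L,
            offsets[1] == 1L,
            offsets[n_reads + 1L] == length(tx) + 1L,
            all(diff(offsets) >= 1L),
            length(pos) == length(tx),
            length(strand) == length(tx),
            sample_tag %in% c("pure", "mixed"))
  structure(list(read_ids = as.character(read_ids), offsets = offsets,
                 tx = as.integer(tx), pos = as.integer(pos),
                 strand = as.integer(strand), qlen = as.integer(qlen),
                 n_reads = n_reads, n_alignments = length(tx),
                 sample_tag = sample_tag, stats = stats),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set (%s): %d reads, %d alignments (%d multi-mapped reads)\n",
              x$sample_tag, x$n_reads, x$n_alignments,
              sum(diff(x$offsets) > 1L)))
  invisible(x)
}

## group index (read number) per alignment row
aln_group_index <- function(aln) rep.int(seq_len(aln$n_reads), diff(aln$offsets))

#' Extract one read's alignment group
#'
#' @param aln an \code{alignment_set}.
#' @param i read index.
#' @return list with \code{read_id} and a data.frame of \code{candidates}
#'   (tx, pos, strand, qlen).
#' @export
alignment_group <- function(aln, i) {
  stopifnot(i >= 1, i <= aln$n_reads)
  j <- aln$offsets[i]:(aln$offsets[i + 1L] - 1L)
  list(read_id = aln$read_ids[i],
       sample_tag = aln$sample_tag,
       candidates = data.frame(tx = aln$tx[j], pos = aln$pos[j],
                               strand = aln$strand[j], qlen = aln$qlen[j]))
}

#' Parse single-end SAM alignments against a transcript catalog
#'
#' Reads a SAM file (as written by a transcriptome aligner reporting up to
#' k candidate alignments per read), groups records by read name, converts
#' 1-based SAM POS to 0-based transcript offsets, and returns an
#' \code{alignment_set}.  Records of one read must be contiguous
#' (name-grouped, the default aligner output order); pass
#' \code{group_sort = TRUE} to sort scattered records in memory first.
#'
#' @param path SAM file path.
#' @param catalog a \code{transcript_catalog}; every SAM reference name
#'   must be one of its ids.
#' @param max_candidates keep at most this many alignments per read,
#'   first-in-file-order (default 10, mirroring an aligner reporting up to
#'   10 hits).
#' @param sample_tag "pure" or "mixed" label carried on the result.
#' @param group_sort sort records by read name before grouping.
#' @return an \code{alignment_set}; \code{$stats} holds total_reads,
#'   aligned_reads, multimapped_reads, skipped_reads, out_of_range,
#'   dropped_candidates, duplicate_candidates.
#' @export
parse_sam <- function(path, catalog, max_candidates = 10L,
                      sample_tag = "pure", group_sort = FALSE) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  if (!file.exists(path)) stop("SAM file not found: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth")))[[1]]

  unknown <- setdiff(levels(res$rname), catalog$ids)
  if (length(unknown))
    stop("SAM reference name(s) absent from catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) " ..." else "")

  mapped <- !bitwAnd(res$flag, 4L)
  skipped <- sum(!mapped)
  qname <- res$qname[mapped]
  tx <- match(as.character(res$rname[mapped]), catalog$ids)
  pos <- res$pos[mapped] - 1L
  strand <- as.integer(bitwAnd(res$flag[mapped], 16L) > 0L)
  qlen <- res$qwidth[mapped]
  qlen[is.na(qlen)] <- 0L

  if (any(is.na(tx)))
    stop("mapped record with reference name absent from catalog")
  if (any(pos < 0L) || any(pos >= catalog$lengths[tx]))
    stop("SAM POS outside transcript bounds")

  if (group_sort) {
    o <- order(qname)
    qname <- qname[o]; tx <- tx[o]; pos <- pos[o]
    strand <- strand[o]; qlen <- qlen[o]
  }

  if (length(qname) == 0L) stop("SAM file contains no mapped reads: ", path)
  runs <- rle(qname)
  if (anyDuplicated(runs$values))
    stop("SAM is not name-grouped (read names recur non-contiguously); ",
         "re-run with group_sort = TRUE or pre-sort by name")
  grp <- rep.int(seq_along(runs$lengths), runs$lengths)

  ## drop duplicate (transcript, start, strand) candidates within a read
  dup <- duplicated(data.frame(grp, tx, pos, strand))
  n_dup <- sum(dup)
  if (n_dup) {
    keep <- !dup
    grp <- grp[keep]; tx <- tx[keep]; pos <- pos[keep]
    strand <- strand[keep]; qlen <- qlen[keep]
  }

  ## truncate to max_candidates, keeping file order
  rank_in_grp <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  drop <- rank_in_grp > max_candidates
  n_drop <- sum(drop)
  if (n_drop) {
    keep <- !drop
    grp <- grp[keep]; tx <- tx[keep]; pos <- pos[keep]
    strand <- strand[keep]; qlen <- qlen[keep]
  }

  counts <- tabulate(grp, nbins = length(runs$lengths))
  offsets <- c(1L, cumsum(counts) + 1L)
  out_of_range <- sum(qlen > 0L & pos + qlen > catalog$lengths[tx])
  if (out_of_range)
    warning(out_of_range, " alignment(s) extend past the transcript 3' end")

  alignment_set(
    read_ids = runs$values, offsets = offsets, tx = tx, pos = pos,
    strand = strand, qlen = qlen, sample_tag = sample_tag,
    stats = list(total_reads = length(runs$lengths) + skipped,
                 aligned_reads = length(runs$lengths),
                 multimapped_reads = sum(counts > 1L),
                 skipped_reads = skipped,
                 out_of_range = out_of_range,
                 dropped_candidates = n_drop,
                 duplicate_candidates = n_dup))
}

#' Write an alignment set as SAM
#'
#' Emits a header with one @SQ line per catalog transcript followed by one
#' record per candidate alignment (single-end; FLAG 0 or 16 by strand).
#' If read sequences are supplied, SEQ/QUAL are written for every
#' placement of the read, otherwise "*".
#'
#' @param aln an \code{alignment_set}.
#' @param catalog the matching \code{transcript_catalog}.
#' @param path output SAM path.
#' @param read_seqs optional character vector of read sequences, one per
#'   read (in \code{aln} read order).
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(aln, catalog, path, read_seqs = NULL) {
  stopifnot(inherits(aln, "alignment_set"), inherits(catalog, "transcript_catalog"))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", catalog$ids, catalog$lengths))
  grp <- aln_group_index(aln)
  if (is.null(read_seqs)) {
    seqf <- "*"; qualf <- "*"
  } else {
    stopifnot(length(read_seqs) == aln$n_reads)
    seqf <- read_seqs[grp]
    qualf <- vapply(nchar(seqf), function(n) strrep("I", n), character(1))
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 aln$read_ids[grp],
                 ifelse(aln$strand == 1L, 16L, 0L),
                 catalog$ids[aln$tx],
                 aln$pos + 1L,
                 255L,
                 ifelse(aln$qlen > 0L, paste0(aln$qlen, "M"), "*"),
                 seqf, qualf)
  writeLines(c(header, rec), path)
  invisible(path)
}

REV_COMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

reverse_complement_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(REV_COMP_MAP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Local sequence window around an alignment start
#'
#' Returns the window of length \code{window_L} centred at the read's 5'
#' position on the transcript, padded with \code{N} beyond the transcript
#' ends.  For a forward alignment the 5' position is the 0-based start;
#' for a reverse alignment it is \code{pos + qlen - 1} and the window is
#' reverse-complemented, so that the returned string always reads 5'->3'
#' along the read.
#'
#' @param catalog \code{transcript_catalog} with sequences.
#' @param tx transcript index.
#' @param pos 0-based leftmost aligned position.
#' @param strand 0 forward, 1 reverse.
#' @param window_L odd window length.
#' @param qlen read length (needed for reverse-strand alignments).
#' @return a nucleotide string of length \code{window_L}.
#' @export
local_sequence <- function(catalog, tx, pos, strand = 0L, window_L = 21L,
                           qlen = 0L) {
  local_sequences(catalog, tx, pos, strand, window_L, qlen)
}

## Vectorised window extraction; returns character vector of windows.
local_sequences <- function(catalog, tx, pos, strand, window_L, qlen) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  if (is.null(catalog$sequences))
    stop("catalog has no sequences; disable the bias module or supply sequences")
  if (window_L %% 2L != 1L) stop("window_L must be odd")
  half <- (window_L - 1L) %/% 2L
  center <- ifelse(strand == 1L, pos + pmax(qlen, 1L) - 1L, pos)
  lo <- center - half            # 0-based inclusive
  hi <- center + half
  l <- catalog$lengths[tx]
  from <- pmax(lo, 0L)
  to <- pmin(hi, l - 1L)
  core <- substr(catalog$sequences[tx], from + 1L, to + 1L)
  left <- strrep("N", pmax(0L, -lo))
  right <- strrep("N", pmax(0L, hi - (l - 1L)))
  out <- paste0(left, core, right)
  rev_idx <- which(strand == 1L)
  if (length(rev_idx))
    out[rev_idx] <- reverse_complement_chr(out[rev_idx])
  out
}
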