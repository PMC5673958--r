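#' Scan DNA for extended putative G-quadruplex sequences (PQSs)
#'
#' Finds all extended PQS motifs \code{{G3+ N1-12}3+ G3+}: four or more
#' G-tracts of at least three guanines, interspersed with loops of 1-12
#' nucleotides that may contain guanines but never a G-run of three or more.
#' Nested or chained motifs whose inter-tract gaps are at most 12 nt are
#' merged into the single longest stretch engulfing them, so hits on one
#' strand never overlap.  Both strands can be scanned; reverse-strand hits
#' are reported with forward-strand coordinates and \code{strand == "-"},
#' while \code{pqs_sequence}, tracts and loops are given as read 5'->3' on
#' the hit's own strand.
#'
#' Coordinates are 0-based half-open on the forward strand, so
#' \code{end - start == nchar(pqs_sequence)}.  Candidate tracts or loops
#' containing \code{N} abort the match.
#'
#' @param seqs Named character vector of DNA strings (as from
#'   [read_dna()]), or a single unnamed string.
#' @param strands One of \code{"both"}, \code{"forward"}, \code{"reverse"}.
#' @return A \code{pqs_hits} data frame with columns \code{seq_name},
#'   \code{start}, \code{end}, \code{strand}, \code{length},
#'   \code{pqs_sequence}, and list columns \code{tract_start} (0-based
#'   offsets within \code{pqs_sequence}), \code{tract_len} and \code{loops},
#'   plus empty \code{flank5}/\code{flank3} columns to be filled by
#'   [extract_flanks()].
#' @seealso [extract_flanks()], [filter_isolated()]
#' @examples
#' find_pqs(c(tel = "GGGTTAGGGTTAGGGTTAGGG"))
#' @export
find_pqs <- function(seqs, strands = c("both", "forward", "reverse")) {
  strands <- match.arg(strands)
  if (is.null(names(seqs)) && length(seqs) == 1L) names(seqs) <- "seq1"
  seqs <- toupper(seqs)
  out <- vector("list", 2L * length(seqs))
  k <- 0L
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    nm <- names(seqs)[i]
    if (!nzchar(s)) next
    if (strands %in% c("both", "forward")) {
      k <- k + 1L
      out[[k]] <- scan_strand(s, nm, "+")
    }
    if (strands %in% c("both", "reverse")) {
      k <- k + 1L
      out[[k]] <- scan_strand(revcomp(s), nm, "-", forward_length = nchar(s))
    }
  }
  hits <- do.call(rbind, out[seq_len(k)])
  if (is.null(hits)) hits <- empty_hits()
  hits <- hits[order(hits$seq_name, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("pqs_hits", "data.frame")
  hits
}

# Scan one strand.  `s` is the sequence as read on that strand; for the
# reverse strand pass the reverse complement plus the forward length so
# coordinates can be mirrored back.
scan_strand <- function(s, seq_name, strand, forward_length = NULL) {
  m <- gregexpr("G+", s, perl = TRUE)[[1]]
  if (m[1L] == -1L) return(NULL)
  len <- attr(m, "match.length")
  keep <- len >= 3L
  rs <- as.integer(m[keep])          # 1-based tract starts
  rl <- len[keep]
  if (length(rs) < 4L) return(NULL)
  re <- rs + rl                      # 1-based position just past tract end

  hits <- list()
  chain_from <- 1L
  flush <- function(from, to) {
    if (to - from + 1L < 4L) return(NULL)
    build_hit(s, seq_name, strand, rs[from:to], rl[from:to], forward_length)
  }
  i <- 1L
  while (i < length(rs)) {
    gap_len <- rs[i + 1L] - re[i]
    gap_ok <- gap_len >= 1L && gap_len <= 12L &&
      !grepl("N", substr(s, re[i], rs[i + 1L] - 1L), fixed = TRUE)
    if (!gap_ok) {
      h <- flush(chain_from, i)
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
      chain_from <- i + 1L
    }
    i <- i + 1L
  }
  h <- flush(chain_from, length(rs))
  if (!is.null(h)) hits[[length(hits) + 1L]] <- h
  if (length(hits) == 0L) return(NULL)
  do.call(rbind, hits)
}

build_hit <- function(s, seq_name, strand, tr_start, tr_len, forward_length) {
  start1 <- tr_start[1L]                         # 1-based on scanned strand
  end1 <- tr_start[length(tr_start)] + tr_len[length(tr_len)] - 1L
  pqs <- substr(s, start1, end1)
  n <- length(tr_start)
  loops <- substring(s, tr_start[-n] + tr_len[-n], tr_start[-1L] - 1L)
  start0 <- start1 - 1L                          # 0-based half-open
  end0 <- end1
  if (strand == "-") {
    tmp <- start0
    start0 <- forward_length - end0
    end0 <- forward_length - tmp
  }
  data.frame(
    seq_name = seq_name, start = start0, end = end0, strand = strand,
    length = end1 - start1 + 1L, pqs_sequence = pqs,
    tract_start = I(list(tr_start - start1)), tract_len = I(list(tr_len)),
    loops = I(list(loops)), flank5 = NA_character_, flank3 = NA_character_,
    stringsAsFactors = FALSE
  )
}

empty_hits <- function() {
  structure(
    data.frame(
      seq_name = character(), start = integer(), end = integer(),
      strand = character(), length = integer(), pqs_sequence = character(),
      tract_start = I(list()), tract_len = I(list()), loops = I(list()),
      flank5 = character(), flank3 = character(), stringsAsFactors = FALSE
    ),
    class = c("pqs_hits", "data.frame")
  )
}

#' Attach 5'- and 3'-flanking sequences to PQS hits
#'
#' Fills the \code{flank5}/\code{flank3} columns with up to \code{flank_len}
#' nucleotides on each side of every hit, read 5'->3' on the hit's own
#' strand (i.e. reverse-complemented for minus-strand hits).  Flanks are
#' truncated, not padded, where the sequence end is closer than
#' \code{flank_len}.
#'
#' @param seqs Named character vector of the sequences the hits came from.
#' @param hits A \code{pqs_hits} data frame from [find_pqs()].
#' @param flank_len Maximum flank length in nucleotides (default 50).
#' @return `hits` with flank columns populated.
#' @export
extract_flanks <- function(seqs, hits, flank_len = 50L) {
  if (is.null(names(seqs)) && length(seqs) == 1L) names(seqs) <- "seq1"
  stopifnot(flank_len >= 0L)
  if (nrow(hits) == 0L) return(hits)
  if (!all(hits$seq_name %in% names(seqs)))
    stop("hits refer to sequences absent from `seqs`")
  for (i in seq_len(nrow(hits))) {
    s <- seqs[[hits$seq_name[i]]]
    L <- nchar(s)
    if (hits$end[i] > L || hits$start[i] < 0L)
      stop("hit coordinates outside sequence '", hits$seq_name[i], "'")
    up <- substr(s, max(1L, hits$start[i] - flank_len + 1L), hits$start[i])
    dn <- substr(s, hits$end[i] + 1L, min(L, hits$end[i] + flank_len))
    if (hits$strand[i] == "+") {
      hits$flank5[i] <- up
      hits$flank3[i] <- dn
    } else {
      hits$flank5[i] <- if (nzchar(dn)) revcomp(dn) else ""
      hits$flank3[i] <- if (nzchar(up)) revcomp(up) else ""
    }
  }
  hits
}

#' Write a PQS hit table
#'
#' Writes detected hits as a tab-separated table with 1-based inclusive
#' coordinates (genome-browser convention).
#'
#' @param hits A \code{pqs_hits} data frame.
#' @param path Output path.
#' @param extra Optional data frame of extra columns (e.g. mm%, scores).
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, extra = NULL) {
  tab <- data.frame(
    seq_name = hits$seq_name, start = hits$start + 1L, end = hits$end,
    strand = hits$strand, length = hits$length,
    sequence = hits$pqs_sequence, stringsAsFactors = FALSE
  )
  if (!is.null(extra)) tab <- cbind(tab, extra)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
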