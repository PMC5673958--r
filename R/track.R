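#' Read a per-bin mismatch-level (mm%) track
#'
#' Reads a bedGraph-like 4-column text file (sequence name, 0-based start,
#' end, mm%) such as the per-15-nt mismatch-level output of G4-seq.
#' Bins are validated and sorted on load.
#'
#' @param path Path to a 4-column tab- or space-separated file.
#' @return An \code{mm_track} data frame with columns \code{seq_name},
#'   \code{start}, \code{end}, \code{mm}.
#' @export
read_mm_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 4L || anyNA(suppressWarnings(as.numeric(p[2:4]))))
      stop("malformed track line ", i, ": '", lines[i], "'")
  }
  m <- do.call(rbind, parts)
  mm_track(data.frame(
    seq_name = m[, 1L], start = as.numeric(m[, 2L]),
    end = as.numeric(m[, 3L]), mm = as.numeric(m[, 4L]),
    stringsAsFactors = FALSE
  ))
}

mm_track <- function(df) {
  stopifnot(all(c("seq_name", "start", "end", "mm") %in% names(df)))
  if (any(df$start < 0 | df$end <= df$start))
    stop("track bins must satisfy 0 <= start < end")
  if (any(!is.finite(df$mm)))
    stop("non-finite mm% value in track")
  df <- df[order(df$seq_name, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mm_track", "data.frame")
  df
}

#' Write an mm% track as bedGraph-like text
#'
#' @param track An \code{mm_track} data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mm_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assign experimental mm% values to PQS hits
#'
#' For each hit, takes the maximum mm% over all track bins that overlap
#' the PQS extended by \code{flank_len} nt on each side (by at least one
#' base).  Hits without any overlapping bin get \code{NA}: they lack
#' G4-seq coverage and are excluded from training (but kept for
#' prediction).
#'
#' @param hits A \code{pqs_hits} data frame.
#' @param track An \code{mm_track} data frame.
#' @param flank_len Flank length added on both sides (default 50).
#' @return `hits` with an added numeric \code{mm} column.
#' @export
assign_mm <- function(hits, track, flank_len = 50L) {
  stopifnot(inherits(track, "mm_track") || all(
    c("seq_name", "start", "end", "mm") %in% names(track)))
  mm <- rep(NA_real_, nrow(hits))
  for (nm in unique(hits$seq_name)) {
    tr <- track[track$seq_name == nm, , drop = FALSE]
    idx <- which(hits$seq_name == nm)
    if (nrow(tr) == 0L) next
    for (i in idx) {
      lo <- hits$start[i] - flank_len
      hi <- hits$end[i] + flank_len
      ov <- tr$mm[tr$end > lo & tr$start < hi]
      if (length(ov)) mm[i] <- max(ov)
    }
  }
  hits$mm <- mm
  hits
}

#' Drop PQSs with neighbouring PQSs inside their flanks
#'
#' G4-seq resolution is comparable to the 50-nt flanks, so a neighbouring
#' PQS within the flanks inflates the shared mm% peak.  This filter keeps
#' only hits whose nearest neighbour on the same sequence (either strand)
#' is at least \code{flank_len} nt away; inter-motif gaps of at most 12 nt
#' never occur here because such motifs are already merged by
#' [find_pqs()].  The filter is idempotent.
#'
#' @param hits A \code{pqs_hits} data frame (one scan, both strands).
#' @param flank_len Exclusion window in nt (default 50); hits with a
#'   neighbour at a gap strictly smaller than this are removed.
#' @return The isolated subset of `hits`.
#' @export
filter_isolated <- function(hits, flank_len = 50L) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- rep(TRUE, nrow(hits))
  for (nm in unique(hits$seq_name)) {
    idx <- which(hits$seq_name == nm)
    if (length(idx) < 2L) next
    o <- idx[order(hits$start[idx])]
    gap_prev <- hits$start[o][-1L] - hits$end[o][-length(o)]
    crowded <- gap_prev < flank_len
    keep[o[-1L][crowded]] <- FALSE
    keep[o[-length(o)][crowded]] <- FALSE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Copy-number analysis of identical PQSs with different flanks
#'
#' Groups mapped hits by identical PQS sequence, keeps groups with at
#' least \code{min_copies} genomic occurrences, and reports the mean and
#' standard deviation of their mm% values together with a Lowess trend of
#' SD versus mean -- the flank-effect analysis: identical motifs differ
#' only in their flanks, so within-group spread measures the flank
#' contribution to G4 stability.
#'
#' @param hits A \code{pqs_hits} data frame with an \code{mm} column
#'   (see [assign_mm()]); rows with missing mm% are ignored.
#' @param min_copies Minimum genomic copies per group (default 5).
#' @param lowess_f Lowess smoother span (default 2/3).
#' @return A list with \code{groups} (data frame: \code{pqs_sequence},
#'   \code{n_copies}, \code{mean_mm}, \code{sd_mm}) and \code{trend}
#'   (the [stats::lowess()] fit of sd_mm on mean_mm, or \code{NULL} with
#'   a warning when fewer than two groups qualify).
#' @export
copy_number_stats <- function(hits, min_copies = 5L, lowess_f = 2 / 3) {
  stopifnot("mm" %in% names(hits))
  h <- hits[!is.na(hits$mm), , drop = FALSE]
  grp <- split(h$mm, h$pqs_sequence)
  grp <- grp[lengths(grp) >= min_copies]
  groups <- data.frame(
    pqs_sequence = names(grp),
    n_copies = lengths(grp, use.names = FALSE),
    mean_mm = vapply(grp, mean, numeric(1), USE.NAMES = FALSE),
    sd_mm = vapply(grp, stats::sd, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  trend <- NULL
  if (nrow(groups) < 2L) {
    warning("fewer than 2 groups with >= ", min_copies,
            " copies; trend omitted")
  } else {
    trend <- stats::lowess(groups$mean_mm, groups$sd_mm, f = lowess_f)
  }
  list(groups = groups, trend = trend)
}
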