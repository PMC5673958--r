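#' Simulate a genome with planted PQSs of known latent stability
#'
#' Builds a single synthetic chromosome in which PQS motifs of two
#' stability classes are planted at well-separated positions inside a
#' PQS-free background, mimicking the bimodal stability landscape of
#' genomic PQSs: \emph{weak} motifs (latent mm% mode near 8) have minimal
#' 3-G tracts and long loops (5-12 nt), \emph{strong} motifs (mode near
#' 40) have 4-5-G tracts, sometimes a fifth tract, and short loops
#' (1-4 nt).  The latent mm% of each planted PQS is a declared
#' deterministic function of its mean tract length t, mean loop length l
#' and the G fraction g of its two flanks (on its own strand):
#' \deqn{mm = clip(11 + 16(t - 3) + 1.5(6 - l) + a(mm_0)(g - g_0),
#'   0, 100)}
#' with \eqn{g_0 = gc/2} the background's expected G fraction,
#' where the flank-effect amplitude \eqn{a} equals `flank_amp` below a
#' 20-mm% knee and decays linearly to 30\% of it by 60 mm% -- so part of
#' the learnable signal lives in flank features, and the within-group
#' spread of identical motifs with different flanks shrinks with
#' increasing stability.  Motif loops are drawn from \{A,C,T\} with
#' C-runs of 3+ broken (they would read as G-tracts on the other strand),
#' and the background carries no G- or C-run of 3 or more (accidental
#' runs are broken and junction bases forced to A/T), so a scan of both
#' strands recovers exactly the planted intervals.
#'
#' @param n_pqs Number of planted PQSs.
#' @param spacing Mean background gap between consecutive planted motifs
#'   in nt (at least 101 so the default isolation filter keeps all hits;
#'   default 150).
#' @param gc Background G+C fraction (default 0.4).
#' @param p_strong Probability that a planted PQS is strong (default 0.5).
#' @param copy_groups Number of motif sequences planted repeatedly (with
#'   different flanks) for copy-number analyses (default 0).
#' @param copies_per_group Occurrences per copy group (default 6).
#' @param flank_amp Flank-effect amplitude in mm% per unit G fraction
#'   (default 70; 0 disables the flank effect).
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @return List with \code{genome} (named character vector, one
#'   chromosome \code{"chrS"}) and \code{truth}, a data frame of planted
#'   records: \code{seq_name}, 0-based \code{start}/\code{end},
#'   \code{strand}, \code{pqs_sequence}, \code{class}
#'   (\code{"weak"}/\code{"strong"}), \code{mean_tract},
#'   \code{mean_loop}, \code{flank_g}, \code{mm_latent}.
#' @export
simulate_genome <- function(n_pqs, spacing = 150L, gc = 0.4,
                            p_strong = 0.5, copy_groups = 0L,
                            copies_per_group = 6L, flank_amp = 70,
                            seed = 1L) {
  stopifnot(n_pqs >= 0L, spacing >= 101L, gc > 0, gc < 1,
            copy_groups * copies_per_group <= n_pqs)
  with_seed(seed, {
    motifs <- character(n_pqs)
    classes <- character(n_pqs)
    if (n_pqs > 0L) {
      classes <- ifelse(stats::runif(n_pqs) < p_strong, "strong", "weak")
      motifs <- vapply(classes, random_motif, character(1))
      if (copy_groups > 0L) {
        slots <- seq_len(copy_groups * copies_per_group)
        proto <- rep(seq_len(copy_groups), each = copies_per_group)
        motifs[slots] <- motifs[slots[!duplicated(proto)]][proto]
        classes[slots] <- classes[slots[!duplicated(proto)]][proto]
      }
      ord <- sample.int(n_pqs)   # scatter copy groups along the genome
      motifs <- motifs[ord]
      classes <- classes[ord]
    }
    strands <- if (n_pqs) sample(c("+", "-"), n_pqs, replace = TRUE)
               else character()
    gaps <- spacing + sample(-20:20, n_pqs + 1L, replace = TRUE)
    chunks <- vapply(gaps, background_chunk, character(1), gc = gc)
    pieces <- character(2L * n_pqs + 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <- chunks
    planted <- ifelse(strands == "+", motifs, revcomp(motifs))
    if (n_pqs) pieces[seq(2L, length(pieces), by = 2L)] <- planted
    genome <- paste(pieces, collapse = "")
    starts <- cumsum(nchar(pieces)) - nchar(pieces)  # 0-based piece starts
    pqs_start <- if (n_pqs) starts[seq(2L, length(pieces), by = 2L)]
                 else integer(0)
    truth <- data.frame(
      seq_name = rep("chrS", n_pqs), start = pqs_start,
      end = pqs_start + nchar(planted), strand = strands,
      pqs_sequence = motifs, class = classes, stringsAsFactors = FALSE
    )
    if (n_pqs) {
      truth$mean_tract <- vapply(motifs, function(m)
        mean(motif_runs(m)$len), numeric(1), USE.NAMES = FALSE)
      truth$mean_loop <- vapply(motifs, function(m)
        mean(nchar(motif_runs(m)$loops)), numeric(1), USE.NAMES = FALSE)
      truth$flank_g <- mapply(flank_g_fraction, truth$start, truth$end,
                              truth$strand,
                              MoreArgs = list(genome = genome))
      truth$mm_latent <- latent_mm(truth$mean_tract, truth$mean_loop,
                                   truth$flank_g, flank_amp, g0 = gc / 2)
    } else {
      truth$mean_tract <- truth$mean_loop <- truth$flank_g <-
        truth$mm_latent <- numeric(0)
    }
    list(genome = c(chrS = genome), truth = truth)
  })
}

# One random planted motif of the given stability class.  Loops over
# {A,C,T} keep the grammar valid without post-editing.
random_motif <- function(class) {
  if (class == "strong") {
    n_tracts <- sample(4:5, 1L, prob = c(0.8, 0.2))
    tracts <- sample(4:5, n_tracts, replace = TRUE)
    loop_lens <- sample(1:4, n_tracts - 1L, replace = TRUE)
  } else {
    n_tracts <- 4L
    tracts <- rep(3L, n_tracts)
    loop_lens <- sample(5:12, n_tracts - 1L, replace = TRUE)
  }
  loops <- vapply(loop_lens, function(l) {
    b <- sample(c("A", "C", "T"), l, replace = TRUE)
    # no C-run >= 3 either: it would read as a G-tract on the other strand
    if (l >= 3L) {
      hit <- b == "C"
      run3 <- which(hit[-(1:2)] & hit[-c(1L, l)] &
                      hit[-((l - 1):l)]) + 2L
      b[run3] <- sample(c("A", "T"), length(run3), replace = TRUE)
    }
    paste(b, collapse = "")
  }, character(1))
  paste0(paste0(strrep("G", tracts[-n_tracts]), loops, collapse = ""),
         strrep("G", tracts[n_tracts]))
}

motif_runs <- function(m) {
  r <- gregexpr("G+", m)[[1]]
  len <- attr(r, "match.length")
  keep <- len >= 3L
  st <- as.integer(r[keep])
  len <- len[keep]
  n <- length(st)
  list(len = len,
       loops = substring(m, st[-n] + len[-n], st[-1L] - 1L))
}

# Background free of G- and C-runs >= 3 (tracts on either strand) with
# A/T first and last bases, so planted motif boundaries are exact and no
# accidental PQS can arise on either strand.
background_chunk <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  b <- sample(names(p), n, replace = TRUE, prob = p)
  b[c(1L, n)][b[c(1L, n)] %in% c("G", "C")] <- "T"
  if (n >= 3L) {
    for (base in c("G", "C")) {
      hit <- b == base
      run3 <- which(hit[-(1:2)] & hit[-c(1L, n)] & hit[-((n - 1):n)]) + 2L
      b[run3] <- sample(c("A", "T"), length(run3), replace = TRUE)
    }
  }
  paste(b, collapse = "")
}

flank_g_fraction <- function(start, end, strand, genome, flank_len = 50L) {
  L <- nchar(genome)
  up <- substr(genome, max(1L, start - flank_len + 1L), start)
  dn <- substr(genome, end + 1L, min(L, end + flank_len))
  fl <- paste0(up, dn)
  # minus-strand flanks are read on the other strand: count G there
  if (strand == "-") fl <- revcomp(fl)
  n <- nchar(fl)
  if (n == 0L) return(NA_real_)
  lengths(regmatches(fl, gregexpr("G", fl))) / n
}

# Declared latent mm% model; the flank term is centred on the
# background's expected G fraction and its amplitude decays above a
# 20 mm% knee to 30% of its low-stability value by 60 mm%.
latent_mm <- function(mean_tract, mean_loop, flank_g, flank_amp = 70,
                      g0 = 0.2) {
  mm0 <- 11 + 16 * (mean_tract - 3) + 1.5 * (6 - mean_loop)
  amp <- flank_amp * ifelse(mm0 < 20, 1, pmax(0.3, 1 - (mm0 - 20) / 40))
  pmin(100, pmax(0, mm0 + amp * (flank_g - g0)))
}

#' Simulate a G4-seq-like mm% track for a synthetic genome
#'
#' Tiles each chromosome with fixed-width bins.  Background bins get
#' half-normal noise near 0 (SD `noise_sd / 2`); the bin containing each
#' planted PQS's centre gets its latent mm% plus Gaussian noise of SD
#' `noise_sd`, clipped to [0, 100].  With `noise_sd = 0` the peak bins
#' carry exactly the latent means on a zero background.
#'
#' @param sim A [simulate_genome()] result.
#' @param bin Bin width in nt (default 15).
#' @param noise_sd Peak noise SD in mm% (default 5).
#' @param seed Integer seed.
#' @return An \code{mm_track} data frame.
#' @export
simulate_mm_track <- function(sim, bin = 15L, noise_sd = 5, seed = 1L) {
  stopifnot(bin >= 1L, noise_sd >= 0)
  with_seed(seed, {
    out <- lapply(names(sim$genome), function(nm) {
      L <- nchar(sim$genome[[nm]])
      starts <- seq(0L, L - 1L, by = bin)
      mm <- pmax(0, abs(stats::rnorm(length(starts), 0, noise_sd / 2)))
      tr <- sim$truth[sim$truth$seq_name == nm, , drop = FALSE]
      if (nrow(tr)) {
        centre <- (tr$start + tr$end) %/% 2L
        peak_bin <- centre %/% bin + 1L
        peak <- pmin(100, pmax(0, tr$mm_latent +
                                 stats::rnorm(nrow(tr), 0, noise_sd)))
        mm[peak_bin] <- pmax(mm[peak_bin], peak)
      }
      data.frame(seq_name = nm, start = starts,
                 end = pmin(starts + bin, L), mm = mm,
                 stringsAsFactors = FALSE)
    })
    mm_track(do.call(rbind, out))
  })
}

#' Assemble the model-ready dataset from a synthetic (or real) world
#'
#' Runs the full upstream pipeline: scans both strands for PQSs, drops
#' non-isolated hits, extracts flanks and the 209 features, and maps mm%
#' values; rows without mm% coverage are dropped.
#'
#' @param genome Named character vector of sequences.
#' @param track An \code{mm_track}.
#' @param table A [build_energy_table()] for loop energies.
#' @param flank_len Flank length (default 50).
#' @return List with \code{x} (n x 209 feature matrix), \code{mm}
#'   (numeric targets) and \code{hits} (the corresponding
#'   \code{pqs_hits} rows, sorted by sequence and start).
#' @export
make_dataset <- function(genome, track, table = build_energy_table(),
                         flank_len = 50L) {
  hits <- find_pqs(genome, "both")
  hits <- filter_isolated(hits, flank_len)
  hits <- extract_flanks(genome, hits, flank_len)
  hits <- assign_mm(hits, track, flank_len)
  covered <- !is.na(hits$mm)
  hits <- hits[covered, , drop = FALSE]
  rownames(hits) <- NULL
  x <- extract_features(hits, table)
  list(x = x, mm = hits$mm, hits = hits)
}
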