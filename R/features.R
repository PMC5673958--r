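#' Canonical names of the 209 PQS sequence features
#'
#' The feature vector holds, for each of the three segments PQS
#' (prefix \code{G4}), 5'-flank (\code{5f}) and 3'-flank (\code{3f}):
#' the 64 overlapping triad counts (suffix \code{AAA} ... \code{TTT}, in
#' lexicographic order) and 3 singleton counts (\code{G}, \code{C},
#' \code{A}); followed by five motif-topology features (\code{G4_length},
#' \code{G4_numlps}, \code{G4_lp1len}, \code{G4_lp2len}, \code{G4_lp3len})
#' and the ensemble folding free energies of the first three loops
#' (\code{G4_lp1efe}, \code{G4_lp2efe}, \code{G4_lp3efe}, kcal/mol).
#'
#' @return Character vector of length 209.
#' @export
feature_names <- function() {
  triads <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES)[, 3:1],
                  1L, paste0, collapse = "")
  comp <- unlist(lapply(c("G4", "5f", "3f"),
                        function(p) paste0(p, "_", c(triads, SINGLETONS))))
  c(comp, paste0("G4_", c("length", "numlps", "lp1len", "lp2len", "lp3len",
                          "lp1efe", "lp2efe", "lp3efe")))
}

DNA_BASES <- c("A", "C", "G", "T")
# Three of the four bases suffice: the T count is linearly dependent given
# the segment length (G + C + A + T == length).
SINGLETONS <- c("G", "C", "A")

#' Count overlapping triads in DNA segments
#'
#' Sliding-window trinucleotide counts: every overlapping occurrence is
#' counted, so e.g. \code{GGGG} contributes 2 to the \code{GGG} count.
#' Windows containing \code{N} count towards nothing.  Segments shorter
#' than 3 nt give all-zero counts.
#'
#' @param segments Character vector of DNA strings (may be empty strings).
#' @return Integer matrix, one row per segment, 64 lexicographic columns.
#' @export
count_triads <- function(segments) {
  Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(segments), width = 3L, step = 1L
  )
}

#' Count G, C and A singletons in DNA segments
#'
#' @param segments Character vector of DNA strings.
#' @return Integer matrix with columns \code{G}, \code{C}, \code{A}.
#' @export
count_singletons <- function(segments) {
  Biostrings::letterFrequency(Biostrings::DNAStringSet(segments), SINGLETONS)
}

# ---------------------------------------------------------------------------
# Loop-energy engines and lookup table

#' Loop folding free-energy engines
#'
#' An engine maps short DNA loop sequences to ensemble-averaged folding
#' free energies (kcal/mol at 37 degrees C), quantifying their hairpin
#' propensity.  \code{"viennarna"} shells out to the \code{RNAfold}
#' command-line program with DNA (Mathews 2004) parameters and partition
#' function, the engine used for the shipped fixtures.  \code{"hairpin"}
#' is a self-contained base-pair-maximisation (Nussinov-style)
#' approximation with stacking-free pair scores; it is not a calibrated
#' nearest-neighbour model and is labelled non-canonical in the table
#' provenance.
#'
#' @param name Engine name, \code{"viennarna"} or \code{"hairpin"}.
#' @return An object of class \code{g4_energy_engine}: a list with
#'   \code{name}, \code{provenance} and \code{fn(seqs) -> numeric}.
#' @export
energy_engine <- function(name = c("viennarna", "hairpin")) {
  name <- match.arg(name)
  if (name == "viennarna" && !nzchar(Sys.which("RNAfold")))
    stop("RNAfold executable not found; use energy_engine(\"hairpin\")")
  fn <- switch(name, viennarna = vienna_efe, hairpin = hairpin_efe)
  structure(
    list(name = name, fn = fn,
         provenance = switch(name,
           viennarna = "RNAfold -p0 -P DNA (ensemble free energy, 37C)",
           hairpin = "non-canonical base-pair-maximisation approximation")),
    class = "g4_energy_engine"
  )
}

vienna_efe <- function(seqs) {
  if (length(seqs) == 0L) return(numeric())
  infile <- tempfile("loops", fileext = ".seq")
  on.exit(unlink(infile))
  writeLines(seqs, infile)
  out <- suppressWarnings(system2(
    "RNAfold", c("--noPS", "-p0", "-P", "DNA"),
    stdin = infile, stdout = TRUE, stderr = FALSE
  ))
  eline <- grep("free energy of ensemble", out, value = TRUE)
  if (length(eline) != length(seqs))
    stop("RNAfold failed on loop batch starting '", seqs[1L], "'")
  as.numeric(sub(".*=\\s*(-?[0-9.]+)\\s*kcal/mol.*", "\\1", eline))
}

# Nussinov-style maximum weighted pairing with a minimum hairpin loop of
# 3 nt; pair scores approximate DNA pair strength (G:C > A:T >> G:T) and
# are rescaled to kcal/mol-like magnitudes.  Deliberately crude: a
# provenance-tagged stand-in, not a nearest-neighbour thermodynamic model.
hairpin_efe <- function(seqs) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 5L) return(0)
    b <- strsplit(s, "")[[1]]
    score <- function(x, y) {
      p <- paste0(x, y)
      if (p %in% c("GC", "CG")) 2 else if (p %in% c("AT", "TA")) 1
      else if (p %in% c("GT", "TG")) 0.5 else 0
    }
    M <- matrix(0, n, n)
    for (span in 4:(n - 1L)) {
      for (i in 1:(n - span)) {
        j <- i + span
        best <- max(M[i + 1L, j], M[i, j - 1L],
                    M[i + 1L, j - 1L] + score(b[i], b[j]))
        if (j - i > 1L) {
          ks <- (i + 1L):(j - 1L)
          best <- max(best, max(M[i, ks] + M[ks + 1L, j]))
        }
        M[i, j] <- best
      }
    }
    -max(0, M[1L, n] - 1.5)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build a (lazy) loop-energy lookup table
#'
#' The full table over all 5-12-nt DNA loops has
#' \eqn{\sum_{i=5}^{12} 4^i = 22{,}369{,}280} entries; computing it is an
#' explicit offline undertaking, so the table is lazily memoized: energies
#' are computed on first lookup and cached.  \code{precompute} forces
#' eager evaluation of the given sequences.
#'
#' @param len_min,len_max Inclusive loop-length range covered (defaults 5
#'   and 12); loops shorter than \code{len_min} are assigned 0 by
#'   [loop_energy()] without consulting the engine.
#' @param engine A [energy_engine()] object.
#' @param precompute Optional character vector of loops to evaluate now.
#' @return An object of class \code{g4_energy_table}.
#' @export
build_energy_table <- function(len_min = 5L, len_max = 12L,
                               engine = energy_engine(),
                               precompute = NULL) {
  stopifnot(len_min <= len_max, len_min >= 1L)
  tab <- structure(
    list(len_min = as.integer(len_min), len_max = as.integer(len_max),
         engine = engine, cache = new.env(parent = emptyenv()),
         n_slots = sum(4^(len_min:len_max))),
    class = "g4_energy_table"
  )
  if (!is.null(precompute)) loop_energy(precompute, tab)
  tab
}

#' @export
print.g4_energy_table <- function(x, ...) {
  cat("Loop folding free-energy table (", x$len_min, "-", x$len_max,
      " nt, ", format(x$n_slots, big.mark = ","), " slots, ",
      length(ls(x$cache)), " cached)\n  engine: ", x$engine$provenance,
      "\n", sep = "")
  invisible(x)
}

#' Ensemble folding free energy of PQS loops
#'
#' Loops shorter than the table's minimum length (default 5 nt: too short
#' to fold back into a hairpin) get 0.0 kcal/mol.  Other values come from
#' the table's engine and are memoized.
#'
#' @param loops Character vector of loop sequences (lengths at most the
#'   table's \code{len_max}).
#' @param table A [build_energy_table()] object.
#' @return Numeric vector of energies in kcal/mol.
#' @export
loop_energy <- function(loops, table = build_energy_table()) {
  if (length(loops) == 0L) return(numeric())
  if (any(nchar(loops) > table$len_max))
    stop("loop longer than table maximum of ", table$len_max, " nt")
  out <- numeric(length(loops))
  eligible <- nchar(loops) >= table$len_min
  todo <- unique(loops[eligible & !vapply(loops, exists, logical(1),
                                          envir = table$cache)])
  if (length(todo)) {
    vals <- tryCatch(table$engine$fn(todo), error = function(e)
      stop("energy engine failed on loop(s) ", paste(todo, collapse = ","),
           ": ", conditionMessage(e)))
    for (i in seq_along(todo)) assign(todo[i], vals[i], envir = table$cache)
  }
  out[eligible] <- vapply(loops[eligible], get, numeric(1),
                          envir = table$cache)
  out
}

# ---------------------------------------------------------------------------
# Feature extraction

#' Digest PQS hits into the 209 sequence features
#'
#' Computes, for each hit with populated flanks, the triad and singleton
#' contents of the PQS and both 50-nt flanks (201 composition features),
#' the motif topology (overall length, number of loops -- which can exceed
#' 3 for merged nested motifs -- and the lengths of the first three loops
#' 5'->3'), and the ensemble folding free energies of the first three loop
#' sequences.  Missing loops (fewer than three) contribute length 0 and
#' energy 0; loops beyond the third contribute only to \code{G4_numlps}.
#'
#' @param hits A \code{pqs_hits} data frame with flanks populated
#'   (see [extract_flanks()]).
#' @param table A [build_energy_table()] lookup used for loop energies.
#' @return Numeric matrix, one row per hit, 209 columns named as
#'   [feature_names()].
#' @export
extract_features <- function(hits, table = build_energy_table()) {
  fn <- feature_names()
  if (nrow(hits) == 0L)
    return(matrix(numeric(), 0L, length(fn), dimnames = list(NULL, fn)))
  if (anyNA(hits$flank5) || anyNA(hits$flank3))
    stop("hits lack flanks; run extract_flanks() first")
  seg <- list(hits$pqs_sequence, hits$flank5, hits$flank3)
  comp <- do.call(cbind, lapply(seg, function(s)
    cbind(count_triads(s), count_singletons(s))))
  lp <- function(k, what) vapply(hits$loops, function(l) {
    if (length(l) >= k) what(l[[k]]) else 0
  }, numeric(1))
  lens <- cbind(
    hits$length,
    vapply(hits$loops, length, integer(1)),
    lp(1L, nchar), lp(2L, nchar), lp(3L, nchar)
  )
  loops_k <- lapply(1:3, function(k) vapply(hits$loops, function(l)
    if (length(l) >= k) l[[k]] else "", character(1)))
  efe <- vapply(loops_k, function(lk) {
    e <- numeric(length(lk))
    e[nzchar(lk)] <- loop_energy(lk[nzchar(lk)], table)
    e
  }, numeric(nrow(hits)))
  if (nrow(hits) == 1L) efe <- matrix(efe, nrow = 1L)
  x <- cbind(comp, lens, efe)
  dimnames(x) <- list(NULL, fn)
  x
}

# ---------------------------------------------------------------------------
# Median/SD scaler

#' Fit the per-feature median/SD scaler
#'
#' Learns, per feature, the median and standard deviation on training data
#' only; [apply_scaler()] then centres by the median and divides by the
#' SD.  Constant features (SD 0) are mapped to 0.
#'
#' @param x Numeric feature matrix (rows = PQSs).
#' @return An object of class \code{g4_scaler}.
#' @export
fit_scaler <- function(x) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  structure(
    list(center = apply(x, 2L, stats::median),
         scale = apply(x, 2L, stats::sd),
         features = colnames(x)),
    class = "g4_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler A fitted \code{g4_scaler}.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "g4_scaler"))
  if (!identical(colnames(x), scaler$features))
    stop("feature names do not match the scaler")
  s <- ifelse(scaler$scale > 0, scaler$scale, Inf)
  scaled <- sweep(sweep(x, 2L, scaler$center), 2L, s, "/")
  scaled[, scaler$scale == 0] <- 0
  scaled
}

#' Project a feature matrix onto a selected feature subset
#'
#' @param x Feature matrix with the canonical names.
#' @param selected Ordered character vector of feature names to keep.
#' @return `x` restricted to `selected`, order preserved as given.
#' @export
reduce_features <- function(x, selected) {
  unknown <- setdiff(selected, colnames(x))
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  if (length(selected) == 0L)
    warning("empty feature selection")
  x[, selected, drop = FALSE]
}
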