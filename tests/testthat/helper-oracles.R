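# Independent oracles used to cross-check the implementation paths.

random_dna <- function(n, p = c(A = 0.25, C = 0.2, G = 0.35, T = 0.2)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Run-length parse of a candidate PQS string: valid iff it starts and ends
# with a G-tract (run of >= 3 Gs), has >= 4 tracts, every span between
# consecutive tracts is 1-12 nt, and contains no N.  Deliberately coded
# via rle(), a different route from the package's regex scanner.
is_valid_pqs <- function(s) {
  b <- strsplit(s, "")[[1]]
  if (any(b == "N")) return(FALSE)
  r <- rle(b == "G")
  tract <- r$values & r$lengths >= 3L
  if (sum(tract) < 4L) return(FALSE)
  first <- which(tract)[1L]
  last <- which(tract)[sum(tract)]
  if (first != 1L || last != length(r$lengths)) return(FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tr_idx <- which(tract)
  for (k in seq_len(length(tr_idx) - 1L)) {
    gap <- starts[tr_idx[k + 1L]] - ends[tr_idx[k]] - 1L
    if (gap < 1L || gap > 12L) return(FALSE)
  }
  TRUE
}

# Exhaustive brute-force scanner: every substring that starts and ends
# with GGG is validated; valid substrings contained in a longer valid one
# are dropped, leaving the longest-match set.
oracle_find_pqs <- function(s) {
  n <- nchar(s)
  starts <- integer()
  ends <- integer()
  gpos <- which(strsplit(s, "")[[1]] == "G")
  i_cand <- gpos[gpos <= n - 2L]
  i_cand <- i_cand[substring(s, i_cand, i_cand + 2L) == "GGG"]
  j_cand <- gpos[gpos >= 3L]
  j_cand <- j_cand[substring(s, j_cand - 2L, j_cand) == "GGG"]
  for (i in i_cand) {
    for (j in j_cand) {
      if (j - i + 1L < 15L) next   # 4 tracts + 3 loops need >= 15 nt
      if (is_valid_pqs(substr(s, i, j))) {
        starts <- c(starts, i)
        ends <- c(ends, j)
      }
    }
  }
  if (length(starts) == 0L)
    return(data.frame(start = integer(), end = integer()))
  keep <- vapply(seq_along(starts), function(k) {
    !any(starts <= starts[k] & ends >= ends[k] &
           (starts < starts[k] | ends > ends[k]))
  }, logical(1))
  out <- unique(data.frame(start = starts[keep] - 1L, end = ends[keep]))
  out[order(out$start), , drop = FALSE]
}

# Naive O(n * 64) overlapping triad counter.
naive_triads <- function(seg) {
  triads <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T"))[, 3:1],
                  1L, paste0, collapse = "")
  n <- nchar(seg)
  counts <- integer(64)
  names(counts) <- triads
  if (n >= 3L) {
    wins <- substring(seg, 1:(n - 2L), 3:n)
    tb <- table(wins[wins %in% triads])
    counts[names(tb)] <- as.integer(tb)
  }
  counts
}

# Shared small synthetic world for the model-level tests, built once per
# test run.
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_genome(600, seed = 42)
      track <- simulate_mm_track(sim, noise_sd = 5, seed = 42)
      ds <- make_dataset(sim$genome, track, test_energy_table())
      cache <<- list(sim = sim, track = track, ds = ds)
    }
    cache
  }
})

# Energy table on the fallback engine: fast, self-contained, adequate for
# model-level tests where only energies' presence matters.
test_energy_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- build_energy_table(engine =
                                                   energy_engine("hairpin"))
    tab
  }
})
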