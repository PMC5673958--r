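---
title: "Modelling sequence-driven G-quadruplex stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sequence-driven G-quadruplex stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4boost)
```

## The model in one paragraph

`g4boost` regresses an experimental G4 stability signal — the per-bin
base-mismatch level (mm%) produced by G4-seq-style assays, where higher
mm% means a more stable quadruplex — on 209 features computed from
nothing but the DNA sequence of a putative quadruplex sequence (PQS) and
its two 50-nt flanks.  The learner is a gradient boosted ensemble of
regression trees.  A regression (rather than a binary classifier) is
used because mm% is a graded stability measure; a stable/non-forming
call is obtained afterwards by thresholding the predicted score.

## Motif grammar and scanning

The extended PQS motif is `{G3+ N1-12}3+ G3+`: at least four G-tracts of
three or more guanines, with 1-12-nt loops that may contain Gs but never
a G-run of three or more (a maximal G-run of 3+ is always a tract).
Nested or chained motifs with inter-tract gaps of at most 12 nt are
merged into the single longest engulfing hit, so same-strand hits never
overlap, and a merged hit can have more than three loops.  Scanning is
greedy leftmost-longest over maximal G-runs; the reverse strand is
scanned on the reverse complement and mapped back to forward
coordinates.  Coordinates are 0-based half-open internally and 1-based
inclusive in written tables (the common genome-browser convention; the
choice is ours).  Input is uppercased at load; any `N` inside a
candidate tract or loop aborts that match — a conservative rule for
assembly gaps.  Strands are scanned independently; we do not merge hits
across strands.

## The 209 features

For each of the three segments — PQS (`G4_`), 5'-flank (`5f_`),
3'-flank (`3f_`) —

* 64 overlapping triad counts (`AAA` … `TTT`), counted with a sliding
  window so nested occurrences all count: `GGGG` contributes 2 to
  `GGG`.  Windows containing `N` count towards nothing.
* 3 singleton counts.  We count G, C and A; the T count is linearly
  dependent given the segment length, so carrying it would add no
  information.  The choice of which three is configurable in spirit but
  fixed here.

plus five topology features (PQS length; number of loops, which exceeds
3 for merged motifs; lengths of the first three loops 5'→3') and the
ensemble folding free energies of the first three loop sequences
(kcal/mol).  Missing loops (motif with fewer than three) contribute
length 0 and energy 0; loops past the third contribute only to the loop
count.  Truncated flanks at sequence ends are used as-is, without
padding.

### Loop energies

Loop hairpin propensity (a loop that folds back on itself can clip and
stabilise the quadruplex) is quantified by the partition-function
ensemble free energy of the loop sequence.  The default engine shells
out to `RNAfold` with DNA (Mathews 2004) parameters at 37 °C; a bundled
Nussinov-style base-pair-maximisation approximation
(`energy_engine("hairpin")`) is a self-contained alternative whose
provenance string labels it non-canonical — it preserves the sign and
rough ordering of hairpin propensity but is not a calibrated
thermodynamic model.  Loops shorter than 5 nt get energy 0: a hairpin
needs a ≥3-nt loop plus a stem, so the lookup table covers 5-12-mers
only.  The full table has $\sum_{i=5}^{12} 4^i = 22{,}369{,}280$
entries; building it eagerly is an hours-long offline job, so the table
is lazily memoized and persists only its provenance plus cached values.
Every shipped fixture records which engine produced it.

### Scaling

Each feature is centred by its training-set median and divided by its
training-set standard deviation; the pairs are stored with the model and
re-applied at prediction time.  SD-0 (constant) features map to 0.  The
scaler is always fit on training rows only — inside each CV round as
well, so no information leaks from the internal test fold.

## Mapping mm% onto PQSs

The mm% track is bedGraph-like (sequence, 0-based start, end, value),
typically 15-nt bins.  Because polymerase stalling produces the mismatch
peak *near* rather than exactly on the G4, each PQS takes the maximum
mm% over all bins overlapping the PQS ± 50-nt flanks by at least one
base ("overlap" has no minimum beyond one base; that reading is ours).
PQSs with no overlapping bin are uncovered: excluded from training,
kept in prediction output.

Because the 50-nt resolution also means two PQSs within each other's
flanks share one inflated peak, such non-isolated PQSs are excluded from
training: a hit is kept only if its nearest neighbour on the same
sequence — either strand, since an opposite-strand PQS inflates the
signal just as well — is at least 50 nt away.  Gaps of exactly 50 nt are
kept (we read "within the flanks" as a strict `< 50` gap); gaps ≤ 12 nt
cannot occur because the scanner has already merged them.

The copy-number analysis (`copy_number_stats()`) groups identical PQS
sequences with ≥5 genomic occurrences — same motif, different flanks —
and summarises the mean and SD of their mm%, with a Lowess trend of SD
versus mean.  It is the package's direct probe of how much the flanks
modulate stability.

## Learning workflow

* **Split**: random 70/30 train/test, seeded.
* **Tuning metric**: RMSE of predicted vs. actual mm%, the sole
  objective throughout.
* **Repeated CV**: twice-repeated 3-fold cross-validation — the data are
  shuffled per repeat, partitioned in three, and each partition held out
  once (2/3 train, 1/3 internal test), giving six rounds whose RMSEs are
  averaged.  Fold membership is derived from a canonical row order (by
  target, then feature values) before the seeded shuffle, so the CV
  result is a function of the data content and seed, not of row order.
* **Grid search**: every candidate architecture is scored with the same
  seed (identical folds); best = lowest mean RMSE, ties to the earlier
  config.  The shipped default grid is a deliberately small analogue
  (4 configurations around 400 trees, learning rate 0.05) of a full
  multi-cycle sweep; the `gbm_config()` *default* remains the
  full-scale optimum (2500 trees, interaction depth 14, min child
  weight 65, learning rate 0.01, bag fraction 0.6), which is what a
  user refitting against a real genome-scale track should start from.
* **Final model**: the chosen architecture refit on the complete
  training set, without CV cycles.

The five GBM parameters are expressed in classic GBM terms and mapped
onto xgboost as: `nrounds = n_trees`, `eta = learning_rate`,
`subsample = bag_fraction`, `min_child_weight` directly, and
interaction depth (splits per tree) as `grow_policy = "lossguide"` with
`max_leaves = interaction_depth + 1` and unbounded depth — a tree with
*d* splits has *d* + 1 leaves, so this reproduces the intended tree
topology rather than re-interpreting depth as tree height.  Training is
single-threaded with a fixed internal seed for bit-reproducibility.

## Classification threshold and metrics

Stable G4s are positives.  `choose_threshold()` scans a candidate grid;
at each candidate *t* the ground truth is mm% ≥ *t* and the prediction
is score ≥ *t* (one single threshold on both axes), and the chosen *t*
maximises min(TPR, TNR) — pushing both rates up together — with ties
resolved to the lowest *t*.  Degenerate candidates (single-class truth)
are skipped.  The shipped default operating point when no data are
consulted is 19.1 mm%, this model family's published threshold on human
G4-seq data.  `confusion_metrics()` reports TPR, TNR, FPR and FDR in
percent, returning `NA` with a warning (never silent NaN) when a
denominator is empty.

## Feature importance and directionality

Importance comes from the ensemble's split statistics (gain: squared
improvement summed over splits using the feature), normalised so the top
feature is 1 and unused features are 0.  The directionality mark is a
declared crude approximation: the sign of the Spearman rank correlation
between feature and mm% on training data ("+" stabilising, "−"
destabilising), with "*" when |ρ| < 0.05 — it ignores conditional
interdependencies by construction.

## The synthetic world

The simulator exists so every stage — readers included, since it emits
real FASTA and bedGraph files — can be tested without downloads.  It
plants `n_pqs` motifs in two classes mirroring the bimodal stability
landscape of genomic PQSs: weak (minimal 3-G tracts, 5-12-nt loops;
latent mode ≈ 8 mm%) and strong (4-5-G tracts, occasionally a fifth
tract, 1-4-nt loops; mode ≈ 40 mm%).  The latent mm% is a declared
deterministic function of mean tract length, mean loop length and flank
G fraction,

$$mm = \mathrm{clip}\big(11 + 16(t-3) + 1.5(6-l) + a(mm_0)(g - g_0),\ 0, 100\big)$$

with the flank amplitude $a$ = 70 below a 20-mm% knee, decaying to 30 %
of that by 60 mm% — so part of the signal deliberately lives in flank
features, and identical motifs with different flanks show a
within-group SD that shrinks with increasing mean stability, which is
what the copy-number analysis recovers.  The mm% track gets one peak
bin per PQS (latent mean + Gaussian noise, default SD 5, clipped to
[0, 100]) over a near-zero half-normal background; with noise 0 the
mapped values equal the latent means exactly.  Clipping at 0 is a mild
nonlinearity the model must tolerate, documented rather than removed.

Determinism over realism: the background is made PQS-free by
construction (G- and C-runs of 3+ broken, junction bases forced to A/T,
and C-runs inside motif loops broken too, since those read as G-tracts
on the other strand) instead of rejection sampling, so planted
intervals are recovered exactly and every byte of the world is a
function of the seed.

What the simulator does **not** emulate: real genomes' long-range G+C
heterogeneity, repeat structure, non-canonical G4s (bulged or 2-G
tracts — out of scope for the canonical motif altogether), assay
chemistry (stalling profiles, coverage gaps, background correction),
or flank effects beyond a monotone G-content term.  Passing the
end-to-end tests therefore shows the machinery is correct and the
workflow can recover a planted sequence→stability mapping at the stated
noise; it does not certify real-genome accuracy, which depends on
refitting against real G4-seq data.

## Problem sizes and numerical choices

The reference end-to-end study (tests and `scripts/acceptance.R`) uses
5000 planted PQSs, modes 8/40, noise SD 5, a 4-point tuning grid, and
70/30 splitting — sizes chosen to exercise every stage at comfortable
desk scale.  Unit fuzzing uses 300-1000 random sequences per property.
Other numerical choices: tie-breaks are always "first/lowest wins"
(grid configs, thresholds); empty feature selections warn; malformed
track lines report their line number; `find_pqs` on an empty sequence
returns an empty table rather than erroring.

## Known limitations

* Canonical PQSs only; bulged and 2-G-tract quadruplexes are not
  scanned.
* The shipped default threshold (19.1 mm%) and architecture optimum are
  carried over from genome-scale fitting of this model family; on new
  data both should be re-derived with `grid_search()` and
  `choose_threshold()`.
* The fallback energy engine is a ranking approximation, not a
  thermodynamic model; mixing engines between training and prediction
  is not supported (the table records its provenance for this reason).
* The directionality marks are univariate and deliberately crude.
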