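#' Gradient-boosting architecture configuration
#'
#' The five tunable learning parameters of the tree-based gradient
#' boosting machine, in classic GBM parlance: number of trees, interaction
#' depth (branching points per tree), minimum child weight, learning rate
#' (shrinkage), and bag fraction (row-subsampling ratio per boosting
#' iteration).  The default is the architecture found optimal for the
#' human-genome G4-seq regression problem; desk-scale studies typically
#' use smaller, faster configurations.
#'
#' Internally the configuration maps onto xgboost as
#' \code{grow_policy = "lossguide"} with \code{max_leaves =
#' interaction_depth + 1} (a tree with d splits has d + 1 leaves),
#' unbounded depth, histogram tree method, and a fixed internal seed per
#' fit for reproducibility.
#'
#' @param n_trees Number of boosted trees (default 2500).
#' @param interaction_depth Splits per tree (default 14).
#' @param min_child_weight Minimum child weight (default 65).
#' @param learning_rate Shrinkage factor in (0, 1] (default 0.01).
#' @param bag_fraction Row-subsampling ratio in (0, 1] (default 0.6).
#' @return An object of class \code{gbm_config}.
#' @export
gbm_config <- function(n_trees = 2500L, interaction_depth = 14L,
                       min_child_weight = 65, learning_rate = 0.01,
                       bag_fraction = 0.6) {
  stopifnot(
    n_trees >= 1L, interaction_depth >= 1L, min_child_weight > 0,
    learning_rate > 0, learning_rate <= 1,
    bag_fraction > 0, bag_fraction <= 1
  )
  structure(
    list(n_trees = as.integer(n_trees),
         interaction_depth = as.integer(interaction_depth),
         min_child_weight = min_child_weight,
         learning_rate = learning_rate, bag_fraction = bag_fraction),
    class = "gbm_config"
  )
}

#' @export
print.gbm_config <- function(x, ...) {
  cat("GBM architecture: ", x$n_trees, " trees, interaction depth ",
      x$interaction_depth, ", min child weight ", x$min_child_weight,
      ", learning rate ", x$learning_rate, ", bag fraction ",
      x$bag_fraction, "\n", sep = "")
  invisible(x)
}

xgb_params <- function(config, seed) {
  list(objective = "reg:squarederror",
       eta = config$learning_rate,
       subsample = config$bag_fraction,
       min_child_weight = config$min_child_weight,
       tree_method = "hist", grow_policy = "lossguide",
       max_leaves = config$interaction_depth + 1L, max_depth = 0L,
       seed = seed %% .Machine$integer.max, nthread = 1L)
}

fit_booster <- function(x, y, config, seed) {
  d <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
  xgboost::xgb.train(xgb_params(config, seed), d,
                     nrounds = config$n_trees, verbose = 0L)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Random 70/30-style train/test partition
#'
#' @param n Number of rows to partition.
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with integer index vectors \code{train} and \code{test};
#'   disjoint and jointly exhaustive.
#' @export
split_train_test <- function(n, train_frac = 0.7, seed = 1L) {
  stopifnot(n >= 2L, train_frac > 0, train_frac < 1)
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(train_frac * n)
  list(train = sort(idx[seq_len(n_train)]),
       test = sort(idx[-seq_len(n_train)]))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Content-based canonical row order (by target, then features) so fold
# assignment -- hence CV RMSE -- does not depend on input row order.
canonical_order <- function(x, y) {
  do.call(order, c(list(y), lapply(seq_len(ncol(x)), function(j) x[, j])))
}

#' Repeated k-fold cross-validation of one GBM architecture
#'
#' Shuffles the training data once per repeat, partitions it into
#' \code{folds} equal chunks, and runs one training/internal-testing round
#' per held-out chunk (2/3 train, 1/3 internal test for the default
#' 3-fold design).  Each round contributes an RMSE of predicted versus
#' actual mm%; the architecture's performance is the arithmetic mean of
#' the \code{repeats * folds} round RMSEs.  Rows are canonically ordered
#' internally, so results depend only on the data content and the seed.
#'
#' @param x Numeric feature matrix (raw scale; each round fits its own
#'   median/SD scaler on its training fold only).
#' @param y Numeric mm% targets.
#' @param config A [gbm_config()].
#' @param repeats,folds CV design (defaults 2 and 3: six rounds).
#' @param seed Integer seed for the shuffles.
#' @return An object of class \code{g4_cv}: list with \code{rmse_rounds}
#'   (length \code{repeats * folds}), \code{mean_rmse}, \code{config},
#'   \code{repeats}, \code{folds}, \code{seed}.
#' @export
repeated_cv <- function(x, y, config = gbm_config(), repeats = 2L,
                        folds = 3L, seed = 1L) {
  stopifnot(nrow(x) == length(y), nrow(x) >= folds)
  ord <- canonical_order(x, y)
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  n <- nrow(x)
  rounds <- numeric(0)
  for (r in seq_len(repeats)) {
    perm <- with_seed(seed + r, sample.int(n))
    fold_id <- rep(seq_len(folds), length.out = n)[order(perm)]
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      sc <- fit_scaler(x[tr, , drop = FALSE])
      booster <- fit_booster(apply_scaler(sc, x[tr, , drop = FALSE]),
                             y[tr], config, seed + 1000L * r + k)
      pred <- predict(booster, apply_scaler(sc, x[!tr, , drop = FALSE]))
      rounds <- c(rounds, rmse(y[!tr], pred))
    }
  }
  structure(
    list(rmse_rounds = rounds, mean_rmse = mean(rounds), config = config,
         repeats = repeats, folds = folds, seed = seed),
    class = "g4_cv"
  )
}

#' @export
print.g4_cv <- function(x, ...) {
  cat("Repeated ", x$repeats, "x", x$folds, "-fold CV: mean RMSE ",
      format(x$mean_rmse, digits = 4), " mm% over ",
      length(x$rmse_rounds), " rounds\n", sep = "")
  invisible(x)
}

#' Grid search over GBM architectures
#'
#' Evaluates each candidate architecture with the same repeated
#' cross-validation design and seed (so every configuration sees the same
#' folds) and ranks them by mean RMSE; ties keep the earlier
#' configuration.
#'
#' @param x,y,repeats,folds,seed As in [repeated_cv()].
#' @param configs List of [gbm_config()] objects.
#' @return An object of class \code{g4_grid}: list with \code{results}
#'   (one \code{g4_cv} per config, input order), \code{table} (data frame
#'   of parameters + mean RMSE), \code{best} (index of the best config)
#'   and \code{best_config}.
#' @export
grid_search <- function(x, y, configs, repeats = 2L, folds = 3L,
                        seed = 1L) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  results <- lapply(configs, function(cf)
    repeated_cv(x, y, cf, repeats = repeats, folds = folds, seed = seed))
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(unclass(r$config), mean_rmse = r$mean_rmse)))
  rownames(tab) <- NULL
  best <- which.min(tab$mean_rmse)
  structure(
    list(results = results, table = tab, best = best,
         best_config = configs[[best]]),
    class = "g4_grid"
  )
}

#' @export
print.g4_grid <- function(x, ...) {
  cat("GBM architecture grid search (", nrow(x$table), " configurations)\n",
      sep = "")
  print(x$table[order(x$table$mean_rmse), ], row.names = FALSE, ...)
  cat("best: configuration ", x$best, "\n", sep = "")
  invisible(x)
}

#' Train the final sequence-to-mm% model
#'
#' Fits the median/SD scaler and the gradient boosted tree ensemble on the
#' complete training data (no cross-validation cycles), optionally on a
#' reduced feature subset, and stores the classification threshold used to
#' call stable G4s from predicted scores.  The default threshold of
#' 19.1 mm% is the published operating point of this model family on
#' human G4-seq data; [choose_threshold()] re-derives it from data.
#'
#' @param x Numeric feature matrix (raw scale, canonical names).
#' @param y Numeric mm% targets.
#' @param config A [gbm_config()].
#' @param features Optional ordered subset of feature names to train on
#'   (see [reduce_features()]); default all columns of `x`.
#' @param threshold Stable/non-forming mm% threshold (default 19.1).
#' @param seed Integer seed for the stochastic bagging.
#' @return An object of class \code{g4_model} with \code{print},
#'   \code{summary}, \code{predict} and \code{plot} methods.
#' @export
g4_train <- function(x, y, config = gbm_config(), features = NULL,
                     threshold = 19.1, seed = 1L) {
  stopifnot(nrow(x) == length(y), all(is.finite(y)),
            threshold >= 0, threshold <= 100)
  if (!is.null(features)) x <- reduce_features(x, features)
  scaler <- fit_scaler(x)
  booster <- fit_booster(apply_scaler(scaler, x), y, config, seed)
  fit <- structure(
    list(booster = booster, scaler = scaler, features = colnames(x),
         config = config, threshold = threshold, seed = seed,
         n_train = nrow(x)),
    class = "g4_model"
  )
  fit$train_rmse <- rmse(y, predict(fit, x))
  fit
}

#' Predict mm%-scale G4 stability scores
#'
#' @param object A fitted [g4_train()] model.
#' @param newdata Numeric feature matrix with (at least) the model's
#'   feature columns, raw scale.
#' @param ... Unused.
#' @return Numeric vector of predicted scores (mm% scale), one per row of
#'   `newdata`, in input order.
#' @export
predict.g4_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "))
  newdata <- newdata[, object$features, drop = FALSE]
  as.numeric(predict(object$booster, apply_scaler(object$scaler, newdata)))
}

#' @export
print.g4_model <- function(x, ...) {
  cat("Sequence-based G4 stability model (gradient boosted trees)\n")
  print(x$config)
  cat("  features: ", length(x$features), "; training PQSs: ", x$n_train,
      "; training RMSE: ", format(x$train_rmse, digits = 4),
      " mm%\n  stable-G4 threshold: ", x$threshold, " mm%\n", sep = "")
  invisible(x)
}

#' @method summary g4_model
#' @export
summary.g4_model <- function(object, ...) {
  print(object)
  imp <- importance_report(object)
  cat("Top 10 features by relative importance:\n")
  print(utils::head(imp, 10L), row.names = FALSE)
  invisible(imp)
}

#' Plot feature importances of a fitted model
#'
#' Horizontal bar chart of the top `n` relative feature importances.
#'
#' @param x A \code{g4_model}.
#' @param n Number of features to show (default 20).
#' @param ... Passed to [graphics::barplot()].
#' @method plot g4_model
#' @export
plot.g4_model <- function(x, n = 20L, ...) {
  imp <- importance_report(x)
  imp <- imp[seq_len(min(n, nrow(imp))), ]
  graphics::barplot(rev(imp$importance), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, cex.names = 0.6,
                    xlab = "relative importance", ...)
  invisible(imp)
}

#' Relative feature importance with crude directionality
#'
#' Importances come from the tree ensemble's split statistics (number of
#' splits on each feature weighted by the squared improvement they
#' achieve) and are normalised so the most influential feature scores 1;
#' features never used for a split score 0.  When training data are
#' supplied, each feature also gets a crude directionality mark: the sign
#' of its Spearman rank correlation with mm% ("+" stabilising, "-"
#' destabilising), or "*" when |rho| falls below `cutoff` -- a declared
#' approximation that ignores conditional interdependencies.
#'
#' @param model A fitted \code{g4_model}.
#' @param x,y Optional training features and mm% targets for the
#'   directionality marks.
#' @param cutoff Absolute Spearman correlation below which a feature is
#'   marked "*" (default 0.05).
#' @return Data frame (class \code{g4_importance}) with columns
#'   \code{feature}, \code{importance}, and \code{direction} when
#'   `x`/`y` are given, sorted by decreasing importance.
#' @export
importance_report <- function(model, x = NULL, y = NULL, cutoff = 0.05) {
  stopifnot(inherits(model, "g4_model"))
  imp <- xgboost::xgb.importance(model = model$booster)
  gain <- stats::setNames(rep(0, length(model$features)), model$features)
  gain[imp$Feature] <- imp$Gain
  gain <- gain / max(gain)
  out <- data.frame(feature = names(gain), importance = as.numeric(gain),
                    stringsAsFactors = FALSE)
  if (!is.null(x) && !is.null(y)) {
    rho <- vapply(out$feature, function(f)
      suppressWarnings(stats::cor(x[, f], y, method = "spearman")),
      numeric(1))
    out$direction <- ifelse(is.na(rho) | abs(rho) < cutoff, "*",
                            ifelse(rho > 0, "+", "-"))
  }
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  class(out) <- c("g4_importance", "data.frame")
  out
}

#' Classification metrics for stable-G4 calls
#'
#' Positives are stable G4s.  TPR = TP/(TP+FN), TNR = TN/(TN+FP),
#' FPR = FP/(FP+TN), FDR = FP/(FP+TP), all reported as percentages.
#' A metric whose denominator is empty is returned as \code{NA} with a
#' warning naming it.
#'
#' @param truth,pred Logical vectors (or 0/1) of true and predicted
#'   stable-G4 labels.
#' @return Named numeric vector \code{c(TPR, TNR, FPR, FDR)} in percent.
#' @export
confusion_metrics <- function(truth, pred) {
  truth <- as.logical(truth)
  pred <- as.logical(pred)
  stopifnot(length(truth) == length(pred), !anyNA(truth), !anyNA(pred))
  tp <- sum(truth & pred)
  fn <- sum(truth & !pred)
  tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred)
  ratio <- function(num, den, name) {
    if (den == 0L) {
      warning(name, " undefined: empty denominator")
      return(NA_real_)
    }
    100 * num / den
  }
  c(TPR = ratio(tp, tp + fn, "TPR"), TNR = ratio(tn, tn + fp, "TNR"),
    FPR = ratio(fp, fp + tn, "FPR"), FDR = ratio(fp, fp + tp, "FDR"))
}

#' Choose the stable/non-forming mm% operating threshold
#'
#' Scans candidate thresholds t; at each, ground truth is the experimental
#' mm% dichotomised at t and predictions are the scores dichotomised at
#' the same t.  The threshold maximising the worse of TPR and TNR (both
#' rates jointly pushed up) is returned; ties go to the lowest t.
#' Candidates where the ground truth is single-class are skipped; if all
#' are, an error is raised.
#'
#' @param scores Predicted mm%-scale scores.
#' @param mm Paired experimental mm% values.
#' @param candidates Numeric candidate grid (default 1 to 99 by 0.1,
#'   clipped to the observed mm% range).
#' @return The chosen threshold (scalar).
#' @export
choose_threshold <- function(scores, mm,
                             candidates = seq(1, 99, by = 0.1)) {
  stopifnot(length(scores) == length(mm), length(scores) > 0)
  candidates <- candidates[candidates > min(mm) & candidates <= max(mm)]
  best_t <- NA_real_
  best_obj <- -Inf
  for (t in candidates) {
    truth <- mm >= t
    if (all(truth) || !any(truth)) next
    m <- suppressWarnings(confusion_metrics(truth, scores >= t))
    obj <- min(m["TPR"], m["TNR"])
    if (is.finite(obj) && obj > best_obj) {
      best_obj <- obj
      best_t <- t
    }
  }
  if (!is.finite(best_obj))
    stop("no candidate threshold separates the data into two classes")
  best_t
}

# ---------------------------------------------------------------------------
# Model bundle persistence: one directory holding the library-native
# ensemble plus plain-text scaler/feature-list/config/threshold.

#' Save / load a fitted model bundle
#'
#' The bundle directory holds the tree ensemble in xgboost's native
#' serialisation plus the scaler, feature list, architecture and
#' threshold as plain-text key-value tables, so a reloaded model gives
#' bit-identical predictions.
#'
#' @param model A \code{g4_model}.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (for `g4_save`) or the reloaded \code{g4_model}.
#' @export
g4_save <- function(model, dir) {
  stopifnot(inherits(model, "g4_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "ensemble.ubj"))
  utils::write.table(
    data.frame(feature = model$scaler$features,
               center = model$scaler$center, scale = model$scaler$scale),
    file.path(dir, "scaler.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  meta <- c(unlist(unclass(model$config)), threshold = model$threshold,
            seed = model$seed, n_train = model$n_train,
            train_rmse = model$train_rmse)
  writeLines(paste(names(meta), meta, sep = "\t"),
             file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' @rdname g4_save
#' @export
g4_load <- function(dir) {
  ens <- file.path(dir, "ensemble.ubj")
  if (!file.exists(ens))
    stop("no model bundle at '", dir, "'")
  sc <- utils::read.table(file.path(dir, "scaler.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                            row.names = 1L)
  val <- function(k) as.numeric(meta[k, 1L])
  scaler <- structure(
    list(center = stats::setNames(sc$center, sc$feature),
         scale = stats::setNames(sc$scale, sc$feature),
         features = sc$feature),
    class = "g4_scaler"
  )
  structure(
    list(booster = xgboost::xgb.load(ens), scaler = scaler,
         features = sc$feature,
         config = gbm_config(val("n_trees"), val("interaction_depth"),
                             val("min_child_weight"), val("learning_rate"),
                             val("bag_fraction")),
         threshold = val("threshold"), seed = val("seed"),
         n_train = val("n_train"), train_rmse = val("train_rmse")),
    class = "g4_model"
  )
}
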