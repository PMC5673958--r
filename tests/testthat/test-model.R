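# Model-level tests share one small simulated world (600 PQSs, bimodal
# latent mm%, noise SD 5) built in helper-oracles.R.

test_that("gbm_config validates ranges and defaults to the optimum", {
  cfg <- gbm_config()
  expect_equal(cfg$n_trees, 2500L)
  expect_equal(cfg$interaction_depth, 14L)
  expect_equal(cfg$min_child_weight, 65)
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$bag_fraction, 0.6)
  expect_error(gbm_config(learning_rate = 0))
  expect_error(gbm_config(bag_fraction = 1.2))
  expect_error(gbm_config(n_trees = 0))
})

test_that("train/test split is disjoint, exhaustive and seed-reproducible", {
  sp <- split_train_test(10L, 0.7, seed = 4)
  expect_length(sp$train, 7L)
  expect_length(sp$test, 3L)
  expect_equal(sort(c(sp$train, sp$test)), 1:10)
  expect_identical(sp, split_train_test(10L, 0.7, seed = 4))
  expect_false(identical(sp, split_train_test(10L, 0.7, seed = 5)))
})

test_that("repeated 2x3 CV yields 6 rounds, their mean, and is deterministic", {
  w <- shared_world()
  sp <- split_train_test(nrow(w$ds$x), 0.7, seed = 1)
  x <- w$ds$x[sp$train, ]
  y <- w$ds$mm[sp$train]
  cfg <- gbm_config(60L, 6L, 5, 0.1, 0.8)
  cv <- repeated_cv(x, y, cfg, repeats = 2L, folds = 3L, seed = 7)
  expect_length(cv$rmse_rounds, 6L)
  expect_equal(cv$mean_rmse, mean(cv$rmse_rounds))
  # deterministic under a fixed seed
  cv2 <- repeated_cv(x, y, cfg, repeats = 2L, folds = 3L, seed = 7)
  expect_identical(cv$rmse_rounds, cv2$rmse_rounds)
  # invariant to dataset row order given the same seed
  perm <- sample(nrow(x))
  cv3 <- repeated_cv(x[perm, ], y[perm], cfg, repeats = 2L, folds = 3L,
                     seed = 7)
  expect_equal(cv$rmse_rounds, cv3$rmse_rounds)
  # a learnable target is predicted far better than its own spread
  expect_lt(cv$mean_rmse, sd(y) / 2)
  # constant target: a constant-predicting ensemble has (near) zero RMSE
  cvc <- repeated_cv(x[1:30, ], rep(5, 30), gbm_config(5L, 2L, 1, 0.5, 1),
                     seed = 1)
  expect_lt(cvc$mean_rmse, 1e-6)
})

test_that("grid search ranks architectures by mean CV RMSE with stable ties", {
  w <- shared_world()
  sp <- split_train_test(nrow(w$ds$x), 0.7, seed = 1)
  x <- w$ds$x[sp$train, ]
  y <- w$ds$mm[sp$train]
  sane <- gbm_config(60L, 6L, 5, 0.1, 0.8)
  # over-regularized: child weight larger than the data forces stumps
  crippled <- gbm_config(5L, 1L, 1e6, 0.1, 0.8)
  gs <- grid_search(x, y, list(crippled, sane), seed = 3)
  expect_equal(nrow(gs$table), 2L)
  expect_equal(gs$best, 2L)
  expect_identical(gs$best_config, sane)
  # pure function of the config list for fixed data and seed
  gs2 <- grid_search(x, y, list(crippled, sane), seed = 3)
  expect_equal(gs$table, gs2$table)
  # singleton grid returns its only member
  gs1 <- grid_search(x[1:60, ], y[1:60], list(sane), seed = 3)
  expect_equal(gs1$best, 1L)
  # tie-break: identical configs -> the earlier one wins
  gs3 <- grid_search(x[1:60, ], y[1:60], list(sane, sane), seed = 3)
  expect_equal(gs3$best, 1L)
  # results serialise to a plain table
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(gs$table, tmp, sep = "\t", row.names = FALSE)
  expect_equal(read.delim(tmp)$mean_rmse, gs$table$mean_rmse)
})

test_that("the final model learns the synthetic mm% signal", {
  w <- shared_world()
  sp <- split_train_test(nrow(w$ds$x), 0.7, seed = 1)
  fit <- g4_train(w$ds$x[sp$train, ], w$ds$mm[sp$train],
                  gbm_config(200L, 8L, 5, 0.1, 0.8), seed = 2)
  expect_s3_class(fit, "g4_model")
  pred_te <- predict(fit, w$ds$x[sp$test, ])
  expect_true(all(is.finite(pred_te)))
  expect_gt(cor(pred_te, w$ds$mm[sp$test]), 0.7)
  # training fit is at least as good as internal CV error
  cv <- repeated_cv(w$ds$x[sp$train, ], w$ds$mm[sp$train],
                    gbm_config(200L, 8L, 5, 0.1, 0.8), seed = 2)
  expect_lte(fit$train_rmse, cv$mean_rmse)
  # permuting prediction rows permutes outputs identically
  perm <- sample(length(sp$test))
  expect_equal(predict(fit, w$ds$x[sp$test, ][perm, ]), pred_te[perm])
  # stronger planted G4s score higher on average
  truth <- w$sim$truth[order(w$sim$truth$start), ]
  hits <- w$ds$hits
  key <- paste(hits$start, hits$end)
  tkey <- paste(truth$start, truth$end)
  cls <- truth$class[match(key, tkey)]
  scores <- predict(fit, w$ds$x)
  expect_gt(mean(scores[cls == "strong"]), mean(scores[cls == "weak"]) + 15)
  expect_error(predict(fit, w$ds$x[, 1:100]), "lacks feature")
})

test_that("model bundles reload to bit-identical predictions", {
  w <- shared_world()
  fit <- g4_train(w$ds$x, w$ds$mm, gbm_config(50L, 6L, 5, 0.1, 0.8),
                  seed = 5, threshold = 22)
  dir <- withr::local_tempdir()
  g4_save(fit, dir)
  fit2 <- g4_load(dir)
  expect_equal(predict(fit2, w$ds$x), predict(fit, w$ds$x))
  expect_equal(fit2$threshold, 22)
  expect_equal(fit2$config, fit$config)
  expect_error(g4_load(withr::local_tempdir()), "bundle")
})

test_that("confusion metrics implement TPR/TNR/FPR/FDR with safe degeneracy", {
  lab <- function(tp, fn, tn, fp)
    list(truth = rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fn, tn, fp)),
         pred = rep(c(TRUE, FALSE, FALSE, TRUE), c(tp, fn, tn, fp)))
  d <- lab(80, 20, 80, 20)
  expect_equal(confusion_metrics(d$truth, d$pred),
               c(TPR = 80, TNR = 80, FPR = 20, FDR = 20))
  d <- lab(10, 0, 10, 0)
  expect_equal(confusion_metrics(d$truth, d$pred),
               c(TPR = 100, TNR = 100, FPR = 0, FDR = 0))
  # FDR and FPR diverge on unbalanced data
  d <- lab(842, 158, 400, 100)
  m <- confusion_metrics(d$truth, d$pred)
  expect_equal(unname(m["FDR"]), 100 * 100 / 942, tolerance = 1e-12)
  expect_equal(unname(m["FPR"]), 20)
  # identities on fuzzed tables
  set.seed(31)
  for (i in 1:50) {
    truth <- runif(200) > runif(1, 0.2, 0.8)
    pred <- runif(200) > runif(1, 0.2, 0.8)
    if (all(truth) || !any(truth) || all(pred) || !any(pred)) next
    m <- confusion_metrics(truth, pred)
    fnr <- 100 * sum(truth & !pred) / sum(truth)
    expect_equal(unname(m["TPR"] + fnr), 100)
    expect_equal(unname(m["TNR"] + m["FPR"]), 100)
  }
  # empty class: flagged NA, not silent
  w <- capture_warnings(m <- confusion_metrics(c(TRUE, TRUE),
                                               c(TRUE, FALSE)))
  expect_true(any(grepl("TNR", w)) && any(grepl("FPR", w)))
  expect_true(is.na(m[["TNR"]]) && is.na(m[["FPR"]]))
})

test_that("threshold choice maximises min(TPR, TNR) and breaks ties low", {
  # perfectly separated bimodal toy: any inter-mode threshold works and
  # the scan returns the lowest maximiser on the grid
  mm <- c(rep(5, 50), rep(40, 50))
  scores <- mm + rnorm(100, 0, 0.01)
  t_star <- choose_threshold(scores, mm, candidates = seq(1, 50, 1))
  expect_equal(t_star, 6)
  # exhaustive oracle over the same grid
  oracle <- function(scores, mm, grid) {
    best <- -Inf
    at <- NA
    for (t in grid) {
      tr <- mm >= t
      if (all(tr) || !any(tr)) next
      tp <- sum(tr & scores >= t)
      tn <- sum(!tr & scores < t)
      obj <- min(tp / sum(tr), tn / sum(!tr))
      if (obj > best) {
        best <- obj
        at <- t
      }
    }
    at
  }
  set.seed(12)
  for (i in 1:20) {
    mm <- c(rnorm(60, 8, 4), rnorm(60, 40, 6))
    sc <- mm + rnorm(120, 0, 5)
    grid <- seq(2, 45, by = 0.5)
    expect_equal(choose_threshold(sc, mm, grid), oracle(sc, mm, grid))
  }
  expect_error(choose_threshold(c(1, 2), c(5, 5), candidates = 10),
               "threshold")
  # the shipped default operating point when no data are consulted
  expect_equal(g4_train(matrix(rnorm(40), 20, 2,
                               dimnames = list(NULL, c("a", "b"))),
                        rnorm(20),
                        gbm_config(5L, 2L, 1, 0.5, 1))$threshold, 19.1)
})

test_that("importance report normalises to 1 and marks directionality", {
  set.seed(8)
  n <- 400
  x <- cbind(up = runif(n), down = runif(n), noise = runif(n))
  y <- 10 * x[, "up"] - 8 * x[, "down"] + rnorm(n, 0, 0.1)
  fit <- g4_train(x, y, gbm_config(100L, 4L, 2, 0.2, 0.9), seed = 3)
  rep <- importance_report(fit, x, y)
  expect_equal(max(rep$importance), 1)
  expect_true(all(rep$importance >= 0 & rep$importance <= 1))
  expect_equal(rep$direction[rep$feature == "up"], "+")
  expect_equal(rep$direction[rep$feature == "down"], "-")
  expect_equal(rep$direction[rep$feature == "noise"], "*")
  # a feature the trees never split on has importance 0
  x2 <- cbind(x, flat = rep(1, n))
  fit2 <- g4_train(x2, y, gbm_config(100L, 4L, 2, 0.2, 0.9), seed = 3)
  rep2 <- importance_report(fit2)
  expect_equal(rep2$importance[rep2$feature == "flat"], 0)
})
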