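# Folds, cross-validation, K-L screening, feature-set search, ROC,
# consistency analysis.

test_that("stratified folds balance both classes to within one example", {
  y <- rep(c(1L, 0L), c(152, 1520))
  f <- stratified_folds(y, k = 5, seed = 1)
  pos_sizes <- as.integer(table(f[y == 1L]))
  expect_setequal(pos_sizes, c(31L, 30L))
  expect_equal(sort(pos_sizes, decreasing = TRUE), c(31L, 31L, 30L, 30L, 30L))
  expect_equal(as.integer(table(f[y == 0L])), rep(304L, 5))

  y2 <- rep(c(1L, 0L), c(10, 100))
  f2 <- stratified_folds(y2, k = 5, seed = 2)
  expect_equal(as.integer(table(f2[y2 == 1L])), rep(2L, 5))
  expect_equal(as.integer(table(f2[y2 == 0L])), rep(20L, 5))

  expect_identical(stratified_folds(y, 5, seed = 9),
                   stratified_folds(y, 5, seed = 9))
  expect_error(stratified_folds(rep(c(1L, 0L), c(3, 50)), k = 5),
               "at least k")
})

test_that("cross-validation separates a clean signal and conserves counts", {
  set.seed(21)
  n <- 60L
  x <- data.frame(sig = c(rnorm(n, 8), rnorm(5 * n, 0)))
  y <- rep(c(1L, 0L), c(n, 5L * n))
  folds <- stratified_folds(y, 5, seed = 3)
  cv <- cross_validate(x, y, folds, threshold = 0)
  expect_equal(cv$mean[["f"]], 1)
  # per-fold conservation: TP + FN equals the fold's positive count
  for (i in 1:5) {
    expect_equal(cv$per_fold$tp[i] + cv$per_fold$fn[i],
                 sum(y == 1L & folds == i))
    expect_equal(cv$per_fold$tn[i] + cv$per_fold$fp[i],
                 sum(y == 0L & folds == i))
  }
  # shuffled labels destroy the signal
  set.seed(4)
  ys <- sample(y)
  cvs <- suppressWarnings(
    cross_validate(x, ys, stratified_folds(ys, 5, seed = 3), threshold = 0))
  expect_lt(cvs$mean[["f"]], 0.35)
  expect_lt(cvs$mean[["f"]], cv$mean[["f"]] - 0.5)
})

test_that("K-L screening finds separating features and honors the cut", {
  set.seed(6)
  n <- 100L
  x <- data.frame(sep = c(rep(1, n), rep(0, n)) ,
                  null = rnorm(2 * n))
  y <- rep(c(1L, 0L), each = n)
  folds <- stratified_folds(y, 5, seed = 1)
  scr <- kl_screen(x, y, folds, min_kl = 0.2)
  expect_gt(scr$mean_kl[scr$feature == "sep"],
            10 * scr$mean_kl[scr$feature == "null"])
  expect_true(scr$keep[scr$feature == "sep"])
  expect_false(scr$keep[scr$feature == "null"])

  # five identical fold blocks give identical training sets, hence sd 0
  blk <- data.frame(f = rep(c(3, 3, 0, 0), 5))
  yb <- rep(c(1L, 1L, 0L, 0L), 5)
  fb <- structure(rep(1:5, each = 4), k = 5L, seed = 0L)
  scr2 <- kl_screen(blk, yb, fb, n_bins = 10)
  expect_equal(scr2$sd_kl, 0, tolerance = 1e-12)
})

test_that("feature-set enumeration spans the one-or-two-template space", {
  sets <- enumerate_feature_sets()
  expect_length(sets, 1296L)
  keys <- vapply(sets, paste, "", collapse = "+")
  expect_false(any(duplicated(keys)))
  expect_true(all(lengths(sets) >= 4L & lengths(sets) <= 8L))
  # each set takes one or two templates from every source
  for (s in sets[c(1L, 500L, 1296L)]) {
    src <- sub("\\.(Score|DiffToMax|Rank)$", "", s)
    expect_setequal(unique(src), c("PPIWeight", "RandomWalkProximity",
                                   "SemanticSim.BP", "SemanticSim.MF"))
    expect_true(all(table(src) %in% 1:2))
  }
  expect_length(enumerate_feature_sets(sources = "PPIWeight"), 6L)
})

test_that("the search ranks a perfectly separating candidate first", {
  set.seed(13)
  n <- 40L
  x <- data.frame(PPIWeight.Score = c(rnorm(n, 10), rnorm(10 * n)),
                  PPIWeight.Rank = sample(0:5, 11 * n, TRUE),
                  SemanticSim.BP.Score = rnorm(11 * n))
  y <- rep(c(1L, 0L), c(n, 10L * n))
  folds <- stratified_folds(y, 5, seed = 2)
  cands <- list("PPIWeight.Rank",
                "SemanticSim.BP.Score",
                "PPIWeight.Score",
                c("PPIWeight.Rank", "SemanticSim.BP.Score"))
  res <- suppressWarnings(
    search_best_feature_set(x, y, folds, cands, threshold = 0))
  expect_equal(res$features[1L], "PPIWeight.Score")
  expect_equal(res$mean_f[1L], 1)
  res2 <- suppressWarnings(
    search_best_feature_set(x, y, folds, cands, threshold = 0))
  expect_identical(res, res2)
  single <- suppressWarnings(
    search_best_feature_set(x, y, folds, list("PPIWeight.Rank")))
  expect_equal(nrow(single), 1L)
  expect_equal(single$features, "PPIWeight.Rank")
})

test_that("ROC pools fold counts, anchors the curve and integrates AUC", {
  scores <- c(rep(1.5, 30), rep(-0.5, 300))
  labels <- rep(c(1L, 0L), c(30, 300))
  r <- roc_curve(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(nrow(r$points), length(seq(-1, 1.95, by = 0.05)))

  # label-independent scores give a chance-level AUC
  set.seed(12)
  s <- runif(4000, -1, 1.95)
  l <- rep(c(1L, 0L), 2000)
  r0 <- roc_curve(s, l)
  expect_equal(r0$auc, 0.5, tolerance = 0.05)

  # the fixed grid approximates the all-cutpoints curve
  rall <- roc_curve(s, l, thresholds = sort(unique(s)))
  expect_equal(r0$auc, rall$auc, tolerance = 0.05)

  expect_error(roc_curve(c(1, 2), c(1L, 1L)), "both classes")
})

test_that("consistency counts tabulate per-class classifier agreement", {
  # two classifiers, four examples, hand-computed histogram
  pred <- cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 1L))
  y <- c(1L, 1L, 0L, 0L)
  cc <- consistency_counts(pred, y)
  expect_equal(unname(cc["positive", ]), c(0L, 1L, 1L))
  expect_equal(unname(cc["negative", ]), c(0L, 1L, 1L))
  expect_equal(rowSums(cc), c(positive = 2, negative = 2))

  # perfect classifiers put all mass in the last column
  pred2 <- cbind(y, y, y)
  cc2 <- consistency_counts(pred2, y)
  expect_equal(unname(cc2[, "3"]), c(2L, 2L))
  expect_true(all(cc2[, 1:3] == 0L))
})

test_that("cv_predictions applies every fold classifier to every example", {
  set.seed(30)
  n <- 40L
  x <- data.frame(sig = c(rnorm(n, 6), rnorm(5 * n)))
  y <- rep(c(1L, 0L), c(n, 5L * n))
  folds <- stratified_folds(y, 5, seed = 1)
  cv <- cross_validate(x, y, folds, threshold = 0)
  pm <- cv_predictions(cv, x)
  expect_equal(dim(pm), c(length(y), 5L))
  cc <- consistency_counts(pm, y)
  expect_equal(sum(cc), length(y))
  expect_equal(unname(rowSums(cc)), c(n, 5L * n))
})
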