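# Cross-validation, K-L screening, exhaustive feature-set search, ROC.

#' Stratified fold assignment
#'
#' Assigns examples to `k` folds separately within each class: a seeded
#' shuffle followed by round-robin assignment, so per-class fold sizes
#' differ by at most one.  With 152 positives and 1520 negatives and
#' `k = 5` this yields positive fold sizes \{31, 31, 30, 30, 30\} and 304
#' negatives in every fold.
#'
#' @param y 0/1 class labels.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return Integer vector of fold indices in `1..k`, with attributes `k`
#'   and `seed`.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.integer(y)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  classes <- unique(y)
  if (any(tabulate(factor(y)) < k)) {
    stop("every class must have at least k members")
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(classes)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(folds, k = k, seed = as.integer(seed))
}

fold_stats <- function(tp, fn, tn, fp) {
  precision <- if (tp + fp == 0L) {
    warning("fold with no predicted positives; precision reported as 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f = f)
}

#' Cross-validate the naive Bayes classifier
#'
#' For every fold the classifier is fitted on the remaining folds only
#' (binning schemes, conditionals and the default class-prior ratio all
#' come from the training portion) and evaluated on the held-out fold.
#' Per-fold confusion counts and precision/recall/F are reported, with
#' means and standard deviations across folds; every example is scored
#' exactly once, so the pooled scores support ROC analysis and the per-fold
#' classifiers support consistency analysis.
#'
#' @param x data frame of raw feature values (id/label columns dropped).
#' @param y 0/1 labels.
#' @param folds a [stratified_folds()] assignment.
#' @param features optional character vector restricting `x` to a feature
#'   subset.
#' @param class_ratio optional prior ratio override (default: per-fold
#'   training ratio).
#' @param pseudocount,threshold,n_bins passed to [dimer_nb()].
#' @return An object of class `dimer_cv`: list with `per_fold` (data
#'   frame of fold, tp, fn, tn, fp, precision, recall, f), `mean`/`sd`
#'   (named vectors over precision/recall/f), `scores` and `predicted`
#'   (aligned with the rows of `x`), `classifiers` (one [dimer_nb()] per
#'   fold), `folds`, `threshold`, `features`.
#' @export
cross_validate <- function(x, y, folds, features = NULL,
                           class_ratio = NULL, pseudocount = 1,
                           threshold = 0.6, n_bins = 10L) {
  xf <- feature_columns(as.data.frame(x))
  dom_attr <- attr(x, "domains")
  if (!is.null(features)) {
    miss <- setdiff(features, names(xf))
    if (length(miss)) {
      stop("feature(s) not in x: ", paste(miss, collapse = ", "))
    }
    xf <- xf[features]
  }
  y <- as.integer(y)
  k <- attr(folds, "k")
  stopifnot(length(y) == nrow(xf), length(folds) == nrow(xf))
  scores <- numeric(nrow(xf))
  predicted <- integer(nrow(xf))
  classifiers <- vector("list", k)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- folds != i
    te <- !tr
    xtr <- xf[tr, , drop = FALSE]
    if (!is.null(dom_attr)) attr(xtr, "domains") <- dom_attr
    clf <- dimer_nb(xtr, y[tr], class_ratio = class_ratio,
                    pseudocount = pseudocount, threshold = threshold,
                    n_bins = n_bins)
    classifiers[[i]] <- clf
    s <- normalized_llr(clf, xf[te, , drop = FALSE])
    p <- as.integer(s > threshold)
    scores[te] <- s
    predicted[te] <- p
    tp <- sum(p == 1L & y[te] == 1L)
    fn <- sum(p == 0L & y[te] == 1L)
    tn <- sum(p == 0L & y[te] == 0L)
    fp <- sum(p == 1L & y[te] == 0L)
    st <- fold_stats(tp, fn, tn, fp)
    rows[[i]] <- data.frame(fold = i, tp = tp, fn = fn, tn = tn, fp = fp,
                            precision = st[["precision"]],
                            recall = st[["recall"]], f = st[["f"]])
  }
  per_fold <- do.call(rbind, rows)
  mu <- c(precision = mean(per_fold$precision),
          recall = mean(per_fold$recall), f = mean(per_fold$f))
  sdv <- c(precision = sd(per_fold$precision),
           recall = sd(per_fold$recall), f = sd(per_fold$f))
  structure(list(per_fold = per_fold, mean = mu, sd = sdv,
                 scores = scores, predicted = predicted,
                 classifiers = classifiers, folds = folds,
                 threshold = threshold, features = names(xf)),
            class = "dimer_cv")
}

#' @export
print.dimer_cv <- function(x, ...) {
  cat("Cross-validation over ", attr(x$folds, "k"), " stratified folds (",
      length(x$features), " features)\n", sep = "")
  print(x$per_fold, row.names = FALSE)
  cat(sprintf("mean +/- sd:  precision %.3f +/- %.3f   recall %.3f +/- %.3f   F %.3f +/- %.3f\n",
              x$mean[["precision"]], x$sd[["precision"]],
              x$mean[["recall"]], x$sd[["recall"]],
              x$mean[["f"]], x$sd[["f"]]))
  invisible(x)
}

#' Symmetric K-L divergence screen over cross-validation folds
#'
#' For every feature and every fold, fits the binning scheme and the two
#' smoothed class-conditional multinomials on that fold's \emph{training}
#' portion and computes their [symmetric_kl()] divergence; reports the
#' mean and standard deviation across folds.  Features whose divergence is
#' low (the screen's customary cut is 0.2 bits) carry little class signal
#' and can be dropped before the feature-set search.
#'
#' @inheritParams cross_validate
#' @param min_kl optional cut: the returned `keep` column flags features
#'   with mean divergence strictly greater than `min_kl`.
#' @return A data frame with columns `feature`, `mean_kl`, `sd_kl` (and
#'   `keep` when `min_kl` is given), in the column order of `x`.
#' @export
kl_screen <- function(x, y, folds, pseudocount = 1, n_bins = 10L,
                      min_kl = NULL) {
  xf <- feature_columns(as.data.frame(x))
  dom <- feature_domains(names(xf))
  adom <- attr(x, "domains")
  if (!is.null(adom)) dom[names(adom)[names(adom) %in% names(dom)]] <-
      adom[names(adom) %in% names(dom)]
  y <- as.integer(y)
  k <- attr(folds, "k")
  kl <- matrix(NA_real_, nrow = ncol(xf), ncol = k,
               dimnames = list(names(xf), NULL))
  for (i in seq_len(k)) {
    tr <- folds != i
    for (f in names(xf)) {
      sc <- fit_binning(xf[[f]][tr], dom[[f]], n_bins = n_bins, name = f)
      cp <- fit_conditionals(discretize(sc, xf[[f]][tr]), y[tr],
                             n_bins = sc$n_bins, pseudocount = pseudocount)
      kl[f, i] <- symmetric_kl(cp$p_pos, cp$p_neg)
    }
  }
  out <- data.frame(feature = rownames(kl),
                    mean_kl = rowMeans(kl),
                    sd_kl = apply(kl, 1L, sd),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(min_kl)) out$keep <- out$mean_kl > min_kl
  out
}

#' Enumerate candidate feature sets
#'
#' Builds the exhaustive search space for the feature-set search: from
#' each score function's three template features (Score, DiffToMax, Rank),
#' choose either one or two -- six options per source -- and take the
#' Cartesian product over the four sources, giving \eqn{6^4 = 1296}
#' candidate sets.  Order is deterministic.
#'
#' @param sources score-function names (default: all four).
#' @param templates template names (default: Score, DiffToMax, Rank).
#' @return A list of character vectors of feature names.
#' @export
#' @examples
#' length(enumerate_feature_sets())  # 1296
enumerate_feature_sets <- function(sources = c("PPIWeight",
                                               "RandomWalkProximity",
                                               "SemanticSim.BP",
                                               "SemanticSim.MF"),
                                   templates = c("Score", "DiffToMax",
                                                 "Rank")) {
  per_source <- lapply(sources, function(src) {
    opts <- c(lapply(templates, function(t) t),
              combn(templates, 2L, simplify = FALSE))
    lapply(opts, function(t) paste(src, t, sep = "."))
  })
  idx <- expand.grid(rev(lapply(per_source, seq_along)),
                     KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(per_source)), drop = FALSE]
  lapply(seq_len(nrow(idx)), function(r) {
    unlist(lapply(seq_along(per_source), function(s) {
      per_source[[s]][[idx[r, s]]]
    }), use.names = FALSE)
  })
}

#' Exhaustive feature-set search by cross-validation
#'
#' Runs [cross_validate()] for every candidate feature set using the
#' \emph{same} fold assignment throughout (so mean F-measures are
#' comparable across candidates) and ranks candidates by mean test
#' F-measure, breaking ties by higher mean precision and then
#' lexicographically by feature names.
#'
#' @inheritParams cross_validate
#' @param candidates list of character vectors of feature names, e.g. from
#'   [enumerate_feature_sets()].
#' @param verbose print progress every 200 candidates.
#' @return A data frame ranked best-first with columns `rank`, `features`
#'   (collapsed with `"+"`), `n_features`, `mean_f`, `sd_f`,
#'   `mean_precision`, `mean_recall`; the full candidate list is attached
#'   as attribute `feature_sets` (in ranked order).
#' @export
search_best_feature_set <- function(x, y, folds, candidates,
                                    class_ratio = NULL, pseudocount = 1,
                                    threshold = 0.6, n_bins = 10L,
                                    verbose = FALSE) {
  stopifnot(length(candidates) >= 1L)
  res <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cv <- cross_validate(x, y, folds, features = candidates[[i]],
                         class_ratio = class_ratio,
                         pseudocount = pseudocount,
                         threshold = threshold, n_bins = n_bins)
    res[[i]] <- c(mean_f = cv$mean[["f"]], sd_f = cv$sd[["f"]],
                  mean_precision = cv$mean[["precision"]],
                  mean_recall = cv$mean[["recall"]])
    if (verbose && i %% 200L == 0L) {
      message("evaluated ", i, " / ", length(candidates), " feature sets")
    }
  }
  m <- do.call(rbind, res)
  key <- vapply(candidates, paste, "", collapse = "+")
  ord <- order(-m[, "mean_f"], -m[, "mean_precision"], key)
  out <- data.frame(rank = seq_along(ord),
                    features = key[ord],
                    n_features = lengths(candidates)[ord],
                    mean_f = m[ord, "mean_f"],
                    sd_f = m[ord, "sd_f"],
                    mean_precision = m[ord, "mean_precision"],
                    mean_recall = m[ord, "mean_recall"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "feature_sets") <- candidates[ord]
  out
}

#' ROC curve and AUC from pooled cross-validation scores
#'
#' Sweeps the decision threshold over a fixed grid (default -1 to 1.95 in
#' steps of 0.05, the customary range for normalized LLR scores); at each
#' threshold the confusion counts are pooled over folds (TP is the sum of
#' per-fold true positives) and the false and true positive rates
#' FP/(FP+TN) and TP/(TP+FN) are recorded.  The curve is anchored at
#' (0,0) and (1,1) and the AUC computed by the trapezoid rule over sorted
#' FPR.
#'
#' @param scores numeric classifier scores (pooled over folds).
#' @param labels 0/1 labels aligned with `scores`; both classes required.
#' @param thresholds threshold grid.
#' @return An object of class `roc_curve`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels,
                      thresholds = seq(-1, 1.95, by = 0.05)) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("ROC requires both classes")
  }
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  pts <- t(vapply(thresholds, function(th) {
    pred <- scores > th
    c(fpr = sum(pred & labels == 0L) / nn,
      tpr = sum(pred & labels == 1L) / np)
  }, c(fpr = 0, tpr = 0)))
  pts <- data.frame(threshold = thresholds, fpr = pts[, "fpr"],
                    tpr = pts[, "tpr"])
  fpr <- c(0, pts$fpr, 1)
  tpr <- c(0, pts$tpr, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve over ", nrow(x$points), " thresholds; AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  ord <- order(x$points$fpr, x$points$tpr)
  graphics::plot(c(0, x$points$fpr[ord], 1), c(0, x$points$tpr[ord], 1),
                 type = "l", xlab = "false positive rate",
                 ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Apply every fold classifier to every example
#'
#' @param cv a [cross_validate()] result.
#' @param x the feature data frame the cross-validation used (all rows).
#' @param threshold optional threshold override.
#' @return Integer matrix of predicted labels, examples x classifiers.
#' @export
cv_predictions <- function(cv, x, threshold = NULL) {
  stopifnot(inherits(cv, "dimer_cv"))
  xf <- feature_columns(as.data.frame(x))[cv$features]
  sapply(cv$classifiers, function(clf) {
    predict(clf, xf, type = "class", threshold = threshold)
  })
}

#' Consistency of per-fold classifier predictions
#'
#' Given the predictions of all `k` fold classifiers on every example,
#' tabulates per class how many of the `k` classifiers predict each
#' example correctly -- a measure of agreement between the fold models.
#' Row sums equal the class sizes.
#'
#' @param predictions integer matrix (examples x classifiers) of predicted
#'   0/1 labels, e.g. from [cv_predictions()].
#' @param y true 0/1 labels.
#' @return Integer matrix with rows `positive`, `negative` and one column
#'   per correct-count `0..k`.
#' @export
consistency_counts <- function(predictions, y) {
  predictions <- as.matrix(predictions)
  y <- as.integer(y)
  stopifnot(nrow(predictions) == length(y))
  k <- ncol(predictions)
  ncorrect <- rowSums(predictions == y)
  tab <- function(cl) {
    tabulate(ncorrect[y == cl] + 1L, nbins = k + 1L)
  }
  out <- rbind(positive = tab(1L), negative = tab(0L))
  colnames(out) <- as.character(0:k)
  out
}
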