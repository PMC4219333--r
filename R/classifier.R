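#' Fit a naive Bayes heterodimer classifier
#'
#' Trains the classifier on raw feature values of labeled example pairs.
#' Each feature is discretized by its own [fit_binning()] scheme (fitted on
#' the pooled training values of both classes), and a pair of smoothed
#' class-conditional multinomials is estimated per feature
#' ([fit_conditionals()]).  A pair with feature values
#' \eqn{x_1, \dots, x_M} is scored by the normalized log-likelihood ratio
#' \deqn{LLR = \frac{1}{M+1}\Big[\log\frac{P(C=1)}{P(C=0)} +
#'   \sum_{j=1}^{M} \log\frac{P(X_j = x_j \mid C=1)}
#'                            {P(X_j = x_j \mid C=0)}\Big]}
#' (natural logs; the division by \eqn{M+1} makes scores comparable across
#' feature sets of different sizes).  The class prior ratio
#' \eqn{P(C=1)/P(C=0)} defaults to the ratio of positive to negative
#' training examples, and a pair is predicted positive when its LLR is
#' strictly greater than `threshold` (default 0.6, chosen to keep false
#' positives low).
#'
#' @param x data frame of raw feature values, one row per example -- e.g. a
#'   [build_feature_matrix()] result (`protein1`/`protein2`/`label` columns
#'   are dropped automatically).
#' @param y 0/1 labels aligned with the rows of `x`.
#' @param class_ratio prior ratio \eqn{P(C=1)/P(C=0)}; default
#'   `sum(y == 1) / sum(y == 0)`.
#' @param pseudocount Dirichlet pseudocount per bin (default 1).
#' @param threshold decision threshold on the normalized LLR (default 0.6).
#' @param domains named character vector giving each feature's value domain
#'   (`"real"`, `"integer"`, `"categorical"`); defaults to the
#'   [feature_registry()] entry for recognized names and `"real"`
#'   otherwise, with any `domains` attribute of `x` taking precedence.
#' @param n_bins bins per feature (default 10).
#' @return An object of class `dimer_nb` with components `features`,
#'   `domains`, `bins`, `conditionals`, `class_llr`, `threshold`,
#'   `pseudocount`, `n_pos`, `n_neg`.
#' @seealso [predict.dimer_nb()], [normalized_llr()], [feature_kl()],
#'   [write_dimer_nb()]
#' @export
#' @examples
#' x <- data.frame(f = c(rnorm(20, 2), rnorm(20)))
#' y <- rep(1:0, each = 20)
#' clf <- dimer_nb(x, y)
#' clf
dimer_nb <- function(x, y, class_ratio = NULL, pseudocount = 1,
                     threshold = 0.6, domains = NULL, n_bins = 10L) {
  xf <- feature_columns(as.data.frame(x))
  if (!ncol(xf)) stop("no feature columns in x")
  y <- as.integer(y)
  stopifnot(length(y) == nrow(xf))
  if (!all(y %in% c(0L, 1L))) stop("y must be 0/1")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (!n_pos || !n_neg) stop("both classes must be present")
  dom <- feature_domains(names(xf))
  adom <- attr(x, "domains")
  if (!is.null(adom)) dom[names(adom)[names(adom) %in% names(dom)]] <-
      adom[names(adom) %in% names(dom)]
  if (!is.null(domains)) dom[names(domains)] <- domains
  if (is.null(class_ratio)) class_ratio <- n_pos / n_neg
  stopifnot(class_ratio > 0)

  bins <- vector("list", ncol(xf))
  conds <- vector("list", ncol(xf))
  names(bins) <- names(conds) <- names(xf)
  for (f in names(xf)) {
    bins[[f]] <- fit_binning(xf[[f]], dom[[f]], n_bins = n_bins, name = f)
    conds[[f]] <- fit_conditionals(discretize(bins[[f]], xf[[f]]), y,
                                   n_bins = bins[[f]]$n_bins,
                                   pseudocount = pseudocount)
  }
  structure(list(features = names(xf), domains = dom, bins = bins,
                 conditionals = conds, class_llr = log(class_ratio),
                 threshold = threshold, pseudocount = pseudocount,
                 n_pos = n_pos, n_neg = n_neg),
            class = "dimer_nb")
}

#' Normalized log-likelihood ratio of example pairs
#'
#' Computes the classifier's score for rows of raw feature values: the
#' class-prior log ratio plus the per-feature conditional log ratios,
#' divided by \eqn{M+1}.  `predict()` with `type = "score"` is equivalent.
#'
#' @param clf a fitted [dimer_nb()] classifier.
#' @param x data frame containing the classifier's feature columns (extra
#'   columns are ignored).
#' @return Numeric vector of normalized LLR scores.
#' @export
normalized_llr <- function(clf, x) {
  stopifnot(inherits(clf, "dimer_nb"))
  x <- as.data.frame(x)
  miss <- setdiff(clf$features, names(x))
  if (length(miss)) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  }
  M <- length(clf$features)
  total <- rep(clf$class_llr, nrow(x))
  for (f in clf$features) {
    b <- discretize(clf$bins[[f]], x[[f]])
    cp <- clf$conditionals[[f]]
    total <- total + log(cp$p_pos[b + 1L] / cp$p_neg[b + 1L])
  }
  total / (M + 1)
}

#' Predict method for dimer_nb classifiers
#'
#' @param object a fitted [dimer_nb()] classifier.
#' @param newdata data frame of raw feature values.
#' @param type `"score"` for the normalized LLR, `"class"` for 0/1 labels
#'   (positive iff score strictly exceeds the threshold), or `"both"` for a
#'   data frame with both.
#' @param threshold optional override of the classifier's threshold.
#' @param ... unused.
#' @return Numeric scores, integer labels, or a two-column data frame.
#' @export
predict.dimer_nb <- function(object, newdata,
                             type = c("score", "class", "both"),
                             threshold = NULL, ...) {
  type <- match.arg(type)
  s <- normalized_llr(object, newdata)
  if (type == "score") return(s)
  thr <- if (is.null(threshold)) object$threshold else threshold
  cl <- as.integer(s > thr)
  if (type == "class") cl else data.frame(score = s, class = cl)
}

#' Classify example pairs
#'
#' Convenience wrapper returning both the normalized LLR score and the
#' 0/1 decision (positive iff score strictly greater than the threshold).
#'
#' @inheritParams predict.dimer_nb
#' @param clf a fitted [dimer_nb()] classifier.
#' @param x data frame of raw feature values.
#' @return Data frame with columns `score` and `class`.
#' @export
classify <- function(clf, x, threshold = NULL) {
  predict(clf, x, type = "both", threshold = threshold)
}

#' Per-feature symmetric K-L divergence of a fitted classifier
#'
#' @param clf a fitted [dimer_nb()] classifier.
#' @return Named numeric vector: [symmetric_kl()] between each feature's
#'   positive- and negative-class conditionals.
#' @export
feature_kl <- function(clf) {
  stopifnot(inherits(clf, "dimer_nb"))
  vapply(clf$conditionals, function(cp) symmetric_kl(cp$p_pos, cp$p_neg), 0)
}

#' @export
print.dimer_nb <- function(x, ...) {
  cat("Naive Bayes heterodimer classifier\n")
  cat("  features (M = ", length(x$features), "): ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  cat("  class LLR log(P(C=1)/P(C=0)): ", format(x$class_llr, digits = 4),
      "   threshold: ", format(x$threshold), "\n", sep = "")
  cat("  trained on ", x$n_pos, " positive / ", x$n_neg,
      " negative examples\n", sep = "")
  invisible(x)
}

#' @export
summary.dimer_nb <- function(object, ...) {
  structure(list(clf = object, kl = feature_kl(object)),
            class = "summary.dimer_nb")
}

#' @export
print.summary.dimer_nb <- function(x, ...) {
  print(x$clf)
  cat("\nPer-feature symmetric K-L divergence (bits):\n")
  kl <- sort(x$kl, decreasing = TRUE)
  print(data.frame(feature = names(kl), kl = round(unname(kl), 4)),
        row.names = FALSE)
  invisible(x)
}

#' Coefficients of a dimer_nb classifier
#'
#' Returns the fitted per-bin parameters in long form: for every feature
#' and bin, the two conditional probabilities and the bin's contribution
#' `log(p_pos/p_neg)` to the (unnormalized) LLR.
#'
#' @param object a fitted [dimer_nb()] classifier.
#' @param ... unused.
#' @return A data frame with columns `feature`, `bin`, `p_pos`, `p_neg`,
#'   `llr`.
#' @export
coef.dimer_nb <- function(object, ...) {
  do.call(rbind, lapply(object$features, function(f) {
    cp <- object$conditionals[[f]]
    data.frame(feature = f, bin = seq_along(cp$p_pos) - 1L,
               p_pos = cp$p_pos, p_neg = cp$p_neg,
               llr = log(cp$p_pos / cp$p_neg),
               stringsAsFactors = FALSE)
  }))
}

#' Plot method for dimer_nb classifiers
#'
#' Bar plot of the per-feature symmetric K-L divergence between the two
#' fitted conditional distributions -- the discriminativeness screen used
#' for feature selection.
#'
#' @param x a fitted [dimer_nb()] classifier.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.dimer_nb <- function(x, ...) {
  kl <- sort(feature_kl(x), decreasing = TRUE)
  op <- graphics::par(mar = c(10, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(kl, las = 2, ylab = "symmetric K-L divergence (bits)",
                    ...)
  invisible(x)
}

#' Serialize a fitted classifier to JSON
#'
#' Writes all fitted parameters -- feature names and domains, binning
#' schemes, both conditional multinomials per feature, the class LLR,
#' pseudocount, threshold and training counts -- to a JSON file, and reads
#' them back.  Serialization is deterministic: retraining on identical
#' input and re-serializing yields an identical file.
#'
#' @param clf a fitted [dimer_nb()] classifier.
#' @param path JSON file path.
#' @return `write_dimer_nb()` returns `path` invisibly; `read_dimer_nb()`
#'   returns the reconstructed `dimer_nb` object.
#' @export
write_dimer_nb <- function(clf, path) {
  stopifnot(inherits(clf, "dimer_nb"))
  obj <- list(
    features = clf$features,
    domains = as.list(clf$domains),
    bins = lapply(clf$bins, unclass),
    conditionals = lapply(clf$conditionals, function(cp) {
      list(p_pos = cp$p_pos, p_neg = cp$p_neg,
           pseudocount = cp$pseudocount)
    }),
    class_llr = clf$class_llr,
    threshold = clf$threshold,
    pseudocount = clf$pseudocount,
    n_pos = clf$n_pos, n_neg = clf$n_neg)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_dimer_nb
#' @export
read_dimer_nb <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bins <- lapply(obj$bins, function(b) {
    b$n_bins <- as.integer(b$n_bins)
    structure(b, class = "binning_scheme")
  })
  conds <- lapply(obj$conditionals, function(cp) {
    structure(list(p_pos = as.numeric(cp$p_pos),
                   p_neg = as.numeric(cp$p_neg),
                   pseudocount = cp$pseudocount),
              class = "conditional_pair")
  })
  structure(list(features = obj$features,
                 domains = unlist(obj$domains),
                 bins = bins[obj$features],
                 conditionals = conds[obj$features],
                 class_llr = obj$class_llr,
                 threshold = obj$threshold,
                 pseudocount = obj$pseudocount,
                 n_pos = obj$n_pos, n_neg = obj$n_neg),
            class = "dimer_nb")
}
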