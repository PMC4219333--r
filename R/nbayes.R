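# Discretization and multinomial machinery of the naive Bayes classifier.
#
# Real-valued features are cut into 10 equal-width bins over [min, max] of
# the training values (positives and negatives pooled); integer count
# features get bins for 0..8 plus one covering ">= 9"; the ternary
# Localization feature keeps its own three categories.  Bin indices are
# 0-based.  Conditional distributions are multinomials smoothed with a
# Dirichlet pseudocount so no bin has probability zero.

#' Fit a discretization scheme for one feature
#'
#' @param values numeric training values of the feature (positive and
#'   negative examples pooled).
#' @param domain `"real"` (10 equal-width bins over the training range),
#'   `"integer"` (bins for counts 0..8 plus one for 9 and more) or
#'   `"categorical"` (one bin per value in \{-1, 0, 1\}).
#' @param n_bins number of bins for the equal-width mode (default 10).
#' @param name optional feature name, used in error messages.
#' @return An object of class `binning_scheme`.
#' @seealso [discretize()]
#' @export
#' @examples
#' sc <- fit_binning(c(0, 2.5, 10), "real")
#' discretize(sc, c(0, 4.99, 10))  # bins 0, 4, 9
fit_binning <- function(values, domain = c("real", "integer", "categorical"),
                        n_bins = 10L, name = NULL) {
  domain <- match.arg(domain)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  scheme <- switch(
    domain,
    real = {
      stopifnot(is.numeric(values), length(values) >= 2L)
      lo <- min(values); hi <- max(values)
      if (lo == hi) {
        stop("feature ", if (is.null(name)) "" else paste0("'", name, "' "),
             "is constant on the training data; equal-width binning ",
             "is undefined")
      }
      list(mode = "equal_width", n_bins = n_bins, lo = lo, hi = hi)
    },
    integer = list(mode = "integer_capped", n_bins = n_bins),
    categorical = list(mode = "categorical", n_bins = 3L,
                       categories = c(-1, 0, 1)))
  structure(scheme, class = "binning_scheme")
}

#' Map feature values to bin indices
#'
#' Bins are 0-based.  Equal-width intervals are left-closed/right-open with
#' the last bin closed (the training maximum falls in the last bin);
#' values outside the fitted range clamp to the edge bins, so discretization
#' is total and monotone on test data.  In the integer mode a count of 9 or
#' more falls in the last bin.
#'
#' @param scheme a [fit_binning()] result.
#' @param x numeric vector of raw feature values.
#' @return Integer vector of bin indices in `0 .. n_bins - 1`.
#' @export
discretize <- function(scheme, x) {
  stopifnot(inherits(scheme, "binning_scheme"))
  switch(
    scheme$mode,
    equal_width = {
      w <- (scheme$hi - scheme$lo) / scheme$n_bins
      b <- floor((x - scheme$lo) / w)
      as.integer(pmin(pmax(b, 0), scheme$n_bins - 1L))
    },
    integer_capped = {
      as.integer(pmin(pmax(round(x), 0), scheme$n_bins - 1L))
    },
    categorical = {
      b <- match(x, scheme$categories)
      if (anyNA(b)) {
        stop("value outside categorical bins: ", x[which(is.na(b))[1L]])
      }
      as.integer(b - 1L)
    })
}

#' Fit the class-conditional multinomials of one feature
#'
#' Maximum-likelihood multinomial estimates with a Dirichlet pseudocount
#' added to every bin:
#' \eqn{P(\mathrm{bin}=i \mid C=c) = (n_{c,i} + s) / (n_c + B s)} for
#' pseudocount \eqn{s} and \eqn{B} bins, so every bin has strictly positive
#' probability.
#'
#' @param binned 0-based bin indices of the training examples
#'   ([discretize()] output).
#' @param labels 0/1 class labels aligned with `binned`; both classes must
#'   be present.
#' @param n_bins number of bins of the scheme.
#' @param pseudocount Dirichlet pseudocount per bin (default 1).
#' @return An object of class `conditional_pair`: list with `p_pos`,
#'   `p_neg` (numeric vectors of length `n_bins`, each summing to 1) and
#'   `pseudocount`.
#' @export
fit_conditionals <- function(binned, labels, n_bins, pseudocount = 1) {
  stopifnot(length(binned) == length(labels), pseudocount > 0)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("both classes must be present to fit conditionals")
  }
  n_bins <- as.integer(n_bins)
  est <- function(b) {
    counts <- tabulate(b + 1L, nbins = n_bins)
    (counts + pseudocount) / (length(b) + n_bins * pseudocount)
  }
  structure(list(p_pos = est(binned[labels == 1L]),
                 p_neg = est(binned[labels == 0L]),
                 pseudocount = pseudocount),
            class = "conditional_pair")
}

#' Symmetric Kullback-Leibler divergence
#'
#' \eqn{KL_{sym}(P \| Q) = \frac{1}{2}\,(KL(P\|Q) + KL(Q\|P))} with
#' \eqn{KL(P\|Q) = \sum_i P(i) \log_2 (P(i)/Q(i))} (base-2 logs).  Applied
#' to the two fitted class-conditional distributions of a feature it
#' measures how discriminative the feature is; pseudocount smoothing
#' guarantees the strictly positive entries the divergence requires.
#'
#' @param p,q multinomial probability vectors on the same support, all
#'   entries strictly positive.
#' @return A non-negative number.
#' @export
#' @examples
#' symmetric_kl(c(.5, .5), c(.25, .75))  # ~0.19812
symmetric_kl <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p <= 0) || any(q <= 0)) {
    stop("symmetric_kl requires strictly positive entries ",
         "(use pseudocount smoothing)")
  }
  kl <- function(a, b) sum(a * log2(a / b))
  (kl(p, q) + kl(q, p)) / 2
}
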