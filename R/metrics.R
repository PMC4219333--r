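# Overlap-ratio matching between predicted clusters and known complexes.

#' Overlap ratio of two protein sets
#'
#' \eqn{ov(s,t) = |s \cap t| / \sqrt{|s| \cdot |t|}} when the sets share at
#' least two proteins, and 0 otherwise.  The ratio is 1 for identical sets.
#' Defining a single shared protein as no overlap prevents randomly
#' generated size-2 clusters from matching known dimers by chance at the
#' customary threshold \eqn{\eta = \sqrt{0.2} \approx 0.4472}.
#'
#' @param s,t character vectors of protein ids, each with at least two
#'   distinct members.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' overlap_ratio(c("a", "b"), c("a", "b", "c"))  # 2/sqrt(6)
#' overlap_ratio(c("a", "b"), c("a", "c"))       # 0
overlap_ratio <- function(s, t) {
  s <- unique(as.character(s)); t <- unique(as.character(t))
  if (length(s) < 2L || length(t) < 2L) {
    stop("overlap_ratio requires sets of size >= 2")
  }
  k <- length(intersect(s, t))
  if (k < 2L) return(0)
  k / sqrt(length(s) * length(t))
}

#' Matching criteria for cluster evaluation
#'
#' The `exact` criterion restricts both predictions and catalog to size-2
#' sets and demands identity (\eqn{\eta = 1}); the `approximate` criterion
#' uses \eqn{\eta = \sqrt{0.2}} (stored at full precision; 0.4472 is a
#' display rounding) and compares size-2 predictions against complexes of
#' any size for precision, and clusters of any size against known dimers
#' for recall.
#'
#' @param mode `"approximate"` or `"exact"`.
#' @param eta optional threshold override.
#' @return A list with elements `mode` and `eta`.
#' @export
match_criterion <- function(mode = c("approximate", "exact"), eta = NULL) {
  mode <- match.arg(mode)
  if (is.null(eta)) eta <- if (mode == "exact") 1 else sqrt(0.2)
  stopifnot(eta > 0, eta <= 1)
  list(mode = mode, eta = eta)
}

# number of sets in A matched (ov >= eta) by at least one set in B
n_matched <- function(A, B, eta) {
  if (!length(A) || !length(B)) return(0L)
  sum(vapply(A, function(a) {
    for (b in B) if (overlap_ratio(a, b) >= eta) return(TRUE)
    FALSE
  }, TRUE))
}

#' Overlap-ratio matching metrics
#'
#' Scores a set of predicted clusters `C` against a catalog of known
#' complexes `K`.  \eqn{N_{pc}} counts predicted clusters matched with at
#' least one known complex and \eqn{N_{kc}} known complexes matched with
#' at least one predicted cluster; precision is \eqn{N_{pc}} over the
#' number of (evaluated) predictions, recall \eqn{N_{kc}} over the number
#' of (evaluated) complexes, and F their harmonic mean.
#'
#' Under the `exact` criterion both sides are restricted to their size-2
#' subsets (\eqn{C|_2}, \eqn{K|_2}) and \eqn{\eta = 1}.  Under the
#' `approximate` criterion (\eqn{\eta = \sqrt{0.2}}) precision evaluates
#' \eqn{C|_2} against the full catalog `K` (a size-2 prediction can match
#' a known complex of up to 10 members) while recall evaluates known
#' dimers \eqn{K|_2} against all predictions `C`.
#'
#' @param clusters list of character vectors (predicted clusters), or a
#'   two-column data frame of predicted pairs; all members size >= 2.
#' @param complexes a [complex_catalog()] or list of character vectors.
#' @param criterion a [match_criterion()], or one of `"approximate"` /
#'   `"exact"`.
#' @return A list with `n_pc`, `n_kc`, `precision`, `recall`, `f`, `eta`,
#'   `mode`, `n_clusters_eval`, `n_complexes_eval`.
#' @export
#' @examples
#' matching_metrics(list(c("a", "b")),
#'                  list(k1 = c("a", "b", "c")), "approximate")
matching_metrics <- function(clusters, complexes,
                             criterion = c("approximate", "exact")) {
  if (is.character(criterion)) criterion <- match_criterion(criterion)
  if (is.data.frame(clusters)) {
    clusters <- lapply(seq_len(nrow(clusters)), function(i) {
      c(as.character(clusters[[1L]][i]), as.character(clusters[[2L]][i]))
    })
  }
  clusters <- lapply(clusters, function(s) unique(as.character(s)))
  complexes <- lapply(complexes, function(s) unique(as.character(s)))
  if (!length(clusters)) stop("empty cluster set")
  if (!length(complexes)) stop("empty complex catalog")
  if (any(lengths(clusters) < 2L) || any(lengths(complexes) < 2L)) {
    stop("all clusters and complexes must have size >= 2")
  }
  eta <- criterion$eta
  C2 <- clusters[lengths(clusters) == 2L]
  K2 <- complexes[lengths(complexes) == 2L]
  if (criterion$mode == "exact") {
    n_pc <- n_matched(C2, K2, eta)
    n_kc <- n_matched(K2, C2, eta)
    nC <- length(C2); nK <- length(K2)
  } else {
    n_pc <- n_matched(C2, complexes, eta)
    n_kc <- n_matched(K2, clusters, eta)
    nC <- length(C2); nK <- length(K2)
  }
  precision <- if (nC == 0L) {
    warning("no size-2 predicted clusters; precision reported as 0")
    0
  } else n_pc / nC
  recall <- if (nK == 0L) {
    warning("no known heterodimers; recall reported as 0")
    0
  } else n_kc / nK
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(n_pc = as.integer(n_pc), n_kc = as.integer(n_kc),
       precision = precision, recall = recall, f = f,
       eta = eta, mode = criterion$mode,
       n_clusters_eval = nC, n_complexes_eval = nK)
}
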