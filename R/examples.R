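#' Build labeled positive/negative example pairs
#'
#' Derives the supervised training examples from a weighted PPI network and
#' a complex catalog.  A protein pair is a positive example when
#' (i) it is a heterodimeric complex (size-2 entry) of the catalog,
#' (ii) its member set is a proper subset of no other catalog complex's
#' member set, and (iii) it is an edge of the network -- so positives are
#' catalog dimers supported by an observed interaction and not explained by
#' a larger complex.  Negative examples are drawn uniformly without
#' replacement from the remaining network edges, excluding \emph{every}
#' edge that corresponds to a size-2 complex of the catalog (whether or not
#' that dimer passed condition (ii)).  The number of negatives is
#' `neg_ratio` times the number of positives.
#'
#' @param net a [ppi_network()].
#' @param catalog a [complex_catalog()].
#' @param neg_ratio negatives per positive (default 10).
#' @param seed integer seed for the negative sampling; stored in the result
#'   so the example set is reproducible.
#' @return An object of class `labeled_examples`: a data frame with columns
#'   `protein1`, `protein2`, `label` (1 = positive, 0 = negative), positives
#'   first, with attributes `seed`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' net <- ppi_network(data.frame(a = c("a", "a", "b", "c"),
#'                               b = c("b", "c", "c", "d"),
#'                               w = c(5, 1, 1, 1)))
#' cat <- complex_catalog(list(d1 = c("a", "b")))
#' ex <- build_labeled_examples(net, cat, neg_ratio = 2, seed = 1)
#' ex
build_labeled_examples <- function(net, catalog, neg_ratio = 10L, seed = 1L) {
  stopifnot(inherits(net, "ppi_network"), inherits(catalog, "complex_catalog"))
  neg_ratio <- as.integer(neg_ratio)
  if (is.na(neg_ratio) || neg_ratio < 1L) stop("neg_ratio must be >= 1")

  sizes <- lengths(catalog)
  dimer_idx <- which(sizes == 2L)
  members <- unclass(catalog)

  # condition (ii): not a proper subset of any other complex's member set
  keep <- vapply(dimer_idx, function(i) {
    d <- members[[i]]
    for (j in seq_along(members)) {
      if (j == i) next
      m <- members[[j]]
      if (length(m) > 2L && all(d %in% m)) return(FALSE)
    }
    TRUE
  }, TRUE)

  dimers_all <- members[dimer_idx]
  eligible <- dimers_all[keep]

  # condition (iii): supported by a network edge; dedup identical pairs
  pos_key <- character()
  if (length(eligible)) {
    p1 <- vapply(eligible, function(m) min(m), "")
    p2 <- vapply(eligible, function(m) max(m), "")
    k <- pair_key(p1, p2)
    is_edge <- k %in% net$key
    pos_key <- unique(k[is_edge])
  }

  # negative pool: all edges except every catalog dimer's edge
  excl <- character()
  if (length(dimers_all)) {
    excl <- pair_key(vapply(dimers_all, function(m) min(m), ""),
                     vapply(dimers_all, function(m) max(m), ""))
  }
  pool <- which(!(net$key %in% excl))

  n_pos <- length(pos_key)
  n_neg <- neg_ratio * n_pos
  if (length(pool) < n_neg) {
    stop("not enough eligible negative edges: need ", n_neg,
         ", only ", length(pool), " available (shortfall ",
         n_neg - length(pool), ")")
  }
  neg_idx <- with_seed(seed, sample(pool, n_neg))

  split_key <- function(k) {
    m <- do.call(rbind, strsplit(k, "\x1f", fixed = TRUE))
    if (is.null(m)) m <- matrix(character(), 0L, 2L)
    m
  }
  pm <- split_key(pos_key)
  out <- data.frame(
    protein1 = c(pm[, 1L], net$edges$protein1[neg_idx]),
    protein2 = c(pm[, 2L], net$edges$protein2[neg_idx]),
    label = rep(c(1L, 0L), c(n_pos, n_neg)),
    stringsAsFactors = FALSE)
  structure(out, seed = as.integer(seed), n_pos = n_pos, n_neg = n_neg,
            class = c("labeled_examples", "data.frame"))
}

#' @export
print.labeled_examples <- function(x, ...) {
  cat("Labeled example set: ", attr(x, "n_pos"), " positives, ",
      attr(x, "n_neg"), " negatives (seed ", attr(x, "seed"), ")\n",
      sep = "")
  NextMethod()
}

#' Write a labeled example set
#'
#' Writes `idA<TAB>idB<TAB>label` records plus a JSON sidecar
#' (`<path>.json`) recording the sampling seed and example counts, so the
#' set can be audited and regenerated.
#'
#' @param examples a [build_labeled_examples()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_labeled_examples <- function(examples, path) {
  stopifnot(inherits(examples, "labeled_examples"))
  utils::write.table(examples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(seed = attr(examples, "seed"),
         n_pos = attr(examples, "n_pos"),
         n_neg = attr(examples, "n_neg")),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
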