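# Pair features for heterodimer prediction.
#
# Three templates (Score, DiffToMax, Rank) applied to four pairwise score
# functions (PPIWeight, RandomWalkProximity, SemanticSim.BP,
# SemanticSim.MF) give twelve concrete features; three individual features
# (Localization, NeighboringCommonNode, NeighboringEdge) complete the
# catalog of fifteen.

#' The feature catalog
#'
#' Declares the fifteen concrete pair features: the three templates applied
#' to each of the four score functions, plus the three individual features.
#' The `domain` column drives discretization in the classifier: `real`
#' features get 10 equal-width bins fitted on training values, `integer`
#' features get bins for counts 0..8 plus one for ">= 9", and the
#' `categorical` Localization feature keeps its three values \{-1, 0, 1\}.
#'
#' @return A data frame with columns `name`, `kind` (template or individual
#'   feature type), `source` (score-function name, `NA` for individual
#'   features) and `domain`.
#' @export
#' @examples
#' feature_registry()
feature_registry <- function() {
  sources <- c("PPIWeight", "RandomWalkProximity",
               "SemanticSim.BP", "SemanticSim.MF")
  templates <- c("Score", "DiffToMax", "Rank")
  grid <- expand.grid(source = sources, kind = templates,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$source, sources),
                     match(grid$kind, templates)), ]
  tmpl <- data.frame(
    name = paste(grid$source, grid$kind, sep = "."),
    kind = grid$kind,
    source = grid$source,
    domain = ifelse(grid$kind == "Rank", "integer", "real"),
    stringsAsFactors = FALSE)
  indiv <- data.frame(
    name = c("Localization", "NeighboringCommonNode", "NeighboringEdge"),
    kind = c("Localization", "NeighboringCommonNode", "NeighboringEdge"),
    source = NA_character_,
    domain = c("categorical", "integer", "integer"),
    stringsAsFactors = FALSE)
  out <- rbind(tmpl, indiv)
  rownames(out) <- NULL
  out
}

# domains for a set of feature names; unknown names fall back to "real"
feature_domains <- function(names) {
  reg <- feature_registry()
  d <- reg$domain[match(names, reg$name)]
  d[is.na(d)] <- "real"
  setNames(d, names)
}

#' Create a pairwise score function
#'
#' Packages one of the four score sources as a vectorized function of a
#' protein pair, for use with the feature templates:
#' \describe{
#'   \item{`PPIWeight`}{the network edge weight, 0 for absent pairs;}
#'   \item{`RandomWalkProximity`}{symmetric random-walk-with-restarts
#'     proximity (see [random_walk_proximity()]);}
#'   \item{`SemanticSim.BP` / `SemanticSim.MF`}{lookups in the
#'     corresponding precomputed [pair_score_table()] supplied via
#'     `tables` (list entries `bp` and `mf`).}
#' }
#'
#' @param source one of `"PPIWeight"`, `"RandomWalkProximity"`,
#'   `"SemanticSim.BP"`, `"SemanticSim.MF"`.
#' @param net a [ppi_network()].
#' @param tables named list of [pair_score_table()] objects (`bp`, `mf`);
#'   required for the semantic-similarity sources.
#' @param alpha,weighted passed to the random-walk proximity.
#' @return An object of class `pair_score_fn` with elements `name` and
#'   `value`, a function `(u, v) -> numeric`.
#' @export
#' @examples
#' net <- ppi_network(data.frame(a = "a", b = "b", w = 79.5))
#' m <- score_function("PPIWeight", net)
#' m$value("b", "a")  # 79.5
score_function <- function(source, net, tables = list(),
                           alpha = 0.6, weighted = TRUE) {
  stopifnot(inherits(net, "ppi_network"))
  value <- switch(
    source,
    PPIWeight = function(u, v) edge_weight(net, u, v),
    RandomWalkProximity = function(u, v) {
      random_walk_proximity(net, u, v, alpha = alpha, weighted = weighted)
    },
    SemanticSim.BP = {
      if (is.null(tables$bp)) stop("SemanticSim.BP requires tables$bp")
      function(u, v) table_score(tables$bp, u, v)
    },
    SemanticSim.MF = {
      if (is.null(tables$mf)) stop("SemanticSim.MF requires tables$mf")
      function(u, v) table_score(tables$mf, u, v)
    },
    stop("unknown score function: ", source))
  structure(list(name = source, value = value), class = "pair_score_fn")
}

# evaluate a score function m over the pair e and over edge indices idx
m_on_pair <- function(m, e) m$value(e[[1L]], e[[2L]])
m_on_edges <- function(m, net, idx) {
  if (!length(idx)) return(numeric())
  m$value(net$edges$protein1[idx], net$edges$protein2[idx])
}

#' Feature templates
#'
#' The three templates turn a pairwise score function \eqn{m} into a
#' concrete classifier feature for a pair \eqn{e = \{u, v\}}:
#' \describe{
#'   \item{Score}{just \eqn{m(e)};}
#'   \item{DiffToMax}{\eqn{m(e) - \max_{e' \in N_e} m(e')}, the margin of
#'     the pair's score over its best adjacent edge.  When \eqn{N_e} is
#'     empty the maximum over the empty set is taken as 0, so the feature
#'     returns \eqn{m(e)}: an isolated high-scoring edge is maximal
#'     evidence for a dimer;}
#'   \item{Rank}{\eqn{|\{e' \in N_e : m(e') > m(e)\}|}, the number of
#'     adjacent edges scoring strictly higher (ties do not count).}
#' }
#' \eqn{N_e} is the adjacent-edge set of [adjacent_edges()]; `e` need not be
#' a network edge.
#'
#' @param m a [score_function()].
#' @param net a [ppi_network()].
#' @param e character vector of length 2: the protein pair.
#' @return A single numeric (Score, DiffToMax) or integer count (Rank).
#' @export
#' @examples
#' net <- ppi_network(data.frame(a = c("a", "b"), b = c("b", "c"),
#'                               w = c(30, 18)))
#' m <- score_function("PPIWeight", net)
#' score_template(m, net, c("a", "b"))        # 30
#' diff_to_max_template(m, net, c("a", "b"))  # 12
#' rank_template(m, net, c("a", "b"))         # 0
score_template <- function(m, net, e) {
  stopifnot(inherits(m, "pair_score_fn"), length(e) == 2L)
  m_on_pair(m, as.character(e))
}

#' @rdname score_template
#' @export
diff_to_max_template <- function(m, net, e) {
  stopifnot(inherits(m, "pair_score_fn"), length(e) == 2L)
  e <- as.character(e)
  check_nodes(net, e)
  idx <- adjacent_edge_idx(net, e[1L], e[2L])
  me <- m_on_pair(m, e)
  if (!length(idx)) return(me)
  me - max(m_on_edges(m, net, idx))
}

#' @rdname score_template
#' @export
rank_template <- function(m, net, e) {
  stopifnot(inherits(m, "pair_score_fn"), length(e) == 2L)
  e <- as.character(e)
  check_nodes(net, e)
  idx <- adjacent_edge_idx(net, e[1L], e[2L])
  if (!length(idx)) return(0L)
  me <- m_on_pair(m, e)
  sum(m_on_edges(m, net, idx) > me)
}

#' Individual pair features
#'
#' `localization_feature()` compares the subcellular category sets of the
#' two proteins: 1 if they share at least one category, 0 if either protein
#' has no categories at all, and -1 if both are annotated but share none.
#' `neighboring_common_node_feature()` is \eqn{|N_u \cap N_v|}, the number
#' of common network neighbors, and `neighboring_edge_feature()` is
#' \eqn{|N_e|}, the number of edges adjacent to the pair -- both inverse
#' indicators of the pair forming a heterodimer rather than belonging to a
#' larger complex.
#'
#' @param loc a [localization_table()].
#' @param net a [ppi_network()].
#' @param e character vector of length 2.
#' @return An integer: in \{-1, 0, 1\} for localization, a count otherwise.
#' @export
localization_feature <- function(loc, e) {
  stopifnot(length(e) == 2L)
  cu <- localization_categories(loc, e[[1L]])
  cv <- localization_categories(loc, e[[2L]])
  if (length(intersect(cu, cv))) return(1L)
  if (!length(cu) || !length(cv)) return(0L)
  -1L
}

#' @rdname localization_feature
#' @export
neighboring_common_node_feature <- function(net, e) {
  length(common_neighbors(net, e[[1L]], e[[2L]]))
}

#' @rdname localization_feature
#' @export
neighboring_edge_feature <- function(net, e) {
  stopifnot(length(e) == 2L)
  e <- as.character(e)
  check_nodes(net, e)
  length(adjacent_edge_idx(net, e[1L], e[2L]))
}

#' Evaluate pair features on a set of example pairs
#'
#' Assembles the raw (pre-discretization) feature matrix: one row per
#' example pair, one column per requested feature, computed with the
#' templates and individual features of this package.  For template
#' features the underlying score function is evaluated once on every
#' network edge and reused across pairs, so the random-walk proximity is
#' solved once for the whole network.
#'
#' @param net a [ppi_network()].
#' @param pairs a two-column data frame/matrix of protein pairs, or a
#'   [build_labeled_examples()] result (its label column is ignored).
#' @param features character vector of feature names from
#'   [feature_registry()] (default: all fifteen).
#' @param tables named list with [pair_score_table()] entries `bp` and `mf`
#'   (required when semantic-similarity features are requested).
#' @param localization a [localization_table()] (required for the
#'   Localization feature).
#' @param alpha,weighted random-walk parameters.
#' @return A data frame with columns `protein1`, `protein2` followed by one
#'   column per feature, in the order of `features`; rows in the order of
#'   `pairs`.  The feature value domains are attached as attribute
#'   `domains`.
#' @export
build_feature_matrix <- function(net, pairs,
                                 features = feature_registry()$name,
                                 tables = list(), localization = NULL,
                                 alpha = 0.6, weighted = TRUE) {
  stopifnot(inherits(net, "ppi_network"))
  reg <- feature_registry()
  unknown <- setdiff(features, reg$name)
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  defs <- reg[match(features, reg$name), ]
  if (is.data.frame(pairs)) {
    u <- as.character(pairs[[1L]]); v <- as.character(pairs[[2L]])
  } else {
    u <- as.character(pairs[, 1L]); v <- as.character(pairs[, 2L])
  }
  check_nodes(net, unique(c(u, v)))
  n <- length(u)

  need_src <- unique(stats::na.omit(defs$source))
  ms <- lapply(need_src, score_function, net = net, tables = tables,
               alpha = alpha, weighted = weighted)
  names(ms) <- need_src
  # score of every network edge, per source (shared across templates/pairs)
  edge_vals <- lapply(ms, function(m) {
    m$value(net$edges$protein1, net$edges$protein2)
  })
  # per-pair score and adjacent-edge indices, computed once
  pair_vals <- lapply(ms, function(m) m$value(u, v))
  adj <- vector("list", n)
  need_adj <- any(defs$kind %in%
                    c("DiffToMax", "Rank", "NeighboringEdge"))
  if (need_adj) {
    for (i in seq_len(n)) adj[[i]] <- adjacent_edge_idx(net, u[i], v[i])
  }
  if ("Localization" %in% defs$kind && is.null(localization)) {
    stop("the Localization feature requires a localization table")
  }

  cols <- vector("list", nrow(defs))
  for (f in seq_len(nrow(defs))) {
    kind <- defs$kind[f]
    src <- defs$source[f]
    cols[[f]] <- switch(
      kind,
      Score = pair_vals[[src]],
      DiffToMax = {
        ev <- edge_vals[[src]]; pv <- pair_vals[[src]]
        vapply(seq_len(n), function(i) {
          idx <- adj[[i]]
          if (!length(idx)) pv[i] else pv[i] - max(ev[idx])
        }, 0)
      },
      Rank = {
        ev <- edge_vals[[src]]; pv <- pair_vals[[src]]
        vapply(seq_len(n), function(i) {
          idx <- adj[[i]]
          if (!length(idx)) 0 else sum(ev[idx] > pv[i])
        }, 0)
      },
      Localization = vapply(seq_len(n), function(i) {
        as.numeric(localization_feature(localization, c(u[i], v[i])))
      }, 0),
      NeighboringCommonNode = vapply(seq_len(n), function(i) {
        length(setdiff(intersect(net$nbrs[[u[i]]], net$nbrs[[v[i]]]),
                       c(u[i], v[i])))
      }, 0),
      NeighboringEdge = vapply(seq_len(n), function(i) {
        length(adj[[i]])
      }, 0),
      stop("unhandled feature kind: ", kind))
  }
  names(cols) <- defs$name
  out <- cbind(data.frame(protein1 = u, protein2 = v,
                          stringsAsFactors = FALSE),
               as.data.frame(cols, check.names = FALSE))
  attr(out, "domains") <- setNames(defs$domain, defs$name)
  out
}

# strip id columns from a feature matrix, keep feature columns only
feature_columns <- function(x) {
  drop <- intersect(c("protein1", "protein2", "label"), names(x))
  x[setdiff(names(x), drop)]
}
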