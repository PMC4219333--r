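#' Construct a weighted PPI network
#'
#' Builds the undirected weighted graph \eqn{G=(V,E)} underlying all
#' network-based pair features.  Nodes are protein identifiers (opaque,
#' case-sensitive strings); each edge carries a positive reliability weight
#' (WI-PHI-style score).  Edge lookup is symmetric in the two proteins,
#' self-edges are not allowed, and duplicate records for the same unordered
#' pair collapse to the maximum weight (the conservative choice for a
#' reliability score).
#'
#' @param edges a data frame whose first three columns are protein A,
#'   protein B and a positive numeric weight.
#' @param drop_self if `TRUE` (default) rows with identical endpoints are
#'   silently removed; if `FALSE` such a row is an error.
#' @return An object of class `ppi_network`: a list with elements
#'   `nodes` (sorted character vector), `edges` (data frame with columns
#'   `protein1`, `protein2`, `weight`, canonically ordered so
#'   `protein1 < protein2`), and internal index structures.
#' @seealso [read_ppi_network()], [edge_weight()], [adjacent_edges()],
#'   [common_neighbors()]
#' @export
#' @examples
#' net <- ppi_network(data.frame(a = c("a", "b"), b = c("b", "c"),
#'                               w = c(5, 2)))
#' net
ppi_network <- function(edges, drop_self = TRUE) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 3L)
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  w <- as.numeric(edges[[3L]])
  if (anyNA(a) || anyNA(b)) stop("missing protein identifier in edge table")
  if (anyNA(w)) stop("non-numeric edge weight")
  self <- a == b
  if (any(self)) {
    if (!drop_self) stop("self-interaction found: ", a[which(self)[1L]])
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  if (any(w <= 0)) {
    stop("non-positive edge weight for pair ",
         a[which(w <= 0)[1L]], " -- ", b[which(w <= 0)[1L]])
  }
  p1 <- pmin(a, b)
  p2 <- pmax(a, b)
  key <- pair_key(p1, p2)
  # duplicate records collapse keeping the maximum weight
  ord <- order(key, -w)
  keep <- !duplicated(key[ord])
  idx <- ord[keep]
  idx <- idx[order(idx)]            # preserve first-appearance order
  p1 <- p1[idx]; p2 <- p2[idx]; w <- w[idx]; key <- key[idx]
  ed <- data.frame(protein1 = p1, protein2 = p2, weight = w,
                   stringsAsFactors = FALSE)
  nodes <- sort(unique(c(p1, p2)))
  ne <- nrow(ed)
  # incident edge indices and neighbor lists, keyed by node id
  ends <- c(p1, p2)
  eidx <- rep.int(seq_len(ne), 2L)
  other <- c(p2, p1)
  incident <- split(eidx, factor(ends, levels = nodes))
  nbrs <- split(other, factor(ends, levels = nodes))
  structure(list(nodes = nodes, edges = ed, key = key,
                 incident = incident, nbrs = nbrs,
                 cache = new.env(parent = emptyenv())),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("Weighted PPI network: ", length(x$nodes), " proteins, ",
      nrow(x$edges), " interactions\n", sep = "")
  if (nrow(x$edges)) {
    cat("  weight range: [", format(min(x$edges$weight)), ", ",
        format(max(x$edges$weight)), "]\n", sep = "")
  }
  invisible(x)
}

#' Network accessors
#'
#' `network_nodes()` returns the sorted protein identifiers;
#' `network_edges()` the canonical edge table (`protein1 < protein2`).
#'
#' @param net a [ppi_network()].
#' @return A character vector, or a data frame with columns `protein1`,
#'   `protein2`, `weight`.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  net$nodes
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  net$edges
}

check_nodes <- function(net, ids) {
  miss <- setdiff(ids, net$nodes)
  if (length(miss)) {
    stop("unknown protein(s): ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

# index of the edge {u, v} in net$edges, or NA if not an edge (vectorized)
edge_index <- function(net, u, v) {
  match(pair_key(u, v), net$key)
}

#' Edge weight of a protein pair
#'
#' Symmetric lookup of the interaction weight; pairs absent from the
#' network have weight 0 by definition (the convention used by the
#' `PPIWeight` score function).
#'
#' @param net a [ppi_network()].
#' @param u,v protein identifiers (vectors of equal length are accepted).
#' @return Numeric vector of weights, 0 for absent pairs.
#' @export
#' @examples
#' net <- ppi_network(data.frame(a = "a", b = "b", w = 79.5))
#' edge_weight(net, "b", "a")   # 79.5
#' edge_weight(net, "a", "zzz") # 0
edge_weight <- function(net, u, v) {
  stopifnot(inherits(net, "ppi_network"))
  i <- edge_index(net, as.character(u), as.character(v))
  w <- net$edges$weight[i]
  w[is.na(i)] <- 0
  w
}

# integer indices of edges adjacent to the unordered pair e = {u, v}:
# edges sharing exactly one endpoint with e (never e itself)
adjacent_edge_idx <- function(net, u, v) {
  iu <- net$incident[[u]]
  iv <- net$incident[[v]]
  idx <- unique(c(iu, iv))
  ei <- edge_index(net, u, v)
  if (!is.na(ei)) idx <- idx[idx != ei]
  sort(idx)
}

#' Edges adjacent to a protein pair
#'
#' Returns the neighborhood \eqn{N_e} of a pair \eqn{e=\{u,v\}}: all network
#' edges sharing exactly one endpoint with \eqn{e}.  The pair itself is never
#' included, and `e` need not be an edge of the network.  This neighborhood
#' is the set over which the DiffToMax and Rank feature templates operate.
#'
#' @param net a [ppi_network()].
#' @param u,v protein identifiers; both must be nodes of `net`.
#' @return A data frame of edges (`protein1`, `protein2`, `weight`).
#' @export
#' @examples
#' net <- ppi_network(data.frame(a = c("a", "b"), b = c("b", "c"),
#'                               w = c(1, 1)))
#' adjacent_edges(net, "a", "b")  # the single edge {b, c}
adjacent_edges <- function(net, u, v) {
  stopifnot(inherits(net, "ppi_network"), length(u) == 1L, length(v) == 1L)
  u <- as.character(u); v <- as.character(v)
  check_nodes(net, c(u, v))
  net$edges[adjacent_edge_idx(net, u, v), , drop = FALSE]
}

#' Common neighbors of a protein pair
#'
#' Nodes adjacent to both members of the pair, excluding the members
#' themselves: \eqn{N_u \cap N_v}.  Its cardinality is the
#' `NeighboringCommonNode` feature, an inverse indicator of the pair being
#' a heterodimer (shared neighbors suggest membership in a larger complex).
#'
#' @inheritParams adjacent_edges
#' @return Character vector of protein identifiers (possibly empty).
#' @export
common_neighbors <- function(net, u, v) {
  stopifnot(inherits(net, "ppi_network"), length(u) == 1L, length(v) == 1L)
  u <- as.character(u); v <- as.character(v)
  check_nodes(net, c(u, v))
  setdiff(intersect(net$nbrs[[u]], net$nbrs[[v]]), c(u, v))
}
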