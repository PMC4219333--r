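# Random walk with restarts (RWR) on the weighted PPI network.
#
# The stationary distribution x_u of a walk restarting at node u with
# probability alpha satisfies
#     x_u = (1 - alpha) A x_u + alpha b_u,
# where A is the column-normalized transition matrix of the graph and b_u
# the indicator vector of u.  Columns of A distribute a node's outgoing
# probability proportionally to edge weights (set `weighted = FALSE` for
# uniform transitions over neighbors).

# column-normalized sparse transition matrix (column u sums to 1)
rwr_transition <- function(net, weighted = TRUE) {
  nodes <- net$nodes
  n <- length(nodes)
  ai <- match(net$edges$protein1, nodes)
  bi <- match(net$edges$protein2, nodes)
  w <- if (weighted) net$edges$weight else rep(1, length(ai))
  i <- c(ai, bi)  # row: destination
  j <- c(bi, ai)  # col: source
  x <- c(w, w)
  colsum <- rep(0, n)
  cs <- tapply(x, j, sum)
  colsum[as.integer(names(cs))] <- cs
  if (any(colsum == 0)) {
    stop("isolated node in network: ", nodes[which(colsum == 0)[1L]],
         " (column normalization undefined)")
  }
  Matrix::sparseMatrix(i = i, j = j, x = x / colsum[j], dims = c(n, n))
}

#' Stationary distribution of a random walk with restarts
#'
#' Solves \eqn{x_u = (1-\alpha) A x_u + \alpha b_u} for the walk restarting
#' at node `u`, either exactly by a direct sparse linear solve
#' (`method = "direct"`) or by power iteration to tolerance `tol`
#' (`method = "power"`).  The two solvers agree to within a small multiple
#' of `tol` and are interchangeable; the direct solve is the default.
#'
#' @param net a [ppi_network()]; every node must have degree >= 1.
#' @param u source protein identifier.
#' @param alpha restart probability in (0, 1); default 0.6.
#' @param method `"direct"` (sparse LU solve) or `"power"` (iteration).
#' @param tol convergence tolerance for power iteration (default 1e-10).
#' @param max_iter iteration cap for power iteration.
#' @param weighted transitions proportional to edge weights (`TRUE`,
#'   default) or uniform over neighbors.
#' @return Named numeric vector of stationary probabilities
#'   \eqn{\pi(u \to v)} over all nodes; non-negative, summing to 1.
#' @export
#' @examples
#' net <- ppi_network(data.frame(a = "a", b = "b", w = 1))
#' rwr_stationary(net, "a")["b"]  # 2/7 for alpha = 0.6
rwr_stationary <- function(net, u, alpha = 0.6,
                           method = c("direct", "power"),
                           tol = 1e-10, max_iter = 100000L,
                           weighted = TRUE) {
  stopifnot(inherits(net, "ppi_network"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(tol > 0)) stop("tol must be > 0")
  method <- match.arg(method)
  u <- as.character(u)
  check_nodes(net, u)
  nodes <- net$nodes
  n <- length(nodes)
  A <- rwr_transition(net, weighted = weighted)
  b <- numeric(n)
  b[match(u, nodes)] <- 1
  if (method == "direct") {
    M <- Matrix::Diagonal(n) - (1 - alpha) * A
    x <- as.numeric(Matrix::solve(M, alpha * b))
  } else {
    x <- b
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      x_new <- as.numeric((1 - alpha) * (A %*% x)) + alpha * b
      if (max(abs(x_new - x)) < tol) {
        x <- x_new
        converged <- TRUE
        break
      }
      x <- x_new
    }
    if (!converged) {
      stop("power iteration did not converge within ", max_iter,
           " iterations (residual ", format(max(abs(
             as.numeric((1 - alpha) * (A %*% x)) + alpha * b - x))), ")")
    }
  }
  setNames(x, nodes)
}

# Full stationary matrix S with S[v, u] = pi(u -> v) for all sources u,
# computed once per (alpha, weighted, method) and cached on the network
# object.  Dense n x n result: intended for networks up to a few thousand
# nodes (one column per node); larger networks should use per-source
# rwr_stationary() calls.
rwr_stationary_matrix <- function(net, alpha = 0.6, weighted = TRUE) {
  key <- paste0("rwr:", format(alpha, digits = 15), ":", weighted)
  cached <- net$cache[[key]]
  if (!is.null(cached)) return(cached)
  nodes <- net$nodes
  n <- length(nodes)
  A <- rwr_transition(net, weighted = weighted)
  M <- Matrix::Diagonal(n) - (1 - alpha) * A
  S <- as.matrix(Matrix::solve(M, alpha * Matrix::Diagonal(n)))
  dimnames(S) <- list(nodes, nodes)
  net$cache[[key]] <- S
  S
}

#' Random-walk proximity of a protein pair
#'
#' The symmetric proximity
#' \eqn{(\pi(u \to v) + \pi(v \to u)) / 2}, averaging the two directed
#' stationary probabilities of random walks with restarts.  Unlike the raw
#' edge weight this score is positive for any pair connected through the
#' network, whether or not \eqn{\{u,v\}} is an edge.
#'
#' When more than one pair is requested the full stationary matrix is
#' computed once (and cached on the network); a single pair uses two direct
#' solves.
#'
#' @param net a [ppi_network()].
#' @param u,v protein identifiers (equal-length vectors accepted).
#' @inheritParams rwr_stationary
#' @return Numeric vector of proximities.
#' @export
random_walk_proximity <- function(net, u, v, alpha = 0.6,
                                  method = c("direct", "power"),
                                  tol = 1e-10, max_iter = 100000L,
                                  weighted = TRUE) {
  stopifnot(inherits(net, "ppi_network"), length(u) == length(v))
  method <- match.arg(method)
  u <- as.character(u); v <- as.character(v)
  check_nodes(net, unique(c(u, v)))
  if (length(u) == 1L && method == "power") {
    xu <- rwr_stationary(net, u, alpha, method, tol, max_iter, weighted)
    xv <- rwr_stationary(net, v, alpha, method, tol, max_iter, weighted)
    return(unname((xu[v] + xv[u]) / 2))
  }
  S <- rwr_stationary_matrix(net, alpha = alpha, weighted = weighted)
  ui <- match(u, net$nodes)
  vi <- match(v, net$nodes)
  (S[cbind(vi, ui)] + S[cbind(ui, vi)]) / 2
}
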