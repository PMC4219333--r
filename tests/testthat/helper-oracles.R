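# Small seeded graph fixtures and brute-force oracles, independent of the
# package's index structures: everything here works directly on the raw
# 3-column edge table.

rand_edges <- function(seed, n = 10, p = 0.35, wmax = 10) {
  set.seed(seed)
  pairs <- t(combn(sprintf("n%02d", seq_len(n)), 2L))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[1L] <- TRUE
  data.frame(a = pairs[keep, 1L], b = pairs[keep, 2L],
             w = round(runif(sum(keep), 0.5, wmax), 3),
             stringsAsFactors = FALSE)
}

net_from <- function(edges) ppi_network(edges)

# brute-force N_e: rows of the edge table sharing exactly one endpoint
oracle_adjacent <- function(edges, u, v) {
  shared <- (edges[[1L]] %in% c(u, v)) + (edges[[2L]] %in% c(u, v))
  edges[shared == 1L, , drop = FALSE]
}

# brute-force common neighbors from the raw edge table
oracle_common_neighbors <- function(edges, u, v) {
  nb <- function(z) {
    c(edges[[2L]][edges[[1L]] == z], edges[[1L]][edges[[2L]] == z])
  }
  setdiff(intersect(nb(u), nb(v)), c(u, v))
}

# brute-force edge-weight templates (PPIWeight score function)
oracle_weight <- function(edges, u, v) {
  hit <- (edges[[1L]] == u & edges[[2L]] == v) |
    (edges[[1L]] == v & edges[[2L]] == u)
  if (any(hit)) max(edges[[3L]][hit]) else 0
}
oracle_difftomax <- function(edges, u, v) {
  adj <- oracle_adjacent(edges, u, v)
  me <- oracle_weight(edges, u, v)
  if (!nrow(adj)) me else me - max(adj[[3L]])
}
oracle_rank <- function(edges, u, v) {
  adj <- oracle_adjacent(edges, u, v)
  if (!nrow(adj)) return(0L)
  sum(adj[[3L]] > oracle_weight(edges, u, v))
}

# dense-matrix power-iteration RWR, written from the fixed-point equation
oracle_rwr <- function(edges, u, alpha = 0.6, iters = 3000L) {
  nodes <- sort(unique(c(edges[[1L]], edges[[2L]])))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    W[edges[[1L]][r], edges[[2L]][r]] <- edges[[3L]][r]
    W[edges[[2L]][r], edges[[1L]][r]] <- edges[[3L]][r]
  }
  A <- sweep(W, 2L, colSums(W), "/")
  b <- as.numeric(nodes == u)
  x <- b
  for (i in seq_len(iters)) x <- (1 - alpha) * as.numeric(A %*% x) + alpha * b
  setNames(x, nodes)
}

# full-Bayes-rule log posterior ratio: priors and per-feature conditionals
# multiplied into joint likelihoods, normalized to posteriors, then logged
oracle_posterior_llr <- function(clf, row) {
  ratio <- exp(clf$class_llr)
  prior1 <- ratio / (1 + ratio)
  prior0 <- 1 - prior1
  lik1 <- 1
  lik0 <- 1
  for (f in clf$features) {
    b <- discretize(clf$bins[[f]], row[[f]])
    lik1 <- lik1 * clf$conditionals[[f]]$p_pos[b + 1L]
    lik0 <- lik0 * clf$conditionals[[f]]$p_neg[b + 1L]
  }
  post1 <- prior1 * lik1 / (prior1 * lik1 + prior0 * lik0)
  log(post1 / (1 - post1))
}

# hand-constructed classifier with fully specified parameters
toy_clf <- function(p_pos_list, p_neg_list, class_llr, threshold = 0.6) {
  feats <- names(p_pos_list)
  bins <- lapply(p_pos_list, function(p) {
    structure(list(mode = "integer_capped", n_bins = length(p)),
              class = "binning_scheme")
  })
  conds <- Map(function(p, q) {
    structure(list(p_pos = p, p_neg = q, pseudocount = 1),
              class = "conditional_pair")
  }, p_pos_list, p_neg_list)
  structure(list(features = feats,
                 domains = setNames(rep("integer", length(feats)), feats),
                 bins = bins, conditionals = conds,
                 class_llr = class_llr, threshold = threshold,
                 pseudocount = 1, n_pos = 1L, n_neg = 1L),
            class = "dimer_nb")
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
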