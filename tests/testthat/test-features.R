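# Feature templates, individual features and feature-matrix assembly.

# an edge of weight 30 whose strongest adjacent edge has weight 18
demo_net <- function() {
  net_from(data.frame(a = c("u", "u", "v", "v"),
                      b = c("v", "p", "q", "r"),
                      w = c(30, 18, 12, 5)))
}

test_that("templates reproduce the worked score/margin/rank example", {
  net <- demo_net()
  m <- score_function("PPIWeight", net)
  e <- c("u", "v")
  expect_equal(score_template(m, net, e), 30)
  expect_equal(diff_to_max_template(m, net, e), 12)
  expect_equal(rank_template(m, net, e), 0L)
})

test_that("rank counts strictly greater adjacent scores only", {
  net <- net_from(data.frame(a = c("u", "u", "u", "v"),
                             b = c("v", "p", "q", "r"),
                             w = c(5, 7, 5, 3)))
  m <- score_function("PPIWeight", net)
  expect_equal(rank_template(m, net, c("u", "v")), 1L)
})

test_that("an isolated edge keeps its own score under DiffToMax", {
  net <- net_from(data.frame(a = "u", b = "v", w = 7))
  m <- score_function("PPIWeight", net)
  expect_equal(diff_to_max_template(m, net, c("u", "v")), 7)
  expect_equal(rank_template(m, net, c("u", "v")), 0L)
})

test_that("localization feature distinguishes shared, missing and disjoint", {
  loc <- localization_table(list(a = "nucleus",
                                 b = c("nucleus", "cyto"),
                                 c = "mito", d = character()))
  expect_equal(localization_feature(loc, c("a", "b")), 1L)
  expect_equal(localization_feature(loc, c("d", "b")), 0L)
  expect_equal(localization_feature(loc, c("unseen", "b")), 0L)
  expect_equal(localization_feature(loc, c("a", "c")), -1L)
})

test_that("neighborhood count features match hand counts", {
  tri <- net_from(data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"),
                             w = 1))
  expect_equal(neighboring_common_node_feature(tri, c("a", "b")), 1L)
  k4p <- t(combn(c("a", "b", "c", "d"), 2))
  k4 <- net_from(data.frame(a = k4p[, 1], b = k4p[, 2], w = 1))
  expect_equal(neighboring_common_node_feature(k4, c("a", "b")), 2L)
  disj <- net_from(data.frame(a = c("a", "c"), b = c("b", "d"), w = 1))
  expect_equal(neighboring_common_node_feature(disj, c("a", "b")), 0L)
  expect_equal(neighboring_edge_feature(disj, c("a", "b")), 0L)

  path <- net_from(data.frame(a = c("a", "b"), b = c("b", "c"), w = 1))
  expect_equal(neighboring_edge_feature(path, c("a", "b")), 1L)
  star <- net_from(data.frame(a = rep("h", 5), b = paste0("x", 1:5), w = 1))
  expect_equal(neighboring_edge_feature(star, c("h", "x1")), 4L)
})

test_that("template features equal exhaustive neighborhood scans", {
  for (seed in 1:25) {
    ed <- rand_edges(seed, n = 9, p = 0.4)
    net <- net_from(ed)
    m <- score_function("PPIWeight", net)
    for (r in seq_len(min(nrow(ed), 5L))) {
      e <- c(ed[[1L]][r], ed[[2L]][r])
      expect_equal(score_template(m, net, e), oracle_weight(ed, e[1], e[2]))
      expect_equal(diff_to_max_template(m, net, e),
                   oracle_difftomax(ed, e[1], e[2]))
      expect_equal(rank_template(m, net, e),
                   oracle_rank(ed, e[1], e[2]))
      # rank 0 exactly when the pair's score matches or beats the maximum
      expect_equal(rank_template(m, net, e) == 0L,
                   diff_to_max_template(m, net, e) >= 0)
      expect_lte(rank_template(m, net, e),
                 neighboring_edge_feature(net, e))
    }
  }
})

test_that("features are invariant under protein relabeling", {
  ed <- rand_edges(3, n = 8, p = 0.45)
  net <- net_from(ed)
  ed2 <- data.frame(a = paste0("Z", ed$a), b = paste0("Z", ed$b), w = ed$w)
  net2 <- net_from(ed2)
  m1 <- score_function("PPIWeight", net)
  m2 <- score_function("PPIWeight", net2)
  for (r in seq_len(nrow(ed))) {
    e1 <- c(ed$a[r], ed$b[r])
    e2 <- paste0("Z", e1)
    expect_equal(diff_to_max_template(m1, net, e1),
                 diff_to_max_template(m2, net2, e2))
    expect_equal(rank_template(m1, net, e1), rank_template(m2, net2, e2))
    expect_equal(neighboring_common_node_feature(net, e1),
                 neighboring_common_node_feature(net2, e2))
  }
})

test_that("the feature registry declares the fifteen-feature catalog", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 15L)
  expect_equal(sum(reg$kind %in% c("Score", "DiffToMax", "Rank")), 12L)
  expect_false(any(duplicated(reg$name)))
  expect_equal(reg$domain[reg$name == "Localization"], "categorical")
  expect_equal(reg$domain[reg$name == "PPIWeight.Rank"], "integer")
})

test_that("the feature matrix composes per-operation calls elementwise", {
  b <- generate_bundle(synth_config(n_proteins = 50,
                                    n_background_edges = 100,
                                    n_planted_dimers = 5,
                                    n_decoy_complexes = 2, seed = 8))
  ed <- network_edges(b$network)
  pairs <- ed[1:6, c("protein1", "protein2")]
  feats <- c("PPIWeight.Score", "PPIWeight.DiffToMax", "SemanticSim.BP.Rank",
             "RandomWalkProximity.Score", "Localization", "NeighboringEdge")
  fm <- build_feature_matrix(b$network, pairs, features = feats,
                             tables = list(bp = b$bp_table,
                                           mf = b$mf_table),
                             localization = b$localization)
  expect_equal(names(fm), c("protein1", "protein2", feats))
  mw <- score_function("PPIWeight", b$network)
  mbp <- score_function("SemanticSim.BP", b$network,
                        tables = list(bp = b$bp_table))
  mrw <- score_function("RandomWalkProximity", b$network)
  for (i in seq_len(nrow(pairs))) {
    e <- c(pairs$protein1[i], pairs$protein2[i])
    expect_equal(fm$PPIWeight.Score[i], score_template(mw, b$network, e))
    expect_equal(fm$PPIWeight.DiffToMax[i],
                 diff_to_max_template(mw, b$network, e))
    expect_equal(fm$SemanticSim.BP.Rank[i],
                 as.numeric(rank_template(mbp, b$network, e)))
    expect_equal(fm$RandomWalkProximity.Score[i],
                 score_template(mrw, b$network, e), tolerance = 1e-9)
    expect_equal(fm$Localization[i],
                 as.numeric(localization_feature(b$localization, e)))
    expect_equal(fm$NeighboringEdge[i],
                 as.numeric(neighboring_edge_feature(b$network, e)))
  }
  expect_error(build_feature_matrix(b$network, pairs,
                                    features = "NoSuchFeature"),
               "unknown feature")
  expect_error(build_feature_matrix(b$network, pairs,
                                    features = "SemanticSim.MF.Score"),
               "tables\\$mf")
})
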