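# Seeded generator of complete synthetic input bundles: a weighted PPI
# network with planted heterodimer edges and dense decoy complexes, pair
# score tables correlated with the planted labels, a localization table,
# and a complex catalog -- everything the pipeline consumes, with known
# ground truth and no external downloads.

#' Configuration of the synthetic bundle generator
#'
#' Defaults emulate a scaled-down, reliability-weighted yeast-style
#' interactome: heavy-tailed (log-normal) edge weights in the tens, a
#' minority of planted heterodimer edges whose weights stochastically
#' dominate the background by a multiplicative shift, decoy complexes of
#' size 3-10 realized as dense, moderately heavy subgraphs (so the
#' classifier must tell isolated strong pairs from members of dense
#' complexes), pair-score tables shifted upward on planted dimers, and a
#' 22-category localization table in which planted dimer partners usually
#' share a category.
#'
#' @param n_proteins number of proteins (default 400).
#' @param n_background_edges random background interactions (default 1500).
#' @param n_planted_dimers planted heterodimer pairs, mutually disjoint
#'   (default 40).
#' @param n_decoy_complexes decoy complexes (default 15), sizes drawn from
#'   `decoy_size_range`.
#' @param decoy_size_range inclusive size range of decoys (default 3-10).
#' @param background_meanlog,background_sdlog log-normal parameters of
#'   background edge weights (default meanlog `log(15)`, sdlog 0.6).
#' @param dimer_weight_shift multiplicative weight shift of planted dimer
#'   edges over background (default 4).
#' @param decoy_weight_shift multiplicative weight shift of decoy-internal
#'   edges (default 2).
#' @param similarity_effect additive mean shift of the pair-score tables on
#'   planted dimers (default 0.35, against noise sd
#'   `similarity_noise_sd`).
#' @param similarity_noise_sd noise sd of pair scores (default 0.15).
#' @param localization_coherence probability that a planted dimer shares a
#'   localization category (default 0.9).
#' @param n_categories number of localization categories (default 22).
#' @param prop_unlocalized probability a protein carries no category
#'   (default 0.25).
#' @param seed integer seed; the whole bundle is deterministic given the
#'   configuration.
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_bundle()]
#' @export
synth_config <- function(n_proteins = 400L,
                         n_background_edges = 1500L,
                         n_planted_dimers = 40L,
                         n_decoy_complexes = 15L,
                         decoy_size_range = c(3L, 10L),
                         background_meanlog = log(15),
                         background_sdlog = 0.6,
                         dimer_weight_shift = 4,
                         decoy_weight_shift = 2,
                         similarity_effect = 0.35,
                         similarity_noise_sd = 0.15,
                         localization_coherence = 0.9,
                         n_categories = 22L,
                         prop_unlocalized = 0.25,
                         seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_background_edges = as.integer(n_background_edges),
              n_planted_dimers = as.integer(n_planted_dimers),
              n_decoy_complexes = as.integer(n_decoy_complexes),
              decoy_size_range = as.integer(decoy_size_range),
              background_meanlog = background_meanlog,
              background_sdlog = background_sdlog,
              dimer_weight_shift = dimer_weight_shift,
              decoy_weight_shift = decoy_weight_shift,
              similarity_effect = similarity_effect,
              similarity_noise_sd = similarity_noise_sd,
              localization_coherence = localization_coherence,
              n_categories = as.integer(n_categories),
              prop_unlocalized = prop_unlocalized,
              seed = as.integer(seed))
  if (cfg$n_planted_dimers * 2L > cfg$n_proteins) {
    stop("2 * n_planted_dimers exceeds n_proteins")
  }
  if (cfg$dimer_weight_shift <= 0 || cfg$decoy_weight_shift <= 0) {
    stop("weight shifts must be positive")
  }
  if (cfg$localization_coherence < 0 || cfg$localization_coherence > 1) {
    stop("localization_coherence must be in [0, 1]")
  }
  n_pairs <- cfg$n_proteins * (cfg$n_proteins - 1) / 2
  if (cfg$n_background_edges + cfg$n_planted_dimers +
      cfg$n_decoy_complexes * choose(max(cfg$decoy_size_range), 2) >
      n_pairs) {
    stop("infeasible configuration: more edges requested than protein ",
         "pairs available")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic input bundle
#'
#' Realizes a [synth_config()] into a complete, internally consistent set
#' of pipeline inputs with known ground truth:
#' \itemize{
#'   \item a [ppi_network()] containing every planted dimer edge, all
#'     within-decoy edges and the random background edges, with log-normal
#'     weights (dimer and decoy edges multiplicatively shifted upward);
#'   \item a [complex_catalog()] of the planted dimers plus the decoy
#'     complexes.  Decoy members are drawn disjointly from dimer members,
#'     so every planted dimer satisfies the proper-subset condition and
#'     [build_labeled_examples()] recovers exactly the planted dimers as
#'     positives;
#'   \item two [pair_score_table()]s (`bp`, `mf`) scoring every network
#'     edge with label-correlated noise: planted dimers are shifted upward
#'     by `similarity_effect`;
#'   \item a [localization_table()] over 22 opaque categories in which
#'     dimer partners share a category with probability
#'     `localization_coherence`;
#'   \item the ground-truth labels of every network edge.
#' }
#' The bundle is deterministic given the configuration (including its
#' seed).
#'
#' @param cfg a [synth_config()].
#' @return An object of class `synth_bundle`: list with elements
#'   `network`, `catalog`, `bp_table`, `mf_table`, `localization`,
#'   `truth` (data frame `protein1`, `protein2`, `label`) and `config`.
#' @export
#' @examples
#' b <- generate_bundle(synth_config(n_proteins = 60,
#'                                   n_background_edges = 120,
#'                                   n_planted_dimers = 6,
#'                                   n_decoy_complexes = 3, seed = 7))
#' b$network
generate_bundle <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    prot <- sprintf("P%04d", seq_len(cfg$n_proteins))

    dimer_members <- sample(prot, 2L * cfg$n_planted_dimers)
    dimers <- matrix(dimer_members, ncol = 2L)
    rest <- setdiff(prot, dimer_members)

    decoy_sizes <- sample(seq(cfg$decoy_size_range[1L],
                              cfg$decoy_size_range[2L]),
                          cfg$n_decoy_complexes, replace = TRUE)
    decoys <- lapply(decoy_sizes, function(s) sample(rest, s))

    rw <- function(n, shift = 1) {
      rlnorm(n, meanlog = cfg$background_meanlog + log(shift),
             sdlog = cfg$background_sdlog)
    }
    dimer_edges <- data.frame(
      a = pmin(dimers[, 1L], dimers[, 2L]),
      b = pmax(dimers[, 1L], dimers[, 2L]),
      w = rw(nrow(dimers), cfg$dimer_weight_shift),
      stringsAsFactors = FALSE)
    decoy_edges <- do.call(rbind, lapply(decoys, function(m) {
      p <- t(combn(sort(m), 2L))
      data.frame(a = p[, 1L], b = p[, 2L],
                 w = rw(nrow(p), cfg$decoy_weight_shift),
                 stringsAsFactors = FALSE)
    }))

    taken <- c(pair_key(dimer_edges$a, dimer_edges$b),
               pair_key(decoy_edges$a, decoy_edges$b))
    bg <- NULL
    need <- cfg$n_background_edges
    while (need > 0L) {
      i <- sample.int(cfg$n_proteins, 2L * need, replace = TRUE)
      j <- sample.int(cfg$n_proteins, 2L * need, replace = TRUE)
      ok <- i != j
      a <- pmin(prot[i[ok]], prot[j[ok]])
      b <- pmax(prot[i[ok]], prot[j[ok]])
      k <- pair_key(a, b)
      fresh <- !(k %in% taken) & !duplicated(k)
      a <- a[fresh][seq_len(min(need, sum(fresh)))]
      b <- b[fresh][seq_len(min(need, sum(fresh)))]
      if (length(a)) {
        bg <- rbind(bg, data.frame(a = a, b = b, w = rw(length(a)),
                                   stringsAsFactors = FALSE))
        taken <- c(taken, pair_key(a, b))
        need <- cfg$n_background_edges - nrow(bg)
      }
    }

    edges <- rbind(dimer_edges, decoy_edges, bg)
    net <- ppi_network(edges)

    catalog <- c(
      setNames(lapply(seq_len(nrow(dimers)),
                      function(i) sort(dimers[i, ])),
               sprintf("HD%03d", seq_len(nrow(dimers)))),
      setNames(lapply(decoys, sort),
               sprintf("CPX%03d", seq_along(decoys))))
    catalog <- complex_catalog(catalog)

    ed <- network_edges(net)
    is_dimer <- pair_key(ed$protein1, ed$protein2) %in%
      pair_key(dimer_edges$a, dimer_edges$b)
    clip01 <- function(x) pmin(pmax(x, 0), 1)
    sim_scores <- function() {
      base <- rnorm(nrow(ed), mean = 0.25, sd = cfg$similarity_noise_sd)
      clip01(base + ifelse(is_dimer, cfg$similarity_effect, 0))
    }
    bp_table <- pair_score_table(
      data.frame(ed$protein1, ed$protein2, sim_scores()))
    mf_table <- pair_score_table(
      data.frame(ed$protein1, ed$protein2, sim_scores()))

    cats <- sprintf("loc%02d", seq_len(cfg$n_categories))
    loc <- lapply(prot, function(p) {
      if (runif(1) < cfg$prop_unlocalized) return(character())
      sample(cats, 1L + rpois(1L, 0.5))
    })
    names(loc) <- prot
    for (i in seq_len(nrow(dimers))) {
      if (runif(1) < cfg$localization_coherence) {
        shared <- sample(cats, 1L)
        loc[[dimers[i, 1L]]] <- unique(c(loc[[dimers[i, 1L]]], shared))
        loc[[dimers[i, 2L]]] <- unique(c(loc[[dimers[i, 2L]]], shared))
      }
    }

    truth <- data.frame(protein1 = ed$protein1, protein2 = ed$protein2,
                        label = as.integer(is_dimer),
                        stringsAsFactors = FALSE)

    structure(list(network = net, catalog = catalog,
                   bp_table = bp_table, mf_table = mf_table,
                   localization = localization_table(loc),
                   truth = truth, config = cfg),
              class = "synth_bundle")
  })
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat("Synthetic bundle (seed ", x$config$seed, "):\n", sep = "")
  cat("  ", length(network_nodes(x$network)), " proteins, ",
      nrow(network_edges(x$network)), " edges; ",
      x$config$n_planted_dimers, " planted dimers, ",
      x$config$n_decoy_complexes, " decoy complexes\n", sep = "")
  invisible(x)
}

#' Write a synthetic bundle to a directory
#'
#' Writes `network.tsv`, `catalog.tsv`, `bp.tsv`, `mf.tsv`,
#' `localization.tsv`, `truth.tsv` in the package's TSV dialects, plus
#' `config.json` recording the full resolved configuration (including the
#' seed).  Running the generator twice with the same configuration writes
#' byte-identical files.
#'
#' @param bundle a [generate_bundle()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  ed <- network_edges(bundle$network)
  wt(data.frame(ed$protein1, ed$protein2, format(ed$weight, digits = 12,
                                                 trim = TRUE)),
     "network.tsv")
  wt(data.frame(names(bundle$catalog),
                vapply(bundle$catalog, paste, "", collapse = ",")),
     "catalog.tsv")
  tabfile <- function(tb, file) {
    k <- do.call(rbind, strsplit(names(tb$scores), "\x1f", fixed = TRUE))
    wt(data.frame(k[, 1L], k[, 2L],
                  format(unname(tb$scores), digits = 12, trim = TRUE)),
       file)
  }
  tabfile(bundle$bp_table, "bp.tsv")
  tabfile(bundle$mf_table, "mf.tsv")
  loc <- unclass(bundle$localization)
  wt(data.frame(names(loc),
                vapply(loc, paste, "", collapse = ",")),
     "localization.tsv")
  wt(bundle$truth, "truth.tsv")
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
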