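# Discretization, conditional estimation, LLR scoring, K-L divergence.

test_that("equal-width binning is left-closed with a closed last bin", {
  sc <- fit_binning(c(0, 3, 10), "real")
  expect_equal(discretize(sc, c(0, 4.99, 5, 9.999, 10)),
               c(0L, 4L, 5L, 9L, 9L))
  # midpoints of each bin land in their own bin
  mids <- (0:9) + 0.5
  expect_equal(discretize(sc, mids), 0:9)
  # out-of-range values clamp to the edge bins
  expect_equal(discretize(sc, c(-5, 99)), c(0L, 9L))
  expect_error(fit_binning(rep(4, 10), "real", name = "PPIWeight.Score"),
               "PPIWeight.Score")
})

test_that("integer binning caps counts at nine-and-more", {
  sc <- fit_binning(c(0, 1, 5), "integer")
  expect_equal(discretize(sc, c(0, 8, 9, 42)), c(0L, 8L, 9L, 9L))
})

test_that("categorical binning maps the ternary localization values", {
  sc <- fit_binning(c(-1, 0, 1), "categorical")
  expect_equal(discretize(sc, c(-1, 0, 1)), c(0L, 1L, 2L))
  expect_error(discretize(sc, 5), "categorical")
})

test_that("conditionals follow the pseudocount formula and normalize", {
  cp <- fit_conditionals(c(rep(0L, 9), 3L), rep(c(1L, 0L), c(9, 1)),
                         n_bins = 10, pseudocount = 1)
  expect_equal(cp$p_pos, c(10, rep(1, 9)) / 19)
  expect_true(all(cp$p_pos > 0) && all(cp$p_neg > 0))
  set.seed(1)
  for (i in 1:10) {
    b <- sample(0:9, 60, replace = TRUE)
    y <- rep(c(1L, 0L), 30)
    cp <- fit_conditionals(b, y, n_bins = 10, pseudocount = 0.5)
    expect_equal(sum(cp$p_pos), 1, tolerance = 1e-12)
    expect_equal(sum(cp$p_neg), 1, tolerance = 1e-12)
  }
  expect_error(fit_conditionals(c(0L, 1L), c(1L, 1L), n_bins = 10),
               "both classes")
})

test_that("no training value is clamped by its own fitted scheme", {
  set.seed(42)
  for (i in 1:10) {
    v <- rnorm(50)
    sc <- fit_binning(v, "real")
    b <- discretize(sc, v)
    expect_true(all(b >= 0L & b <= 9L))
    expect_equal(b[which.min(v)], 0L)
    expect_equal(b[which.max(v)], 9L)
  }
})

test_that("symmetric K-L divergence is non-negative, symmetric and exact", {
  p <- c(.5, .5); q <- c(.25, .75)
  expect_equal(symmetric_kl(p, p), 0)
  expect_equal(symmetric_kl(p, q), 0.19812031, tolerance = 1e-7)
  set.seed(7)
  for (i in 1:20) {
    a <- runif(6); a <- a / sum(a)
    b <- runif(6); b <- b / sum(b)
    expect_equal(symmetric_kl(a, b), symmetric_kl(b, a))
    expect_gte(symmetric_kl(a, b), 0)
  }
  expect_error(symmetric_kl(c(0, 1), c(.5, .5)), "positive")
})

test_that("the class-prior LLR is the natural log of the example ratio", {
  x <- data.frame(f = c(rnorm(10, 3), rnorm(100)))
  y <- rep(c(1L, 0L), c(10, 100))
  clf <- dimer_nb(x, y)
  expect_equal(clf$class_llr, log(1 / 10))
  expect_equal(round(clf$class_llr, 2), -2.30)
  clf1 <- dimer_nb(x, y, class_ratio = 1)
  expect_equal(clf1$class_llr, 0)
  # retraining on identical input is identical
  expect_identical(dimer_nb(x, y), clf)
})

test_that("normalized LLR matches hand arithmetic and the zero-evidence case", {
  clf <- toy_clf(p_pos_list = list(f = c(0.8, 0.2)),
                 p_neg_list = list(f = c(0.2, 0.8)),
                 class_llr = log(1 / 10))
  s <- normalized_llr(clf, data.frame(f = 0))
  expect_equal(s, (log(0.1) + log(4)) / 2)
  expect_equal(s, -0.4581454, tolerance = 1e-6)

  # identical conditionals contribute nothing beyond the M+1 divisor
  clf0 <- toy_clf(p_pos_list = list(f = c(.3, .7), g = c(.6, .4)),
                  p_neg_list = list(f = c(.3, .7), g = c(.6, .4)),
                  class_llr = log(2))
  expect_equal(normalized_llr(clf0, data.frame(f = 1, g = 0)), log(2) / 3)

  # appending a no-evidence feature only rescales by the divisor
  clf2 <- toy_clf(p_pos_list = list(f = c(0.8, 0.2), g = c(.5, .5)),
                  p_neg_list = list(f = c(0.2, 0.8), g = c(.5, .5)),
                  class_llr = log(1 / 10))
  expect_equal(normalized_llr(clf2, data.frame(f = 0, g = 1)) * 3,
               normalized_llr(clf, data.frame(f = 0)) * 2)
  expect_error(normalized_llr(clf, data.frame(wrong = 1)), "missing feature")
})

test_that("classification is strict at the threshold", {
  clf <- toy_clf(p_pos_list = list(f = c(0.8, 0.2)),
                 p_neg_list = list(f = c(0.2, 0.8)),
                 class_llr = 0)
  s <- normalized_llr(clf, data.frame(f = 0))
  expect_equal(predict(clf, data.frame(f = 0), type = "class",
                       threshold = s), 0L)
  expect_equal(predict(clf, data.frame(f = 0), type = "class",
                       threshold = s - 1e-12), 1L)
  expect_equal(predict(clf, data.frame(f = 0), type = "class",
                       threshold = -Inf), 1L)
  both <- classify(clf, data.frame(f = c(0, 1)))
  expect_named(both, c("score", "class"))
})

test_that("normalized LLR agrees with full-Bayes posterior enumeration", {
  set.seed(11)
  for (i in 1:30) {
    n <- 40L
    x <- data.frame(f1 = sample(0:2, n, TRUE), f2 = sample(0:2, n, TRUE),
                    f3 = sample(0:2, n, TRUE))
    y <- sample(c(0L, 1L), n, TRUE, prob = c(.7, .3))
    if (!any(y == 1L) || !any(y == 0L)) next
    clf <- dimer_nb(x, y, domains = c(f1 = "integer", f2 = "integer",
                                      f3 = "integer"))
    for (r in sample(n, 5L)) {
      expect_equal(4 * normalized_llr(clf, x[r, ]),
                   oracle_posterior_llr(clf, x[r, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("classifier JSON serialization round-trips predictions", {
  set.seed(3)
  x <- data.frame(a = rnorm(60), b = sample(0:5, 60, TRUE))
  y <- rep(c(1L, 0L), 30)
  clf <- dimer_nb(x, y, domains = c(a = "real", b = "integer"),
                  threshold = 0.25)
  path <- tempfile(fileext = ".json")
  write_dimer_nb(clf, path)
  back <- read_dimer_nb(path)
  expect_equal(back$class_llr, clf$class_llr)
  expect_equal(back$threshold, 0.25)
  xt <- data.frame(a = rnorm(20), b = sample(0:9, 20, TRUE))
  expect_equal(normalized_llr(back, xt), normalized_llr(clf, xt))
  # serialization itself is deterministic
  path2 <- tempfile(fileext = ".json")
  write_dimer_nb(clf, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("summary, coef and feature_kl expose the fitted parameters", {
  set.seed(5)
  x <- data.frame(good = c(rnorm(30, 4), rnorm(30)), noise = rnorm(60))
  y <- rep(c(1L, 0L), each = 30)
  clf <- dimer_nb(x, y)
  kl <- feature_kl(clf)
  expect_gt(kl[["good"]], kl[["noise"]])
  cf <- coef(clf)
  expect_equal(nrow(cf), 20L)
  expect_equal(cf$llr, log(cf$p_pos / cf$p_neg))
  expect_output(print(summary(clf)), "K-L divergence")
})
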