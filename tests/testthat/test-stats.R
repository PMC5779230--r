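# The statistics harness: routing logic, exactness, calibration.

test_that("identical samples give t = 0, p = 1", {
  r <- t_test_auto(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("equal-variance samples take the Student branch", {
  r <- t_test_auto(c(1, 2, 3), c(11, 12, 13))
  expect_identical(r$test_name, "student_t")
  expect_match(r$method_path, "student")
  r2 <- t_test_auto(c(1, 2, 3, 2, 1, 3), c(0, 40, 80, 10, 60, 30))
  expect_identical(r2$test_name, "welch_t")
})

test_that("degenerate zero-variance samples follow the conventions", {
  expect_equal(t_test_auto(rep(2, 3), rep(2, 4))$p, 1)
  expect_warning(r <- t_test_auto(rep(2, 3), rep(5, 4)), "zero variance")
  expect_equal(r$p, 0)
})

test_that("Welch equals Student under equal variances and sizes", {
  a <- c(1.2, 3.4, 2.2, 4.8, 0.5)
  b <- c(2.1, 5.3, 1.1, 3.3, 4.4)
  ts <- t.test(a, b, var.equal = TRUE)
  tw <- t.test(a, b, var.equal = FALSE)
  # identical group sizes and sample variances differ, but the identity
  # holds whenever the two sample variances coincide; construct that case
  b2 <- (b - mean(b)) * sd(a) / sd(b) + mean(b)
  ts2 <- t.test(a, b2, var.equal = TRUE)
  tw2 <- t.test(a, b2, var.equal = FALSE)
  expect_lt(abs(unname(ts2$statistic) - unname(tw2$statistic)), 1e-12)
  expect_lt(abs(ts2$p.value - tw2$p.value), 1e-12)
  expect_false(isTRUE(all.equal(unname(ts$statistic), unname(tw$statistic),
                                tolerance = 1e-12)) &&
                 abs(unname(ts$parameter) - unname(tw$parameter)) < 1e-9)
})

test_that("ANOVA on identical groups is flat and post hocs agree", {
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- anova_posthoc(v, g, posthoc = "bonferroni")
  expect_equal(r$anova$statistic, 0)
  expect_equal(r$anova$p, 1)
  expect_true(all(r$posthoc$adjusted_p == 1))
})

test_that("Bartlett violation routes auto mode to Games-Howell", {
  hits <- 0
  n_sims <- 200
  for (s in seq_len(n_sims)) {
    v <- withr::with_seed(s, c(rnorm(10), rnorm(10), rnorm(10, 0, 5)))
    g <- rep(c("a", "b", "c"), each = 10)
    r <- anova_posthoc(v, g, posthoc = "auto")
    if (grepl("games_howell", r$method_path)) hits <- hits + 1
  }
  expect_gte(hits / n_sims, 0.99)
})

test_that("a planted 2-sd shift is detected by the auto post hoc", {
  hits <- 0
  n_sims <- 100
  for (s in seq_len(n_sims)) {
    v <- withr::with_seed(1000 + s, c(rnorm(15), rnorm(15), rnorm(15, 2)))
    g <- rep(c("a", "b", "c"), each = 15)
    r <- anova_posthoc(v, g, posthoc = "auto")
    row <- r$posthoc[(r$posthoc$group1 == "a" & r$posthoc$group2 == "c") |
                       (r$posthoc$group1 == "c" & r$posthoc$group2 == "a"), ]
    p <- if (is.na(row$adjusted_p)) row$p else row$adjusted_p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sims, 0.9)
})

test_that("Dunnett compares each group against the control only", {
  v <- withr::with_seed(2, c(rnorm(10), rnorm(10, 3), rnorm(10)))
  g <- rep(c("ctrl", "hi", "same"), each = 10)
  r <- anova_posthoc(v, g, posthoc = "dunnett", control_group = "ctrl")
  expect_identical(nrow(r$posthoc), 2L)
  expect_true(all(r$posthoc$group2 == "ctrl"))
  hi <- r$posthoc[r$posthoc$group1 == "hi", ]
  same <- r$posthoc[r$posthoc$group1 == "same", ]
  expect_lt(hi$adjusted_p, 0.01)
  expect_gt(same$adjusted_p, 0.2)
  expect_error(anova_posthoc(v, g, posthoc = "dunnett"), "control")
})

test_that("Games-Howell gives p near 1 for equal-mean groups", {
  v <- withr::with_seed(3, c(rnorm(12), rnorm(12)))
  g <- rep(c("a", "b"), each = 12)
  r <- games_howell(v, g)
  expect_gt(r$p, 0.1)
  ident <- games_howell(rep(c(1, 1, 2, 2), 2),
                        rep(c("a", "b"), each = 4))
  expect_gte(min(ident$p), 0.99)
})

test_that("Games-Howell matches Tukey HSD in the balanced equal-variance limit", {
  # with equal n and equal true variances the two procedures coincide
  # asymptotically; compare on data whose sample variances are equalized
  v0 <- withr::with_seed(4, rnorm(36))
  g <- rep(c("a", "b", "c"), each = 12)
  v <- unlist(lapply(split(v0, g), function(x) (x - mean(x)) / sd(x))) +
    rep(c(0, 0.5, 1.2), each = 12)
  gh <- games_howell(v, g)
  tk <- TukeyHSD(aov(v ~ factor(g)))$`factor(g)`
  tk_p <- tk[, "p adj"]
  for (i in seq_len(nrow(gh))) {
    key <- paste0(gh$group2[i], "-", gh$group1[i])
    expect_lt(abs(gh$p[i] - unname(tk_p[key])), 0.01)
  }
})

test_that("Fisher p matches exhaustive enumeration on canonical tables", {
  expect_equal(fisher_exact_bonferroni(matrix(c(5, 5, 5, 5), 2))$p, 1)
  extreme <- matrix(c(10, 0, 0, 10), 2)
  r <- fisher_exact_bonferroni(extreme)
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r$p, oracle_fisher_2x2(extreme), tolerance = 1e-12)
  # a spread of random tables against the enumeration oracle
  for (s in 1:50) {
    tab <- withr::with_seed(s, matrix(rpois(4, 6), 2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_bonferroni(tab)$p, oracle_fisher_2x2(tab),
                 tolerance = 1e-9)
  }
})

test_that("Bonferroni multiplies by the number of tables", {
  tab <- matrix(c(8, 2, 3, 7), 2)
  r <- fisher_exact_bonferroni(list(tab, tab, tab))
  expect_equal(r$adjusted_p, pmin(1, 3 * r$p))
  expect_error(fisher_exact_bonferroni(matrix(c(1.5, 2, 3, 4), 2)),
               "integer")
})

test_that("r x c tables fall back to a flagged Monte-Carlo p", {
  tab <- matrix(c(10, 2, 3, 2, 9, 4), 2)
  r <- fisher_exact_bonferroni(tab, b = 2000, seed = 5)
  expect_true(r$monte_carlo)
  expect_match(r$method_path, "monte_carlo")
  r2 <- fisher_exact_bonferroni(tab, b = 2000, seed = 5)
  expect_identical(r$p, r2$p)  # seeded
})

test_that("Kruskal-Wallis handles ties, degeneracy and exact enumeration", {
  expect_equal(kruskal_wallis(rep(3, 9), rep(c("a", "b", "c"), 3))$p, 1)
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  r <- kruskal_wallis(v, g, exact = TRUE)
  expect_equal(r$statistic,
               unname(kruskal.test(v, factor(g))$statistic))
  expect_equal(r$p_exact, oracle_kw_exact(v, g))
})

test_that("BH adjustment matches the hand step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  p <- withr::with_seed(6, runif(50))
  expect_equal(bh_adjust(p), oracle_bh(p))
  # monotone: raising a raw p never lowers any adjusted p
  p2 <- p
  p2[7] <- min(1, p2[7] + 0.3)
  expect_true(all(bh_adjust(p2) >= bh_adjust(p) - 1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("adjusted p values never fall below raw p values", {
  tabs <- lapply(1:4, function(i) {
    withr::with_seed(i, matrix(rpois(4, 5) + 1, 2))
  })
  r <- fisher_exact_bonferroni(tabs)
  expect_true(all(r$adjusted_p >= r$p))
  expect_true(all(r$p >= 0 & r$p <= 1))
})

test_that("log10 conversion rejects non-positive records by name", {
  expect_equal(log10_transform(c(100, 1)), c(2, 0))
  expect_error(log10_transform(c(10, 0, 5), ids = c("a", "b", "c")),
               "b")
})

test_that("null type-I error rates are calibrated", {
  n_reps <- 2000
  alpha <- 0.05
  rej_t <- rej_kw <- 0
  for (s in seq_len(n_reps)) {
    x <- withr::with_seed(2 * s, rnorm(20))
    y <- withr::with_seed(2 * s + 1, rnorm(20))
    if (t_test_auto(x[1:10], x[11:20])$p < alpha) rej_t <- rej_t + 1
    g <- rep(c("a", "b", "c"), each = 6)
    if (kruskal_wallis(c(x[1:12], y[1:6]), g)$p < alpha) rej_kw <- rej_kw + 1
  }
  band <- function(rate) {
    hw <- qnorm(0.995) * sqrt(alpha * (1 - alpha) / n_reps)
    rate >= alpha - hw & rate <= alpha + hw
  }
  expect_true(band(rej_t / n_reps))
  expect_true(band(rej_kw / n_reps))
})

test_that("studentized-range tail probabilities match Monte Carlo", {
  # the Games-Howell p uses ptukey; spot-check its calibration
  for (cfg in list(c(k = 3, df = 10), c(k = 4, df = 30))) {
    k <- cfg[["k"]]; df <- cfg[["df"]]
    draws <- withr::with_seed(k * 100 + df, {
      n_mc <- 200000
      z <- matrix(rnorm(n_mc * k), n_mc, k)
      s <- sqrt(rchisq(n_mc, df) / df)
      (apply(z, 1, max) - apply(z, 1, min)) / s
    })
    for (pr in c(0.90, 0.95, 0.99)) {
      q <- quantile(draws, pr)
      expect_lt(abs(ptukey(q, k, df) - pr), 0.005)
    }
  }
})
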