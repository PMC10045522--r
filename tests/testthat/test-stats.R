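test_that("t-tests versus control match the pooled-variance formula", {
  vals <- c(2.1, 2.2, 2.3, 1.1, 1.2, 1.3)
  grp <- rep(c("CTRL", "HP"), each = 3)
  res <- t_test_vs_control(vals, grp, control = "CTRL")
  # independent computation of the equal-variance t statistic
  x <- vals[4:6]; y <- vals[1:3]
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 4), tolerance = 1e-12)
  expect_true(res$significant)

  ident <- t_test_vs_control(rep(c(1, 1), each = 3),
                             rep(c("CTRL", "HP"), each = 3), "CTRL")
  expect_equal(ident$p_value, 1)
  expect_false(ident$significant)

  expect_error(
    t_test_vs_control(c(1, 2, 3), c("CTRL", "CTRL", "HP"), "CTRL"),
    "at least 2")
  expect_error(t_test_vs_control(1:4, rep("A", 4), "CTRL"), "not present")
})

test_that("identical groups share one letter; a separated group gets its own", {
  set.seed(42)
  d <- data.frame(y = rnorm(15, 5, 1), g = rep(c("A", "B", "C"), each = 5))
  res <- anova_tukey_kramer(d, "y", "g")
  expect_equal(unique(res$letters$letters), "a")

  d2 <- data.frame(y = c(rnorm(10, 0, 0.01), rnorm(5, 10, 0.01)),
                   g = rep(c("A", "B", "C"), each = 5))
  res2 <- anova_tukey_kramer(d2, "y", "g")
  lt <- setNames(res2$letters$letters, res2$letters$group)
  expect_equal(unname(lt["C"]), "a")  # highest mean labelled first
  expect_equal(unname(lt["A"]), unname(lt["B"]))
  expect_false(lt["A"] == lt["C"])
})

test_that("adjusted p-values equal the studentized-range computation", {
  set.seed(7)
  # deliberately unbalanced: the Kramer correction must be applied
  d <- data.frame(y = c(rnorm(4, 0), rnorm(6, 1), rnorm(8, 3)),
                  g = rep(c("A", "B", "C"), c(4, 6, 8)))
  res <- anova_tukey_kramer(d, "y", "g")
  fit <- aov(y ~ g, data = d)
  mse <- sum(residuals(fit)^2) / df.residual(fit)
  ns <- table(d$g)
  ms <- tapply(d$y, d$g, mean)
  for (i in seq_len(nrow(res$comparisons))) {
    g1 <- res$comparisons$group1[i]; g2 <- res$comparisons$group2[i]
    expect_equal(res$comparisons$p_adj[i],
                 unname(tukey_kramer_p(ms[g1], ms[g2], ns[g1], ns[g2], mse,
                                       df.residual(fit), k = 3)),
                 tolerance = 1e-6)
  }
})

test_that("letters satisfy the shares-letter <=> non-significant biconditional", {
  set.seed(314)
  for (i in 1:40) {
    k <- sample(3:6, 1)
    n <- sample(3:6, 1)
    mu <- rnorm(k, 0, sample(c(0.5, 2, 5), 1))
    d <- data.frame(y = rnorm(k * n, rep(mu, each = n)),
                    g = rep(LETTERS[1:k], each = n))
    res <- anova_tukey_kramer(d, "y", "g")
    lt <- setNames(strsplit(res$letters$letters, ""), res$letters$group)
    for (j in seq_len(nrow(res$comparisons))) {
      shared <- length(intersect(lt[[res$comparisons$group1[j]]],
                                 lt[[res$comparisons$group2[j]]])) > 0
      expect_identical(shared, !res$comparisons$significant[j])
    }
    expect_true(all(lengths(lt) > 0))
  }
})

test_that("two-way layouts use interaction only when replicated", {
  set.seed(9)
  d <- expand.grid(g = c("A", "B", "C"), b = c("x", "y"), rep = 1:3)
  d$y <- rnorm(nrow(d))
  res <- anova_tukey_kramer(d, "y", c("g", "b"))
  expect_true("g:b" %in% trimws(rownames(res$anova_table)))

  d1 <- expand.grid(g = c("A", "B", "C"), b = c("x", "y"))
  d1$y <- rnorm(nrow(d1))
  res1 <- anova_tukey_kramer(d1, "y", c("g", "b"))
  expect_false("g:b" %in% trimws(rownames(res1$anova_table)))

  dempty <- d[!(d$g == "A" & d$b == "x"), ]
  expect_error(anova_tukey_kramer(dempty, "y", c("g", "b")), "degenerate")
  expect_error(anova_tukey_kramer(d[d$g == "A", ], "y", c("g", "b")),
               "at least 2 levels")
})

test_that("correlation matrix matches cor.test pair by pair", {
  set.seed(21)
  d <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  d$b <- d$b + d$a
  pm <- pearson_matrix(d)
  expect_equal(diag(pm$r), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(pm$r))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ct <- cor.test(d[[pair[1]]], d[[pair[2]]])
    expect_equal(pm$r[pair[1], pair[2]], unname(ct$estimate))
    expect_equal(pm$p[pair[1], pair[2]], ct$p.value, tolerance = 1e-10)
  }
})

test_that("perfect anticorrelation, zero variance and BH adjust behave", {
  d <- data.frame(x = 1:10, y = -2 * (1:10))
  pm <- pearson_matrix(d)
  expect_equal(pm$r["x", "y"], -1)
  expect_lt(pm$p["x", "y"], 1e-12)

  dz <- data.frame(x = 1:10, y = rnorm(10), z = rep(1, 10))
  expect_warning(pmz <- pearson_matrix(dz), "zero-variance")
  expect_true(is.na(pmz$r["x", "z"]))

  set.seed(3)
  d4 <- as.data.frame(matrix(rnorm(40), ncol = 4))
  raw <- pearson_matrix(d4)
  adj <- pearson_matrix(d4, adjust = "BH")
  up <- upper.tri(raw$p)
  expect_equal(adj$p[up], p.adjust(raw$p[up], "BH"))
  expect_true(isSymmetric(adj$p))
})

test_that("a known correlation is recovered from simulated data", {
  set.seed(8)
  n <- 100
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  pm <- pearson_matrix(data.frame(x = x, y = y))
  expect_equal(pm$r["x", "y"], 0.8, tolerance = 0.1)
})

test_that("correlation p-values are uniform under the null", {
  set.seed(19)
  p <- replicate(200, pearson_matrix(data.frame(a = rnorm(20),
                                                b = rnorm(20)))$p[1, 2])
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("PCA variance fractions, sign convention and geometry", {
  set.seed(5)
  d <- data.frame(a = rnorm(12))
  d$b <- 3 * d$a + 2  # perfectly correlated pair: rank one
  pc <- pca_features(d)
  expect_equal(pc$var_explained[1], 1)

  d2 <- as.data.frame(matrix(rnorm(60), ncol = 5))
  pc2 <- pca_features(d2)
  expect_equal(sum(pc2$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(pc2$var_explained) <= 1e-12))
  # deterministic sign: each component's largest loading is positive
  for (j in seq_len(ncol(pc2$loadings))) {
    v <- pc2$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # all components retained: score distances equal standardized distances
  z <- scale(as.matrix(d2))
  expect_equal(as.matrix(dist(pc2$scores)), as.matrix(dist(z)),
               tolerance = 1e-9)

  d3 <- cbind(d2, k = 1)
  expect_warning(pc3 <- pca_features(d3), "constant")
  expect_equal(ncol(pc3$loadings), 5)
})

test_that("uncorrelated features spread variance roughly evenly", {
  set.seed(6)
  d <- as.data.frame(matrix(rnorm(3000), ncol = 3))
  pc <- pca_features(d)
  expect_true(all(abs(pc$var_explained - 1 / 3) < 0.1))
})
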