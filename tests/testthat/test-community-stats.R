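# IndVal, permutation inference, SIMPER and the classical tables.

test_that("IndVal hand cases: perfect, half, symmetric", {
  # present on every transect of A (equal cover), absent elsewhere
  m <- matrix(c(3, 3, 3, 0, 0, 0), ncol = 1)
  expect_equal(indval(m, rep(c("A", "B"), each = 3))$summary$indval, 1)
  # A abundances (2, 0), B (0, 0): A = 1, B(fidelity) = 0.5
  m2 <- matrix(c(2, 0, 0, 0), ncol = 1)
  iv2 <- indval(m2, c("A", "A", "B", "B"))$summary
  expect_equal(iv2$indval, 0.5)
  expect_equal(iv2$best_group, "A")
  # equal mean abundance and full frequency in 3 groups -> 1/3 each
  m3 <- matrix(rep(1, 6), ncol = 1)
  iv3 <- indval(m3, c("A", "A", "B", "B", "C", "C"))
  expect_equal(unname(iv3$indval[, 1L]), rep(1 / 3, 3))
})

test_that("IndVal equals exhaustive brute force on random 10 x 5 matrices", {
  set.seed(13)
  for (rep in 1:25) {
    m <- matrix(rbinom(50, 1, 0.6) * rgamma(50, 2), 10, 5)
    g <- sample(rep(c("A", "B", "C"), length.out = 10))
    if (min(table(g)) == 0 || any(colSums(m) == 0)) next
    iv <- indval(m, g)$indval
    for (j in 1:5) for (lev in c("A", "B", "C")) {
      expect_equal(iv[lev, j], unname(indval_brute(m[, j], g, lev)),
                   tolerance = 1e-12)
    }
  }
})

test_that("permutation p-values behave like p-values", {
  # minimum attainable p with 99 permutations is 1/100
  m <- matrix(c(5, 5, 5, 0, 0, 0, 0, 0, 0, 0), ncol = 1)
  g <- rep(c("A", "B"), c(3, 7))
  r <- indval_pvalue(m, g, n_perm = 99, seed = 1)
  expect_gte(r$p_value, 0.01)
  # a perfect indicator with groups of size >= 5 is highly significant
  m2 <- matrix(c(rep(4, 5), rep(0, 10)), ncol = 1)
  g2 <- rep(c("A", "B", "C"), each = 5)
  r2 <- indval_pvalue(m2, g2, n_perm = 999, seed = 1)
  expect_lte(r2$p_value, 0.01)
  expect_true(r2$indicator)
})

test_that("permutation p-values are seed-reproducible and order-invariant", {
  set.seed(21)
  m <- matrix(rgamma(60, 1), 12, 5)
  g <- rep(c("A", "B", "C"), each = 4)
  r1 <- indval_pvalue(m, g, n_perm = 199, seed = 77)
  r2 <- indval_pvalue(m, g, n_perm = 199, seed = 77)
  expect_identical(r1, r2)
  perm <- sample(12)
  r3 <- indval_pvalue(m[perm, ], g[perm], n_perm = 199, seed = 77)
  expect_equal(sort(r3$indval), sort(r1$indval), tolerance = 1e-12)
})

test_that("SIMPER decomposes Bray-Curtis and matches hand examples", {
  # groups differing in exactly one syntaxon: it takes 100%
  m <- rbind(c(10, 5), c(10, 5), c(10, 0), c(10, 0))
  s <- simper(m, c("A", "A", "B", "B"))[["A_vs_B"]]
  expect_equal(s$contributions$contrib_pct[1L], 100)
  # two-syntaxon opposition: BC = 1, 50% each
  s2 <- simper(rbind(c(100, 0), c(0, 100)), c("A", "B"))[["A_vs_B"]]
  expect_equal(s2$overall, 1)
  expect_equal(s2$contributions$contrib_pct, c(50, 50))
  # identical groups: zero dissimilarity, empty ranking
  s3 <- simper(rbind(c(1, 2), c(1, 2)), c("A", "B"))[["A_vs_B"]]
  expect_equal(s3$overall, 0)
  expect_equal(nrow(s3$contributions), 0)
})

test_that("SIMPER contributions sum to the mean Bray-Curtis and match vegan", {
  skip_if_not_installed("vegan")
  set.seed(31)
  m <- matrix(rgamma(80, 1.5), 16, 5)
  m[sample(80, 30)] <- 0
  g <- rep(c("A", "B"), each = 8)
  mine <- simper(m, g)[["A_vs_B"]]
  bc <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(mine$overall, mean(bc[1:8, 9:16]), tolerance = 1e-9)
  ref <- summary(vegan::simper(m, g))[["A_B"]]
  expect_equal(sort(mine$contributions$average), sort(ref$average),
               tolerance = 1e-9)
})

test_that("Spearman table applies the printed reporting rule", {
  expect_equal(correlation_table(data.frame(a = 1:5),
                                 data.frame(b = c(1, 3, 2, 5, 4)))$rho,
               0.8)
  expect_equal(correlation_table(data.frame(a = 1:6),
                                 data.frame(b = 6:1))$rho, -1)
  # constant variable: missing rho, never shown
  ct <- correlation_table(data.frame(a = rep(2, 6)),
                          data.frame(b = 1:6))
  expect_true(is.na(ct$rho))
  expect_false(ct$shown)
  # filter keeps only p <= 0.1 rows
  set.seed(41)
  ind <- data.frame(x = rnorm(40), y = rnorm(40))
  env <- data.frame(e1 = ind$x + rnorm(40, sd = 0.2), e2 = rnorm(40))
  full <- correlation_table(ind, env)
  kept <- correlation_table(ind, env, filter = TRUE)
  expect_true(all(kept$p_value <= 0.1))
  expect_equal(nrow(kept), sum(full$shown))
})

test_that("Kruskal-Wallis wrapper matches the two-group Mann-Whitney identity", {
  set.seed(51)
  x <- sample(1:1000, 40)  # no ties
  cl <- rep(c("A", "B"), each = 20)
  gc <- group_comparison(x, cl)
  U <- suppressWarnings(wilcox.test(x[cl == "A"],
                                    x[cl == "B"]))$statistic
  z <- (U - 20 * 20 / 2) / sqrt(20 * 20 * 41 / 12)
  expect_equal(gc$H, unname(z^2), tolerance = 1e-9)
})

test_that("identical class distributions give a null Kruskal-Wallis result", {
  x <- rep(1:10, 3)
  cl <- rep(c("gentle", "moderate", "steep"), each = 10)
  gc <- group_comparison(x, cl)
  expect_lt(gc$H, 1e-9)
  expect_gt(gc$p_value, 0.99)
})

test_that("fully separated classes at the survey class sizes are detected", {
  set.seed(61)
  cl <- rep(c("gentle", "moderate", "steep"), c(36, 180, 44))
  x <- c(runif(36, 0, 1), runif(180, 2, 3), runif(44, 4, 5))
  gc <- group_comparison(x, cl)
  expect_lt(gc$p_value, 0.001)
  expect_true(all(gc$pairwise < 0.001, na.rm = TRUE))
})

test_that("undersized classes are excluded from the pairwise step", {
  x <- c(1, 2, 3, 4, 10)
  cl <- c("A", "A", "B", "B", "C")
  expect_warning(gc <- group_comparison(x, cl), "excluded")
  expect_false("C" %in% colnames(gc$pairwise))
})
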