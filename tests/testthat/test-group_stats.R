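test_that("Mann-Whitney U counts pairs and p matches enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$u, 0)                      # all 9 pairs favour b
  # identical multisets: U = n^2/2 and two-sided exact p = 1
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3), exact = TRUE)
  expect_equal(r2$u, 4.5)
  expect_equal(r2$p, 1)
  # exact p equals the label-permutation oracle, with and without ties
  set.seed(14)
  for (i in 1:10) {
    a <- sample(1:6, 4, replace = i %% 2 == 0)
    b <- sample(1:6, 4, replace = TRUE)
    r <- mann_whitney_u(a, b, exact = TRUE)
    expect_equal(r$u, oracle_mw_u(a, b))
    expect_equal(r$p, oracle_mw_exact_p(a, b), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("approximate Mann-Whitney agrees with wilcox.test", {
  set.seed(2)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  r <- mann_whitney_u(a, b, exact = FALSE)
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$u, unname(wt$statistic))
  expect_equal(r$p, wt$p.value)
})

test_that("Kruskal-Wallis H and p behave across modes", {
  groups <- list(a = c(1, 5, 8), b = c(2, 6, 9), c = c(3, 7, 10))
  r <- kruskal_wallis(groups, exact = FALSE)
  kt <- stats::kruskal.test(unlist(groups), factor(rep(1:3, each = 3)))
  expect_equal(r$statistic, unname(kt$statistic))
  expect_equal(r$p, kt$p.value)
  # degenerate all-equal data: H = 0, no evidence
  expect_equal(kruskal_wallis(list(a = c(1, 1), b = c(1, 1, 1)))$statistic, 0)
  # exact mode matches the assignment-enumeration oracle for (3,3,3)
  set.seed(6)
  g2 <- list(a = sample(1:5, 3, TRUE), b = sample(1:5, 3, TRUE),
             c = sample(1:5, 3, TRUE))
  expect_equal(kruskal_wallis(g2, exact = TRUE)$p, oracle_kw_exact_p(g2),
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
})

test_that("Bonferroni post hoc multiplies and caps p", {
  set.seed(4)
  groups <- list(x = rnorm(6), y = rnorm(6, 2), z = rnorm(6, 4))
  reps <- bonferroni_pairwise(groups)
  expect_equal(length(reps), 3)              # k(k-1)/2
  for (r in reps) {
    expect_equal(r$p_adjusted, min(1, 3 * r$p))
    expect_gte(r$p_adjusted, r$p)
    expect_lte(r$p_adjusted, 1)
  }
  expect_equal(stats::p.adjust(0.02, "bonferroni", n = 3), 0.06)
  expect_equal(stats::p.adjust(0.9, "bonferroni", n = 3), 1)
})

test_that("Spearman correlation matches the rank formula", {
  expect_equal(spearman(1:10, (1:10)^3)$r, 1)
  expect_equal(spearman(1:10, -(1:10)^3)$r, -1)
  expect_equal(spearman(1:4, c(1, 3, 2, 4))$r, 0.8)
  expect_error(spearman(1:4, 1:5), "equal length")
})

test_that("rank tests are invariant under strictly increasing transforms", {
  set.seed(19)
  a <- rnorm(12); b <- rnorm(10, 0.4)
  f <- function(x) exp(x) + x^3
  r1 <- mann_whitney_u(a, b); r2 <- mann_whitney_u(f(a), f(b))
  expect_equal(r1$u, r2$u); expect_equal(r1$p, r2$p)
  g1 <- list(a = a, b = b)
  expect_equal(kruskal_wallis(g1, exact = FALSE)$p,
               kruskal_wallis(lapply(g1, f), exact = FALSE)$p)
})

test_that("Lilliefors K-S screens normality with calibrated p", {
  skip_if_not_installed("nortest")
  set.seed(4)
  x <- rnorm(200)
  lt <- nortest::lillie.test(x)
  r <- ks_normality(x, n_sim = 500, seed = 5)
  # same statistic as the reference implementation, compatible p
  expect_equal(r$statistic, unname(lt$statistic))
  expect_gt(r$p, 0.05)
  expect_lt(abs(r$p - lt$p.value), 0.15)
  # 2-point distribution is flagged at n = 200
  y <- rep(c(0, 1), 100)
  expect_lt(ks_normality(y, n_sim = 500, seed = 5)$p, 0.05)
  # constant sample: degenerate, minimal p
  expect_lt(ks_normality(rep(3, 50))$p, 0.001)
  expect_error(ks_normality(c(1, 2)), "at least 3")
})

test_that("Lilliefors rejection rate under the null is near nominal", {
  set.seed(77)
  rej <- mean(replicate(120, {
    ks_normality(rnorm(40), n_sim = 200, seed = sample.int(1e6, 1))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 120) + 0.02)
})
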