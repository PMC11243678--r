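test_that("Gower centering reproduces the centered inner product", {
  # all-zero distances -> zero matrix
  expect_equal(gower_center(matrix(0, 4, 4)), matrix(0, 4, 4))
  # Euclidean distances from 1-D points -> centered outer product
  x <- c(1.5, -2, 0.25, 4, 1)
  d <- as.matrix(stats::dist(x))
  g <- gower_center(d)
  xc <- x - mean(x)
  expect_equal(g, outer(xc, xc), tolerance = 1e-12)
  # zero row sums for random distance matrices
  set.seed(31)
  for (i in 1:10) {
    p <- matrix(rnorm(24), 8, 3)
    g <- gower_center(stats::dist(p))
    expect_lt(max(abs(rowSums(g))), 1e-10)
  }
  bad <- matrix(runif(16), 4, 4); diag(bad) <- 0
  expect_error(gower_center(bad), "symmetric")
})

test_that("univariate Euclidean pseudo-F equals the classical regression F", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(10:25, 1)
    x <- data.frame(a = rnorm(n))
    y <- 0.8 * x$a + rnorm(n)
    dl <- distlm(matrix(y), x, n_perm = 99, seed = i)
    f_classic <- stats::anova(stats::lm(y ~ x$a))$`F value`[1]
    expect_equal(dl$marginal$pseudo_f[1], f_classic, tolerance = 1e-8)
    expect_equal(dl$marginal$prop_var[1], summary(stats::lm(y ~ x$a))$r.squared,
                 tolerance = 1e-8)
  }
})

test_that("permutation p is seed-reproducible and selection shuns duplicates", {
  set.seed(50)
  x <- data.frame(tmx = rnorm(24), tmn = rnorm(24), prep = rnorm(24))
  y <- 2 * x$tmx + rnorm(24)
  d1 <- distlm(matrix(y), x, n_perm = 199, seed = 7)
  d2 <- distlm(matrix(y), x, n_perm = 199, seed = 7)
  expect_identical(d1$marginal$p_perm, d2$marginal$p_perm)
  expect_gte(min(d1$marginal$p_perm), 1 / 200)

  # duplicated covariate: rank-deficient designs are refused by name
  x2 <- cbind(x, tmx_copy = x$tmx)
  expect_error(distlm(matrix(y), x2, n_perm = 99, seed = 1), "tmx_copy")
  # a merely redundant (correlated) covariate is never selected when it
  # adds no adjusted R^2
  x3 <- cbind(x, tmx_near = x$tmx + rnorm(24, 0, 1e-6))
  d3 <- distlm(matrix(y), x3, n_perm = 99, seed = 1)
  first_two <- d3$selection$covariate[1:2]
  expect_true("tmx" %in% d3$selection$covariate[1])
  expect_false(all(c("tmx", "tmx_near") %in% first_two) &&
                 diff(d3$selection$adj_r2[1:2]) > 0)
})

test_that("dbRDA structure: trace conservation, rank bounds, axis ordering", {
  set.seed(61)
  resp <- matrix(rnorm(60), 20, 3)
  covs <- data.frame(a = rnorm(20), b = rnorm(20))
  db <- dbrda(resp, covs)
  expect_lte(db$n_axes, 2)                        # <= q covariates
  expect_equal(db$ss_fitted + db$ss_residual, db$ss_total, tolerance = 1e-8)
  expect_true(all(diff(db$pct_fitted) <= 1e-9))   # non-increasing
  expect_lte(sum(db$pct_fitted), 100 + 1e-6)
  expect_equal(sum(db$pct_fitted), 100, tolerance = 1e-6)

  # response exactly linear in one covariate: one axis, 100% of fitted
  y <- matrix(3 * covs$a - 1)
  db1 <- dbrda(y, covs["a"])
  expect_equal(db1$n_axes, 1)
  expect_equal(db1$pct_fitted[1], 100)
  expect_equal(db1$pct_total[1], 100, tolerance = 1e-8)
})

test_that("dbRDA agrees with vegan on Euclidean responses", {
  skip_if_not_installed("vegan")
  set.seed(71)
  resp <- matrix(rnorm(54), 18, 3)
  covs <- data.frame(a = rnorm(18), b = rnorm(18))
  db <- dbrda(resp, covs)
  vg <- vegan::dbrda(stats::dist(resp) ~ a + b, data = covs)
  # vegan scales inertia by (n - 1); eigenvalue ratios are scale-free
  vg_eig <- vg$CCA$eig
  expect_equal(db$pct_fitted, as.numeric(100 * vg_eig / sum(vg_eig)),
               tolerance = 1e-8)
  expect_equal(db$eig / (18 - 1), as.numeric(vg_eig), tolerance = 1e-8)
  # constrained (linear-combination) site scores span the same axes
  sc <- vegan::scores(vg, display = "lc", choices = 1:db$n_axes)
  for (k in seq_len(db$n_axes))
    expect_gt(abs(stats::cor(db$scores[, k], sc[, k])), 1 - 1e-8)
})

test_that("marginal DistLM p matches vegan adonis2 term significance shape", {
  skip_if_not_installed("vegan")
  set.seed(81)
  x <- data.frame(a = rnorm(20))
  y <- 1.5 * x$a + rnorm(20)
  dl <- distlm(matrix(y), x, n_perm = 999, seed = 3)
  ad <- vegan::adonis2(stats::dist(matrix(y)) ~ a, data = x,
                       permutations = 999)
  expect_equal(dl$marginal$pseudo_f[1], ad$F[1], tolerance = 1e-8)
  expect_lt(abs(dl$marginal$p_perm[1] - ad$`Pr(>F)`[1]), 0.05)
})

test_that("climate tables validate and attribution joins on (year, month)", {
  clim <- simulate_climate(2011:2012, seed = 5)
  expect_true(all(clim$tmx_c >= clim$tmn_c))
  expect_true(all(clim$prep_mm >= 0))
  p <- file.path(tempdir(), "clim.csv")
  write_climate(clim, p)
  back <- read_climate(p)
  expect_equal(back$tmx_c, round(clim$tmx_c * 10) / 10, tolerance = 1e-9)

  st <- random_stack(4, 4, 2011:2012, seed = 9)
  ser <- seasonal_series(st)
  tab <- attribution_table(ser, back)
  expect_equal(nrow(tab), 24)
  expect_true(all(c("savi_mean", "tmx_c", "tmn_c", "prep_mm") %in% names(tab)))
})
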