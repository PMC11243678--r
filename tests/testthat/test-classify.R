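test_that("SAVI thresholds classify with lower-closed intervals", {
  vals <- c(-0.77, -0.10, 0, 0.1, 0.25, 0.30, 0.35, 0.44, 0.45, 0.50, 0.66)
  want <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 5)
  cm <- classify_savi(grid_new(matrix(vals, 1, length(vals))))
  expect_equal(as.vector(cm$values), want)
  # NoData propagates
  cmna <- classify_savi(grid_new(matrix(c(0.1, NA), 1, 2)))
  expect_identical(as.vector(cmna$valid_mask), c(TRUE, FALSE))
})

test_that("classification is monotone in SAVI", {
  set.seed(11)
  x <- sort(runif(500, -1.5, 1.5))
  codes <- as.vector(classify_savi(grid_new(matrix(x, 1, 500)))$values)
  expect_true(all(diff(codes) >= 0))
})

test_that("cover percentages count valid pixels and sum to 100", {
  cm <- classify_savi(grid_new(matrix(c(-0.1, -0.2, 0.1, 0.3), 2, 2)))
  tab <- cover_percentages(cm)
  expect_equal(tab$percent, c(50, 25, 25, 0, 0))
  expect_equal(tab$count, c(2, 1, 1, 0, 0))
  expect_equal(tab$area_ha, c(2, 1, 1, 0, 0) * 0.09)
  expect_equal(sum(tab$percent), 100)

  uni <- classify_savi(grid_new(matrix(0.5, 3, 3)))
  expect_equal(cover_percentages(uni)$percent, c(0, 0, 0, 0, 100))

  empty <- grid_new(matrix(NA_real_, 2, 2))
  expect_error(cover_percentages(empty), "no valid pixels")

  # random maps always sum to 100 (NoData excluded from the denominator)
  set.seed(3)
  for (r in 1:20) {
    v <- matrix(runif(64, -1, 1), 8, 8)
    v[runif(64) < 0.3] <- NA
    tab <- cover_percentages(classify_savi(grid_new(v)))
    expect_equal(sum(tab$percent), 100, tolerance = 1e-9)
  }
})

test_that("cover differences subtract percentage points and sum to zero", {
  earlier <- classify_savi(grid_new(matrix(c(-0.1, -0.1, -0.1, 0.5, 0.5), 1, 5)))
  later <- classify_savi(grid_new(matrix(c(-0.1, -0.1, 0.5, 0.5, 0.5), 1, 5)))
  d <- cover_difference(cover_percentages(later), cover_percentages(earlier))
  expect_equal(d$diff_pp, c(-20, 0, 0, 0, 20))
  expect_equal(sum(d$diff_pp), 0, tolerance = 1e-9)
  # identical tables -> all zeros
  same <- cover_difference(cover_percentages(later), cover_percentages(later))
  expect_equal(same$diff_pp, rep(0, 5))
  # mismatched schemes refused
  alt <- cover_percentages(classify_savi(grid_new(matrix(0.1, 1, 1)),
                                         category_scheme(c(0, 0.2, 0.4, 0.6))),
                           scheme = category_scheme(c(0, 0.2, 0.4, 0.6)))
  expect_error(cover_difference(alt, cover_percentages(later)), "schemes")
})

test_that("change maps difference category codes and cross-tabulate consistently", {
  set.seed(5)
  v1 <- matrix(runif(100, -0.8, 0.7), 10, 10)
  v2 <- matrix(runif(100, -0.8, 0.7), 10, 10)
  v1[runif(100) < 0.1] <- NA; v2[runif(100) < 0.1] <- NA
  e <- classify_savi(grid_new(v1)); l <- classify_savi(grid_new(v2))
  dm <- change_map(l, e)
  expect_true(all(abs(grid_values(dm)) <= 4))
  expect_identical(dm$valid_mask, e$valid_mask & l$valid_mask)
  # pixel shifting 2 -> 5 gives +3
  e1 <- classify_savi(grid_new(matrix(0.1, 1, 1)))
  l1 <- classify_savi(grid_new(matrix(0.5, 1, 1)))
  expect_equal(change_map(l1, e1)$values[1, 1], 3)
  # identical maps -> all zeros
  expect_true(all(grid_values(change_map(e, e)) == 0))
  # shift histogram margins agree with the aggregate cover difference on
  # the shared valid set
  both <- dm$valid_mask
  shifts <- dm$values[both]
  codes_l <- l$values[both]; codes_e <- e$values[both]
  n <- sum(both)
  for (k in 1:5) {
    agg <- 100 * (sum(codes_l == k) - sum(codes_e == k)) / n
    # net inflow into class k from the pixelwise cross-tabulation
    net <- 100 * (sum(codes_l == k & shifts != 0) -
                  sum(codes_e == k & shifts != 0)) / n
    expect_equal(net, agg, tolerance = 1e-9)
  }
})

test_that("cover composition is invariant to breakpoint-fixing monotone rescales", {
  set.seed(8)
  v <- matrix(runif(100, -1, 1), 10, 10)
  base <- cover_percentages(classify_savi(grid_new(v)))
  # piecewise-linear strictly increasing map fixing {0, 0.25, 0.35, 0.45}
  warp <- function(x) {
    br <- c(-1.5, 0, 0.25, 0.35, 0.45, 1.5)
    to <- c(-1.5, 0, 0.25, 0.35, 0.45, 1.5)
    i <- findInterval(x, br, all.inside = TRUE)
    lam <- (x - br[i]) / (br[i + 1] - br[i])
    to[i] + (lam^1.3) * (to[i + 1] - to[i])
  }
  warped <- cover_percentages(classify_savi(grid_new(matrix(warp(v), 10, 10))))
  expect_equal(warped$percent, base$percent)
})
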