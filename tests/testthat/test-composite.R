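test_that("season assignment follows the regional calendar", {
  expect_equal(assign_season(3), "dry")
  expect_equal(assign_season(5), "dry")
  expect_equal(assign_season(7), "rainy")
  expect_equal(assign_season(10), "rainy")
  expect_equal(assign_season(c(11, 12, 1, 2)), rep("northerlies", 4))
  expect_error(assign_season(0), "1..12")
  expect_error(assign_season(13), "1..12")
  expect_error(season_calendar(dry_months = 3:6), "partition")

  # northerlies straddling the year boundary are labeled by starting year
  expect_equal(season_year(2011, 1), 2010L)
  expect_equal(season_year(2011, 2), 2010L)
  expect_equal(season_year(2011, 11), 2011L)
  expect_equal(season_year(2011, 7), 2011L)
})

test_that("median composite uses order statistics with the midpoint convention", {
  g <- function(x) grid_new(matrix(x, 1, 1))
  st <- assemble_stack(grids = list(g(0.1), g(0.2), g(0.9)),
                       years = c(2011, 2011, 2011), months = 1:3)
  expect_equal(median_composite(st)$values[1, 1], 0.2)
  st2 <- assemble_stack(grids = list(g(0.1), g(0.3)),
                        years = c(2011, 2011), months = 1:2)
  expect_equal(median_composite(st2)$values[1, 1], 0.2)
  # single scene: unchanged
  st1 <- assemble_stack(grids = list(g(0.7)), years = 2011, months = 1)
  expect_equal(median_composite(st1)$values[1, 1], 0.7)
  expect_error(median_composite(st, select = integer(0)), "empty")
  # zero valid observations -> NoData
  gna <- grid_new(matrix(NA_real_, 1, 1))
  stna <- assemble_stack(grids = list(gna, gna), years = c(2011, 2011),
                         months = 1:2)
  expect_false(median_composite(stna)$valid_mask[1, 1])
})

test_that("biannual layers: five periods, period isolation via a sentinel", {
  st <- random_stack(4, 4, 2011:2020, seed = 1)
  layers <- biannual_layers(st)
  expect_equal(length(layers), 5)
  expect_equal(names(layers)[1], "2011-2012")

  # inject a sentinel in 2013: the 2011-2012 layer must ignore it
  st2 <- st
  k <- which(st2$timestamps$year == 2013)[1]
  st2$grids[[k]] <- grid_new(matrix(1e6, 4, 4))
  l1 <- biannual_layers(st2)[["2011-2012"]]
  expect_equal(l1$values, layers[["2011-2012"]]$values)
  l2 <- biannual_layers(st2)[["2013-2014"]]
  expect_false(isTRUE(all.equal(l2$values, layers[["2013-2014"]]$values)))

  short <- random_stack(2, 2, 2011:2012, seed = 2)
  expect_error(biannual_layers(short), "2013-2014")
})

test_that("median compositing is idempotent, permutation-invariant and monotone", {
  st <- random_stack(5, 5, 2011:2012, seed = 3, na_frac = 0.2)
  comp <- median_composite(st)
  # idempotent: compositing the composite with itself returns it
  st_self <- assemble_stack(grids = list(comp, comp), years = c(2011, 2012),
                            months = c(1, 1))
  expect_equal(median_composite(st_self)$values[comp$valid_mask],
               comp$values[comp$valid_mask])
  # permutation invariance: shuffling scene order leaves the layer unchanged
  set.seed(9)
  o <- sample(stack_length(st))
  st_shuf <- assemble_stack(grids = st$grids[o],
                            years = st$timestamps$year[o],
                            months = st$timestamps$month[o])
  expect_equal(median_composite(st_shuf)$values, comp$values)
  # monotone: raising one valid observation cannot decrease the median
  st_up <- st
  g1 <- st_up$grids[[1]]
  cell <- which(g1$valid_mask, arr.ind = TRUE)[1, ]
  g1$values[cell[1], cell[2]] <- g1$values[cell[1], cell[2]] + 10
  st_up$grids[[1]] <- g1
  up <- median_composite(st_up)
  expect_true(all(up$values[comp$valid_mask] >= comp$values[comp$valid_mask]))
})

test_that("affine scaling commutes with median compositing", {
  st <- random_stack(4, 4, 2011:2011, seed = 4, na_frac = 0.1)
  spec <- scaling_spec(0.0000275, -0.2)
  scaled <- lapply(st$grids, apply_scaling, spec = spec)
  st_scaled <- assemble_stack(grids = scaled, years = st$timestamps$year,
                              months = st$timestamps$month)
  a <- median_composite(st_scaled)
  b <- apply_scaling(median_composite(st), spec)
  expect_equal(a$values[a$valid_mask], b$values[b$valid_mask],
               tolerance = 1e-12)
})

test_that("seasonal series summarises the zone correctly", {
  # uniform value v: zone mean is v each month
  g <- grid_new(matrix(0.37, 4, 4))
  st <- assemble_stack(grids = rep(list(g), 3), years = rep(2011, 3),
                       months = c(1, 4, 7))
  s <- seasonal_series(st)
  expect_equal(s$mean, rep(0.37, 3))
  expect_equal(s$season, c("northerlies", "dry", "rainy"))

  # checkerboard of 0/1: zone mean 0.5
  cb <- grid_new(outer(1:4, 1:4, function(i, j) (i + j) %% 2))
  st2 <- assemble_stack(grids = list(cb), years = 2011, months = 1)
  expect_equal(seasonal_series(st2)$mean, 0.5)

  # single-pixel mask follows that pixel's trajectory
  mask <- matrix(FALSE, 4, 4); mask[2, 3] <- TRUE
  traj <- seasonal_series(st, zone_mask = mask)
  expect_equal(traj$mean, rep(0.37, 3))
  expect_equal(traj$n_valid, rep(1L, 3))

  # empty zone at a timestamp: row kept with NA summaries
  gna <- grid_new(matrix(NA_real_, 4, 4))
  st3 <- assemble_stack(grids = list(g, gna), years = c(2011, 2011),
                        months = 1:2)
  s3 <- seasonal_series(st3)
  expect_equal(nrow(s3), 2)
  expect_true(is.na(s3$mean[2]) && s3$n_valid[2] == 0)
})
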