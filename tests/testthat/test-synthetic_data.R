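test_that("simulation is deterministic and honours degenerate configs", {
  cfg <- sim_config(rows = 8, cols = 8, seed = 123)
  s1 <- simulate_index_stack(cfg)
  s2 <- simulate_index_stack(cfg)
  for (k in seq_len(stack_length(s1$stack))) {
    expect_identical(s1$stack$grids[[k]]$values, s2$stack$grids[[k]]$values)
    expect_identical(s1$stack$grids[[k]]$valid_mask,
                     s2$stack$grids[[k]]$valid_mask)
  }
  # no noise, no clouds, no slope, flat seasons: every scene = baseline map
  flat <- sim_config(rows = 5, cols = 5, noise_sd = 0, cloud_frac = 0,
                     slope = c(0, 0),
                     season_amp = c(dry = 0, rainy = 0, northerlies = 0),
                     seed = 1)
  sf <- simulate_index_stack(flat)
  base <- sf$stack$grids[[1]]$values
  for (g in sf$stack$grids) {
    expect_identical(g$values, base)
    expect_true(all(g$valid_mask))
  }
  expect_error(sim_config(rows = 2, cols = 2,
                          zones = matrix(c(1L, 1L, 1L, 3L), 2, 2),
                          baseline = 1:3, slope = rep(0, 3), seed = 1),
               "zone")
})

test_that("noiseless yearly medians recover the configured slope exactly", {
  cfg <- sim_config(rows = 4, cols = 4, noise_sd = 0, cloud_frac = 0,
                    slope = c(0.02, -0.02),
                    season_amp = c(dry = 0, rainy = 0, northerlies = 0),
                    seed = 2)
  sim <- simulate_index_stack(cfg)
  a <- sapply(2011:2020, function(yr) {
    sel <- sim$stack$timestamps$year == yr
    stats::median(sapply(which(sel), function(k)
      sim$stack$grids[[k]]$values[1, 1]))
  })
  fit <- stats::lm(a ~ I(2011:2020))
  expect_equal(unname(stats::coef(fit)[2]), 0.02, tolerance = 1e-10)
  expect_equal(sim$truth$slope[1, 1], 0.02)
  expect_equal(sim$truth$trend_class[1, 1], 1)
  # noiseless latent category fractions match a direct classification
  lat <- sim$truth$latent
  sel <- sim$stack$timestamps$year %in% 2011:2012
  med <- apply(simplify2array(lat[sel]), c(1, 2), stats::median)
  direct <- tabulate(as.vector(classify_savi(grid_new(med))$values), 5) / 16
  expect_equal(sim$truth$category_fractions[["2011-2012"]], direct)
})

test_that("cloud masking hits the configured fraction; stripes are periodic", {
  cfg <- sim_config(rows = 20, cols = 20, cloud_frac = 0.2, seed = 3)
  sim <- simulate_index_stack(cfg)
  n_cells <- 400 * stack_length(sim$stack)
  masked <- sum(!sapply(sim$stack$grids, function(g) g$valid_mask))
  frac <- masked / n_cells
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n_cells))

  cfg2 <- sim_config(rows = 10, cols = 10, cloud_frac = 0, stripe_period = 5,
                     stripe_width = 1, seed = 4)
  sim2 <- simulate_index_stack(cfg2)
  m <- sim2$stack$grids[[1]]$valid_mask
  diag_id <- outer(1:10, 1:10, `+`)
  expect_identical(m, diag_id %% 5 >= 1)
})

test_that("reflectance pairs invert the SAVI definition exactly", {
  # closed-form spot checks
  tgt <- grid_new(matrix(c(0, 0.45), 1, 2))
  pr <- simulate_reflectance_pair(tgt, red_range = c(0.1, 0.1))
  expect_equal(pr$nir$values[1, 1], pr$red$values[1, 1])   # target 0
  expect_equal(pr$nir$values[1, 2], 0.4, tolerance = 1e-12) # red 0.1, s 0.45

  set.seed(12)
  v <- matrix(runif(100, -1.3, 1.3), 10, 10)
  v[runif(100) < 0.15] <- NA
  tgt <- grid_new(v)
  pr <- simulate_reflectance_pair(tgt, seed = 99)
  got <- savi(pr$nir, pr$red, L = 0.5)
  expect_equal(got$values[tgt$valid_mask], v[tgt$valid_mask],
               tolerance = 1e-12)
  # QA carries the mask: cloud bit set exactly where target is NoData
  ok <- decode_qa_mask(pr$qa)
  expect_identical(ok$valid_mask, tgt$valid_mask)
  expect_error(simulate_reflectance_pair(grid_new(matrix(1.6, 1, 1))),
               "within")
})

test_that("digital-number export survives the full scaling path", {
  set.seed(13)
  tgt <- grid_new(matrix(runif(64, -0.7, 0.7), 8, 8))
  pr <- simulate_reflectance_pair(tgt, seed = 5, as_dn = TRUE)
  spec <- reflectance_scaling()
  got <- savi(apply_scaling(pr$nir, spec), apply_scaling(pr$red, spec))
  # DN quantisation bounds the index error
  expect_lt(max(abs(got$values - tgt$values)), 5e-4)
})

test_that("simulated climate has the seasonal structure and coupling hook", {
  clim <- simulate_climate(2011:2020, seed = 8)
  expect_equal(nrow(clim), 120)
  expect_true(all(clim$tmx_c >= clim$tmn_c))
  north <- clim$season == "northerlies"
  expect_lt(mean(clim$tmx_c[north]), mean(clim$tmx_c[!north]))
  expect_gt(mean(clim$prep_mm[clim$season == "rainy"]),
            mean(clim$prep_mm[clim$season == "dry"]))
  # zero-variance spec: constant per season
  cz <- simulate_climate(2011, seed = 1, sd_temp = 0, sd_prep = 0)
  expect_equal(length(unique(cz$tmx_c[cz$season == "dry"])), 1)
  # coupled response is reproducible and driven by the named covariate
  cc <- simulate_climate(2011:2013, seed = 2, coupling = c(tmx_c = 5),
                         response_noise = 0.5)
  expect_true("response" %in% names(cc))
  expect_gt(abs(stats::cor(cc$response, cc$tmx_c)), 0.7)
})
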