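#' Configuration for the synthetic scene generator
#'
#' Emulates the statistical structure of a decade of monthly SAVI
#' observations over a two-zone coastal dune strip: per-zone baseline
#' level, per-zone linear trend, a seasonal cycle peaking in the
#' northerlies (dry and rainy sit level, as observed in the study
#' system), Gaussian observation noise, independent per-pixel cloud
#' masking, and periodic diagonal stripe gaps imitating the Landsat-7
#' SLC-off pattern. Defaults follow the study system: baselines 0.40
#' (northern zone, NZ) and 0.33 (southern zone, SZ) with a mild recovery
#' trend in the NZ and loss in the SZ, a +0.05 northerlies boost, noise
#' sd 0.05 and 20% cloud cover.
#'
#' @param rows,cols grid size (default 30 x 30).
#' @param years simulated years (default 2011:2020).
#' @param zones integer matrix (rows x cols) of zone ids 1..k, or `NULL`
#'   for a default east-west split into NZ (1) and SZ (2).
#' @param zone_names names for the zone ids.
#' @param baseline per-zone baseline SAVI mean.
#' @param slope per-zone trend in index units per year.
#' @param season_amp named additive season effects
#'   (dry/rainy/northerlies).
#' @param noise_sd observation noise standard deviation on the index
#'   scale.
#' @param noise one of "gaussian" or "t5" (heavy-tailed option to
#'   exercise median robustness).
#' @param cloud_frac per-month independent probability a pixel is cloud
#'   masked.
#' @param stripe_period,stripe_width SLC-off-style diagonal gap bands:
#'   every `stripe_period`-th diagonal, `stripe_width` pixels wide, is
#'   NoData (`stripe_period = 0` disables).
#' @param seed RNG seed (mandatory).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(rows = 30, cols = 30, years = 2011:2020,
                       zones = NULL, zone_names = c("NZ", "SZ"),
                       baseline = c(0.40, 0.33),
                       slope = c(0.002, -0.002),
                       season_amp = c(dry = 0, rainy = 0, northerlies = 0.05),
                       noise_sd = 0.05, noise = c("gaussian", "t5"),
                       cloud_frac = 0.2,
                       stripe_period = 0, stripe_width = 1,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  noise <- match.arg(noise)
  if (is.null(zones)) {
    zones <- matrix(1L, rows, cols)
    zones[, seq_len(cols) > cols / 2] <- 2L
  }
  k <- max(zones)
  if (any(tabulate(zones, k) == 0L)) stop("every zone must contain pixels")
  if (length(baseline) != k || length(slope) != k)
    stop("baseline and slope must have one entry per zone")
  if (cloud_frac < 0 || cloud_frac > 1) stop("cloud_frac must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!all(c("dry", "rainy", "northerlies") %in% names(season_amp)))
    stop("season_amp needs dry, rainy, northerlies entries")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 years = as.integer(years), zones = zones,
                 zone_names = zone_names[seq_len(k)], baseline = baseline,
                 slope = slope, season_amp = season_amp,
                 noise_sd = noise_sd, noise = noise,
                 cloud_frac = cloud_frac,
                 stripe_period = as.integer(stripe_period),
                 stripe_width = as.integer(stripe_width),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# latent noiseless index value per pixel for (year, month)
latent_field <- function(config, year, month, cal = season_calendar()) {
  t_years <- (year - config$years[1]) + (month - 0.5) / 12
  season <- assign_season(month, cal)
  config$baseline[config$zones] + config$slope[config$zones] * t_years +
    config$season_amp[[season]]
}

stripe_mask <- function(config) {
  if (config$stripe_period <= 0)
    return(matrix(FALSE, config$rows, config$cols))
  diag_id <- outer(seq_len(config$rows), seq_len(config$cols), `+`)
  (diag_id %% config$stripe_period) < config$stripe_width
}

#' Simulate a monthly SAVI scene stack with ground truth
#'
#' Per pixel and month:
#' `value = baseline(zone) + slope(zone) * years_elapsed + season(month) + noise`,
#' with cells masked NoData independently at the cloud fraction plus the
#' stripe-gap pattern. Bit-identical under an identical configuration
#' (including seed).
#'
#' @param config a [sim_config()].
#' @param cal a [season_calendar()].
#' @return list with `stack` (a `scene_stack` of SAVI), and `truth`: a
#'   list with per-pixel `slope` and `trend_class` matrices, per-month
#'   noiseless `zone_means` (data.frame), and per-period noiseless
#'   `category_fractions`.
#' @export
simulate_index_stack <- function(config, cal = season_calendar()) {
  stopifnot(inherits(config, "sim_config"))
  meta <- geo_meta(config$rows, config$cols)
  months <- expand.grid(month = 1:12, year = config$years)
  stripes <- stripe_mask(config)
  npx <- config$rows * config$cols
  grids <- vector("list", nrow(months))
  latents <- vector("list", nrow(months))
  withr_seed(config$seed, {
    for (k in seq_len(nrow(months))) {
      lat <- latent_field(config, months$year[k], months$month[k], cal)
      eps <- switch(config$noise,
                    gaussian = stats::rnorm(npx, 0, config$noise_sd),
                    t5 = stats::rt(npx, df = 5) * config$noise_sd)
      v <- matrix(lat + eps, config$rows, config$cols)
      cloud <- matrix(stats::runif(npx) < config$cloud_frac,
                      config$rows, config$cols)
      mask <- !cloud & !stripes
      grids[[k]] <- grid_new(v, valid_mask = mask, meta = meta)
      latents[[k]] <- matrix(lat, config$rows, config$cols)
    }
  })
  stack <- assemble_stack(grids = grids, years = months$year,
                          months = months$month, band_label = "index")

  true_slope <- matrix(config$slope[config$zones], config$rows, config$cols)
  trend_class <- sign(true_slope)
  zone_means <- do.call(rbind, lapply(seq_len(nrow(months)), function(k) {
    lat <- latents[[k]]
    data.frame(year = months$year[k], month = months$month[k],
               zone = config$zone_names,
               mean = vapply(seq_along(config$zone_names), function(z)
                 mean(lat[config$zones == z]), numeric(1)))
  }))
  scheme <- period_scheme(default_periods(config$years))
  cat_frac <- lapply(seq_along(scheme$start), function(p) {
    sel <- months$year >= scheme$start[p] & months$year <= scheme$end[p]
    med <- apply(simplify2array(latents[sel]), c(1, 2), stats::median)
    tabulate(findInterval(med, category_scheme()$breakpoints) + 1L,
             nbins = 5L) / npx
  })
  names(cat_frac) <- scheme$label
  list(stack = stack,
       truth = list(slope = true_slope, trend_class = trend_class,
                    zone_means = zone_means,
                    category_fractions = cat_frac,
                    latent = latents))
}

default_periods <- function(years) {
  starts <- years[seq(1, length(years), by = 2)]
  lapply(starts, function(s) c(s, min(s + 1, max(years))))
}

#' Invert SAVI to a consistent reflectance pair
#'
#' Chooses a red reflectance per pixel and solves the SAVI definition
#' for the near-infrared band, so that `savi(nir, red, L)` reproduces
#' the target exactly:
#' `nir = (red * (1 + L) + s * (red + L)) / (1 + L - s)`.
#' A QA grid is emitted whose cloud bit (bit 3) is set exactly where the
#' target is NoData. With `as_dn = TRUE` the pair is quantised to
#' Collection-2 digital numbers (`DN = round((refl + 0.2) / 0.0000275)`)
#' to exercise the full scaling path; quantisation then limits the
#' round-trip accuracy to about 1e-4 in the index.
#'
#' @param target_savi a `dune_grid` of index values in (-(1+L), 1+L).
#' @param L soil adjustment factor.
#' @param red_range range the red reflectance is drawn from.
#' @param seed RNG seed for the red draw.
#' @param as_dn emit unsigned-integer digital numbers instead of
#'   reflectance.
#' @return list of `dune_grid`s: `nir`, `red`, `qa`.
#' @export
simulate_reflectance_pair <- function(target_savi, L = 0.5,
                                      red_range = c(0.05, 0.15), seed = 1L,
                                      as_dn = FALSE) {
  stopifnot(inherits(target_savi, "dune_grid"))
  s <- target_savi$values
  if (any(abs(s[target_savi$valid_mask]) >= 1 + L))
    stop(sprintf("target SAVI must lie strictly within (-%g, %g)", 1 + L, 1 + L))
  meta <- target_savi$meta
  npx <- meta$rows * meta$cols
  red <- withr_seed(seed, matrix(stats::runif(npx, red_range[1], red_range[2]),
                                 meta$rows, meta$cols))
  s0 <- s; s0[!target_savi$valid_mask] <- 0
  nir <- (red * (1 + L) + s0 * (red + L)) / (1 + L - s0)
  qa_v <- matrix(0, meta$rows, meta$cols)
  qa_v[!target_savi$valid_mask] <- 8  # bit 3: cloud
  if (as_dn) {
    red <- round((red + 0.2) / 0.0000275)
    nir <- round((nir + 0.2) / 0.0000275)
  }
  list(nir = grid_new(nir, meta = meta),
       red = grid_new(red, meta = meta),
       qa = grid_new(qa_v, meta = meta))
}

#' Simulate a monthly climate table
#'
#' Monthly maximum/minimum temperature and precipitation with the
#' regional seasonal structure: cooler northerlies (defaults near the
#' observed 17.4-23.1 degC northerlies range against 27.8-32 degC in the
#' other seasons) and a wet rainy season. Gaussian month-to-month noise;
#' `tmx >= tmn` is enforced by construction. An optional `coupling` adds
#' a response column linearly driven by standardized covariates, for
#' attribution power and calibration experiments.
#'
#' @param years integer years.
#' @param cal a [season_calendar()].
#' @param seed RNG seed.
#' @param tmx_mean,tmn_mean,prep_mean named per-season means
#'   (degC, degC, mm).
#' @param sd_temp,sd_prep noise standard deviations.
#' @param coupling optional named coefficients over
#'   `c(tmx_c, tmn_c, prep_mm)` producing a `response` column.
#' @param response_noise sd of the response residual.
#' @return data.frame with year, month, season, tmx_c, tmn_c, prep_mm
#'   (and `response` when coupled).
#' @export
simulate_climate <- function(years = 2011:2020, cal = season_calendar(),
                             seed = 1L,
                             tmx_mean = c(dry = 31, rainy = 32, northerlies = 23.1),
                             tmn_mean = c(dry = 24, rainy = 25, northerlies = 17.4),
                             prep_mean = c(dry = 30, rainy = 150, northerlies = 80),
                             sd_temp = 0.8, sd_prep = 25,
                             coupling = NULL, response_noise = 1) {
  months <- expand.grid(month = 1:12, year = years)
  season <- assign_season(months$month, cal)
  n <- nrow(months)
  withr_seed(seed, {
    tmx <- tmx_mean[season] + stats::rnorm(n, 0, sd_temp)
    tmn <- tmn_mean[season] + stats::rnorm(n, 0, sd_temp)
    tmn <- pmin(tmn, tmx - 0.1)
    prep <- pmax(0, prep_mean[season] + stats::rnorm(n, 0, sd_prep))
    out <- data.frame(year = months$year, month = months$month,
                      season = season, tmx_c = as.numeric(tmx),
                      tmn_c = as.numeric(tmn), prep_mm = prep)
    if (!is.null(coupling)) {
      covs <- scale(as.matrix(out[, c("tmx_c", "tmn_c", "prep_mm")]))
      beta <- c(tmx_c = 0, tmn_c = 0, prep_mm = 0)
      beta[names(coupling)] <- coupling
      out$response <- as.numeric(covs %*% beta) +
        stats::rnorm(n, 0, response_noise)
    }
    out
  })
}

#' Write a climate table in the TerraClimate storage convention
#'
#' Temperatures are stored x10 (so [read_climate()] recovers degrees
#' Celsius with its 0.1 gain); precipitation is stored as-is.
#'
#' @param climate data.frame from [simulate_climate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_climate <- function(climate, path) {
  utils::write.csv(data.frame(year = climate$year, month = climate$month,
                              tmx = round(climate$tmx_c * 10),
                              tmn = round(climate$tmn_c * 10),
                              prep = round(climate$prep_mm, 1)),
                   path, row.names = FALSE)
  invisible(path)
}
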