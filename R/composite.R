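#' Climatic season calendar for the Yucatan coast
#'
#' Three seasons partition the calendar year: dry (March-May), rainy
#' (June-October), and the northerlies (November-February), the season of
#' polar air-mass intrusions. The three month sets must partition 1..12.
#'
#' @param dry_months,rainy_months,northerlies_months integer month sets.
#' @return an object of class `season_calendar`.
#' @export
season_calendar <- function(dry_months = 3:5, rainy_months = 6:10,
                            northerlies_months = c(11, 12, 1, 2)) {
  all_m <- sort(c(dry_months, rainy_months, northerlies_months))
  if (!identical(as.integer(all_m), 1:12))
    stop("season month sets must partition 1..12")
  structure(list(dry = as.integer(dry_months),
                 rainy = as.integer(rainy_months),
                 northerlies = as.integer(northerlies_months)),
            class = "season_calendar")
}

#' Season of a calendar month
#'
#' @param month integer vector of months in 1..12.
#' @param cal a [season_calendar()].
#' @return character vector: `"dry"`, `"rainy"` or `"northerlies"`.
#' @export
assign_season <- function(month, cal = season_calendar()) {
  if (any(is.na(month)) || any(month < 1 | month > 12) ||
      any(month != round(month)))
    stop("month must be in 1..12")
  out <- character(length(month))
  out[month %in% cal$dry] <- "dry"
  out[month %in% cal$rainy] <- "rainy"
  out[month %in% cal$northerlies] <- "northerlies"
  out
}

#' Year attribution of a season occurrence
#'
#' A northerlies season straddles the calendar boundary (Nov Y .. Feb
#' Y+1) and is labeled by its starting year: January and February of
#' year Y belong to "northerlies Y-1". Dry and rainy seasons keep the
#' calendar year.
#'
#' @param year,month integer vectors.
#' @param cal a [season_calendar()].
#' @return integer vector of season years.
#' @export
season_year <- function(year, month, cal = season_calendar()) {
  s <- assign_season(month, cal)
  ifelse(s == "northerlies" & month <= 2, as.integer(year) - 1L,
         as.integer(year))
}

#' Biannual period scheme
#'
#' @param periods list of `c(start_year, end_year)` pairs, default the
#'   five two-year periods spanning 2011-2020.
#' @return an object of class `period_scheme`.
#' @export
period_scheme <- function(periods = list(c(2011, 2012), c(2013, 2014),
                                         c(2015, 2016), c(2017, 2018),
                                         c(2019, 2020))) {
  st <- vapply(periods, `[`, numeric(1), 1)
  en <- vapply(periods, `[`, numeric(1), 2)
  if (any(en < st)) stop("period end before start")
  if (is.unsorted(st, strictly = TRUE) || any(st[-1] <= en[-length(en)]))
    stop("periods must be ascending and non-overlapping")
  structure(list(start = as.integer(st), end = as.integer(en),
                 label = sprintf("%d-%d", st, en)),
            class = "period_scheme")
}

#' Per-pixel median composite over selected scenes
#'
#' The per-pixel median over valid observations at the selected
#' timestamps; a pixel with no valid observation anywhere in the
#' selection is NoData. Even counts take the midpoint of the two central
#' values. The median is used because it resists outliers and partial
#' cloud gaps.
#'
#' @param stack a `scene_stack`.
#' @param select integer indices into the stack, or a logical vector, or
#'   a 2-column matrix/data.frame of (year, month) pairs; default all.
#' @param min_obs minimum valid observations per pixel (default 1);
#'   pixels below it are NoData.
#' @return a `dune_grid`.
#' @export
median_composite <- function(stack, select = NULL, min_obs = 1L) {
  stopifnot(inherits(stack, "scene_stack"))
  idx <- resolve_selection(stack, select)
  if (length(idx) == 0L) stop("empty scene selection")
  a <- stack_array(stack)[, , idx, drop = FALSE]
  n_ok <- apply(!is.na(a), c(1, 2), sum)
  med <- apply(a, c(1, 2), stats::median, na.rm = TRUE)
  mask <- n_ok >= min_obs
  med[!mask] <- NA_real_
  grid_new(med, valid_mask = mask, meta = stack$grids[[1]]$meta)
}

resolve_selection <- function(stack, select) {
  n <- stack_length(stack)
  if (is.null(select)) return(seq_len(n))
  if (is.logical(select)) {
    if (length(select) != n) stop("logical selector length mismatch")
    return(which(select))
  }
  if (is.matrix(select) || is.data.frame(select)) {
    key <- stack$timestamps$year * 12L + stack$timestamps$month
    want <- as.integer(select[, 1]) * 12L + as.integer(select[, 2])
    idx <- match(want, key)
    if (anyNA(idx)) stop("selection includes timestamps absent from the stack")
    return(idx)
  }
  idx <- as.integer(select)
  if (any(idx < 1L | idx > n)) stop("scene index out of range")
  idx
}

#' Biannual median layers
#'
#' One median composite per period of the scheme, over every scene whose
#' year falls in the period (five layers for the default 2011-2020
#' scheme).
#'
#' @param stack a `scene_stack`.
#' @param scheme a [period_scheme()].
#' @param min_obs per-pixel minimum observation count per layer.
#' @return named list of `dune_grid`s, one per period label.
#' @export
biannual_layers <- function(stack, scheme = period_scheme(), min_obs = 1L) {
  stopifnot(inherits(stack, "scene_stack"), inherits(scheme, "period_scheme"))
  out <- vector("list", length(scheme$start))
  names(out) <- scheme$label
  for (k in seq_along(scheme$start)) {
    sel <- stack$timestamps$year >= scheme$start[k] &
           stack$timestamps$year <= scheme$end[k]
    if (!any(sel))
      stop(sprintf("period %s has no scenes in the stack", scheme$label[k]))
    out[[k]] <- median_composite(stack, select = sel, min_obs = min_obs)
  }
  out
}

#' Monthly zone summaries labeled by season
#'
#' For each scene, the mean and median of valid pixels inside the zone;
#' these zone-level monthly summaries are the sampling unit for the
#' seasonal rank tests. A month with no valid pixel in the zone yields an
#' NA summary row (kept, so the time axis stays complete).
#'
#' @param stack a `scene_stack` of index values.
#' @param zone_mask logical matrix (or `dune_grid`) selecting the zone.
#' @param cal a [season_calendar()].
#' @return data.frame with columns year, month, season, season_year,
#'   mean, median, n_valid.
#' @export
seasonal_series <- function(stack, zone_mask = NULL, cal = season_calendar()) {
  stopifnot(inherits(stack, "scene_stack"))
  m <- stack$grids[[1]]$meta
  if (is.null(zone_mask)) zone_mask <- matrix(TRUE, m$rows, m$cols)
  if (inherits(zone_mask, "dune_grid")) {
    stop_if_misaligned(stack$grids[[1]], zone_mask, "stack and zone mask")
    zone_mask <- zone_mask$valid_mask & zone_mask$values != 0
  }
  if (!identical(dim(zone_mask), c(m$rows, m$cols)))
    stop("zone_mask shape does not match the stack")
  ts <- stack$timestamps
  n <- nrow(ts)
  mean_v <- med_v <- rep(NA_real_, n)
  n_valid <- integer(n)
  for (k in seq_len(n)) {
    g <- stack$grids[[k]]
    sel <- g$valid_mask & zone_mask
    n_valid[k] <- sum(sel)
    if (n_valid[k] > 0) {
      x <- g$values[sel]
      mean_v[k] <- mean(x)
      med_v[k] <- stats::median(x)
    }
  }
  data.frame(year = ts$year, month = ts$month,
             season = assign_season(ts$month, cal),
             season_year = season_year(ts$year, ts$month, cal),
             mean = mean_v, median = med_v, n_valid = n_valid)
}
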