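#' Vegetation-density category scheme for SAVI
#'
#' Five density classes cut the SAVI range at 0, 0.25, 0.35 and 0.45:
#' 1 Bare Soil and/or Water (below 0), 2 Low-Density (herbaceous and
#' creeping), 3 Medium-Low (shrubby), 4 Medium-High (shrubby-arboreal),
#' 5 High-Density Vegetation (arboreal, including mangrove). Intervals
#' are lower-closed / upper-open; classes 1 and 5 are unbounded so any
#' index value classifies.
#'
#' @param breakpoints strictly increasing thresholds delimiting 5
#'   classes.
#' @param labels character length-5 class names.
#' @return an object of class `category_scheme`.
#' @export
category_scheme <- function(breakpoints = c(0, 0.25, 0.35, 0.45),
                            labels = c("Bare Soil/Water",
                                       "Low-Density Vegetation",
                                       "Medium-Low-Density Vegetation",
                                       "Medium-High-Density Vegetation",
                                       "High-Density Vegetation")) {
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  if (length(labels) != length(breakpoints) + 1L)
    stop("need one more label than breakpoints")
  structure(list(breakpoints = as.numeric(breakpoints), labels = labels),
            class = "category_scheme")
}

#' Classify a SAVI layer into density categories
#'
#' Code `k` means the value lies in `[breakpoints[k-1], breakpoints[k])`
#' (lower-closed), with code 1 below the first breakpoint and the top
#' code at or above the last. NoData propagates.
#'
#' @param layer a `dune_grid` of SAVI values.
#' @param scheme a [category_scheme()].
#' @return a `dune_grid` of integer codes 1..5 (a category map).
#' @export
classify_savi <- function(layer, scheme = category_scheme()) {
  stopifnot(inherits(layer, "dune_grid"), inherits(scheme, "category_scheme"))
  codes <- findInterval(layer$values, scheme$breakpoints) + 1
  codes <- matrix(as.numeric(codes), nrow(layer$values), ncol(layer$values))
  codes[!layer$valid_mask] <- NA_real_
  g <- grid_new(codes, valid_mask = layer$valid_mask, meta = layer$meta)
  attr(g, "scheme") <- scheme
  g
}

#' Percent cover by density category
#'
#' Percent of *valid* pixels per category (cloud-masked pixels are
#' excluded from the denominator); all categories are reported, zeros
#' included, and percentages sum to 100. Area is pixel count times the
#' pixel area (0.09 ha at 30 m).
#'
#' @param catmap a category map from [classify_savi()].
#' @param scheme the [category_scheme()]; defaults to the map's attached
#'   scheme.
#' @param period optional period label carried into the table.
#' @return a `cover_table` data.frame with columns period, category,
#'   label, count, percent, area_ha and attribute `n_valid`.
#' @export
cover_percentages <- function(catmap, scheme = NULL, period = NA_character_) {
  stopifnot(inherits(catmap, "dune_grid"))
  if (is.null(scheme)) scheme <- attr(catmap, "scheme")
  if (is.null(scheme)) scheme <- category_scheme()
  n_cat <- length(scheme$labels)
  codes <- catmap$values[catmap$valid_mask]
  n_valid <- length(codes)
  if (n_valid == 0L) stop("category map has no valid pixels")
  count <- tabulate(codes, nbins = n_cat)
  out <- data.frame(period = period, category = seq_len(n_cat),
                    label = scheme$labels, count = count,
                    percent = 100 * count / n_valid,
                    area_ha = count * catmap$meta$pixel_size^2 / 1e4)
  attr(out, "n_valid") <- n_valid
  attr(out, "scheme") <- scheme
  class(out) <- c("cover_table", "data.frame")
  out
}

#' Biannual cover change (percentage points per category)
#'
#' `IVMd = IVM2 - IVM1`: the later period's percent cover minus the
#' earlier's, per category. When both tables sum to 100 the differences
#' sum to 0.
#'
#' @param later,earlier `cover_table`s sharing a category scheme.
#' @return a `change_table` data.frame with columns period_pair,
#'   category, label, diff_pp.
#' @export
cover_difference <- function(later, earlier) {
  stopifnot(inherits(later, "cover_table"), inherits(earlier, "cover_table"))
  sl <- attr(later, "scheme"); se <- attr(earlier, "scheme")
  if (!isTRUE(all.equal(sl$breakpoints, se$breakpoints)) ||
      !identical(sl$labels, se$labels))
    stop("cover tables use different category schemes")
  out <- data.frame(
    period_pair = sprintf("%s vs %s", later$period[1], earlier$period[1]),
    category = later$category, label = later$label,
    diff_pp = later$percent - earlier$percent)
  class(out) <- c("change_table", "data.frame")
  out
}

#' Pixelwise category-shift map
#'
#' Later code minus earlier code per pixel (range -4..+4 for five
#' classes); NoData where either map is NoData. Positive shifts are
#' densification, negative shifts cover loss.
#'
#' @param later,earlier aligned category maps.
#' @return a `dune_grid` of signed integer shifts.
#' @export
change_map <- function(later, earlier) {
  stopifnot(inherits(later, "dune_grid"), inherits(earlier, "dune_grid"))
  stop_if_misaligned(later, earlier, "category maps")
  mask <- later$valid_mask & earlier$valid_mask
  v <- later$values - earlier$values
  v[!mask] <- NA_real_
  grid_new(v, valid_mask = mask, meta = later$meta)
}
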