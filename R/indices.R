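#' Soil-adjusted vegetation index (SAVI)
#'
#' `SAVI = (Nir - Red) / (Nir + Red + L) * (1 + L)` with the soil
#' adjustment factor `L` (0.5 by default; `L = 0` recovers NDVI). A cell
#' is computed only where both bands are valid; cells with a zero
#' denominator become NoData.
#'
#' @param nir,red aligned `dune_grid`s of surface reflectance.
#' @param L soil adjustment factor, `>= 0`.
#' @return a `dune_grid` of index values.
#' @export
savi <- function(nir, red, L = 0.5) {
  stopifnot(inherits(nir, "dune_grid"), inherits(red, "dune_grid"))
  stop_if_misaligned(nir, red, "nir/red bands")
  if (!is.numeric(L) || length(L) != 1L || L < 0)
    stop("L must be a single non-negative number")
  denom <- nir$values + red$values + L
  mask <- nir$valid_mask & red$valid_mask & !is.na(denom) & denom != 0
  v <- (nir$values - red$values) / denom * (1 + L)
  v[!mask] <- NA_real_
  grid_new(v, valid_mask = mask, meta = nir$meta)
}

#' Normalized difference vegetation index (NDVI)
#'
#' `NDVI = (Nir - Red) / (Nir + Red)`; equals [savi()] with `L = 0`.
#' Bounded in \[-1, 1\] for non-negative reflectances.
#'
#' @inheritParams savi
#' @return a `dune_grid` of index values.
#' @export
ndvi <- function(nir, red) savi(nir, red, L = 0)
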