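#' Scaling specification for stored digital numbers
#'
#' Landsat Collection-2 Level-2 surface reflectance is stored as unsigned
#' integer digital numbers converted to reflectance as
#' `DN * 0.0000275 - 0.2`; TerraClimate temperatures are stored x10 and
#' convert with gain 0.1. `valid_range`, when given, sets cells whose
#' scaled value falls outside it to NoData (a plausibility clamp for
#' saturated or corrupt DNs).
#'
#' @param gain multiplicative factor, non-zero.
#' @param offset additive factor.
#' @param valid_range optional numeric length-2 physical-value bounds.
#' @return an object of class `scaling_spec`.
#' @export
scaling_spec <- function(gain, offset = 0, valid_range = NULL) {
  if (!is.numeric(gain) || length(gain) != 1L || gain == 0)
    stop("gain must be a single non-zero number")
  if (!is.null(valid_range) &&
      (length(valid_range) != 2L || valid_range[1] >= valid_range[2]))
    stop("valid_range must be c(lo, hi) with lo < hi")
  structure(list(gain = as.numeric(gain), offset = as.numeric(offset),
                 valid_range = valid_range), class = "scaling_spec")
}

#' @rdname scaling_spec
#' @param clamp apply the Collection-2 reflectance plausibility clamp
#'   \[-0.2, 1.6\] (default `TRUE`).
#' @export
reflectance_scaling <- function(clamp = TRUE)
  scaling_spec(0.0000275, -0.2,
               valid_range = if (clamp) c(-0.2, 1.6) else NULL)

#' @rdname scaling_spec
#' @export
temperature_scaling <- function() scaling_spec(0.1, 0)

#' Cloud/shadow rule for the QA_PIXEL bitmask
#'
#' Landsat Collection-2 QA_PIXEL layout: bit 3 flags cloud, bit 4 cloud
#' shadow, bits 8-9 hold a 2-bit cloud-confidence level (0 none .. 3
#' high). A pixel is rejected when the cloud or shadow bit is set, or the
#' confidence level reaches `confidence_threshold` (default 3: only
#' high-confidence cloud is masked; lower it to 2 to also drop
#' medium-confidence pixels).
#'
#' @param cloud_bit,shadow_bit bit positions (0-based).
#' @param confidence_bits integer length-2, low and high bit of the
#'   confidence field.
#' @param confidence_threshold minimum confidence level treated as
#'   cloudy, in `{1, 2, 3}`.
#' @return an object of class `qa_rule`.
#' @export
qa_rule <- function(cloud_bit = 3, shadow_bit = 4,
                    confidence_bits = c(8, 9), confidence_threshold = 3) {
  bits <- c(cloud_bit, shadow_bit, confidence_bits)
  if (anyDuplicated(bits)) stop("bit positions must be distinct")
  if (!confidence_threshold %in% 1:3)
    stop("confidence_threshold must be 1, 2 or 3")
  structure(list(cloud_bit = as.integer(cloud_bit),
                 shadow_bit = as.integer(shadow_bit),
                 confidence_bits = as.integer(confidence_bits),
                 confidence_threshold = as.integer(confidence_threshold)),
            class = "qa_rule")
}

#' Decode a QA bitmask grid into a validity grid
#'
#' @param qa a `dune_grid` of non-negative integer bitmask values.
#' @param rule a [qa_rule()].
#' @return a `dune_grid` whose values are 1 (clear) / 0 (contaminated);
#'   its `valid_mask` is `TRUE` exactly where the pixel is usable: clear
#'   of cloud, shadow and high-confidence cloud, and not NoData in `qa`.
#' @export
decode_qa_mask <- function(qa, rule = qa_rule()) {
  stopifnot(inherits(qa, "dune_grid"), inherits(rule, "qa_rule"))
  v <- qa$values
  obs <- v[qa$valid_mask]
  if (any(obs < 0)) stop("QA bitmask values must be non-negative")
  if (any(obs != round(obs))) stop("QA bitmask values must be integers")
  vi <- v; vi[!qa$valid_mask] <- 0
  cloud <- bitwAnd(as.integer(vi), bitwShiftL(1L, rule$cloud_bit)) != 0L
  shadow <- bitwAnd(as.integer(vi), bitwShiftL(1L, rule$shadow_bit)) != 0L
  conf <- bitwAnd(bitwShiftR(as.integer(vi), rule$confidence_bits[1]), 3L)
  bad <- cloud | shadow | conf >= rule$confidence_threshold
  ok <- qa$valid_mask & !matrix(bad, nrow(v), ncol(v))
  grid_new(ifelse(ok, 1, 0), valid_mask = ok, meta = qa$meta)
}

#' Convert stored digital numbers to physical units
#'
#' `value' = value * gain + offset` on valid cells; the mask is unchanged
#' except where an optional `valid_range` clamp marks implausible scaled
#' values NoData.
#'
#' @param raw a `dune_grid` of stored digital numbers.
#' @param spec a [scaling_spec()].
#' @return a `dune_grid` in physical units.
#' @export
apply_scaling <- function(raw, spec) {
  stopifnot(inherits(raw, "dune_grid"), inherits(spec, "scaling_spec"))
  v <- raw$values * spec$gain + spec$offset
  mask <- raw$valid_mask
  if (!is.null(spec$valid_range))
    mask <- mask & !is.na(v) & v >= spec$valid_range[1] & v <= spec$valid_range[2]
  grid_new(v, valid_mask = mask, meta = raw$meta)
}

#' Intersect a band's mask with a validity grid
#'
#' Masking never alters stored values, only validity.
#'
#' @param band a `dune_grid`.
#' @param validity a `dune_grid` from [decode_qa_mask()] (its
#'   `valid_mask` is the validity), or a logical matrix.
#' @return `band` with `valid_mask = band$valid_mask & validity`.
#' @export
mask_scene <- function(band, validity) {
  stopifnot(inherits(band, "dune_grid"))
  if (inherits(validity, "dune_grid")) {
    stop_if_misaligned(band, validity)
    vmask <- validity$valid_mask
  } else if (is.logical(validity) && identical(dim(validity), dim(band$values))) {
    vmask <- validity
  } else stop("validity must be an aligned dune_grid or a logical matrix")
  grid_new(band$values, valid_mask = band$valid_mask & vmask, meta = band$meta)
}
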