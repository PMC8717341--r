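#' Vegetation index registry
#'
#' The 14 indices derived from the five reflectance bands.  Five are the
#' indices that proved meaningful for canopy nitrogen (GDVI, the two
#' normalized-difference indices against NIR, the redness index and
#' VARI); the remaining nine are standard productivity/chlorophyll
#' indices drawn from the vegetation-index literature.  Pixels where a
#' formula's denominator is zero become `NA` rather than infinite.
#'
#' @return Named list of index functions taking the five band matrices.
#' @export
index_registry <- function() {
  nd <- function(a, b) safe_divide(a - b, a + b)
  list(
    # indices reported as meaningful nitrogen predictors
    gdvi = function(b) b$nir - b$green,
    ndi_b_nir = function(b) nd(b$blue, b$nir),
    ndi_re_nir = function(b) nd(b$red_edge, b$nir),
    ri = function(b) nd(b$red, b$green),
    vari = function(b) safe_divide(b$green - b$red, b$green + b$red - b$blue),
    # standard complement to reach the 14-index set
    ndvi = function(b) nd(b$nir, b$red),
    gndvi = function(b) nd(b$nir, b$green),
    ndre = function(b) nd(b$nir, b$red_edge),
    sr = function(b) safe_divide(b$nir, b$red),
    grvi = function(b) safe_divide(b$nir, b$green),
    evi = function(b) safe_divide(2.5 * (b$nir - b$red),
                                  b$nir + 6 * b$red - 7.5 * b$blue + 1),
    ci_green = function(b) safe_divide(b$nir, b$green) - 1,
    ci_rededge = function(b) safe_divide(b$nir, b$red_edge) - 1,
    savi = function(b) safe_divide(1.5 * (b$nir - b$red),
                                   b$nir + b$red + 0.5)
  )
}

safe_divide <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Compute one vegetation index layer
#'
#' @param stack a [band_stack()] containing the five reflectance bands.
#' @param name index identifier; one of `names(index_registry())`.
#' @return The index as a numeric matrix; zero-denominator pixels `NA`.
#' @export
compute_index <- function(stack, name) {
  reg <- index_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown index '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")))
  missing_bands <- setdiff(reflectance_bands(), names(stack$bands))
  if (length(missing_bands))
    stop("missing reflectance band(s): ", paste(missing_bands, collapse = ", "))
  reg[[name]](stack$bands)
}

#' Compute the full 19-layer feature stack
#'
#' Returns the five reflectance bands plus the 14 registry indices, the
#' variable set used by both the nitrogen regression and the habitat
#' classifier.
#'
#' @param stack a [band_stack()] with the five reflectance bands.
#' @return A [band_stack()] with 19 named layers (bands first, then
#'   indices in registry order).
#' @export
compute_feature_stack <- function(stack) {
  reg <- index_registry()
  layers <- c(stack$bands[reflectance_bands()],
              lapply(names(reg), function(nm) compute_index(stack, nm)))
  names(layers) <- c(reflectance_bands(), names(reg))
  band_stack(layers, stack$pixel_size_m, stack$origin)
}

#' Names of the 19 feature layers
#' @return Character vector of layer names in stack order.
#' @export
feature_names <- function() c(reflectance_bands(), names(index_registry()))

#' NDVI foliage mask
#'
#' `TRUE` where `NDVI = (NIR - Red)/(NIR + Red) >= ndvi_min`;
#' zero-denominator pixels are masked out (`FALSE`).
#'
#' @param stack a [band_stack()] with `red` and `nir` layers.
#' @param ndvi_min threshold; pixels at or above it pass.
#' @return Logical matrix.
#' @export
ndvi_mask <- function(stack, ndvi_min) {
  for (b in c("red", "nir"))
    if (!b %in% names(stack$bands)) stop("missing reflectance band(s): ", b)
  ndvi <- safe_divide(stack$bands$nir - stack$bands$red,
                      stack$bands$nir + stack$bands$red)
  out <- !is.na(ndvi) & ndvi >= ndvi_min
  matrix(out, nrow(ndvi), ncol(ndvi))
}
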