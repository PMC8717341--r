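#' Multilayer reflectance raster stack
#'
#' A `band_stack` is the package's raster container: a named list of
#' numeric matrices sharing one grid, plus the pixel size (m) and the
#' scene coordinate of the upper-left corner.  Row 1 is the top of the
#' scene; the x coordinate of column `j`'s center is
#' `origin[1] + (j - 0.5) * pixel_size_m` and the y coordinate of row
#' `i`'s center is `origin[2] - (i - 0.5) * pixel_size_m` (origin
#' upper-left, row-major, as in most orthomosaic exports).
#'
#' @param bands named list of numeric matrices with identical dimensions.
#' @param pixel_size_m pixel edge length in meters (> 0).
#' @param origin numeric length-2, scene x/y of the upper-left corner.
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(bands, pixel_size_m, origin = c(0, nrow(bands[[1]]) * pixel_size_m)) {
  stopifnot(is.list(bands), length(bands) >= 1L,
            !is.null(names(bands)), all(nzchar(names(bands))),
            is.numeric(pixel_size_m), pixel_size_m > 0,
            length(origin) == 2L)
  dims <- vapply(bands, dim, integer(2L))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
    stop("all layers of a band_stack must share the same dimensions")
  structure(list(bands = bands,
                 pixel_size_m = as.numeric(pixel_size_m),
                 origin = as.numeric(origin)),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<band_stack> %d layer(s), %d x %d cells @ %g m\n",
              length(x$bands), d[1], d[2], x$pixel_size_m))
  cat("  layers:", paste(names(x$bands), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.band_stack <- function(x) dim(x$bands[[1]])

#' Get a single layer from a band stack
#'
#' @param stack a [band_stack()].
#' @param name layer name.
#' @return The layer as a numeric matrix.
#' @export
get_band <- function(stack, name) {
  stopifnot(inherits(stack, "band_stack"))
  if (!name %in% names(stack$bands))
    stop(sprintf("band '%s' not present in stack (have: %s)", name,
                 paste(names(stack$bands), collapse = ", ")))
  stack$bands[[name]]
}

#' Names of the five reflectance bands, in storage order
#' @return Character vector `c("blue","green","red","red_edge","nir")`.
#' @export
reflectance_bands <- function() c("blue", "green", "red", "red_edge", "nir")

#' Canopy height model raster
#'
#' Heights in meters above ground on the same grid convention as
#' [band_stack()].
#'
#' @param heights numeric matrix of heights (m, >= 0; NA allowed).
#' @param pixel_size_m pixel edge length in meters.
#' @param origin upper-left corner scene coordinate.
#' @param fill_method free-text metadata on how pits were closed.
#' @return An object of class `chm`.
#' @export
chm <- function(heights, pixel_size_m, origin = c(0, nrow(heights) * pixel_size_m),
                fill_method = "none") {
  stopifnot(is.matrix(heights), is.numeric(pixel_size_m), pixel_size_m > 0)
  if (any(heights < 0, na.rm = TRUE)) stop("CHM heights must be >= 0")
  structure(list(heights = heights, pixel_size_m = as.numeric(pixel_size_m),
                 origin = as.numeric(origin), fill_method = fill_method),
            class = "chm")
}

#' @export
print.chm <- function(x, ...) {
  cat(sprintf("<chm> %d x %d cells @ %g m, max height %.2f m\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size_m,
              max(x$heights, na.rm = TRUE)))
  invisible(x)
}

# scene x/y -> fractional (row, col); inverse of the cell-center map
scene_to_cell <- function(x, y, pixel_size_m, origin) {
  list(row = (origin[2] - y) / pixel_size_m + 0.5,
       col = (x - origin[1]) / pixel_size_m + 0.5)
}

cell_to_scene <- function(row, col, pixel_size_m, origin) {
  list(x = origin[1] + (col - 0.5) * pixel_size_m,
       y = origin[2] - (row - 0.5) * pixel_size_m)
}

#' Write / read a band stack as TIFF with a JSON sidecar
#'
#' Layers are written as a multi-directory 32-bit float TIFF; grid
#' georeferencing (pixel size, origin, layer names) goes to a JSON
#' sidecar next to the TIFF, since plain TIFF carries no geo tags.
#'
#' @param stack a [band_stack()].
#' @param path output `.tif` path; the sidecar is `paste0(path, ".json")`.
#' @return `write_band_stack()` returns `path` invisibly;
#'   `read_band_stack()` returns a [band_stack()].
#' @export
write_band_stack <- function(stack, path) {
  stopifnot(inherits(stack, "band_stack"))
  tiff::writeTIFF(stack$bands, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(layers = names(stack$bands),
         pixel_size_m = stack$pixel_size_m,
         origin = stack$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_band_stack
#' @param path path to a `.tif` written by `write_band_stack()`.
#' @export
read_band_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  layers <- tiff::readTIFF(path, all = TRUE)
  names(layers) <- meta$layers
  band_stack(layers, meta$pixel_size_m, meta$origin)
}
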