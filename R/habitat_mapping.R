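#' Crop a feature stack and CHM to a square home range
#'
#' Cuts an aligned `side_m` x `side_m` window (default 200 m = 4 ha,
#' the folivore home-range scale) centered on a scene coordinate.
#'
#' @param features a [band_stack()].
#' @param canopy a [chm()] on the same grid.
#' @param center numeric length-2 scene coordinate `c(x, y)`.
#' @param side_m window side length (m).
#' @return List with cropped `features` and `canopy`.
#' @export
crop_home_range <- function(features, canopy, center, side_m = 200) {
  stopifnot(inherits(features, "band_stack"), inherits(canopy, "chm"),
            length(center) == 2L, side_m > 0)
  if (!isTRUE(all.equal(features$pixel_size_m, canopy$pixel_size_m)) ||
      !isTRUE(all.equal(features$origin, canopy$origin)))
    stop("feature stack and CHM grids are not aligned")
  px <- features$pixel_size_m
  half <- side_m / 2
  cc <- scene_to_cell(center[1] - half, center[2] + half, px, features$origin)
  r0 <- round(cc$row - 0.5) + 1L
  c0 <- round(cc$col - 0.5) + 1L
  n <- round(side_m / px)
  d <- dim(features)
  if (r0 < 1 || c0 < 1 || r0 + n - 1L > d[1] || c0 + n - 1L > d[2])
    stop("home-range window extends outside the raster")
  rows <- r0:(r0 + n - 1L); cols <- c0:(c0 + n - 1L)
  new_origin <- c(features$origin[1] + (c0 - 1L) * px,
                  features$origin[2] - (r0 - 1L) * px)
  list(
    features = band_stack(lapply(features$bands,
                                 function(b) b[rows, cols, drop = FALSE]),
                          px, new_origin),
    canopy = chm(canopy$heights[rows, cols, drop = FALSE], px, new_origin,
                 canopy$fill_method)
  )
}

#' Predict the per-pixel probability of favorable habitat
#'
#' Applies the binomial classifier to every pixel of the feature stack;
#' pixels with any missing feature value come back `NA`.
#'
#' @param classifier an `rf_classifier`.
#' @param features a [band_stack()] containing all the classifier's
#'   training variables.
#' @return Numeric matrix of class-1 probabilities in `[0, 1]`.
#' @export
predict_probability_raster <- function(classifier, features) {
  stopifnot(inherits(classifier, "rf_classifier"),
            inherits(features, "band_stack"))
  missing_vars <- setdiff(classifier$variables, names(features$bands))
  if (length(missing_vars))
    stop("feature stack lacks classifier variable(s): ",
         paste(missing_vars, collapse = ", "))
  d <- dim(features)
  tab <- as.data.frame(lapply(features$bands[classifier$variables],
                              as.vector))
  names(tab) <- classifier$variables
  out <- rep(NA_real_, nrow(tab))
  ok <- complete.cases(tab)
  if (any(ok)) out[ok] <- predict(classifier, tab[ok, , drop = FALSE])
  matrix(out, d[1], d[2])
}

#' Mask non-canopy pixels by minimum subcanopy height
#'
#' Pixels whose CHM height falls below the field-measured minimum
#' subcanopy height represent understory or ground and are removed
#' (set `NA`) from the probability raster.
#'
#' @param probability probability matrix from
#'   [predict_probability_raster()].
#' @param canopy a [chm()] on the same grid.
#' @param min_subcanopy_height_m masking height (m).
#' @return The masked probability matrix.
#' @export
mask_non_canopy <- function(probability, canopy, min_subcanopy_height_m) {
  stopifnot(inherits(canopy, "chm"))
  if (!all(dim(probability) == dim(canopy$heights)))
    stop("probability raster and CHM grids are not aligned")
  probability[is.na(canopy$heights) |
                canopy$heights < min_subcanopy_height_m] <- NA_real_
  probability
}

#' Classify a masked probability raster into the three habitat classes
#'
#' Probability at or above the operating threshold is favorable (1),
#' below it unfavorable (0); masked pixels are non-habitat (255).
#'
#' @param probability masked probability matrix.
#' @param threshold operating threshold in `[0, 1]` (e.g. from
#'   [operating_threshold()]).
#' @param pixel_size_m pixel edge length (m), carried for area math.
#' @return Object of class `habitat_map`: `probability`, `classes`
#'   (integer matrix with codes 1/0/255), `threshold`, `pixel_size_m`.
#' @export
classify_map <- function(probability, threshold, pixel_size_m) {
  stopifnot(threshold >= 0, threshold <= 1, pixel_size_m > 0)
  classes <- matrix(255L, nrow(probability), ncol(probability))
  classes[!is.na(probability) & probability >= threshold] <- 1L
  classes[!is.na(probability) & probability < threshold] <- 0L
  structure(list(probability = probability, classes = classes,
                 threshold = threshold, pixel_size_m = pixel_size_m),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  tab <- table(factor(x$classes, levels = c(1L, 0L, 255L),
                      labels = c("favorable", "unfavorable", "non_habitat")))
  cat(sprintf("<habitat_map> threshold %.3f | %s\n", x$threshold,
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Summarize a habitat map
#'
#' Mean and SD of the favorable-class probability over canopy pixels,
#' per-class area and fraction of the full extent, and per-class
#' clumpiness.  The three class fractions sum to 100%.
#'
#' @param map a `habitat_map`.
#' @return List: `mean_likelihood`, `sd_likelihood`, and a `classes`
#'   data frame (`class`, `n_pixels`, `area_m2`, `fraction_pct`,
#'   `clumpiness`).
#' @export
summarize_habitat <- function(map) {
  stopifnot(inherits(map, "habitat_map"))
  canopy <- !is.na(map$probability)
  if (!any(canopy)) {
    warning("map has zero canopy pixels; likelihood statistics undefined")
    mean_l <- sd_l <- NA_real_
  } else {
    mean_l <- mean(map$probability[canopy])
    sd_l <- sd(map$probability[canopy])
  }
  total <- length(map$classes)
  px_area <- map$pixel_size_m^2
  codes <- c(favorable = 1L, unfavorable = 0L, non_habitat = 255L)
  classes <- do.call(rbind, lapply(names(codes), function(nm) {
    n <- sum(map$classes == codes[[nm]])
    data.frame(class = nm, n_pixels = n, area_m2 = n * px_area,
               fraction_pct = 100 * n / total,
               clumpiness = clumpiness(map$classes, codes[[nm]]))
  }))
  list(mean_likelihood = mean_l, sd_likelihood = sd_l, classes = classes)
}

#' Clumpiness: landscape aggregation of one class
#'
#' The FRAGSTATS CLUMPY metric under rook (4-neighbor) adjacency with
#' double counting and no background exclusion: with `G` the class's
#' like-adjacency proportion and `P` its landscape proportion,
#' `CLUMPY = (G - P) / (1 - P)` when `G >= P` or `P >= 0.5`, else
#' `(G - P) / P`.  A class filling the landscape is 1 by convention;
#' an absent class is `NA`.  A checkerboard scores -1, a solid block
#' near +1.
#'
#' @param classes integer class matrix.
#' @param class_id class code to evaluate.
#' @return Clumpiness in `[-1, 1]`.
#' @export
clumpiness <- function(classes, class_id) {
  stopifnot(length(classes) > 0)
  is_c <- classes == class_id
  n_c <- sum(is_c)
  if (n_c == 0L) return(NA_real_)
  p <- n_c / length(classes)
  if (p == 1) return(1)
  nr <- nrow(is_c); nc <- ncol(is_c)
  # double-counted rook adjacencies: horizontal + vertical pairs, x2
  like <- 0L; tot <- 0L
  if (nc > 1L) {
    a <- is_c[, -nc, drop = FALSE]; b <- is_c[, -1L, drop = FALSE]
    like <- like + 2L * sum(a & b)       # each like pair seen from both sides
    tot <- tot + sum(a) + sum(b)         # class cells with a right/left neighbor
  }
  if (nr > 1L) {
    a <- is_c[-nr, , drop = FALSE]; b <- is_c[-1L, , drop = FALSE]
    like <- like + 2L * sum(a & b)
    tot <- tot + sum(a) + sum(b)
  }
  if (tot == 0L) return(NA_real_)  # isolated single cell on a 1x1 grid
  g <- like / tot
  if (g >= p || p >= 0.5) (g - p) / (1 - p) else (g - p) / p
}

#' Bitterlich expansion: trees per hectare represented by one tally
#'
#' In variable-radius (Bitterlich) point sampling each tallied tree of
#' diameter `d` represents `10000 / (pi * c^2 * d^2)` trees per
#' hectare, with `c` the gauge expansion factor (25 for a basal area
#' factor of 4).
#'
#' @param dbh_m tree diameter at breast height (m, > 0).
#' @param c expansion factor (> 0).
#' @return Represented trees per hectare (vectorized over `dbh_m`).
#' @export
bitterlich_expansion <- function(dbh_m, c = 25) {
  stopifnot(c > 0)
  if (any(dbh_m <= 0)) stop("dbh_m must be positive")
  10000 / (pi * c^2 * dbh_m^2)
}
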