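#' Rasterize height points into a pit-filled canopy height model
#'
#' Each point is splatted as a disk of radius `subcircle_radius_m`; a
#' cell takes the maximum height of all disks covering its center, and
#' cells covered by no disk are 0.  Splatting point returns as small
#' disks closes empty cells (pits) in the gridded surface.
#'
#' @param points data frame with columns `x`, `y`, `z` (heights, m).
#' @param pixel_size_m output resolution (m); the canonical field value
#'   is 0.5 m.
#' @param subcircle_radius_m disk radius per point (m); 0 splats the
#'   containing cell only.
#' @param extent_m optional square extent (m) with origin `c(0,
#'   extent_m)`; if `NULL` the grid is fitted to the points plus the
#'   disk radius.
#' @return A [chm()].
#' @export
rasterize_chm <- function(points, pixel_size_m, subcircle_radius_m = 0,
                          extent_m = NULL) {
  stopifnot(nrow(points) >= 1, pixel_size_m > 0, subcircle_radius_m >= 0,
            all(c("x", "y", "z") %in% names(points)))
  r <- subcircle_radius_m
  if (is.null(extent_m)) {
    x0 <- floor((min(points$x) - r) / pixel_size_m) * pixel_size_m
    y1 <- ceiling((max(points$y) + r) / pixel_size_m) * pixel_size_m
    nc <- max(1L, ceiling((max(points$x) + r - x0) / pixel_size_m))
    nr <- max(1L, ceiling((y1 - (min(points$y) - r)) / pixel_size_m))
    origin <- c(x0, y1)
  } else {
    nr <- nc <- round(extent_m / pixel_size_m)
    origin <- c(0, nr * pixel_size_m)
  }
  heights <- matrix(0, nr, nc)
  for (p in seq_len(nrow(points))) {
    cc <- scene_to_cell(points$x[p], points$y[p], pixel_size_m, origin)
    rows <- max(1L, floor(cc$row - r / pixel_size_m - 1)):
      min(nr, ceiling(cc$row + r / pixel_size_m + 1))
    cols <- max(1L, floor(cc$col - r / pixel_size_m - 1)):
      min(nc, ceiling(cc$col + r / pixel_size_m + 1))
    dr <- (rows - cc$row) * pixel_size_m
    dc <- (cols - cc$col) * pixel_size_m
    d2 <- outer(dr^2, dc^2, "+")
    if (r > 0) {
      hit <- d2 <= r^2
    } else {
      # radius 0: exactly the cell containing the point
      hit <- outer(rows == pmin(nr, pmax(1L, floor(cc$row + 0.5))),
                   cols == pmin(nc, pmax(1L, floor(cc$col + 0.5))), "&")
    }
    if (any(hit)) {
      blk <- heights[rows, cols, drop = FALSE]
      blk[hit] <- pmax(blk[hit], points$z[p])
      heights[rows, cols] <- blk
    }
  }
  chm(heights, pixel_size_m, origin,
      fill_method = sprintf("subcircle r=%g m", r))
}

#' Fit a height-to-crown-width allometry from field measurements
#'
#' Ordinary least squares of mean crown width on tree height; predicted
#' widths are floored at a positive minimum.  The fitted function
#' informs the variable search window of [detect_trees()].
#'
#' @param trees data frame with columns `height_m`, `crown_width_m`.
#' @param min_width_m floor for predicted widths (m).
#' @return Object of class `crown_width_model` with `intercept`,
#'   `slope`, `min_width_m`, and the underlying `lm` fit.
#' @export
fit_crown_width_model <- function(trees, min_width_m = 1) {
  stopifnot(all(c("height_m", "crown_width_m") %in% names(trees)))
  ok <- complete.cases(trees[, c("height_m", "crown_width_m")])
  trees <- trees[ok, ]
  if (nrow(trees) < 2 || length(unique(trees$height_m)) < 2)
    stop("need at least 2 trees with distinct heights to fit the allometry")
  fit <- lm(crown_width_m ~ height_m, data = trees)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 min_width_m = min_width_m, fit = fit),
            class = "crown_width_model")
}

#' @export
predict.crown_width_model <- function(object, newdata, ...) {
  h <- if (is.data.frame(newdata)) newdata$height_m else newdata
  pmax(object$min_width_m, object$intercept + object$slope * h)
}

#' @export
print.crown_width_model <- function(x, ...) {
  cat(sprintf("<crown_width_model> width = %.3f + %.4f * height (floor %g m)\n",
              x$intercept, x$slope, x$min_width_m))
  invisible(x)
}

#' Detect dominant trees with a variable-window local-maximum filter
#'
#' A cell is a tree marker iff its height is at least `min_height_m` and
#' it is the maximum within the square window whose width is
#' `window_fn(height)` meters (typically the predicted crown width at
#' that height), clamped to at least 3 cells.  Equal-height plateau
#' cells that pass the filter and touch (8-neighborhood) are merged and
#' the cell nearest the plateau centroid becomes the marker, which keeps
#' the result deterministic and orientation-independent.
#'
#' @param chm a [chm()].
#' @param window_fn function mapping height (m) to window width (m);
#'   e.g. `function(h) predict(cw_model, h)`.
#' @param min_height_m minimum marker height (m).
#' @return Data frame of markers: `row`, `col`, `x`, `y`, `height_m`
#'   (possibly 0 rows).
#' @export
detect_trees <- function(chm, window_fn, min_height_m = 2) {
  stopifnot(inherits(chm, "chm"), is.function(window_fn))
  h <- chm$heights
  px <- chm$pixel_size_m
  w_m <- window_fn(ifelse(is.na(h) | h < min_height_m, min_height_m, h))
  if (any(w_m <= 0, na.rm = TRUE))
    stop("window_fn must be positive over observed heights")
  w_cells <- pmax(3L, as.integer(ceiling(w_m / px)))
  hw <- matrix(pmax(1L, w_cells %/% 2L), nrow(h), ncol(h))
  cand <- local_max_candidates(h, hw, min_height_m)
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(), col = integer(), x = numeric(),
                      y = numeric(), height_m = numeric()))
  # merge touching equal-height plateau candidates
  comp <- seq_len(nrow(idx))
  if (nrow(idx) > 1L) {
    for (a in seq_len(nrow(idx) - 1L)) {
      for (b in (a + 1L):nrow(idx)) {
        if (abs(idx[a, 1] - idx[b, 1]) <= 1L &&
            abs(idx[a, 2] - idx[b, 2]) <= 1L &&
            h[idx[a, , drop = FALSE]] == h[idx[b, , drop = FALSE]]) {
          old <- comp[b]
          comp[comp == old] <- comp[a]
        }
      }
    }
  }
  rows <- integer(0); cols <- integer(0)
  for (g in unique(comp)) {
    members <- idx[comp == g, , drop = FALSE]
    ctr <- colMeans(members)
    pick <- which.min((members[, 1] - ctr[1])^2 + (members[, 2] - ctr[2])^2)
    rows <- c(rows, members[pick, 1])
    cols <- c(cols, members[pick, 2])
  }
  ord <- order(rows, cols)
  rows <- rows[ord]; cols <- cols[ord]
  sc <- cell_to_scene(rows, cols, px, chm$origin)
  data.frame(row = rows, col = cols, x = sc$x, y = sc$y,
             height_m = h[cbind(rows, cols)])
}

#' Match detected markers to surveyed trees by position
#'
#' Assigns each marker the `tree_id` of the nearest surveyed tree
#' (within `max_dist_m`), the programmatic counterpart of
#' cross-referencing detected crowns against GPS-located sample trees.
#' Markers with no tree in range are dropped with a warning.
#'
#' @param markers data frame from [detect_trees()].
#' @param trees tree table with `tree_id`, `x`, `y`.
#' @param max_dist_m maximum matching distance (m).
#' @return `markers` with a `tree_id` column, one row per matched tree
#'   (the nearest marker wins when several match the same tree).
#' @export
match_markers_to_trees <- function(markers, trees, max_dist_m = 5) {
  stopifnot(all(c("x", "y") %in% names(markers)),
            all(c("tree_id", "x", "y") %in% names(trees)))
  if (nrow(markers) == 0L) return(cbind(markers, tree_id = integer(0)))
  d2 <- outer(markers$x, trees$x, "-")^2 + outer(markers$y, trees$y, "-")^2
  nearest <- apply(d2, 1, which.min)
  dist <- sqrt(d2[cbind(seq_len(nrow(markers)), nearest)])
  markers$tree_id <- trees$tree_id[nearest]
  markers$match_dist_m <- dist
  drop <- dist > max_dist_m
  if (any(drop)) {
    warning(sum(drop), " marker(s) had no surveyed tree within ",
            max_dist_m, " m and were dropped")
    markers <- markers[!drop, , drop = FALSE]
  }
  # nearest marker wins when several claim one tree
  markers <- markers[order(markers$match_dist_m), , drop = FALSE]
  markers <- markers[!duplicated(markers$tree_id), , drop = FALSE]
  markers <- markers[order(markers$row, markers$col), , drop = FALSE]
  rownames(markers) <- NULL
  markers
}

#' Delineate tree crowns by marker-controlled watershed
#'
#' Priority-flood watershed on the height surface seeded at the supplied
#' markers (4-neighbor connectivity); cells below `min_height_m` stay
#' unlabeled.  Every marker yields one segment; segments are disjoint
#' and each contains its marker at its apex.
#'
#' @param chm a [chm()].
#' @param markers data frame with `row`, `col` (from [detect_trees()]),
#'   optionally `tree_id`.
#' @param min_height_m cells below this height stay unlabeled.
#' @return Object of class `crown_segments`: a list with `segments` (one
#'   per marker: `tree_id`, `marker`, `cells` matrix, `apex_height_m`,
#'   `polygon` convex-hull outline in scene coordinates) and `labels`
#'   (the integer label raster; 0 = unlabeled).
#' @export
segment_crowns <- function(chm, markers, min_height_m = 2) {
  stopifnot(inherits(chm, "chm"), nrow(markers) >= 1,
            all(c("row", "col") %in% names(markers)))
  h <- chm$heights
  if (any(markers$row < 1 | markers$row > nrow(h) |
          markers$col < 1 | markers$col > ncol(h)))
    stop("markers must lie within the raster")
  mh <- h[cbind(markers$row, markers$col)]
  if (any(is.na(mh) | mh < min_height_m))
    stop("marker(s) below min_height_m: ",
         paste(which(is.na(mh) | mh < min_height_m), collapse = ", "))
  ids <- if ("tree_id" %in% names(markers)) markers$tree_id
         else seq_len(nrow(markers))
  seeds <- matrix(0L, nrow(h), ncol(h))
  seeds[cbind(markers$row, markers$col)] <- seq_len(nrow(markers))
  labels <- watershed_flood(h, seeds, min_height_m)
  segments <- lapply(seq_len(nrow(markers)), function(k) {
    cells <- which(labels == k, arr.ind = TRUE)
    sc <- cell_to_scene(cells[, 1], cells[, 2], chm$pixel_size_m, chm$origin)
    pts <- cbind(sc$x, sc$y)
    hull <- if (nrow(pts) >= 3L) pts[grDevices::chull(pts), , drop = FALSE]
            else pts
    list(tree_id = ids[k],
         marker = c(row = markers$row[k], col = markers$col[k]),
         cells = cells,
         apex_height_m = max(h[cells], na.rm = TRUE),
         polygon = hull)
  })
  structure(list(segments = segments, labels = labels,
                 pixel_size_m = chm$pixel_size_m, origin = chm$origin),
            class = "crown_segments")
}

#' @export
print.crown_segments <- function(x, ...) {
  cat(sprintf("<crown_segments> %d crown(s), %d labeled cells\n",
              length(x$segments), sum(x$labels > 0)))
  invisible(x)
}

#' Override delineated crowns with externally supplied polygons
#'
#' Replaces the cells of named segments with the cells whose centers
#' fall inside a supplied polygon (even-odd rule), the programmatic
#' counterpart of manual crown correction by image interpretation.
#'
#' @param segments a `crown_segments` object.
#' @param overrides named list (by `tree_id`) of polygon matrices with
#'   columns x, y in scene coordinates.
#' @return The updated `crown_segments`.
#' @export
apply_crown_overrides <- function(segments, overrides) {
  stopifnot(inherits(segments, "crown_segments"))
  nr <- nrow(segments$labels); nc <- ncol(segments$labels)
  cells_all <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  sc <- cell_to_scene(cells_all$row, cells_all$col,
                      segments$pixel_size_m, segments$origin)
  for (nm in names(overrides)) {
    k <- which(vapply(segments$segments, function(s) s$tree_id == nm ||
                        identical(as.character(s$tree_id), nm), logical(1)))
    if (length(k) != 1L) stop("no unique segment with tree_id ", nm)
    poly <- overrides[[nm]]
    inside <- point_in_polygon(sc$x, sc$y, poly[, 1], poly[, 2])
    cells <- as.matrix(cells_all[inside, , drop = FALSE])
    segments$labels[segments$labels == k] <- 0L
    segments$labels[cells] <- k
    segments$segments[[k]]$cells <- cells
    segments$segments[[k]]$polygon <- poly
  }
  segments
}

# even-odd ray-casting point-in-polygon
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
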