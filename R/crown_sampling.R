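#' Extract foliage pixels of one crown under the NDVI mask
#'
#' Takes every cell of the crown segment whose NDVI passes the mask
#' threshold and returns its 19 feature values.  Pixels with any
#' missing feature are dropped so each row carries a complete feature
#' vector.  A fully masked crown yields an empty table with a warning.
#'
#' @param features a 19-layer [band_stack()] from
#'   [compute_feature_stack()].
#' @param crown one element of `crown_segments$segments`.
#' @param ndvi_min NDVI mask threshold for this tree.
#' @return Data frame: `tree_id`, `row`, `col`, then one column per
#'   feature layer.
#' @export
extract_crown_pixels <- function(features, crown, ndvi_min = 0.6) {
  stopifnot(inherits(features, "band_stack"))
  cells <- crown$cells
  d <- dim(features)
  if (nrow(cells) > 0 &&
      (any(cells[, 1] < 1 | cells[, 1] > d[1]) ||
       any(cells[, 2] < 1 | cells[, 2] > d[2])))
    stop("crown extends outside the feature raster")
  mask <- ndvi_mask(features, ndvi_min)
  keep <- mask[cells]
  cells <- cells[keep, , drop = FALSE]
  vals <- matrix(NA_real_, nrow(cells), length(features$bands),
                 dimnames = list(NULL, names(features$bands)))
  for (nm in names(features$bands))
    vals[, nm] <- features$bands[[nm]][cells]
  out <- data.frame(tree_id = rep(crown$tree_id, nrow(cells)),
                    row = cells[, 1], col = cells[, 2], vals,
                    check.names = FALSE)
  out <- out[complete.cases(out), , drop = FALSE]
  if (nrow(out) == 0L)
    warning(sprintf("crown %s has no unmasked foliage pixels",
                    as.character(crown$tree_id)))
  rownames(out) <- NULL
  out
}

#' Subsample pixels per tree without replacement
#'
#' Draws at most `n` rows per `tree_id`; trees with fewer available
#' pixels keep them all.  Reproducible under `seed`.
#'
#' @param pixels pixel table from [extract_crown_pixels()] (rows from
#'   several trees may be concatenated).
#' @param n pixels to keep per tree; the protocol value is 1000.
#' @param seed optional integer seed.
#' @return The subsampled pixel table.
#' @export
subsample_pixels <- function(pixels, n = 1000, seed = NULL) {
  stopifnot(n > 0)
  with_seed_if(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(pixels)), pixels$tree_id),
                          function(ix) {
                            if (length(ix) <= n) ix
                            else sample(ix, n)
                          }), use.names = FALSE)
    out <- pixels[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Summarize one tree's crown as feature means
#'
#' Arithmetic mean of every feature over the tree's sampled pixels
#' (mean of per-pixel index values, not indices of mean reflectance),
#' with the tree's laboratory nitrogen measures attached.
#'
#' @param pixels pixel table rows for one tree.
#' @param lab a one-row data frame with at least `tree_id`,
#'   `n_pct_dm`, and optionally `dign_pct_dm` and `plot_id`.
#' @return One-row data frame: `tree_id`, `n_pixels`, feature means,
#'   `n_pct_dm`, `dign_pct_dm`, `plot_id` (if supplied).
#' @export
summarize_tree <- function(pixels, lab) {
  if (nrow(pixels) == 0L)
    stop(sprintf("no pixels to summarize for tree %s",
                 as.character(lab$tree_id)))
  feats <- setdiff(names(pixels), c("tree_id", "row", "col"))
  means <- vapply(pixels[feats], mean, numeric(1), na.rm = TRUE)
  out <- data.frame(tree_id = lab$tree_id, n_pixels = nrow(pixels),
                    as.list(means),
                    n_pct_dm = lab$n_pct_dm,
                    dign_pct_dm = if ("dign_pct_dm" %in% names(lab))
                      lab$dign_pct_dm else NA_real_,
                    check.names = FALSE)
  if ("plot_id" %in% names(lab)) out$plot_id <- lab$plot_id
  rownames(out) <- NULL
  out
}

#' Sample and summarize all crowns of a scene
#'
#' Convenience wrapper running [extract_crown_pixels()],
#' [subsample_pixels()] and [summarize_tree()] over every segment,
#' using each tree's own NDVI threshold where available.
#'
#' @param features a 19-layer [band_stack()].
#' @param segments a `crown_segments` object whose `tree_id`s appear in
#'   `trees`.
#' @param trees tree table with `tree_id`, `n_pct_dm`, optionally
#'   `dign_pct_dm`, `plot_id`, `ndvi_min`.
#' @param n_pixels subsample size per tree.
#' @param default_ndvi_min fallback mask threshold.
#' @param seed optional integer seed for the subsampling.
#' @return List with `summaries` (one row per crown with >= 1 unmasked
#'   pixel) and `pixels` (the subsampled pixel table).
#' @export
sample_crown_summaries <- function(features, segments, trees,
                                   n_pixels = 1000, default_ndvi_min = 0.6,
                                   seed = NULL) {
  stopifnot(inherits(segments, "crown_segments"))
  pix_list <- list()
  for (s in segments$segments) {
    row <- trees[trees$tree_id == s$tree_id, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("segment tree_id ", s$tree_id, " not found uniquely in trees")
    thr <- if ("ndvi_min" %in% names(row) && is.finite(row$ndvi_min))
      row$ndvi_min else default_ndvi_min
    p <- suppressWarnings(extract_crown_pixels(features, s, thr))
    if (nrow(p)) pix_list[[as.character(s$tree_id)]] <- p
  }
  if (!length(pix_list))
    stop("no crown produced any unmasked foliage pixels")
  pixels <- subsample_pixels(do.call(rbind, pix_list), n = n_pixels,
                             seed = seed)
  rownames(pixels) <- NULL
  summaries <- do.call(rbind, lapply(split(pixels, pixels$tree_id),
    function(p) summarize_tree(p, trees[trees$tree_id == p$tree_id[1], ])))
  rownames(summaries) <- NULL
  list(summaries = summaries, pixels = pixels)
}
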