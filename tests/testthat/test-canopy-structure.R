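test_that("point splatting follows the disk geometry and the max rule", {
  # single point, radius 0: one nonzero cell at the point height
  p <- data.frame(x = 5.1, y = 5.1, z = 20)
  m <- rasterize_chm(p, pixel_size_m = 1, subcircle_radius_m = 0,
                     extent_m = 10)
  expect_equal(sum(m$heights > 0), 1L)
  expect_equal(max(m$heights), 20)

  # radius r: every cell whose center lies within r gets the height
  p2 <- data.frame(x = 5, y = 5, z = 12)
  m2 <- rasterize_chm(p2, pixel_size_m = 0.5, subcircle_radius_m = 1.2,
                      extent_m = 10)
  nr <- nrow(m2$heights)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    cx <- (j - 0.5) * 0.5
    cy <- nr * 0.5 - (i - 0.5) * 0.5
    inside <- (cx - 5)^2 + (cy - 5)^2 <= 1.2^2
    expect_equal(m2$heights[i, j], if (inside) 12 else 0)
  }

  # coincident points: the larger height wins
  p3 <- data.frame(x = c(2.5, 2.5), y = c(2.5, 2.5), z = c(7, 11))
  m3 <- rasterize_chm(p3, 1, 0.5, extent_m = 6)
  expect_equal(max(m3$heights), 11)
})

test_that("CHM differencing is exact on flat terrain and terrain-invariant", {
  set.seed(4)
  pts <- data.frame(x = runif(40, 0, 10), y = runif(40, 0, 10),
                    z = runif(40, 5, 25))
  dsm <- rasterize_chm(pts, 0.5, 0.5, extent_m = 10)
  dtm <- rasterize_chm(transform(pts, z = 0), 0.5, 0.5, extent_m = 10)
  direct <- rasterize_chm(pts, 0.5, 0.5, extent_m = 10)
  expect_equal(dsm$heights - dtm$heights, direct$heights)
  # adding constant elevation to both surfaces leaves the difference unchanged
  dsm_up <- rasterize_chm(transform(pts, z = z + 100), 0.5, 0.5, extent_m = 10)
  dtm_up <- rasterize_chm(transform(pts, z = 100), 0.5, 0.5, extent_m = 10)
  expect_equal(dsm_up$heights - dtm_up$heights, dsm$heights - dtm$heights)
})

test_that("the crown-width allometry fit is exact, affine-consistent, and recovers truth", {
  two <- data.frame(height_m = c(10, 20), crown_width_m = c(2, 4))
  f <- fit_crown_width_model(two)
  expect_equal(f$slope, 0.2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(unname(predict(f, 15)), 3)

  # shifting all widths by a constant moves only the intercept
  set.seed(11)
  d <- data.frame(height_m = runif(40, 10, 35))
  d$crown_width_m <- 1 + 0.15 * d$height_m + rnorm(40, 0, 0.2)
  f1 <- fit_crown_width_model(d)
  d2 <- transform(d, crown_width_m = crown_width_m + 2.5)
  f2 <- fit_crown_width_model(d2)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept + 2.5, tolerance = 1e-10)

  expect_error(fit_crown_width_model(
    data.frame(height_m = c(10, 10), crown_width_m = c(2, 3))), "distinct")

  # parameter recovery from a 500-tree synthetic list
  cfg <- scene_config(extent_m = 600, n_plots = 1, trees_per_plot = 500,
                      background_trees_per_plot = 0, seed = 31)
  trees <- generate_tree_list(cfg)
  fr <- fit_crown_width_model(trees)
  se <- summary(fr$fit)$coefficients["height_m", "Std. Error"]
  expect_lt(abs(fr$slope - cfg$allometry$slope), 2 * se)
})

test_that("local-maximum detection finds dome apices and nothing on flat ground", {
  # one paraboloid dome
  cfg <- scene_config(extent_m = 40, n_plots = 1, trees_per_plot = 1,
                      background_trees_per_plot = 0, noise_sd = 0, seed = 13)
  trees <- generate_tree_list(cfg)
  sc <- render_scene(trees, cfg)
  mk <- detect_trees(sc$chm, function(h) 0.5 * h, min_height_m = 5)
  expect_equal(nrow(mk), 1L)
  true_cell <- c(
    round((sc$chm$origin[2] - trees$y) / cfg$pixel_size_m + 0.5),
    round((trees$x - sc$chm$origin[1]) / cfg$pixel_size_m + 0.5))
  expect_lte(max(abs(c(mk$row, mk$col) - true_cell)), 1)

  # flat raster below the height floor: no markers
  flat <- chm(matrix(1.5, 30, 30), 1)
  expect_equal(nrow(detect_trees(flat, function(h) 5 * h, min_height_m = 2)), 0L)

  # two well-separated domes recover both apices within one cell
  cfg2 <- scene_config(extent_m = 80, n_plots = 1, trees_per_plot = 2,
                       background_trees_per_plot = 0, noise_sd = 0, seed = 17)
  t2 <- generate_tree_list(cfg2)
  sc2 <- render_scene(t2, cfg2)
  cw <- fit_crown_width_model(t2)
  mk2 <- detect_trees(sc2$chm, function(h) predict(cw, h), min_height_m = 10)
  expect_equal(nrow(mk2), 2L)
  mm <- match_markers_to_trees(mk2, t2)
  expect_lte(mean(mm$match_dist_m), cfg2$pixel_size_m * sqrt(2))
})

test_that("watershed segmentation partitions labeled cells around the markers", {
  cfg <- scene_config(extent_m = 80, n_plots = 1, trees_per_plot = 2,
                      background_trees_per_plot = 0, noise_sd = 0, seed = 17)
  trees <- generate_tree_list(cfg)
  sc <- render_scene(trees, cfg)
  cw <- fit_crown_width_model(trees)
  mk <- match_markers_to_trees(
    detect_trees(sc$chm, function(h) predict(cw, h), 10), trees)
  seg <- segment_crowns(sc$chm, mk, min_height_m = 10)
  expect_length(seg$segments, 2L)

  # partition: disjoint segments whose union is every labeled cell
  all_cells <- do.call(rbind, lapply(seg$segments, `[[`, "cells"))
  expect_equal(nrow(all_cells), nrow(unique(all_cells)))
  expect_equal(nrow(all_cells), sum(seg$labels > 0))

  # each segment contains its marker and the apex dominates the segment
  for (s in seg$segments) {
    expect_true(any(s$cells[, 1] == s$marker["row"] &
                      s$cells[, 2] == s$marker["col"]))
    expect_equal(s$apex_height_m, max(sc$chm$heights[s$cells]))
  }

  # separated domes: each segment equals the connected above-threshold
  # region around its own marker (flood-fill oracle)
  comp <- matrix(0L, nrow(sc$chm$heights), ncol(sc$chm$heights))
  for (k in seq_along(seg$segments)) {
    queue <- list(seg$segments[[k]]$marker)
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      i <- cell[[1]]; j <- cell[[2]]
      if (i < 1 || j < 1 || i > nrow(comp) || j > ncol(comp)) next
      if (comp[i, j] != 0L || sc$chm$heights[i, j] < 10) next
      comp[i, j] <- k
      queue <- c(queue, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
    }
  }
  expect_identical(unname(seg$labels), unname(comp))

  # markers below the height floor are rejected
  expect_error(segment_crowns(sc$chm, data.frame(row = 1, col = 1), 10),
               "below min_height")
})

test_that("crown polygon overrides replace segment cells", {
  pl <- get_pipeline()
  seg <- pl$segments
  id <- seg$segments[[1]]$tree_id
  ctr <- colMeans(cell_centers <- do.call(rbind, list(seg$segments[[1]]$polygon)))
  half <- 1.5
  poly <- cbind(c(ctr[1] - half, ctr[1] + half, ctr[1] + half, ctr[1] - half),
                c(ctr[2] - half, ctr[2] - half, ctr[2] + half, ctr[2] + half))
  seg2 <- apply_crown_overrides(seg, setNames(list(poly), id))
  area_cells <- nrow(seg2$segments[[1]]$cells)
  expect_equal(area_cells, round((2 * half / pl$cfg$pixel_size_m)^2),
               tolerance = 0.2)
  expect_true(all(seg2$labels[seg2$segments[[1]]$cells] == 1L))
})
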