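test_that("home-range cropping is exact arithmetic and commutes with index computation", {
  pl <- get_pipeline()
  crop <- crop_home_range(pl$scene$stack, pl$scene$chm, center = c(70, 70),
                          side_m = 100)
  expect_equal(dim(crop$features), c(400L, 400L))
  expect_equal(dim(crop$canopy$heights), c(400L, 400L))
  # 200 m at 0.25 m resolution would be an 800 x 800 crop
  expect_equal(round(200 / 0.25), 800)
  expect_error(crop_home_range(pl$scene$stack, pl$scene$chm, center = c(0, 0),
                               side_m = 100), "outside")
  # crop-then-index equals index-then-crop
  fs_then_crop <- crop_home_range(pl$features, pl$scene$chm,
                                  center = c(70, 70), side_m = 100)$features
  crop_then_fs <- compute_feature_stack(crop$features)
  for (nm in feature_names())
    expect_equal(fs_then_crop$bands[[nm]], crop_then_fs$bands[[nm]],
                 tolerance = 1e-12)
})

test_that("probability rasters agree with row-wise tabular prediction", {
  pl <- get_pipeline()
  lab <- label_pixels(pl$pixels, pl$trees)
  bal <- balance_subsample(lab, n_per_class = 800, seed = 4)
  ev <- evaluate_classifier(bal, seed = 5, ntree = 150)
  crop <- crop_home_range(pl$features, pl$scene$chm, center = c(35, 35),
                          side_m = 20)
  prob <- predict_probability_raster(ev$classifier, crop$features)
  expect_true(all(prob >= 0 & prob <= 1, na.rm = TRUE))
  # reshaping oracle
  tab <- as.data.frame(lapply(crop$features$bands[ev$classifier$variables],
                              as.vector))
  ok <- complete.cases(tab)
  direct <- rep(NA_real_, nrow(tab))
  direct[ok] <- predict(ev$classifier, tab[ok, , drop = FALSE])
  expect_equal(as.vector(prob), direct)
  # constant features give a constant probability
  const <- band_stack(setNames(lapply(feature_names(), function(nm)
    matrix(0.4, 3, 3)), feature_names()), 1)
  pc <- predict_probability_raster(ev$classifier, const)
  expect_equal(sd(pc), 0)
  expect_error(predict_probability_raster(
    ev$classifier,
    band_stack(list(green = matrix(1, 2, 2)), 1)), "lacks classifier")
})

test_that("sub-canopy masking counts match brute force and edge thresholds behave", {
  h <- matrix(c(0, 3, 7, 12), 2, 2)
  cm <- chm(h, 1)
  prob <- matrix(0.5, 2, 2)
  m5 <- mask_non_canopy(prob, cm, 5)
  expect_equal(sum(is.na(m5)), sum(h < 5))
  expect_true(all(is.na(mask_non_canopy(prob, chm(matrix(0, 2, 2), 1), 5))))
  expect_equal(sum(is.na(mask_non_canopy(prob, cm, 0))), 0L)
  expect_error(mask_non_canopy(matrix(0.5, 3, 3), cm, 5), "not aligned")
})

test_that("classification partitions the extent into the three classes", {
  prob <- matrix(c(0.2, 0.6, NA, 0.49, 0.51, 0.49), 2, 3)
  map <- classify_map(prob, threshold = 0.49, pixel_size_m = 0.25)
  expect_equal(sum(map$classes == 1L), sum(prob >= 0.49, na.rm = TRUE))
  expect_equal(sum(map$classes == 0L), sum(prob < 0.49, na.rm = TRUE))
  expect_equal(sum(map$classes == 255L), sum(is.na(prob)))
  expect_equal(sum(table(map$classes)), length(prob))
  # threshold 0: every canopy pixel favorable
  m0 <- classify_map(prob, 0, 0.25)
  expect_equal(sum(m0$classes == 1L), sum(!is.na(prob)))
})

test_that("habitat summaries recompute from the rasters and conserve fractions", {
  set.seed(30)
  prob <- matrix(runif(400), 20, 20)
  prob[sample(400, 120)] <- NA
  map <- classify_map(prob, 0.5, 0.25)
  s <- summarize_habitat(map)
  canopy <- !is.na(prob)
  expect_equal(s$mean_likelihood, mean(prob[canopy]))
  expect_equal(s$sd_likelihood, sd(prob[canopy]))
  expect_equal(sum(s$classes$fraction_pct), 100, tolerance = 1e-9)
  expect_equal(s$classes$area_m2, s$classes$n_pixels * 0.25^2)
  # fixed probability: mean equals it, SD zero
  mapc <- classify_map(matrix(0.7, 4, 4), 0.5, 1)
  sc <- summarize_habitat(mapc)
  expect_equal(sc$mean_likelihood, 0.7)
  expect_equal(sc$sd_likelihood, 0)
  # 640,000-pixel extent with 160,000 favorable -> 25%
  expect_equal(100 * 160000 / 640000, 25)
})

test_that("clumpiness matches brute-force adjacency counting on exhaustive small rasters", {
  # checkerboard: maximal disaggregation
  cb <- (outer(1:4, 1:4, "+") %% 2L)
  expect_equal(clumpiness(cb, 0L), -1)
  expect_equal(clumpiness(cb, 1L), -1)
  expect_equal(oracle_clumpiness(cb, 1L), -1)
  # solid block in a large background: strongly aggregated
  big <- matrix(0L, 30, 30)
  big[5:20, 5:20] <- 1L
  expect_gt(clumpiness(big, 1L), 0.9)
  expect_equal(clumpiness(big, 1L), oracle_clumpiness(big, 1L))
  # full-landscape class: 1 by convention
  expect_equal(clumpiness(matrix(1L, 5, 5), 1L), 1)
  # absent class
  expect_true(is.na(clumpiness(matrix(0L, 3, 3), 7L)))
  # random rasters up to 8x8, 2-3 classes
  set.seed(17)
  for (k in 1:40) {
    nr <- sample(1:8, 1); nc <- sample(1:8, 1)
    ncl <- sample(2:3, 1)
    m <- matrix(sample(0:(ncl - 1), nr * nc, replace = TRUE), nr, nc)
    for (cl in 0:(ncl - 1))
      expect_equal(clumpiness(m, cl), oracle_clumpiness(m, cl),
                   label = sprintf("raster %d class %d", k, cl))
  }
})

test_that("Bitterlich expansion follows the closed form and its scaling laws", {
  expect_equal(bitterlich_expansion(0.2, c = 25), 10000 / (pi * 625 * 0.04))
  expect_equal(bitterlich_expansion(0.2, c = 25), 127.3, tolerance = 1e-3)
  expect_equal(bitterlich_expansion(0.564, c = 25), 16.0, tolerance = 1e-3)
  # doubling diameter quarters the represented density
  expect_equal(bitterlich_expansion(0.4) * 4, bitterlich_expansion(0.2))
  # strictly decreasing in dbh and in the expansion factor
  d <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(bitterlich_expansion(d)) < 0))
  expect_gt(bitterlich_expansion(0.3, c = 20), bitterlich_expansion(0.3, c = 25))
  expect_error(bitterlich_expansion(-0.1), "positive")
})
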