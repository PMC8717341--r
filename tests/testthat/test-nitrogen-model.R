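test_that("correlation pruning handles exact duplicates, clean sets, and constants", {
  set.seed(2)
  a <- rnorm(50)
  dup <- data.frame(a = a, b = a)          # r = 1
  expect_length(prune_correlated(dup), 1L)

  clean <- data.frame(x = rnorm(50), y = rnorm(50), z = rnorm(50))
  expect_setequal(prune_correlated(clean), c("x", "y", "z"))

  with_const <- data.frame(a = a, k = rep(1, 50), b = rnorm(50))
  expect_warning(kept <- prune_correlated(with_const), "constant")
  expect_false("k" %in% kept)
})

test_that("greedy pruning attains a minimal-removal solution on a constructed case", {
  set.seed(9)
  n <- 200
  u <- rnorm(n); v <- rnorm(n)
  x <- data.frame(
    a1 = u, a2 = u + rnorm(n, 0, 0.1),       # correlated pair 1
    b1 = v, b2 = v + rnorm(n, 0, 0.1),       # correlated pair 2
    c1 = rnorm(n), c2 = rnorm(n)             # independent
  )
  kept <- prune_correlated(x, 0.8)
  # brute force: smallest removal sets leaving all |r| < 0.8
  cm <- abs(cor(x))
  feats <- names(x)
  valid <- list()
  for (size in 0:length(feats)) {
    for (rm in utils::combn(feats, size, simplify = FALSE)) {
      keep <- setdiff(feats, rm)
      if (length(keep) < 2) next
      sub <- cm[keep, keep]
      diag(sub) <- 0
      if (max(sub) < 0.8) valid <- c(valid, list(sort(keep)))
    }
    if (length(valid)) break
  }
  expect_true(any(vapply(valid, identical, logical(1), y = sort(kept))))
})

test_that("stratified partition yields 105/45 on 150 rows and balances bins", {
  set.seed(3)
  y <- rnorm(150)
  part <- stratified_partition(y, seed = 5)
  expect_length(part$train, 105L)
  expect_length(part$test, 45L)
  expect_setequal(c(part$train, part$test), 1:150)
  # each quantile bin contributes ~70% of its rows
  bins <- ceiling(rank(y, ties.method = "first") * 5 / 150)
  for (b in 1:5)
    expect_equal(sum(part$train %in% which(bins == b)), 21L)
  # both sides span the response in seeded repetition
  cover <- vapply(1:200, function(s) {
    yy <- runif(60)
    p <- stratified_partition(yy, seed = s)
    rtr <- range(yy[p$train]); rte <- range(yy[p$test])
    rte[1] <= rtr[2] && rtr[1] <= rte[2]
  }, logical(1))
  expect_gte(mean(cover), 0.95)
})

test_that("the forest finds signal when present and none when absent", {
  set.seed(14)
  # recoverable signal: noiseless monotone function of one feature
  x <- as.data.frame(matrix(runif(200 * 3), 200, 3))
  y <- 2 * x[[1]]
  f <- train_rf_regressor(x, y, ntree_grid = 500, seed = 1)
  r2 <- 1 - sum((y - f$forest$predicted)^2) / sum((y - mean(y))^2)
  expect_gte(r2, 0.9)

  # pure-noise response: OOB R-squared near zero on average over seeds
  null_r2 <- vapply(1:10, function(i) {
    xx <- as.data.frame(matrix(rnorm(100 * 5), 100, 5))
    yy <- rnorm(100)
    ff <- train_rf_regressor(xx, yy, ntree_grid = 300, seed = i)
    1 - sum((yy - ff$forest$predicted)^2) / sum((yy - mean(yy))^2)
  }, numeric(1))
  expect_lt(abs(mean(null_r2)), 0.15)

  # determinism under a seed
  f2 <- train_rf_regressor(x, y, ntree_grid = 500, seed = 1)
  expect_identical(f$forest$predicted, f2$forest$predicted)

  expect_error(train_rf_regressor(x[1, , drop = FALSE], y[1]), "at least 2")
})

test_that("importance-based selection drops a pure-noise variable", {
  dropped <- vapply(1:20, function(i) {
    set.seed(100 + i)
    n <- 150
    x <- data.frame(a = runif(n), b = runif(n), c = runif(n), d = runif(n),
                    noise = runif(n))
    y <- x$a + x$b + 0.8 * x$c + 0.6 * x$d + rnorm(n, 0, 0.1)
    f <- train_rf_regressor(x, y, ntree_grid = 300, seed = i)
    sv <- select_variables(f, x, y, inc_mse_threshold = 5, seed = i)
    !("noise" %in% sv$variables)
  }, logical(1))
  expect_gte(mean(dropped), 0.9)

  # all strong variables: set unchanged
  set.seed(2)
  x <- data.frame(a = runif(120), b = runif(120))
  y <- x$a + x$b
  f <- train_rf_regressor(x, y, ntree_grid = 300, seed = 3)
  sv <- select_variables(f, x, y, inc_mse_threshold = 5)
  expect_setequal(sv$variables, c("a", "b"))

  # an impossible threshold errors with advice
  expect_error(select_variables(f, x, y, inc_mse_threshold = 1e6), "lower")
})

test_that("repeated evaluation aggregates equal recomputation from per-repeat values", {
  pl <- get_pipeline()
  ds <- make_model_dataset(pl$summaries)
  expect_true(all(abs(cor(ds$x)[upper.tri(cor(ds$x))]) < 0.8))
  ev <- evaluate_repeated(ds, n_repeats = 8, base_seed = 5)
  expect_equal(nrow(ev$per_repeat), 8L)
  agg <- ev$aggregates
  for (m in agg$metric) {
    v <- ev$per_repeat[[m]]
    row <- agg[agg$metric == m, ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$median, median(v))
    expect_equal(row$sd, sd(v))
    expect_equal(row$se, sd(v) / sqrt(8))
  }
  expect_true(all(ev$per_repeat$cv_rmse >= ev$per_repeat$cv_mae))
  expect_true(all(ev$per_repeat$cv_r2 <= 1))
  expect_equal(ev$best_r2_repeat, which.max(ev$per_repeat$iv_r2))
  expect_equal(ev$best_rmse_repeat, which.min(ev$per_repeat$iv_rmse))
  # SE convention: SD 0.038 over 100 repeats -> SE 0.0038
  expect_equal(0.038 / sqrt(100), 0.0038)
})

test_that("more reflectance noise never helps cross-validation accuracy", {
  r2_at <- vapply(c(0.01, 0.08, 0.2), function(noise) {
    pl <- build_pipeline(scene_config(extent_m = 140, n_plots = 4, seed = 11,
                                      noise_sd = noise))
    ds <- make_model_dataset(pl$summaries)
    ev <- evaluate_repeated(ds, n_repeats = 5, base_seed = 42)
    mean(ev$per_repeat$cv_r2)
  }, numeric(1))
  expect_true(all(diff(r2_at) <= 0))
})

test_that("plot-level regression reduces to hand-computed means and handles degeneracy", {
  obs <- c(1.0, 1.2, 1.6, 1.8)
  pred <- c(1.1, 1.3, 1.5, 1.7)
  plots <- c(1, 1, 2, 2)
  r <- plot_level_regression(obs, pred, plots)
  expect_equal(r$per_plot$observed_mean, c(1.1, 1.7))
  expect_equal(r$per_plot$predicted_mean, c(1.2, 1.6))
  # perfect predictions: R^2 = 1
  p <- plot_level_regression(obs, obs, plots)
  expect_equal(p$r2, 1)
  # single plot: undefined
  s <- plot_level_regression(obs[1:2], pred[1:2], c(1, 1))
  expect_true(is.na(s$r2))
})
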