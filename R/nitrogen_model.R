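#' Drop highly correlated features
#'
#' Iteratively finds the feature pair with the highest absolute Pearson
#' correlation at or above the threshold and drops the member with the
#' larger mean absolute correlation to all remaining features, until no
#' pair reaches the threshold.  Constant features (undefined
#' correlation) are dropped first with a warning.
#'
#' @param features data frame or matrix of candidate predictors.
#' @param r_threshold absolute correlation at or above which a pair is
#'   considered redundant; protocol value 0.8.
#' @return Character vector of retained feature names.
#' @export
prune_correlated <- function(features, r_threshold = 0.8) {
  x <- as.data.frame(features)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3)
  const <- vapply(x, function(v) sd(v, na.rm = TRUE) == 0 ||
                    !is.finite(sd(v, na.rm = TRUE)), logical(1))
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  keep <- names(x)
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(cor(x[, keep, drop = FALSE],
                  use = "pairwise.complete.obs"))
    diag(cm) <- 0
    top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (cm[top[1], top[2]] < r_threshold) break
    mac <- rowMeans(cm)
    drop_ix <- if (mac[top[1]] >= mac[top[2]]) top[1] else top[2]
    keep <- keep[-drop_ix]
  }
  keep
}

#' Stratified 70/30 train/test partition on a numeric response
#'
#' Sorts the response into `n_bins` quantile bins (by rank, so bins are
#' as equal as possible) and samples `train_fraction` of each bin into
#' the training set, ensuring both sets span the response range.  The
#' union of the two index sets covers every row exactly once.
#'
#' @param response numeric vector.
#' @param train_fraction fraction per bin assigned to training
#'   (protocol value 0.7).
#' @param n_bins number of quantile bins.
#' @param seed optional integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_partition <- function(response, train_fraction = 0.7, n_bins = 5,
                                 seed = NULL) {
  n <- length(response)
  stopifnot(n >= n_bins, train_fraction > 0, train_fraction < 1)
  with_seed_if(seed, {
    bins <- ceiling(rank(response, ties.method = "first") * n_bins / n)
    train <- unlist(lapply(split(seq_len(n), bins), function(ix) {
      k <- round(train_fraction * length(ix))
      k <- max(1L, min(length(ix) - 1L, k))
      if (length(ix) == 1L) return(ix)
      sample(ix, k)
    }), use.names = FALSE)
    list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
  })
}

#' Train a random-forest regressor with an OOB-tuned tree count
#'
#' Grows a forest at the largest candidate size, reads the out-of-bag
#' error curve, and refits at the candidate tree count minimizing OOB
#' MSE.  When the curve is flat across the grid (relative spread below
#' 1%), the conventional 500 trees are used.
#'
#' @param x predictor data frame (training rows).
#' @param y numeric response (training rows).
#' @param ntree_grid candidate tree counts.
#' @param mtry variables tried per split; default `ceiling(p / 3)`.
#' @param seed optional integer seed (forest growth is stochastic).
#' @return Object of class `rf_regressor`: `forest` (a
#'   [randomForest::randomForest] fit with permutation importance),
#'   `ntree`, `oob_curve` (MSE at each grid point), `variables`.
#' @export
train_rf_regressor <- function(x, y, ntree_grid = seq(100, 1000, by = 100),
                               mtry = NULL, seed = NULL) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < 2) stop("training set must contain at least 2 rows")
  if (is.null(mtry)) mtry <- max(1L, ceiling(ncol(x) / 3))
  ntree_grid <- sort(unique(as.integer(ntree_grid)))
  with_seed_if(seed, {
    probe <- randomForest::randomForest(x, y, ntree = max(ntree_grid),
                                        mtry = mtry)
    oob_curve <- setNames(probe$mse[ntree_grid], ntree_grid)
    spread <- (max(oob_curve) - min(oob_curve)) / min(oob_curve)
    ntree <- if (spread < 0.01 && 500L %in% ntree_grid) 500L
             else ntree_grid[which.min(oob_curve)]
    forest <- randomForest::randomForest(x, y, ntree = ntree, mtry = mtry,
                                         importance = TRUE)
    structure(list(forest = forest, ntree = ntree, oob_curve = oob_curve,
                   variables = names(x)),
              class = "rf_regressor")
  })
}

#' @export
print.rf_regressor <- function(x, ...) {
  cat(sprintf("<rf_regressor> %d trees, %d variables, OOB MSE %.4g\n",
              x$ntree, length(x$variables),
              tail(x$forest$mse, 1)))
  invisible(x)
}

#' @importFrom utils tail
#' @export
predict.rf_regressor <- function(object, newdata, ...) {
  predict(object$forest, newdata = newdata, ...)
}

#' Permutation importance as percent increase in OOB MSE
#'
#' Raw permutation importance (mean increase in OOB MSE when the
#' variable is permuted) expressed as a percentage of the forest's
#' OOB MSE.
#'
#' @param model an `rf_regressor`.
#' @return Named numeric vector (one value per variable, in percent).
#' @export
importance_pct_inc_mse <- function(model) {
  stopifnot(inherits(model, "rf_regressor"))
  raw <- randomForest::importance(model$forest, type = 1, scale = FALSE)[, 1]
  100 * raw / tail(model$forest$mse, 1)
}

#' Select variables contributing at least a given % incMSE
#'
#' Drops variables whose permutation importance falls below the
#' threshold and refits the forest on the survivors.
#'
#' @param model an `rf_regressor` fitted with importance.
#' @param x,y the training data the model was fitted on.
#' @param inc_mse_threshold importance floor in percent (protocol 5).
#' @param seed optional integer seed for the refit.
#' @return List: `model` (refit `rf_regressor`), `variables`,
#'   `importance` (of the original fit, in % incMSE).
#' @export
select_variables <- function(model, x, y, inc_mse_threshold = 5,
                             seed = NULL) {
  imp <- importance_pct_inc_mse(model)
  keep <- names(imp)[imp >= inc_mse_threshold]
  if (length(keep) == 0L)
    stop("no variable reaches the importance threshold; lower it")
  refit <- if (length(keep) == length(imp)) model
           else train_rf_regressor(as.data.frame(x)[, keep, drop = FALSE], y,
                                   ntree_grid = model$ntree, seed = seed)
  list(model = refit, variables = keep, importance = imp)
}

#' Assemble a modelling dataset from tree spectral summaries
#'
#' Applies correlation pruning to the 19 features, drops rows with a
#' missing response, and removes outlying observations whose absolute
#' studentized residual from a preliminary linear fit exceeds
#' `outlier_sigma` (a reproducible stand-in for visual outlier
#' screening).
#'
#' @param summaries tree summary table from [sample_crown_summaries()].
#' @param response `"n_pct_dm"` or `"dign_pct_dm"`.
#' @param r_threshold correlation pruning threshold.
#' @param outlier_sigma studentized-residual cutoff; `Inf` disables.
#' @return List of class `model_dataset`: `x` (pruned features), `y`,
#'   `variables`, `tree_id`, `plot_id` (if available), `dropped_outliers`.
#' @export
make_model_dataset <- function(summaries, response = "n_pct_dm",
                               r_threshold = 0.8, outlier_sigma = 4) {
  stopifnot(response %in% names(summaries))
  feats <- intersect(feature_names(), names(summaries))
  ok <- is.finite(summaries[[response]])
  dat <- summaries[ok, , drop = FALSE]
  keep <- prune_correlated(dat[, feats, drop = FALSE], r_threshold)
  x <- dat[, keep, drop = FALSE]
  y <- dat[[response]]
  dropped <- integer(0)
  if (is.finite(outlier_sigma) && nrow(x) > length(keep) + 2) {
    prelim <- lm(y ~ ., data = cbind(x, y = y))
    rs <- rstudent(prelim)
    dropped <- which(abs(rs) > outlier_sigma)
    if (length(dropped)) {
      x <- x[-dropped, , drop = FALSE]
      y <- y[-dropped]
      dat <- dat[-dropped, , drop = FALSE]
    }
  }
  structure(list(x = x, y = y, variables = keep,
                 tree_id = dat$tree_id,
                 plot_id = if ("plot_id" %in% names(dat)) dat$plot_id else NULL,
                 response = response, dropped_outliers = dropped),
            class = "model_dataset")
}

regression_metrics <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  c(r2 = 1 - ss_res / ss_tot,
    rmse = sqrt(mean((obs - pred)^2)),
    mae = mean(abs(obs - pred)))
}

#' Repeated stratified evaluation of the nitrogen model
#'
#' Runs `n_repeats` independent stratified 70/30 splits.  For each
#' repeat a forest is fitted on the training rows; cross-validation
#' metrics are computed from the forest's out-of-bag predictions on the
#' training split and independent-validation metrics from predictions
#' on the held-out split.  Aggregates (mean, median, SD, SE = SD /
#' sqrt(repeats), CV) are reported per metric, along with the repeats
#' achieving the best R-squared and the lowest RMSE.
#'
#' @param dataset a `model_dataset`.
#' @param n_repeats number of random splits (protocol value 100).
#' @param base_seed integer; repeat `i` uses seed `base_seed + i`.
#' @param ntree trees per forest (a fixed count keeps repeats cheap).
#' @param train_fraction,n_bins passed to [stratified_partition()].
#' @return Object of class `eval_summary`: `per_repeat` (data frame of
#'   per-repeat metrics), `aggregates` (data frame), `best_r2_repeat`,
#'   `best_rmse_repeat` (indices by independent validation), `seeds`.
#' @export
evaluate_repeated <- function(dataset, n_repeats = 100, base_seed = 1,
                              ntree = 500, train_fraction = 0.7, n_bins = 5) {
  stopifnot(inherits(dataset, "model_dataset"))
  seeds <- base_seed + seq_len(n_repeats)
  rows <- vector("list", n_repeats)
  preds_best <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    part <- stratified_partition(dataset$y, train_fraction, n_bins,
                                 seed = seeds[i])
    fit <- train_rf_regressor(dataset$x[part$train, , drop = FALSE],
                              dataset$y[part$train],
                              ntree_grid = ntree, seed = seeds[i])
    cv <- regression_metrics(dataset$y[part$train], fit$forest$predicted)
    iv <- regression_metrics(dataset$y[part$test],
                             predict(fit, dataset$x[part$test, , drop = FALSE]))
    rows[[i]] <- data.frame(repeat_id = i,
                            cv_r2 = cv["r2"], cv_rmse = cv["rmse"],
                            cv_mae = cv["mae"],
                            iv_r2 = iv["r2"], iv_rmse = iv["rmse"],
                            iv_mae = iv["mae"], row.names = NULL)
    preds_best[[i]] <- list(fit = fit, part = part)
  }
  per_repeat <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_repeat), "repeat_id")
  aggregates <- do.call(rbind, lapply(metric_cols, function(m) {
    v <- per_repeat[[m]]
    data.frame(metric = m, mean = mean(v), median = median(v),
               sd = sd(v), se = sd(v) / sqrt(n_repeats),
               cv = sd(v) / mean(v))
  }))
  best_r2 <- which.max(per_repeat$iv_r2)
  best_rmse <- which.min(per_repeat$iv_rmse)
  structure(list(per_repeat = per_repeat, aggregates = aggregates,
                 best_r2_repeat = best_r2, best_rmse_repeat = best_rmse,
                 best_r2_model = preds_best[[best_r2]],
                 seeds = seeds),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> %d repeats\n", nrow(x$per_repeat)))
  print(x$aggregates, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot-level regression of observed versus predicted mean nitrogen
#'
#' Averages observed and predicted tree nitrogen per plot and reports
#' the ordinary least-squares R-squared between the two plot means.
#' Plots with no trees are excluded with a warning; with fewer than two
#' plots the R-squared is undefined and returned as `NA`.
#'
#' @param observed,predicted per-tree values.
#' @param plot_id per-tree plot membership.
#' @return List: `per_plot` data frame (`plot_id`, `observed_mean`,
#'   `predicted_mean`), `r2`, and the `lm` fit (`NULL` when undefined).
#' @export
plot_level_regression <- function(observed, predicted, plot_id) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(plot_id))
  if (anyNA(plot_id)) {
    warning("trees with missing plot_id excluded")
    ok <- !is.na(plot_id)
    observed <- observed[ok]; predicted <- predicted[ok]
    plot_id <- plot_id[ok]
  }
  per_plot <- data.frame(
    plot_id = sort(unique(plot_id)),
    observed_mean = vapply(split(observed, plot_id), mean, numeric(1)),
    predicted_mean = vapply(split(predicted, plot_id), mean, numeric(1)),
    row.names = NULL)
  if (nrow(per_plot) < 2L)
    return(list(per_plot = per_plot, r2 = NA_real_, fit = NULL))
  fit <- lm(predicted_mean ~ observed_mean, data = per_plot)
  list(per_plot = per_plot, r2 = summary(fit)$r.squared, fit = fit)
}
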