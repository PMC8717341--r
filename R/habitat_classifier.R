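#' Label crown pixels against the 1% nitrogen threshold
#'
#' Every pixel inherits its tree's class: favorable (1) when the tree's
#' foliar nitrogen is at or above the threshold (% DM), unfavorable (0)
#' below it.
#'
#' @param pixels pixel table (from [extract_crown_pixels()] /
#'   [subsample_pixels()]).
#' @param trees tree table with `tree_id` and `n_pct_dm`.
#' @param threshold_pct_dm class boundary; the folivore habitat
#'   threshold is 1% N DM, boundary inclusive.
#' @return The pixel table with a `label` column (integer 0/1).
#' @export
label_pixels <- function(pixels, trees, threshold_pct_dm = 1.0) {
  m <- match(pixels$tree_id, trees$tree_id)
  if (anyNA(m))
    stop("pixels reference tree(s) absent from the tree table: ",
         paste(unique(pixels$tree_id[is.na(m)]), collapse = ", "))
  n_val <- trees$n_pct_dm[m]
  if (anyNA(n_val))
    stop("tree(s) missing an N value: ",
         paste(unique(pixels$tree_id[is.na(n_val)]), collapse = ", "))
  pixels$label <- as.integer(n_val >= threshold_pct_dm)
  pixels
}

#' Balanced subsample of a labeled pixel set
#'
#' Draws up to `n_per_class` pixels per class without replacement
#' (protocol value 25,000 each).  If the minority class has fewer
#' pixels, all of it is kept and the majority draw is matched to its
#' size, with a warning.  The result is shuffled deterministically
#' under the seed.
#'
#' @param labeled pixel table with a `label` column.
#' @param n_per_class target pixels per class.
#' @param seed optional integer seed.
#' @return The balanced pixel table (equal class counts).
#' @export
balance_subsample <- function(labeled, n_per_class = 25000, seed = NULL) {
  stopifnot("label" %in% names(labeled))
  counts <- table(factor(labeled$label, levels = c(0, 1)))
  if (any(counts == 0))
    stop("both classes must be present to balance (counts: ",
         paste(counts, collapse = "/"), ")")
  n_take <- min(n_per_class, counts)
  if (n_take < n_per_class)
    warning(sprintf("minority class has only %d pixels; taking %d per class",
                    min(counts), n_take))
  with_seed_if(seed, {
    ix <- unlist(lapply(c(0L, 1L), function(cl) {
      pool <- which(labeled$label == cl)
      if (length(pool) == n_take) pool else sample(pool, n_take)
    }), use.names = FALSE)
    out <- labeled[sample(ix), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Train a binomial random-forest classifier on pixel features
#'
#' @param x feature data frame (training rows).
#' @param y integer/factor labels (both classes must be present).
#' @param ntree trees in the forest.
#' @param seed optional integer seed.
#' @return Object of class `rf_classifier` exposing per-pixel
#'   probability of class 1 via `predict()`.
#' @export
train_rf_classifier <- function(x, y, ntree = 500, seed = NULL) {
  x <- as.data.frame(x)
  y <- factor(y, levels = c(0, 1))
  if (length(unique(y)) < 2L)
    stop("training labels are single-class; cannot fit a classifier")
  with_seed_if(seed, {
    forest <- randomForest::randomForest(x, y, ntree = ntree)
    structure(list(forest = forest, variables = names(x), ntree = ntree),
              class = "rf_classifier")
  })
}

#' @export
predict.rf_classifier <- function(object, newdata, ...) {
  predict(object$forest, newdata = newdata, type = "prob")[, "1"]
}

#' @export
print.rf_classifier <- function(x, ...) {
  cat(sprintf("<rf_classifier> %d trees, %d variables\n",
              x$ntree, length(x$variables)))
  invisible(x)
}

#' Skill metrics from a confusion matrix
#'
#' @param tp,fp,tn,fn confusion counts at the operating threshold
#'   (positives = favorable habitat).
#' @return Named list: `accuracy`, `sensitivity` (TPR), `specificity`
#'   (TNR), `tss` (= sensitivity + specificity - 1); empty classes give
#'   `NA` for the affected rate.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       sensitivity = sens, specificity = spec,
       tss = sens + spec - 1)
}

#' Cohen's kappa from a confusion matrix
#'
#' @inheritParams confusion_metrics
#' @return Kappa statistic.
#' @export
cohen_kappa <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  (po - pe) / (1 - pe)
}

#' Rank-based AUC (Mann-Whitney), ties counted one half
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`; `NA` when one class is absent.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Operating threshold maximizing TPR + TNR
#'
#' Scans candidate thresholds at the unique score values (scores at or
#' above the threshold are classified positive) and returns the one
#' maximizing sensitivity + specificity, breaking ties toward the
#' lowest threshold.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels (both classes required).
#' @return List: `threshold`, `tpr`, `tnr`.
#' @export
operating_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to choose a threshold")
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  best <- list(threshold = NA_real_, tpr = NA_real_, tnr = NA_real_)
  best_j <- -Inf
  for (t in cand) {
    pos <- scores >= t
    tpr <- sum(pos & labels == 1L) / n1
    tnr <- sum(!pos & labels == 0L) / n0
    if (tpr + tnr > best_j + 1e-12) {
      best_j <- tpr + tnr
      best <- list(threshold = t, tpr = tpr, tnr = tnr)
    }
  }
  best
}

#' Train and evaluate the habitat classifier end to end
#'
#' Splits the balanced pixel set 70/30 (stratified by class), fits the
#' binomial forest on the training rows, chooses the operating
#' threshold maximizing TPR + TNR on the held-out scores, and reports
#' the confusion counts and skill metrics at that threshold.
#'
#' @param balanced balanced pixel table from [balance_subsample()].
#' @param train_fraction fraction used for training.
#' @param ntree trees in the forest.
#' @param seed integer seed driving split and forest.
#' @param group_by_tree if `TRUE`, all pixels of a tree fall on the
#'   same side of the split (avoids tree-identity leakage); default
#'   `FALSE`, a plain pixel-level split.
#' @return Object of class `classifier_eval`: `classifier`,
#'   `threshold`, confusion counts `tp`/`fp`/`tn`/`fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `tss`, `auc`, `kappa`, `n_holdout`,
#'   `scores`, `holdout_labels`.
#' @export
evaluate_classifier <- function(balanced, train_fraction = 0.7, ntree = 500,
                                seed = 1, group_by_tree = FALSE) {
  feats <- intersect(feature_names(), names(balanced))
  stopifnot(length(feats) >= 1, "label" %in% names(balanced))
  with_seed_if(seed, {
    if (group_by_tree) {
      ids <- unique(balanced$tree_id)
      tr_ids <- sample(ids, round(train_fraction * length(ids)))
      train_ix <- which(balanced$tree_id %in% tr_ids)
    } else {
      train_ix <- unlist(lapply(c(0L, 1L), function(cl) {
        pool <- which(balanced$label == cl)
        sample(pool, round(train_fraction * length(pool)))
      }), use.names = FALSE)
    }
    test_ix <- setdiff(seq_len(nrow(balanced)), train_ix)
    clf <- train_rf_classifier(balanced[train_ix, feats, drop = FALSE],
                               balanced$label[train_ix], ntree = ntree)
    scores <- predict(clf, balanced[test_ix, feats, drop = FALSE])
    labs <- balanced$label[test_ix]
    op <- operating_threshold(scores, labs)
    pos <- scores >= op$threshold
    tp <- sum(pos & labs == 1L); fp <- sum(pos & labs == 0L)
    tn <- sum(!pos & labs == 0L); fn <- sum(!pos & labs == 1L)
    met <- confusion_metrics(tp, fp, tn, fn)
    structure(c(list(classifier = clf, threshold = op$threshold,
                     tp = tp, fp = fp, tn = tn, fn = fn),
                met,
                list(auc = auc(scores, labs),
                     kappa = cohen_kappa(tp, fp, tn, fn),
                     n_holdout = length(test_ix),
                     scores = scores, holdout_labels = labs)),
              class = "classifier_eval")
  })
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf(paste0("<classifier_eval> threshold %.3f | acc %.3f | ",
                     "sens %.3f | spec %.3f | TSS %.3f | AUC %.3f | ",
                     "kappa %.3f | n = %d\n"),
              x$threshold, x$accuracy, x$sensitivity, x$specificity,
              x$tss, x$auc, x$kappa, x$n_holdout))
  invisible(x)
}
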