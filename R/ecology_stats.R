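#' Plot survey table from the eucalypt field campaign
#'
#' The 30-plot survey table shipped with the package: ten plots in each
#' of three elevation bands of mixed-species eucalypt forest, with the
#' dominant canopy species, mean measured foliar nitrogen and
#' digestible nitrogen of the five sampled trees (% DM; digestible
#' nitrogen missing where laboratory samples were lost), the number of
#' greater gliders observed on the plot's spotlighting transect, and
#' the home-range scale mapping summaries (predicted mean nitrogen,
#' mean likelihood of favorable pixels, favorable area fraction,
#' clumpiness of the favorable class).
#'
#' @return Data frame with 30 rows.
#' @export
glider_plot_survey <- function() {
  path <- system.file("extdata", "glider_plot_survey.csv",
                      package = "nitroscape", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble a plot-level survey table
#'
#' Mean plot nitrogen is the arithmetic mean of the sampled trees'
#' measurements; detections and habitat-map summaries are joined by
#' plot id.
#'
#' @param trees tree table with `plot_id`, `n_pct_dm`, optionally
#'   `dign_pct_dm` and a logical `sampled` flag (all trees used when
#'   absent).
#' @param detections data frame with `plot_id` and `detected` (0/1) or
#'   `n_gliders` counts.
#' @param habitat optional data frame with `plot_id` plus any of
#'   `predicted_mean_n`, `mean_likelihood`, `favorable_fraction_pct`,
#'   `clumpiness`.
#' @return Data frame with one row per plot: `plot_id`,
#'   `mean_n_pct_dm`, `mean_dign_pct_dm`, `n_gliders`, `detected`, and
#'   any joined habitat columns.
#' @export
assemble_plot_table <- function(trees, detections, habitat = NULL) {
  use <- if ("sampled" %in% names(trees)) trees[trees$sampled, ] else trees
  if (nrow(use) == 0L) stop("no sampled trees supplied")
  sp <- split(use, use$plot_id)
  tab <- data.frame(
    plot_id = as.integer(names(sp)),
    mean_n_pct_dm = vapply(sp, function(d) mean(d$n_pct_dm), numeric(1)),
    mean_dign_pct_dm = vapply(sp, function(d) {
      v <- d$dign_pct_dm
      if (is.null(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1)),
    row.names = NULL)
  missing_plots <- setdiff(tab$plot_id, detections$plot_id)
  if (length(missing_plots))
    stop("plots without detection records: ",
         paste(missing_plots, collapse = ", "))
  m <- match(tab$plot_id, detections$plot_id)
  tab$n_gliders <- if ("n_gliders" %in% names(detections))
    detections$n_gliders[m] else detections$detected[m]
  tab$detected <- as.integer(tab$n_gliders >= 1)
  if (!is.null(habitat)) {
    hm <- match(tab$plot_id, habitat$plot_id)
    for (cl in setdiff(names(habitat), "plot_id"))
      tab[[cl]] <- habitat[[cl]][hm]
  }
  tab
}

#' Binomial GLM of detection on mean plot nitrogen
#'
#' Maximum-likelihood logistic regression fitted by iteratively
#' reweighted least squares (relative convergence tolerance 1e-8),
#' with Wald standard errors from the final weighted information
#' matrix and 95% confidence intervals `estimate +/- 1.96 * SE`
#' (profile-likelihood intervals behind `profile_ci = TRUE`).
#' Complete separation is flagged rather than silently reported.
#'
#' @param detected 0/1 detection indicator per plot.
#' @param mean_n mean plot nitrogen (% DM) per plot.
#' @param profile_ci use profile-likelihood confidence intervals.
#' @return Object of class `glm_result`: `coefficients` data frame
#'   (`term`, `estimate`, `se`, `ci_lo`, `ci_hi`, `p_value`),
#'   `converged`, `iterations`, `separation`, and the underlying `fit`.
#' @export
fit_logistic <- function(detected, mean_n, profile_ci = FALSE) {
  stopifnot(length(detected) == length(mean_n))
  detected <- as.integer(detected)
  if (length(unique(detected)) < 2L)
    stop("both detection outcomes must be present")
  dat <- data.frame(detected = detected, mean_n = mean_n)
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(detected ~ mean_n, family = binomial(), data = dat,
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  separation <- warned || any(mu < 1e-10) || any(mu > 1 - 1e-10) ||
    max(abs(coef(fit))) > 1e3
  if (separation)
    warning("possible complete separation: coefficient estimates diverge")
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (profile_ci) {
    ci <- suppressMessages(suppressWarnings(stats::confint(fit)))
  } else {
    ci <- cbind(est - 1.96 * se, est + 1.96 * se)
  }
  p <- 2 * pnorm(-abs(est / se))
  structure(list(
    coefficients = data.frame(term = c("(Intercept)", "mean_n"),
                              estimate = unname(est), se = unname(se),
                              ci_lo = unname(ci[, 1]),
                              ci_hi = unname(ci[, 2]),
                              p_value = unname(p), row.names = NULL),
    converged = fit$converged && !separation,
    iterations = fit$iter,
    separation = separation,
    fit = fit), class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> converged: %s (%d IRLS iterations)\n",
              x$converged, x$iterations))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Detection thresholds over a plot survey table
#'
#' Among plots with at least one detection, reports the minimum mean
#' measured nitrogen, minimum mean likelihood of favorable pixels, and
#' minimum favorable area fraction; plus detection rates per elevation
#' band and per mean-nitrogen bin (< 1.1, 1.1-1.4, > 1.4 % DM).
#' Invariant to row order.
#'
#' @param table plot table with `detected` (or `n_gliders`),
#'   `mean_n_pct_dm`, and optionally `mean_likelihood`,
#'   `favorable_fraction_pct`, `position` / `band`.
#' @return List: `min_mean_n`, `min_mean_likelihood`,
#'   `min_favorable_fraction_pct`, `rate_by_band` (named vector or
#'   `NULL`), `rate_by_n_bin` (named vector), `n_detection_plots`.
#' @export
detection_thresholds <- function(table) {
  det <- if ("detected" %in% names(table)) table$detected >= 1
         else table$n_gliders >= 1
  if (!any(det)) {
    warning("no detection plots; threshold summary undefined")
    return(list(min_mean_n = NA_real_, min_mean_likelihood = NA_real_,
                min_favorable_fraction_pct = NA_real_,
                rate_by_band = NULL, rate_by_n_bin = NULL,
                n_detection_plots = 0L))
  }
  get_min <- function(col) {
    if (col %in% names(table)) min(table[[col]][det], na.rm = TRUE)
    else NA_real_
  }
  band_col <- intersect(c("band", "position"), names(table))[1]
  rate_by_band <- if (!is.na(band_col)) {
    vapply(split(det, table[[band_col]]), mean, numeric(1))
  } else NULL
  bins <- cut(table$mean_n_pct_dm, c(-Inf, 1.1, 1.4, Inf),
              labels = c("<1.1", "1.1-1.4", ">1.4"), right = FALSE)
  rate_by_n_bin <- vapply(split(det, bins), mean, numeric(1))
  list(min_mean_n = get_min("mean_n_pct_dm"),
       min_mean_likelihood = get_min("mean_likelihood"),
       min_favorable_fraction_pct = get_min("favorable_fraction_pct"),
       rate_by_band = rate_by_band,
       rate_by_n_bin = rate_by_n_bin,
       n_detection_plots = sum(det))
}
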