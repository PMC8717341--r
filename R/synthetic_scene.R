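#' Configuration for a synthetic multispectral forest scene
#'
#' Defines the study conditions a generated scene emulates: a square
#' extent at home-range scale, a plot network spread over three
#' elevation bands, a species pool with per-species foliar nitrogen
#' distributions, a documented monotone reflectance-nitrogen link, and
#' a height-to-crown-width allometry.  The seed fully determines every
#' raster and table derived from the configuration.
#'
#' The reflectance link is linear per band: for a crown pixel of a tree
#' with foliar nitrogen `N` (% dry matter), `green = g0 + g1 * N` and
#' `nir = n0 + n1 * N` with positive slopes, the red-edge band carries a
#' weak positive slope and blue/red are flat baselines.  Ground and
#' understory pixels get baselines with low NDVI.  This places the
#' recoverable signal in the green band and in green/NIR difference
#' indices, the leading predictors of canopy nitrogen.
#'
#' @param extent_m square scene side length (m); default 200 (4 ha).
#' @param pixel_size_m raster resolution (m); default 0.25.
#' @param n_plots number of survey plots laid out on a grid.
#' @param trees_per_plot dominant (foliage-sampled) trees per plot.
#' @param background_trees_per_plot additional unsampled canopy trees.
#' @param species_pool data frame with columns `species`, `band`
#'   (elevation band), `mean_n`, `sd_n` (% DM), `digestibility`
#'   (fraction of N digestible, in `[0.5, 1]`).
#' @param noise_sd per-pixel, per-band reflectance noise SD.
#' @param crown_n_sd within-crown per-pixel SD of effective nitrogen
#'   (% DM) feeding the reflectance link; 0 makes crowns spectrally
#'   uniform so the link inverts exactly.
#' @param link reflectance-link coefficients; see Details above.
#' @param allometry crown-width allometry `width = intercept + slope *
#'   height + noise`, with `sd` the noise SD and `min_width` a floor (m).
#' @param height_range_m uniform range for tree heights (m).
#' @param min_subcanopy_height_m per-plot masking height (m): pixels
#'   below it count as understory/ground (non-habitat).
#' @param missing_dign_fraction fraction of trees with digestible N
#'   missing, emulating laboratory sample loss.
#' @param detection_beta logit intercept and slope used to simulate
#'   per-plot folivore detections from mean plot nitrogen.
#' @param ndvi_min default NDVI foliage-mask threshold.
#' @param seed integer; fully determines the generated scene.
#' @return An object of class `scene_config` (a validated list).
#' @export
scene_config <- function(extent_m = 200,
                         pixel_size_m = 0.25,
                         n_plots = 6,
                         trees_per_plot = 5,
                         background_trees_per_plot = 8,
                         species_pool = default_species_pool(),
                         noise_sd = 0.01,
                         crown_n_sd = 0,
                         link = list(green = c(0.08, 0.05),
                                     nir = c(0.45, 0.10),
                                     red_edge = c(0.28, 0.02),
                                     blue = 0.05,
                                     red = 0.04,
                                     ground = c(blue = 0.06, green = 0.10,
                                                red = 0.12, red_edge = 0.14,
                                                nir = 0.15)),
                         allometry = list(intercept = 1.0, slope = 0.16,
                                          sd = 0.25, min_width = 1),
                         height_range_m = c(20, 38),
                         min_subcanopy_height_m = 8,
                         missing_dign_fraction = 0.2,
                         detection_beta = c(-5.6, 3.6),
                         ndvi_min = 0.6,
                         seed = 1L) {
  stopifnot(extent_m > 0, pixel_size_m > 0, n_plots >= 1,
            trees_per_plot >= 1, background_trees_per_plot >= 0,
            is.data.frame(species_pool),
            all(c("species", "band", "mean_n", "sd_n", "digestibility") %in%
                  names(species_pool)),
            noise_sd >= 0, crown_n_sd >= 0,
            length(height_range_m) == 2L, diff(height_range_m) >= 0,
            length(detection_beta) == 2L, all(is.finite(detection_beta)))
  if (any(species_pool$mean_n < 0.5 | species_pool$mean_n > 2.0))
    stop("species mean N values must lie within [0.5, 2.0] % DM")
  if (any(species_pool$digestibility < 0.5 | species_pool$digestibility > 1))
    stop("species digestibility must lie within [0.5, 1]")
  if (link$green[2] <= 0 || link$nir[2] <= 0)
    stop("green and NIR link slopes must be positive")
  structure(list(extent_m = extent_m, pixel_size_m = pixel_size_m,
                 n_plots = as.integer(n_plots),
                 trees_per_plot = as.integer(trees_per_plot),
                 background_trees_per_plot = as.integer(background_trees_per_plot),
                 species_pool = species_pool, noise_sd = noise_sd,
                 crown_n_sd = crown_n_sd, link = link, allometry = allometry,
                 height_range_m = height_range_m,
                 min_subcanopy_height_m = min_subcanopy_height_m,
                 missing_dign_fraction = missing_dign_fraction,
                 detection_beta = detection_beta, ndvi_min = ndvi_min,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Default eucalypt species pool for synthetic scenes
#'
#' Nine species spread over the three elevation bands, with mean foliar
#' nitrogen rising from the lowlands (~1% DM) to high elevation
#' (~1.5% DM), bracketing the observed field range.
#'
#' @return A data frame usable as `species_pool` in [scene_config()].
#' @export
default_species_pool <- function() {
  data.frame(
    species = c("E. sieberi", "E. globoidea", "E. consideniana",
                "E. obliqua", "E. cypellocarpa", "E. fastigata",
                "E. croajingolensis", "E. viminalis", "E. delegatensis"),
    band = rep(c("lowlands", "mid_hills", "high_elevation"), each = 3L),
    mean_n = c(1.00, 0.95, 1.05, 1.25, 1.50, 1.35, 1.55, 1.45, 1.50),
    sd_n = rep(0.15, 9L),
    digestibility = c(0.80, 0.85, 0.75, 0.75, 0.65, 0.70, 0.60, 0.75, 0.65),
    stringsAsFactors = FALSE
  )
}

#' Read a scene configuration from YAML
#'
#' Top-level YAML keys map to [scene_config()] arguments;
#' `species_pool`, when present, must be a list of per-species records.
#'
#' @param path path to a YAML file.
#' @return A `scene_config`.
#' @export
read_scene_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$species_pool))
    raw$species_pool <- do.call(rbind, lapply(raw$species_pool, as.data.frame))
  do.call(scene_config, raw)
}

# plot centers on a grid across the extent, cycled over elevation bands
plot_layout <- function(config) {
  k <- ceiling(sqrt(config$n_plots))
  cell <- config$extent_m / k
  idx <- seq_len(config$n_plots) - 1L
  bands <- unique(config$species_pool$band)
  data.frame(
    plot_id = seq_len(config$n_plots),
    x = (idx %% k + 0.5) * cell,
    y = (idx %/% k + 0.5) * cell,
    band = bands[(idx %% length(bands)) + 1L],
    min_subcanopy_height_m = config$min_subcanopy_height_m,
    stringsAsFactors = FALSE
  )
}

#' Generate a ground-truth tree list for a synthetic scene
#'
#' Trees are placed on a jittered grid inside each plot so that crown
#' centers never coincide and crowns of neighboring trees do not
#' overlap; per-species foliar nitrogen is drawn around the pool mean,
#' and crown width follows the configured height allometry with noise,
#' so [fit_crown_width_model()] can recover it.  The first
#' `trees_per_plot` trees of each plot are flagged `sampled` (the
#' foliage-sampled dominant trees); the rest are background canopy.
#'
#' @param config a [scene_config()].
#' @return Data frame with one row per tree: `tree_id`, `plot_id`, `x`,
#'   `y`, `species`, `dbh_m`, `height_m`, `crown_width_m`, `n_pct_dm`,
#'   `dign_pct_dm` (NA for a configured fraction), `sampled`,
#'   `ndvi_min`.
#' @export
generate_tree_list <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed_if(config$seed, {
    plots <- plot_layout(config)
    k <- ceiling(sqrt(config$n_plots))
    plot_side <- config$extent_m / k * 0.9
    n_tree <- config$trees_per_plot + config$background_trees_per_plot
    m <- ceiling(sqrt(n_tree))
    spacing <- plot_side / m
    # worst-case crown width under the allometry + 4 SD of noise
    max_cw <- config$allometry$intercept +
      config$allometry$slope * config$height_range_m[2] +
      4 * config$allometry$sd
    if (max_cw > 0.65 * spacing)
      stop(sprintf(paste0("overcrowded configuration: worst-case crown width ",
                          "%.1f m exceeds 65%% of the %.1f m tree spacing; ",
                          "reduce trees per plot or enlarge the extent"),
                   max_cw, spacing))
    jitter <- 0.15 * spacing
    pool <- config$species_pool
    out <- vector("list", nrow(plots))
    for (p in seq_len(nrow(plots))) {
      sp_band <- pool[pool$band == plots$band[p], , drop = FALSE]
      if (nrow(sp_band) == 0L) sp_band <- pool
      gi <- seq_len(n_tree) - 1L
      gx <- plots$x[p] - plot_side / 2 + (gi %% m + 0.5) * spacing
      gy <- plots$y[p] - plot_side / 2 + (gi %/% m + 0.5) * spacing
      sp <- sp_band[sample.int(nrow(sp_band), n_tree, replace = TRUE), ]
      height <- runif(n_tree, config$height_range_m[1], config$height_range_m[2])
      cw <- pmax(config$allometry$min_width,
                 config$allometry$intercept + config$allometry$slope * height +
                   rnorm(n_tree, 0, config$allometry$sd))
      n_pct <- pmin(2.5, pmax(0.3, rnorm(n_tree, sp$mean_n, sp$sd_n)))
      dign <- n_pct * sp$digestibility
      dign[runif(n_tree) < config$missing_dign_fraction] <- NA_real_
      out[[p]] <- data.frame(
        plot_id = plots$plot_id[p],
        x = gx + runif(n_tree, -jitter, jitter),
        y = gy + runif(n_tree, -jitter, jitter),
        species = sp$species,
        dbh_m = pmax(0.1, height * 0.025 + rnorm(n_tree, 0, 0.05)),
        height_m = height,
        crown_width_m = cw,
        n_pct_dm = n_pct,
        dign_pct_dm = dign,
        sampled = seq_len(n_tree) <= config$trees_per_plot,
        ndvi_min = config$ndvi_min,
        stringsAsFactors = FALSE
      )
    }
    trees <- do.call(rbind, out)
    trees <- cbind(tree_id = seq_len(nrow(trees)), trees)
    rownames(trees) <- NULL
    trees
  })
}

#' Render a synthetic scene from a tree list
#'
#' Each crown is a paraboloid dome (height `H * (1 - (r/R)^2)` inside
#' radius `R = crown_width / 2`, giving a single local height maximum
#' per tree); where domes overlap, the taller surface wins.  Crown
#' pixels take reflectance from the configured linear nitrogen link
#' plus zero-mean sensor noise; ground pixels take low-NDVI baselines.
#' All reflectance is clipped to `[0, 1]`.
#'
#' @param trees data frame from [generate_tree_list()].
#' @param config the matching [scene_config()].
#' @return A list of class `scene` with elements `stack` (5-band
#'   [band_stack()]), `chm` (a [chm()]), and `truth` (list with `trees`,
#'   `plot_centers`, `detections`, `min_subcanopy_height_m`, `owner`
#'   raster of tree ids, `label_truth` raster coded 1 = favorable,
#'   0 = unfavorable, 255 = non-habitat).
#' @export
render_scene <- function(trees, config) {
  stopifnot(inherits(config, "scene_config"))
  if (nrow(trees) > 0 &&
      (any(trees$x < 0 | trees$x > config$extent_m) ||
       any(trees$y < 0 | trees$y > config$extent_m)))
    stop("trees must lie inside the scene extent")
  px <- config$pixel_size_m
  n <- round(config$extent_m / px)
  origin <- c(0, n * px)
  heights <- matrix(0, n, n)
  owner <- matrix(0L, n, n)
  for (t in seq_len(nrow(trees))) {
    R <- trees$crown_width_m[t] / 2
    H <- trees$height_m[t]
    cc <- scene_to_cell(trees$x[t], trees$y[t], px, origin)
    rows <- max(1L, floor(cc$row - R / px)):min(n, ceiling(cc$row + R / px))
    cols <- max(1L, floor(cc$col - R / px)):min(n, ceiling(cc$col + R / px))
    if (length(rows) == 0L || length(cols) == 0L) next
    dr <- (rows - cc$row) * px
    dc <- (cols - cc$col) * px
    r2 <- outer(dr^2, dc^2, "+")
    dome <- H * (1 - r2 / R^2)
    dome[r2 > R^2] <- -Inf
    cur <- heights[rows, cols, drop = FALSE]
    take <- dome > cur
    if (any(take)) {
      cur[take] <- dome[take]
      heights[rows, cols] <- cur
      ow <- owner[rows, cols, drop = FALSE]
      ow[take] <- trees$tree_id[t]
      owner[rows, cols] <- ow
    }
  }

  with_seed_if(config$seed + 1L, {
    g <- config$link$ground
    bands <- list(
      blue = matrix(g[["blue"]], n, n),
      green = matrix(g[["green"]], n, n),
      red = matrix(g[["red"]], n, n),
      red_edge = matrix(g[["red_edge"]], n, n),
      nir = matrix(g[["nir"]], n, n)
    )
    idx <- which(owner > 0L)
    if (length(idx)) {
      n_pix <- trees$n_pct_dm[match(owner[idx], trees$tree_id)]
      if (config$crown_n_sd > 0)
        n_pix <- n_pix + rnorm(length(idx), 0, config$crown_n_sd)
      bands$green[idx] <- config$link$green[1] + config$link$green[2] * n_pix
      bands$nir[idx] <- config$link$nir[1] + config$link$nir[2] * n_pix
      bands$red_edge[idx] <- config$link$red_edge[1] +
        config$link$red_edge[2] * n_pix
      bands$blue[idx] <- config$link$blue
      bands$red[idx] <- config$link$red
    }
    if (config$noise_sd > 0)
      bands <- lapply(bands, function(b) b + rnorm(length(b), 0, config$noise_sd))
    bands <- lapply(bands, function(b) {
      b[b < 0] <- 0; b[b > 1] <- 1
      matrix(b, n, n)
    })

    plots <- plot_layout(config)
    label <- matrix(255L, n, n)
    if (length(idx)) {
      tree_row <- match(owner[idx], trees$tree_id)
      canopy <- heights[idx] >=
        plots$min_subcanopy_height_m[match(trees$plot_id[tree_row], plots$plot_id)]
      lab <- ifelse(trees$n_pct_dm[tree_row] >= 1.0, 1L, 0L)
      label[idx[canopy]] <- lab[canopy]
    }

    mean_n <- vapply(split(trees$n_pct_dm[trees$sampled],
                           trees$plot_id[trees$sampled]),
                     mean, numeric(1))
    mn <- as.numeric(mean_n[as.character(plots$plot_id)])
    det <- integer(nrow(plots))
    ok <- is.finite(mn)
    det[ok] <- simulate_detections(mn[ok],
                                   beta0 = config$detection_beta[1],
                                   beta1 = config$detection_beta[2],
                                   seed = config$seed + 2L)
    detections <- data.frame(plot_id = plots$plot_id,
                             mean_n_pct_dm = mn,
                             detected = det)

    structure(list(
      stack = band_stack(bands, px, origin),
      chm = chm(heights, px, origin, fill_method = "rendered"),
      truth = list(trees = trees, plot_centers = plots,
                   detections = detections,
                   min_subcanopy_height_m = config$min_subcanopy_height_m,
                   owner = owner, label_truth = label)
    ), class = "scene")
  })
}

#' Simulate per-plot folivore detections from mean plot nitrogen
#'
#' Detections are Bernoulli draws with success probability
#' `plogis(beta0 + beta1 * meanN)` per plot.
#'
#' @param plot_mean_n numeric vector of mean plot nitrogen (% DM).
#' @param beta0,beta1 logit intercept and slope; defaults are the
#'   plot-level detection model coefficients (-5.6, 3.6).
#' @param seed optional integer seed.
#' @return Integer vector of 0/1 detections, one per plot.
#' @export
simulate_detections <- function(plot_mean_n, beta0 = -5.6, beta1 = 3.6,
                                seed = NULL) {
  stopifnot(is.finite(beta0), is.finite(beta1))
  with_seed_if(seed,
    rbinom(length(plot_mean_n), 1L, plogis(beta0 + beta1 * plot_mean_n)))
}

#' Write scene truth tables as CSV
#'
#' Writes `trees.csv`, `plots.csv` and `detections.csv` into `dir`.
#'
#' @param truth the `truth` element of a rendered scene.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(truth$trees, file.path(dir, "trees.csv"), row.names = FALSE)
  write.csv(truth$plot_centers, file.path(dir, "plots.csv"), row.names = FALSE)
  write.csv(truth$detections, file.path(dir, "detections.csv"), row.names = FALSE)
  invisible(dir)
}
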