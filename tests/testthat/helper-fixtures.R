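# Shared fixtures and independent brute-force oracles.
# The full synthetic-scene pipeline is built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A 140 m scene (4 plots, 13 trees each) at 0.25 m: big enough for the
# regression/classification protocols, small enough to run in seconds.
test_scene_config <- function(noise_sd = 0.02, seed = 7) {
  scene_config(extent_m = 140, n_plots = 4, seed = seed, noise_sd = noise_sd)
}

# full pipeline: scene -> CHM -> markers -> crowns -> sampled summaries
build_pipeline <- function(cfg) {
  trees <- generate_tree_list(cfg)
  sc <- render_scene(trees, cfg)
  fs <- compute_feature_stack(sc$stack)
  cw <- fit_crown_width_model(trees)
  mk <- detect_trees(sc$chm, function(h) predict(cw, h), min_height_m = 10)
  mk_m <- match_markers_to_trees(mk, trees)
  seg <- segment_crowns(sc$chm, mk_m, min_height_m = 10)
  res <- sample_crown_summaries(fs, seg, trees, seed = 1)
  list(cfg = cfg, trees = trees, scene = sc, features = fs, cw_model = cw,
       markers_raw = mk, markers = mk_m, segments = seg,
       summaries = res$summaries, pixels = res$pixels)
}

get_pipeline <- function() {
  if (is.null(.fixtures$pipeline))
    .fixtures$pipeline <- build_pipeline(test_scene_config())
  .fixtures$pipeline
}

# random 5-band stack for per-pixel oracles
random_stack <- function(nr = 8, nc = 8, seed = 1) {
  set.seed(seed)
  band_stack(setNames(lapply(1:5, function(i)
    matrix(runif(nr * nc, 0.01, 0.9), nr, nc)), reflectance_bands()), 0.5)
}

# --- independent oracles -------------------------------------------------

# per-pixel index formulas written out longhand, scalar at a time
oracle_index <- function(stack, name) {
  b <- stack$bands
  d <- dim(b[[1]])
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    blue <- b$blue[i, j]; green <- b$green[i, j]; red <- b$red[i, j]
    re <- b$red_edge[i, j]; nir <- b$nir[i, j]
    val <- switch(name,
      gdvi = nir - green,
      ndi_b_nir = if (blue + nir == 0) NA else (blue - nir) / (blue + nir),
      ndi_re_nir = if (re + nir == 0) NA else (re - nir) / (re + nir),
      ri = if (red + green == 0) NA else (red - green) / (red + green),
      vari = if (green + red - blue == 0) NA
             else (green - red) / (green + red - blue),
      ndvi = if (nir + red == 0) NA else (nir - red) / (nir + red),
      gndvi = if (nir + green == 0) NA else (nir - green) / (nir + green),
      ndre = if (nir + re == 0) NA else (nir - re) / (nir + re),
      sr = if (red == 0) NA else nir / red,
      grvi = if (green == 0) NA else nir / green,
      evi = if (nir + 6 * red - 7.5 * blue + 1 == 0) NA
            else 2.5 * (nir - red) / (nir + 6 * red - 7.5 * blue + 1),
      ci_green = if (green == 0) NA else nir / green - 1,
      ci_rededge = if (re == 0) NA else nir / re - 1,
      savi = if (nir + red + 0.5 == 0) NA
             else 1.5 * (nir - red) / (nir + red + 0.5),
      stop("unknown index"))
    out[i, j] <- val
  }
  out
}

# clumpiness by explicit neighbor loops (rook, double count)
oracle_clumpiness <- function(classes, class_id) {
  nr <- nrow(classes); nc <- ncol(classes)
  n_c <- sum(classes == class_id)
  if (n_c == 0) return(NA_real_)
  p <- n_c / (nr * nc)
  if (p == 1) return(1)
  like <- 0; tot <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (classes[i, j] != class_id) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      a <- i + d[1]; b <- j + d[2]
      if (a < 1 || a > nr || b < 1 || b > nc) next
      tot <- tot + 1
      if (classes[a, b] == class_id) like <- like + 1
    }
  }
  if (tot == 0) return(NA_real_)
  g <- like / tot
  if (g >= p || p >= 0.5) (g - p) / (1 - p) else (g - p) / p
}

# AUC as the average over all positive-negative score pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# operating threshold by exhaustive scan over a fine fixed grid
oracle_threshold_grid <- function(scores, labels, step = 0.001) {
  grid <- seq(min(scores), max(scores), by = step)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best_j <- -Inf; best_t <- NA
  for (t in grid) {
    tpr <- sum(scores >= t & labels == 1) / n1
    tnr <- sum(scores < t & labels == 0) / n0
    if (tpr + tnr > best_j + 1e-12) {
      best_j <- tpr + tnr; best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}
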