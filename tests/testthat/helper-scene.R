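# Shared fixtures, built lazily and cached so expensive objects (the default
# 200x200 scene and its full feature stack) are simulated once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_scene <- function() {
  cached("scene200", function() simulate_scene(scene_config(seed = 7)))
}

default_composites <- function() {
  cached("comp200", function() {
    sc <- default_scene()
    list(optical = percentile_range_composite(mask_clouds(sc$optical, 0.5)),
         radar = percentile_range_composite(sc$radar))
  })
}

default_features <- function() {
  cached("feat200", function() {
    sc <- default_scene()
    cp <- default_composites()
    assemble_combination("S2+S1+DEM", optical = cp$optical, radar = cp$radar,
                         radar_series = sc$radar, dem = sc$dem)
  })
}

default_table <- function() {
  cached("table200", function() {
    standardize(extract_training_pixels(default_features(), default_scene()$reference))
  })
}

default_model <- function() {
  cached("model200", function() train_rf(default_table(), 100, 2, seed = 7))
}

# small scene + per-tag standardised training tables and test points, used by
# the multi-seed ordering properties; feature layers are assembled once for
# the fullest combination and subset per tag
tag_tables <- function(seed, rows = 100, cols = 100, n_points = 25) {
  cfg <- scene_config(rows = rows, cols = cols, seed = seed)
  sc <- simulate_scene(cfg, n_polygons_per_class = 2,
                       n_points_per_class = n_points)
  oc <- percentile_range_composite(mask_clouds(sc$optical, 0.5))
  rc <- percentile_range_composite(sc$radar)
  feats <- assemble_combination("S2+S1+DEM", optical = oc, radar = rc,
                                radar_series = sc$radar, dem = sc$dem)
  full <- standardize(extract_training_pixels(feats, sc$reference))
  list(scene = sc, features = feats, full_table = full)
}

subset_table <- function(full, tag) {
  full$x <- full$x[, combination_features(tag), drop = FALSE]
  full
}

# held-out OA for a tag: train on the training table, score the test points
tag_test_oa <- function(tt, tag, seed, ntree = 100, mtry = 2) {
  tab <- subset_table(tt$full_table, tag)
  model <- train_rf(tab, ntree, mtry, seed = seed)
  map <- predict_map(model, tt$features)
  confusion(map, tt$scene$reference)$oa
}

# brute-force composite oracle: per pixel/band, quantile() the valid values
# and average those inside the closed percentile interval
oracle_composite_value <- function(v, p_lo, p_hi) {
  v <- sort(v[!is.na(v)])
  if (!length(v)) return(NA_real_)
  q <- stats::quantile(v, c(p_lo, p_hi) / 100, type = 7, names = FALSE)
  inside <- v[v >= q[1] & v <= q[2]]
  if (length(inside)) return(mean(inside))
  # empty interval: observation nearest the midpoint, ties to the smaller
  mid <- mean(q)
  d <- abs(v - mid)
  v[which(d <= min(d) + 1e-9 * (1 + abs(mid)))][1]
}

# brute-force per-pixel GLCM oracle: build the explicit normalised symmetric
# co-occurrence matrix pooled over the offsets and evaluate the three
# statistics from their definitions
oracle_glcm_pixel <- function(q, r, c, spec) {
  nr <- nrow(q); nc <- ncol(q)
  k <- (spec$kernel - 1) / 2
  offs <- list("0" = c(0, spec$distance), "45" = c(-spec$distance, spec$distance),
               "90" = c(-spec$distance, 0),
               "135" = c(-spec$distance, -spec$distance))[spec$directions]
  offs <- c(offs, lapply(offs, function(o) -o))  # both senses per direction
  ng <- spec$n_grey
  P <- matrix(0, ng, ng)
  for (off in offs) {
    for (dr in -k:k) {
      for (dc in -k:k) {
        r1 <- r + dr; c1 <- c + dc
        r2 <- r1 + off[1]; c2 <- c1 + off[2]
        if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        i <- q[r1, c1] + 1; j <- q[r2, c2] + 1
        P[i, j] <- P[i, j] + 1
        P[j, i] <- P[j, i] + 1
      }
    }
  }
  if (sum(P) == 0) return(c(contrast = NA, correlation = NA, variance = NA))
  P <- P / sum(P)
  lv <- 0:(ng - 1)
  pi_ <- rowSums(P)
  mu_i <- sum(lv * pi_)
  var_i <- sum((lv - mu_i)^2 * pi_)
  contrast <- sum(outer(lv, lv, function(a, b) (a - b)^2) * P)
  corr <- if (var_i > 0) {
    sum(outer(lv - mu_i, lv - mu_i) * P) / var_i
  } else 0
  variance <- sum(P * outer((lv - mu_i)^2, rep(1, ng)))
  c(contrast = contrast, correlation = corr, variance = variance)
}

# independent quantisation for the GLCM oracle
oracle_quantise <- function(m, ng) {
  rng <- range(m, na.rm = TRUE)
  if (rng[2] == rng[1]) return(m * 0)
  q <- floor((m - rng[1]) / (rng[2] - rng[1]) * ng)
  pmin(q, ng - 1)
}
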