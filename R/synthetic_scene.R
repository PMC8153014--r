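# Smooth unit-variance Gaussian random field via FFT (circular convolution
# with a Gaussian kernel of the given correlation length, in pixels).
smooth_field <- function(nr, nc, scale) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (scale <= 0 || nr * nc == 1) return(z)
  fr <- fft_freq(nr)
  fc <- fft_freq(nc)
  h <- exp(-2 * pi^2 * scale^2 * outer(fr^2, fc^2, "+"))
  zs <- Re(stats::fft(stats::fft(z) * h, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(zs)
  if (s > 0) zs / s else zs
}

fft_freq <- function(n) {
  (((seq_len(n) - 1) + floor(n / 2)) %% n - floor(n / 2)) / n
}

#' Generate a synthetic digital elevation model
#'
#' A coastal-plain terrain: a monotone trend rising inland (south to north)
#' over `relief_m` metres, small-scale roughness from a smooth random field,
#' and a few meandering valley lines carved towards the coast. All values are
#' finite and the result is a pure function of the configuration (seed).
#'
#' @param config a [scene_config()].
#' @return a `raster_grid` in metres on the DEM grid (`dem_pixel_size`).
#' @export
generate_dem <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  extent_x <- config$cols * config$pixel_size
  extent_y <- config$rows * config$pixel_size
  nr <- max(2L, as.integer(ceiling(extent_y / config$dem_pixel_size)))
  nc <- max(2L, as.integer(ceiling(extent_x / config$dem_pixel_size)))
  withr::with_seed(config$seed + 2L, {
    trend <- matrix(rep(config$relief_m * (rev(seq_len(nr)) - 1) / (nr - 1),
                        times = nc), nr, nc)
    rough <- config$roughness_m * smooth_field(nr, nc, scale = 3)
    valleys <- matrix(0, nr, nc)
    n_valley <- 3L
    depth <- 0.25 * config$relief_m
    for (v in seq_len(n_valley)) {
      col <- stats::runif(1, 0.15, 0.85) * nc
      mask <- matrix(0, nr, nc)
      for (r in seq_len(nr)) {
        col <- col + stats::rnorm(1, 0, 0.8)
        col <- min(max(col, 1), nc)
        mask[r, round(col)] <- 1
      }
      sm <- Re(stats::fft(stats::fft(mask) *
                            exp(-2 * pi^2 * 2.5^2 *
                                  outer(fft_freq(nr)^2, fft_freq(nc)^2, "+")),
                          inverse = TRUE)) / (nr * nc)
      if (max(sm) > 0) valleys <- valleys + sm / max(sm)
    }
    dem <- trend + rough - depth * pmin(valleys, 1)
    raster_grid(dem, config$dem_pixel_size)
  })
}

#' Generate the true class map
#'
#' Class patches arise from per-class suitability surfaces: an elevation
#' affinity (zero inside the class's preferred elevation interval, decreasing
#' linearly outside it) plus a smooth random field at the configured patch
#' correlation length. Each pixel takes the class with maximal suitability,
#' which places water and the peatland classes preferentially in valley
#' bottoms and the coastal strip, and yields spatially autocorrelated patches.
#'
#' @param config a [scene_config()].
#' @param dem optional `raster_grid` DEM to condition on; generated from the
#'   same configuration when omitted.
#' @return a categorical `raster_grid` of class indices with a `classes`
#'   element naming the index levels.
#' @export
generate_class_map <- function(config, dem = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(dem)) dem <- generate_dem(config)
  target <- raster_grid(matrix(0, config$rows, config$cols), config$pixel_size)
  dem20 <- resample_to_grid(dem, target)$values
  sigs <- config$signatures
  k <- length(sigs)
  withr::with_seed(config$seed + 1L, {
    noise_w <- 1.6  # balances elevation affinity (m-scaled) vs patchiness
    soft_m <- 2.5   # metres of affinity loss per metre outside the interval
    score <- vector("list", k)
    for (i in seq_len(k)) {
      s <- sigs[[i]]
      lo <- s$elevation_range_m[1]; hi <- s$elevation_range_m[2]
      aff <- -pmax(0, lo - dem20, dem20 - hi) / soft_m
      score[[i]] <- aff + noise_w * smooth_field(config$rows, config$cols,
                                                 config$patch_scale)
    }
    # calibrate per-class bias toward the configured target proportions
    # (multiplicative-weights update on log shares; deterministic)
    target <- as.numeric(config$target_proportions[names(sigs)])
    bias <- numeric(k)
    idx <- NULL
    for (it in seq_len(40)) {
      best <- matrix(-Inf, config$rows, config$cols)
      idx <- matrix(1L, config$rows, config$cols)
      for (i in seq_len(k)) {
        sc <- score[[i]] + bias[i]
        upd <- sc > best
        best[upd] <- sc[upd]
        idx[upd] <- i
      }
      share <- tabulate(idx, k) / length(idx)
      bias <- bias + 0.6 * log(target / pmax(share, 1e-4))
      bias <- bias - mean(bias)
    }
    out <- raster_grid(idx, config$pixel_size, categorical = TRUE)
    out$classes <- names(sigs)
    out
  })
}

#' Generate the optical image time series
#'
#' One stack per date with the 10 reflectance bands plus the two cloud-proxy
#' detector layers. Per pixel and band, reflectance is the class mean plus a
#' sinusoidal annual cycle and Gaussian noise, clipped to `[0, 1]`. Each date
#' carries a spatially contiguous cloud field covering approximately the
#' configured fraction; cloudy pixels are brightened in all bands and
#' overwritten with high values in Blue and both proxy layers. The true cloud
#' mask is kept on each stack as `cloud_truth` so detection can be scored.
#'
#' @param truth categorical `raster_grid` from [generate_class_map()].
#' @param config a [scene_config()].
#' @return an `image_series` of `scene_stack`s.
#' @export
generate_optical_series <- function(truth, config) {
  sigs <- config$signatures
  check_truth_signatures(truth, sigs)
  nr <- nrow(truth$values); nc <- ncol(truth$values)
  cls <- truth$values
  n <- config$n_optical
  withr::with_seed(config$seed + 3L, {
    stacks <- vector("list", n)
    mean_mat <- vapply(sigs, function(s) s$optical_mean, numeric(length(OPTICAL_BANDS)))
    sd_mat <- vapply(sigs, function(s) s$optical_sd, numeric(length(OPTICAL_BANDS)))
    amp_mat <- vapply(sigs, function(s) s$seasonal_amplitude,
                      numeric(length(OPTICAL_BANDS)))
    for (d in seq_len(n)) {
      tfrac <- (d - 0.5) / n
      season <- sin(2 * pi * tfrac)
      bands <- stats::setNames(vector("list", length(OPTICAL_BANDS)), OPTICAL_BANDS)
      for (b in seq_along(OPTICAL_BANDS)) {
        mu <- matrix(mean_mat[b, cls] + amp_mat[b, cls] * season, nr, nc)
        sdv <- matrix(sd_mat[b, cls], nr, nc)
        v <- mu + matrix(stats::rnorm(nr * nc), nr, nc) * sdv
        bands[[b]] <- pmin(pmax(v, 0), 1)
      }
      bands$Aerosol <- pmin(pmax(0.9 * bands$Blue +
                                   matrix(stats::rnorm(nr * nc, 0, 0.003), nr, nc),
                                 0), 1)
      bands$Cirrus <- pmin(pmax(matrix(stats::rnorm(nr * nc, 0.005, 0.002), nr, nc),
                                0), 1)
      cloudy <- matrix(FALSE, nr, nc)
      if (config$cloud_fraction > 0) {
        f <- smooth_field(nr, nc, scale = 8)
        thr <- stats::quantile(f, 1 - config$cloud_fraction, type = 7)
        cloudy <- f >= thr
        if (config$cloud_fraction >= 1) cloudy[] <- TRUE
        ncl <- sum(cloudy)
        if (ncl > 0) {
          for (b in OPTICAL_BANDS) {
            bands[[b]][cloudy] <- pmin(pmax(
              0.6 * 0.7 + 0.4 * bands[[b]][cloudy] +
                stats::rnorm(ncl, 0, 0.02), 0), 1)
          }
          bands$Blue[cloudy] <- pmin(pmax(0.45 + stats::rnorm(ncl, 0, 0.05), 0), 1)
          bands$Aerosol[cloudy] <- pmin(pmax(0.45 + stats::rnorm(ncl, 0, 0.05), 0), 1)
          bands$Cirrus[cloudy] <- pmin(pmax(0.15 + stats::rnorm(ncl, 0, 0.02), 0), 1)
        }
      }
      st <- scene_stack(bands, truth$pixel_size, truth$origin, time = d)
      st$cloud_truth <- cloudy
      stacks[[d]] <- st
    }
    image_series(stacks, seq_len(n))
  })
}

#' Generate the radar image time series
#'
#' Per date, linear-power backscatter is the class mean power multiplied by
#' Gamma(`looks`, rate = `looks`) speckle (unit mean), stored in dB. Radar is
#' all-weather, so no cloud contamination is simulated.
#'
#' @param truth categorical `raster_grid`.
#' @param config a [scene_config()].
#' @return an `image_series` with bands `VV` and `VH`.
#' @export
generate_sar_series <- function(truth, config) {
  sigs <- config$signatures
  check_truth_signatures(truth, sigs)
  looks <- vapply(sigs, function(s) s$speckle_looks, 0)
  if (any(looks < 1)) stop("speckle_looks must be >= 1", call. = FALSE)
  nr <- nrow(truth$values); nc <- ncol(truth$values)
  cls <- truth$values
  withr::with_seed(config$seed + 4L, {
    stacks <- vector("list", config$n_radar)
    for (d in seq_len(config$n_radar)) {
      bands <- list()
      for (b in SAR_BANDS) {
        mdb <- vapply(sigs, function(s) s$sar_mean_db[[b]], 0)
        pow <- 10^(mdb[cls] / 10)
        shp <- looks[cls]
        speck <- stats::rgamma(nr * nc, shape = shp, rate = shp)
        bands[[b]] <- matrix(10 * log10(pow * speck), nr, nc)
      }
      stacks[[d]] <- scene_stack(bands, truth$pixel_size, truth$origin, time = d)
    }
    image_series(stacks, seq_len(config$n_radar))
  })
}

check_truth_signatures <- function(truth, sigs) {
  stopifnot(inherits(truth, "raster_grid"))
  used <- sort(unique(as.vector(truth$values)))
  if (any(used < 1) || any(used > length(sigs))) {
    stop("truth contains a class index with no signature", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample reference data from a true class map
#'
#' Training data are rectangular polygons fully inside single-class patches;
#' testing data are stratified-random points disjoint from the training
#' polygons. Labels are copied from the truth, so reference labels agree with
#' the truth at every sampled location by construction.
#'
#' @param truth categorical `raster_grid` with a `classes` element.
#' @param n_polygons_per_class rectangles per class (default 2).
#' @param n_points_per_class test points per class (default 50).
#' @param seed integer seed.
#' @param max_side largest attempted polygon side in pixels (default 6).
#' @return an object of class `reference_set` with `training` (one row per
#'   polygon: class, pixel-row/col bounds, map-coordinate bounds) and
#'   `testing` (one row per point: class, row, col, x, y).
#' @export
sample_reference <- function(truth, n_polygons_per_class = 2,
                             n_points_per_class = 50, seed = 1,
                             max_side = 6) {
  stopifnot(inherits(truth, "raster_grid"), truth$categorical)
  classes <- truth$classes
  if (is.null(classes)) stop("truth lacks class names", call. = FALSE)
  cls <- truth$values
  nr <- nrow(cls); nc <- ncol(cls)
  px <- truth$pixel_size
  present <- sort(unique(as.vector(cls)))
  withr::with_seed(seed, {
    polys <- list()
    in_poly <- matrix(FALSE, nr, nc)
    for (i in seq_along(classes)) {
      if (!(i %in% present)) {
        stop(sprintf("class '%s' is absent from the truth map", classes[i]),
             call. = FALSE)
      }
      got <- 0L
      cand <- which(cls == i, arr.ind = TRUE)
      for (side in seq(max_side, 2)) {
        if (got >= n_polygons_per_class) break
        for (try in seq_len(600)) {
          if (got >= n_polygons_per_class) break
          p <- cand[sample.int(nrow(cand), 1), ]
          r0 <- p[1]; c0 <- p[2]
          r1 <- r0 + side - 1L; c1 <- c0 + side - 1L
          if (r1 > nr || c1 > nc) next
          block <- cls[r0:r1, c0:c1]
          if (all(block == i) && !any(in_poly[r0:r1, c0:c1])) {
            in_poly[r0:r1, c0:c1] <- TRUE
            polys[[length(polys) + 1L]] <- data.frame(
              class = classes[i], row0 = r0, row1 = r1, col0 = c0, col1 = c1,
              stringsAsFactors = FALSE)
            got <- got + 1L
          }
        }
      }
      if (got == 0L) {
        stop(sprintf("no single-class polygon found for class '%s'", classes[i]),
             call. = FALSE)
      }
    }
    training <- do.call(rbind, polys)
    training$id <- seq_len(nrow(training))
    training$xmin <- truth$origin[1] + (training$col0 - 1) * px
    training$xmax <- truth$origin[1] + training$col1 * px
    training$ymax <- truth$origin[2] - (training$row0 - 1) * px
    training$ymin <- truth$origin[2] - training$row1 * px

    pts <- list()
    if (n_points_per_class > 0) {
      for (i in seq_along(classes)) {
        avail <- which(cls == i & !in_poly, arr.ind = TRUE)
        if (nrow(avail) == 0) {
          stop(sprintf("no test pixels left for class '%s'", classes[i]),
               call. = FALSE)
        }
        take <- avail[sample.int(nrow(avail), min(n_points_per_class, nrow(avail))), ,
                      drop = FALSE]
        pts[[i]] <- data.frame(class = classes[i],
                               row = take[, 1], col = take[, 2],
                               stringsAsFactors = FALSE)
      }
    }
    testing <- if (length(pts)) do.call(rbind, pts) else
      data.frame(class = character(), row = integer(), col = integer(),
                 stringsAsFactors = FALSE)
    if (nrow(testing)) {
      testing$x <- truth$origin[1] + (testing$col - 0.5) * px
      testing$y <- truth$origin[2] - (testing$row - 0.5) * px
    } else {
      testing$x <- numeric(0); testing$y <- numeric(0)
    }
    rownames(training) <- NULL; rownames(testing) <- NULL
    structure(list(training = training, testing = testing, classes = classes),
              class = "reference_set")
  })
}

#' Simulate a complete labelled multi-sensor scene
#'
#' Runs the whole simulator: DEM, class map conditioned on the DEM, optical
#' and radar time series, and reference data sampled from the truth. The
#' result is a pure function of the configuration, including its seed.
#'
#' @param config a [scene_config()].
#' @param n_polygons_per_class,n_points_per_class reference sampling sizes.
#' @return an object of class `labeled_scene` with elements `truth`,
#'   `optical`, `radar`, `dem`, `reference` and `config`.
#' @export
simulate_scene <- function(config = scene_config(),
                           n_polygons_per_class = 2, n_points_per_class = 50) {
  dem <- generate_dem(config)
  truth <- generate_class_map(config, dem)
  optical <- generate_optical_series(truth, config)
  radar <- generate_sar_series(truth, config)
  reference <- sample_reference(truth, n_polygons_per_class,
                                n_points_per_class, seed = config$seed + 5L)
  structure(list(truth = truth, optical = optical, radar = radar, dem = dem,
                 reference = reference, config = config),
            class = "labeled_scene")
}
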