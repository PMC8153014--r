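# reflection (symmetric-with-edge) padding indices: for n cells and pad k,
# returns an index vector of length n + 2k
reflect_idx <- function(n, k) {
  if (k > n) stop("window larger than raster", call. = FALSE)
  c(rev(seq_len(k)), seq_len(n), n + 1 - seq_len(k))
}

pad_reflect <- function(m, k) {
  m[reflect_idx(nrow(m), k), reflect_idx(ncol(m), k), drop = FALSE]
}

# sum of (2k+1)x(2k+1) windows of a padded matrix, returned at original size
box_sum_padded <- function(padded, k, nr, nc) {
  out <- matrix(0, nr, nc)
  for (di in 0:(2 * k)) {
    for (dj in 0:(2 * k)) {
      out <- out + padded[di + seq_len(nr), dj + seq_len(nc), drop = FALSE]
    }
  }
  out
}

#' Moving-window standard deviation
#'
#' Per-pixel population standard deviation of the values in an odd-sided
#' square window (default 5x5), the texture metric applied to NDVI and to
#' the VV/VH backscatter composites. Edges are handled by reflection
#' padding; nodata cells are excluded from each window's statistics and a
#' window with no valid member yields nodata.
#'
#' @param layer a `raster_grid` or plain matrix.
#' @param window odd window side in pixels (default 5).
#' @return a `raster_grid` (or matrix, matching the input type).
#' @export
window_stddev <- function(layer, window = 5) {
  m <- if (inherits(layer, "raster_grid")) layer$values else layer
  if (window %% 2 != 1 || window < 1) stop("window must be odd", call. = FALSE)
  k <- (window - 1) / 2
  if (window > nrow(m) || window > ncol(m)) {
    stop("window larger than raster", call. = FALSE)
  }
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_reflect(m, k)
  ok <- !is.na(p)
  pz <- p; pz[!ok] <- 0
  n <- box_sum_padded(ok * 1, k, nr, nc)
  s1 <- box_sum_padded(pz, k, nr, nc)
  s2 <- box_sum_padded(pz^2, k, nr, nc)
  v <- s2 / n - (s1 / n)^2
  out <- sqrt(pmax(v, 0))
  out[n == 0] <- NA_real_
  if (inherits(layer, "raster_grid")) {
    raster_grid(out, layer$pixel_size, layer$origin)
  } else out
}

#' GLCM texture specification
#'
#' Pairs of quantised grey levels are collected at `distance` pixels along
#' the requested symmetric directions, for every anchor pixel inside a
#' `kernel` x `kernel` neighbourhood of the centre pixel; pairs falling
#' outside the raster are skipped. Values are quantised to `n_grey` levels
#' by linear rescaling over the layer's global valid range.
#'
#' @param kernel odd neighbourhood side (default 3).
#' @param distance co-occurrence offset in pixels (default 4).
#' @param n_grey number of grey levels, >= 2 (default 32).
#' @param directions subset of `c("0", "45", "90", "135")` degrees.
#' @return an object of class `glcm_spec`.
#' @export
glcm_spec <- function(kernel = 3, distance = 4, n_grey = 32,
                      directions = c("0", "45", "90", "135")) {
  if (n_grey < 2) stop("n_grey must be >= 2", call. = FALSE)
  if (distance < 1) stop("distance must be >= 1", call. = FALSE)
  if (kernel %% 2 != 1) stop("kernel must be odd", call. = FALSE)
  directions <- match.arg(directions, c("0", "45", "90", "135"),
                          several.ok = TRUE)
  structure(list(kernel = as.integer(kernel), distance = as.integer(distance),
                 n_grey = as.integer(n_grey), directions = directions),
            class = "glcm_spec")
}

glcm_offsets <- function(spec) {
  d <- spec$distance
  base <- list("0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  # both senses of every direction, the symmetric-counting convention
  out <- list()
  for (nm in spec$directions) {
    out[[paste0(nm, "+")]] <- base[[nm]]
    out[[paste0(nm, "-")]] <- -base[[nm]]
  }
  out
}

quantise_layer <- function(m, n_grey) {
  rng <- range(m, na.rm = TRUE)
  if (!all(is.finite(rng))) stop("layer has no valid values", call. = FALSE)
  if (rng[2] > rng[1]) {
    q <- floor((m - rng[1]) / (rng[2] - rng[1]) * n_grey)
    q[q == n_grey] <- n_grey - 1L
  } else {
    q <- m * 0
  }
  q
}

#' GLCM texture statistics (contrast, correlation, variance)
#'
#' Per pixel, a symmetric normalised grey-level co-occurrence matrix is
#' accumulated over all pair offsets of the spec (pooled across directions),
#' and three statistics are derived from it: contrast
#' `sum (i-j)^2 P(i,j)`, correlation
#' `sum P(i,j) (i - mu_i)(j - mu_j) / (sigma_i sigma_j)` (defined as 0 where
#' the marginal variance vanishes, so stacks stay dense), and variance
#' `sum P(i,j) (i - mu)^2`. The implementation accumulates pair moments with
#' box filters, which is algebraically identical to building the matrix.
#'
#' @param layer a `raster_grid` or matrix.
#' @param spec a [glcm_spec()].
#' @param prefix name prefix for the returned layers.
#' @return named list of `raster_grid`s (or matrices):
#'   `<prefix>_contrast`, `<prefix>_correlation`, `<prefix>_variance`.
#' @export
glcm_features <- function(layer, spec = glcm_spec(), prefix = "glcm") {
  m <- if (inherits(layer, "raster_grid")) layer$values else layer
  q <- quantise_layer(m, spec$n_grey)
  nr <- nrow(q); nc <- ncol(q)
  k <- (spec$kernel - 1) / 2
  cnt <- s1 <- s2 <- sab <- sd2 <- matrix(0, nr, nc)
  for (off in glcm_offsets(spec)) {
    dr <- off[1]; dc <- off[2]
    rA <- seq_len(nr)[seq_len(nr) + dr >= 1 & seq_len(nr) + dr <= nr]
    cA <- seq_len(nc)[seq_len(nc) + dc >= 1 & seq_len(nc) + dc <= nc]
    if (!length(rA) || !length(cA)) next
    A <- q[rA, cA, drop = FALSE]
    B <- q[rA + dr, cA + dc, drop = FALSE]
    okp <- !is.na(A) & !is.na(B)
    Az <- A; Az[!okp] <- 0
    Bz <- B; Bz[!okp] <- 0
    put <- function(vals) {
      full <- matrix(0, nr, nc)
      full[rA, cA] <- vals
      full
    }
    # pairs are anchored at their first pixel; each centre pools the pairs
    # anchored inside its kernel neighbourhood (zero padding: no phantom
    # pairs beyond the raster edge)
    pcnt <- put(okp * 1)
    ps1 <- put(Az + Bz)
    ps2 <- put(Az^2 + Bz^2)
    psab <- put(Az * Bz)
    psd2 <- put((Az - Bz)^2 * okp)
    pad0 <- function(x) {
      big <- matrix(0, nr + 2 * k, nc + 2 * k)
      big[k + seq_len(nr), k + seq_len(nc)] <- x
      big
    }
    cnt <- cnt + box_sum_padded(pad0(pcnt), k, nr, nc)
    s1 <- s1 + box_sum_padded(pad0(ps1), k, nr, nc)
    s2 <- s2 + box_sum_padded(pad0(ps2), k, nr, nc)
    sab <- sab + box_sum_padded(pad0(psab), k, nr, nc)
    sd2 <- sd2 + box_sum_padded(pad0(psd2), k, nr, nc)
  }
  # symmetric matrix: ordered-pair moments from unordered-pair sums
  mu <- s1 / (2 * cnt)
  ei2 <- s2 / (2 * cnt)
  varm <- ei2 - mu^2
  eij <- sab / cnt
  covm <- eij - mu^2
  contrast <- sd2 / cnt
  correlation <- ifelse(varm > 0, covm / varm, 0)
  none <- cnt == 0
  contrast[none] <- NA_real_; correlation[none] <- NA_real_
  varm[none] <- NA_real_
  wrap <- function(x) {
    if (inherits(layer, "raster_grid")) {
      raster_grid(x, layer$pixel_size, layer$origin)
    } else x
  }
  stats::setNames(
    list(wrap(contrast), wrap(correlation), wrap(varm)),
    paste0(prefix, c("_contrast", "_correlation", "_variance")))
}

#' Temporal amplitude of a band
#'
#' Per pixel, the difference between the 90th and 10th percentiles (linear
#' interpolation) of the band's valid time series — a soil-moisture-related
#' dynamic-range feature for radar backscatter. Pixels with fewer than two
#' valid observations become nodata. Always non-negative.
#'
#' @param series an `image_series`.
#' @param band band name.
#' @return a `raster_grid`.
#' @export
temporal_amplitude <- function(series, band) {
  stopifnot(inherits(series, "image_series"))
  proto <- series$stacks[[1]]
  if (!band %in% names(proto$bands)) {
    stop(sprintf("band '%s' not in series", band), call. = FALSE)
  }
  nr <- nrow(proto$bands[[1]]); nc <- ncol(proto$bands[[1]])
  npix <- nr * nc
  obs <- vapply(series$stacks, function(s) {
    v <- as.vector(s$bands[[band]])
    v[!as.vector(s$valid)] <- NA_real_
    v
  }, numeric(npix))
  obs <- matrix(obs, npix, length(series))
  nv <- rowSums(!is.na(obs))
  sorted <- apply(obs, 1, sort.int, na.last = TRUE, method = "quick")
  sorted <- matrix(sorted, length(series), npix)
  amp <- interp_percentile(sorted, nv, 90) - interp_percentile(sorted, nv, 10)
  amp[nv < 2] <- NA_real_
  raster_grid(matrix(amp, nr, nc), proto$pixel_size, proto$origin)
}

#' Vegetation indices from an optical composite
#'
#' Computes the ten spectral indices used as candidate classification
#' features: NDVI, NDWI, LSWI, EVI, ARVI, NBR, NBR2, GNDVI, S2REP and
#' MSAVI2, pixel-wise from the named reflectance bands. Zero-denominator
#' pixels (and non-finite results) become nodata.
#'
#' @param optical a `scene_stack` with the 10 reflectance bands.
#' @return named list of matrices, one per index.
#' @export
vegetation_indices <- function(optical) {
  b <- function(nm) stack_band(optical, nm)
  blue <- b("Blue"); green <- b("Green"); red <- b("Red")
  re1 <- b("RedEdge1"); re2 <- b("RedEdge2"); re3 <- b("RedEdge3")
  nir <- b("NIR"); swir1 <- b("SWIR1"); swir2 <- b("SWIR2")
  nd <- function(a, bb) {
    den <- a + bb
    out <- (a - bb) / den
    out[den == 0] <- NA_real_
    out
  }
  evi_den <- nir + 6 * red - 7.5 * blue + 1
  evi <- 2.5 * (nir - red) / evi_den
  evi[evi_den == 0] <- NA_real_
  arvi_rb <- 2 * red - blue
  arvi <- nd(nir, arvi_rb)
  s2rep_den <- re2 - re1
  s2rep <- 705 + 35 * (((re3 + red) / 2 - re1) / s2rep_den)
  s2rep[s2rep_den == 0] <- NA_real_
  disc <- (2 * nir + 1)^2 - 8 * (nir - red)
  msavi2 <- (2 * nir + 1 - sqrt(pmax(disc, 0))) / 2
  msavi2[disc < 0] <- NA_real_
  out <- list(NDVI = nd(nir, red),
              GNDVI = nd(nir, green),
              LSWI = nd(nir, swir1),
              S2REP = s2rep,
              NDWI = nd(green, nir),
              NBR = nd(nir, swir2),
              NBR2 = nd(swir1, swir2),
              EVI = evi,
              ARVI = arvi,
              MSAVI2 = msavi2)
  lapply(out, function(m) { m[!is.finite(m)] <- NA_real_; m })
}

#' Terrain features from a DEM
#'
#' Elevation plus slope and aspect from Horn's 3x3 weighted finite
#' differences. Slope is in degrees; aspect in degrees clockwise from north
#' of the downslope direction, with flat cells (zero gradient) flagged as
#' nodata. Edges use reflection padding.
#'
#' @param dem a `raster_grid` in metres with square pixels.
#' @return named list of `raster_grid`s: `Elevation`, `Slope`, `Aspect`.
#' @export
terrain_features <- function(dem) {
  stopifnot(inherits(dem, "raster_grid"))
  z <- pad_reflect(dem$values, 1)
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  px <- dem$pixel_size
  sub <- function(dr, dc) z[1 + dr + seq_len(nr), 1 + dc + seq_len(nc), drop = FALSE]
  gx <- ((sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)) -
           (sub(-1, -1) + 2 * sub(0, -1) + sub(1, -1))) / (8 * px)
  gy <- ((sub(-1, -1) + 2 * sub(-1, 0) + sub(-1, 1)) -
           (sub(1, -1) + 2 * sub(1, 0) + sub(1, 1))) / (8 * px)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[gx == 0 & gy == 0] <- NA_real_
  list(Elevation = raster_grid(dem$values, px, dem$origin),
       Slope = raster_grid(slope, px, dem$origin),
       Aspect = raster_grid(aspect, px, dem$origin))
}

#' Canonical feature list of a dataset combination
#'
#' @param tag one of `"S2"`, `"S2+"`, `"S1"`, `"S1+"`, `"S2+S1+"`,
#'   `"S2+S1+DEM"`.
#' @return character vector of feature names (10, 21, 2, 12, 33 or 36).
#' @export
combination_features <- function(tag) {
  s2 <- c("Blue", "Red", "Green", "NIR", "SWIR1", "SWIR2",
          "RedEdge1", "RedEdge2", "RedEdge3", "RedEdge4")
  vi <- c("NDVI", "GNDVI", "LSWI", "S2REP", "NDWI", "NBR", "NBR2",
          "EVI", "ARVI", "MSAVI2")
  s2p <- c(s2, vi, "NDVI_stdDev")
  s1 <- c("VH", "VV")
  s1p <- c(s1, "VV_correlation", "VV_variance", "VV_contrast",
           "VH_correlation", "VH_variance", "VH_contrast",
           "VV_stdDev", "VH_stdDev", "VV_amplitude", "VH_amplitude")
  switch(tag,
         "S2" = s2,
         "S2+" = s2p,
         "S1" = s1,
         "S1+" = s1p,
         "S2+S1+" = c(s2p, s1p),
         "S2+S1+DEM" = c(s2p, s1p, "Elevation", "Slope", "Aspect"),
         stop(sprintf("unknown combination tag '%s'", tag), call. = FALSE))
}

#' Feature stack container
#'
#' @param layers named list of matrices on one grid.
#' @param pixel_size,origin grid metadata.
#' @param tag dataset combination tag.
#' @param provenance optional named list of per-feature notes.
#' @return an object of class `feature_stack`.
#' @export
feature_stack <- function(layers, pixel_size, origin = c(0, 0), tag = NA_character_,
                          provenance = list()) {
  st <- scene_stack(layers, pixel_size, origin)
  st$tag <- tag
  st$provenance <- provenance
  class(st) <- c("feature_stack", class(st))
  st
}

#' Assemble a dataset combination of features
#'
#' Produces exactly the canonical feature list for the tag, computing
#' derived layers as needed: vegetation indices and NDVI texture from the
#' optical composite, GLCM textures and moving-window standard deviation
#' from the radar composite, temporal amplitudes from the radar series, and
#' terrain features from the DEM (computed at DEM resolution, then
#' resampled). All layers end up on the analysis grid of the optical (or,
#' for radar-only tags, radar) composite.
#'
#' @param tag combination tag, see [combination_features()].
#' @param optical optical composite `scene_stack` (for S2 tags).
#' @param radar radar composite `scene_stack` with VV/VH (for S1 tags).
#' @param radar_series radar `image_series` (for amplitude features).
#' @param dem `raster_grid` DEM (for the DEM tag).
#' @param glcm a [glcm_spec()] for the radar textures.
#' @return a `feature_stack` with the canonical layers for the tag.
#' @export
assemble_combination <- function(tag, optical = NULL, radar = NULL,
                                 radar_series = NULL, dem = NULL,
                                 glcm = glcm_spec()) {
  wanted <- combination_features(tag)
  needs <- list(optical = any(wanted %in% c("Blue", "NDVI")),
                radar = any(c("VV", "VH") %in% wanted),
                radar_series = any(grepl("_amplitude$", wanted)),
                dem = "Elevation" %in% wanted)
  missing_in <- c(if (needs$optical && is.null(optical)) "optical composite",
                  if (needs$radar && is.null(radar)) "radar composite",
                  if (needs$radar_series && is.null(radar_series)) "radar series",
                  if (needs$dem && is.null(dem)) "dem")
  if (length(missing_in)) {
    stop(sprintf("combination '%s' needs missing input(s): %s", tag,
                 paste(missing_in, collapse = ", ")), call. = FALSE)
  }
  ref <- if (!is.null(optical)) optical else radar
  target <- raster_grid(matrix(0, nrow(ref$bands[[1]]), ncol(ref$bands[[1]])),
                        ref$pixel_size, ref$origin)
  align <- function(x, categorical = FALSE) {
    g <- if (inherits(x, "raster_grid")) x else raster_grid(x, ref$pixel_size, ref$origin)
    if (same_grid(g, target)) g$values else resample_to_grid(g, target)$values
  }
  layers <- list()
  prov <- list()
  if (needs$optical) {
    for (bn in intersect(combination_features("S2"), wanted)) {
      layers[[bn]] <- align(stack_band(optical, bn))
      prov[[bn]] <- "optical composite band"
    }
    if ("NDVI" %in% wanted) {
      vi <- vegetation_indices(optical)
      for (nm in names(vi)) {
        layers[[nm]] <- align(vi[[nm]])
        prov[[nm]] <- "spectral index from optical composite"
      }
      if ("NDVI_stdDev" %in% wanted) {
        layers$NDVI_stdDev <- align(window_stddev(vi$NDVI, 5))
        prov$NDVI_stdDev <- "5x5 moving-window sd of NDVI"
      }
    }
  }
  if (needs$radar) {
    for (bn in c("VH", "VV")) {
      if (bn %in% wanted) {
        layers[[bn]] <- align(stack_band(radar, bn))
        prov[[bn]] <- "radar composite band"
      }
    }
    if ("VV_contrast" %in% wanted) {
      for (bn in c("VV", "VH")) {
        gl <- glcm_features(stack_band(radar, bn), glcm, prefix = bn)
        for (nm in names(gl)) {
          layers[[nm]] <- align(gl[[nm]])
          prov[[nm]] <- sprintf("GLCM statistic of %s (d=%d, Ng=%d)",
                                bn, glcm$distance, glcm$n_grey)
        }
        layers[[paste0(bn, "_stdDev")]] <- align(
          window_stddev(stack_band(radar, bn), 5))
        prov[[paste0(bn, "_stdDev")]] <- sprintf("5x5 moving-window sd of %s", bn)
      }
    }
    if ("VV_amplitude" %in% wanted) {
      for (bn in c("VV", "VH")) {
        layers[[paste0(bn, "_amplitude")]] <- align(temporal_amplitude(radar_series, bn))
        prov[[paste0(bn, "_amplitude")]] <- sprintf("p90 - p10 of %s time series", bn)
      }
    }
  }
  if (needs$dem) {
    tf <- terrain_features(dem)
    for (nm in names(tf)) {
      layers[[nm]] <- align(tf[[nm]])
      prov[[nm]] <- "terrain feature from DEM"
    }
  }
  layers <- layers[wanted]
  if (anyNA(names(layers))) {
    stop(sprintf("assembly for '%s' failed to produce: %s", tag,
                 paste(setdiff(wanted, names(layers)), collapse = ", ")),
         call. = FALSE)
  }
  feature_stack(layers, ref$pixel_size, ref$origin, tag = tag, provenance = prov)
}
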