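#' Composite specification
#'
#' Defines the percentile-range composite: per pixel and band, observations
#' between the lower and upper percentile values (linear interpolation
#' between order statistics) are averaged. The 40-60 default is less
#' variable than the full range and damps residual atmospheric extremes and
#' phenological outliers.
#'
#' @param p_lo,p_hi lower/upper percentiles, `0 <= p_lo <= p_hi <= 100`.
#' @param min_valid minimum valid observations per pixel (>= 1); pixels with
#'   fewer become nodata.
#' @return an object of class `composite_spec`.
#' @export
composite_spec <- function(p_lo = 40, p_hi = 60, min_valid = 1) {
  if (p_lo < 0 || p_hi > 100 || p_lo > p_hi) {
    stop("need 0 <= p_lo <= p_hi <= 100", call. = FALSE)
  }
  if (min_valid < 1) stop("min_valid must be >= 1", call. = FALSE)
  structure(list(p_lo = p_lo, p_hi = p_hi, min_valid = as.integer(min_valid),
                 interpolation = "linear"),
            class = "composite_spec")
}

#' Per-pixel cloud likelihood score
#'
#' A mean-of-ramps score over the five cloud-sensitive layers (Blue, NIR,
#' SWIR1 and the two detector proxy layers Aerosol and Cirrus). Each band is
#' rescaled linearly between a documented clear value (score 0) and cloudy
#' value (score 1), clipped to `[0, 1]`; the pixel score is the mean of the
#' five ramps, hence monotone non-decreasing in every input band.
#'
#' @param stack a `scene_stack` providing the five required layers.
#' @param anchors named list of `c(clear, cloudy)` per band; the defaults
#'   bracket typical clear-sky land/water reflectance below and optically
#'   thick cloud above.
#' @return a `raster_grid` of scores in `[0, 1]`.
#' @export
cloud_score <- function(stack,
                        anchors = list(Blue = c(0.1, 0.3),
                                       Aerosol = c(0.1, 0.3),
                                       Cirrus = c(0.02, 0.1),
                                       NIR = c(0.5, 0.8),
                                       SWIR1 = c(0.35, 0.7))) {
  stopifnot(inherits(stack, "scene_stack"))
  acc <- NULL
  for (b in names(anchors)) {
    v <- stack_band(stack, b)
    a <- anchors[[b]]
    ramp <- pmin(pmax((v - a[1]) / (a[2] - a[1]), 0), 1)
    acc <- if (is.null(acc)) ramp else acc + ramp
  }
  raster_grid(acc / length(anchors), stack$pixel_size, stack$origin)
}

#' Invalidate cloudy pixels across a time series
#'
#' Updates each date's validity mask to `FALSE` where the cloud score reaches
#' the threshold. Band values are left untouched; downstream operators honour
#' the mask.
#'
#' @param series an `image_series`.
#' @param threshold score threshold in `[0, 1]` (default 0.5).
#' @param anchors passed to [cloud_score()].
#' @return the series with updated validity masks.
#' @export
mask_clouds <- function(series, threshold = 0.5, anchors = NULL) {
  stopifnot(inherits(series, "image_series"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]", call. = FALSE)
  for (d in seq_along(series$stacks)) {
    sc <- if (is.null(anchors)) cloud_score(series$stacks[[d]]) else
      cloud_score(series$stacks[[d]], anchors)
    series$stacks[[d]]$valid <- series$stacks[[d]]$valid & !(sc$values >= threshold)
  }
  series
}

# kth-order-statistic percentile with linear interpolation on a date x pixel
# matrix whose columns are sorted with NAs last; nv = valid count per column
interp_percentile <- function(sorted, nv, p) {
  npix <- ncol(sorted)
  h <- (nv - 1) * p / 100 + 1
  lo <- pmax(floor(h), 1)
  hi <- pmin(lo + 1, nv)
  frac <- h - lo
  vlo <- sorted[cbind(pmin(lo, nrow(sorted)), seq_len(npix))]
  vhi <- sorted[cbind(pmin(hi, nrow(sorted)), seq_len(npix))]
  vlo + frac * (vhi - vlo)
}

#' Percentile-range composite of a time series
#'
#' Per pixel and band, over valid observations only: the lower and upper
#' percentile values are computed with linear interpolation between order
#' statistics, then all observations inside the closed percentile interval
#' are averaged. If the interval captures no observation (possible with few
#' dates), the single observation nearest the interval midpoint is used
#' (equidistant ties resolve to the smaller observation). Pixels with fewer
#' valid observations than `spec$min_valid` become nodata.
#'
#' @param series an `image_series` (validity masks respected).
#' @param spec a [composite_spec()].
#' @return a `scene_stack` with the same band names.
#' @export
percentile_range_composite <- function(series, spec = composite_spec()) {
  stopifnot(inherits(series, "image_series"))
  if (length(series) == 0) stop("empty series", call. = FALSE)
  proto <- series$stacks[[1]]
  nr <- nrow(proto$bands[[1]]); nc <- ncol(proto$bands[[1]])
  npix <- nr * nc
  ndates <- length(series)
  vmask <- vapply(series$stacks, function(s) as.vector(s$valid), logical(npix))
  vmask <- matrix(vmask, npix, ndates)
  nv <- rowSums(vmask)
  out <- stats::setNames(vector("list", length(proto$bands)), names(proto$bands))
  for (b in names(proto$bands)) {
    obs <- vapply(series$stacks, function(s) as.vector(s$bands[[b]]), numeric(npix))
    obs <- matrix(obs, npix, ndates)
    obs[!vmask] <- NA_real_
    sorted <- apply(obs, 1, sort.int, na.last = TRUE, method = "quick")
    sorted <- matrix(sorted, ndates, npix)  # dates x pixels, NAs last
    vlo <- interp_percentile(sorted, nv, spec$p_lo)
    vhi <- interp_percentile(sorted, nv, spec$p_hi)
    inb <- sweep(sorted, 2, vlo, ">=") & sweep(sorted, 2, vhi, "<=")
    inb[is.na(inb)] <- FALSE
    cnt <- colSums(inb)
    s <- colSums(sorted * inb, na.rm = TRUE)
    val <- s / cnt
    empty <- which(cnt == 0 & nv > 0)
    if (length(empty)) {
      mid <- (vlo[empty] + vhi[empty]) / 2
      for (k in seq_along(empty)) {
        j <- empty[k]
        v <- sorted[seq_len(nv[j]), j]
        d <- abs(v - mid[k])
        # near-exact distance ties resolve to the smaller observation
        val[j] <- v[which(d <= min(d) + 1e-9 * (1 + abs(mid[k])))][1]
      }
    }
    val[nv < spec$min_valid] <- NA_real_
    out[[b]] <- matrix(val, nr, nc)
  }
  scene_stack(out, proto$pixel_size, proto$origin,
              valid = matrix(nv >= spec$min_valid, nr, nc))
}
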