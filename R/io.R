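# Raster I/O: multi-page 32-bit-float TIFF for the pixel data, plus a JSON
# sidecar (<path>.json) carrying grid metadata, band names and class levels.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a raster or band stack to TIFF
#'
#' Each band becomes one 32-bit float page; pixel size, origin, band names,
#' categorical flag and class levels go to a JSON sidecar next to the file.
#' `NA` cells are stored as NaN.
#'
#' @param x a `raster_grid`, `scene_stack` or `feature_stack`.
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  if (inherits(x, "raster_grid")) {
    bands <- list(layer = x$values)
    meta <- list(kind = "grid", pixel_size = x$pixel_size, origin = x$origin,
                 bands = "layer", categorical = x$categorical,
                 classes = x$classes)
  } else if (inherits(x, "scene_stack")) {
    bands <- x$bands
    meta <- list(kind = "stack", pixel_size = x$pixel_size, origin = x$origin,
                 bands = names(x$bands), categorical = FALSE,
                 tag = x$tag)
  } else stop("unsupported raster object", call. = FALSE)
  # the TIFF backend stores float samples on [0, 1]; each band is rescaled
  # to that interval and the affine parameters go to the sidecar
  ranges <- lapply(bands, function(m) {
    r <- suppressWarnings(range(m, na.rm = TRUE))
    if (!all(is.finite(r))) r <- c(0, 1)
    if (r[1] == r[2]) r[2] <- r[1] + 1
    r
  })
  pages <- mapply(function(m, r) {
    m <- (m - r[1]) / (r[2] - r[1])
    m[is.na(m)] <- NaN
    m
  }, bands, ranges, SIMPLIFY = FALSE)
  meta$band_min <- vapply(ranges, `[`, 0, 1)
  meta$band_max <- vapply(ranges, `[`, 0, 2)
  # nodata survives as one 0/1 validity page per band (the float backend
  # does not preserve NaN samples)
  masks <- lapply(pages, function(m) (!is.nan(m)) * 1)
  pages <- lapply(pages, function(m) { m[is.nan(m)] <- 0; m })
  meta$has_mask <- TRUE
  tiff::writeTIFF(c(pages, masks), path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a raster or band stack from TIFF
#'
#' Restores the object written by [write_raster()]. Without a sidecar, bands
#' get positional names and the grid defaults to 1 m pixels at origin (0, 0)
#' with a message.
#'
#' @param path path to the `.tif` file.
#' @return a `raster_grid` or `scene_stack`, per the sidecar's `kind`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) {
                      stop(sprintf("cannot read '%s' as TIFF: %s", path,
                                   conditionMessage(e)), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m[is.nan(m)] <- NA_real_
    m
  })
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  } else {
    message(sprintf("no sidecar for %s; assuming 1 m pixels, positional bands",
                    path))
    meta <- list(kind = if (length(pages) == 1) "grid" else "stack",
                 pixel_size = 1, origin = c(0, 0),
                 bands = paste0("band", seq_along(pages)), categorical = FALSE)
  }
  if (isTRUE(meta$has_mask)) {
    nb <- length(pages) / 2
    masks <- pages[nb + seq_len(nb)]
    pages <- pages[seq_len(nb)]
    pages <- lapply(seq_len(nb), function(i) {
      m <- pages[[i]]
      m[masks[[i]] < 0.5] <- NA_real_
      m
    })
  }
  if (!is.null(meta$band_min)) {
    mins <- unlist(meta$band_min); maxs <- unlist(meta$band_max)
    pages <- lapply(seq_along(pages), function(i) {
      pages[[i]] * (maxs[i] - mins[i]) + mins[i]
    })
  }
  if (identical(meta$kind, "grid")) {
    g <- raster_grid(pages[[1]], meta$pixel_size, unlist(meta$origin),
                     categorical = isTRUE(meta$categorical))
    if (!is.null(meta$classes)) g$classes <- unlist(meta$classes)
    g
  } else {
    scene_stack(stats::setNames(pages, unlist(meta$bands)),
                meta$pixel_size, unlist(meta$origin))
  }
}

#' Write reference data as GeoJSON
#'
#' Training rectangles become Polygon features and test points Point
#' features, each with a `class` and `role` property.
#'
#' @param reference a `reference_set`.
#' @param path output path (`.geojson`).
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "reference_set"))
  feats <- list()
  tr <- reference$training
  for (i in seq_len(nrow(tr))) {
    ring <- list(c(tr$xmin[i], tr$ymin[i]), c(tr$xmax[i], tr$ymin[i]),
                 c(tr$xmax[i], tr$ymax[i]), c(tr$xmin[i], tr$ymax[i]),
                 c(tr$xmin[i], tr$ymin[i]))
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(class = tr$class[i], role = "training"))
  }
  te <- reference$testing
  for (i in seq_len(nrow(te))) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(te$x[i], te$y[i])),
      properties = list(class = te$class[i], role = "testing"))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reference data from GeoJSON
#'
#' Polygon features become training rectangles (their bounding box; the
#' generator only emits axis-aligned rectangles), Point features test
#' points. Classes are checked against the catalogue; unknown names error.
#'
#' @param path path to a GeoJSON FeatureCollection with a `class` property
#'   per feature.
#' @param catalogue a [class_catalogue()].
#' @return a `reference_set` (testing rows carry `x`/`y`; use
#'   [locate_points()] to attach pixel indices for a given grid).
#' @export
read_reference <- function(path, catalogue = class_catalogue()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats) || length(feats) == 0) {
    stop("empty reference file", call. = FALSE)
  }
  tr <- list(); te <- list()
  bad <- character(0)
  for (f in feats) {
    cls <- f$properties$class
    if (is.null(cls)) stop("feature without a class property", call. = FALSE)
    if (!cls %in% catalogue$class) bad <- c(bad, cls)
    gt <- f$geometry$type
    if (identical(gt, "Polygon")) {
      ring <- f$geometry$coordinates[[1]]
      xs <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
      ys <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
      tr[[length(tr) + 1L]] <- data.frame(class = cls,
                                          xmin = min(xs), xmax = max(xs),
                                          ymin = min(ys), ymax = max(ys),
                                          stringsAsFactors = FALSE)
    } else if (identical(gt, "Point")) {
      p <- f$geometry$coordinates
      te[[length(te) + 1L]] <- data.frame(class = cls,
                                          x = as.numeric(p[[1]]),
                                          y = as.numeric(p[[2]]),
                                          stringsAsFactors = FALSE)
    } else {
      stop(sprintf("unsupported geometry type '%s'", gt), call. = FALSE)
    }
  }
  if (length(bad)) {
    stop(sprintf("unknown class name(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  training <- if (length(tr)) do.call(rbind, tr) else
    data.frame(class = character(), xmin = numeric(), xmax = numeric(),
               ymin = numeric(), ymax = numeric(), stringsAsFactors = FALSE)
  testing <- if (length(te)) do.call(rbind, te) else
    data.frame(class = character(), x = numeric(), y = numeric(),
               stringsAsFactors = FALSE)
  structure(list(training = training, testing = testing,
                 classes = catalogue$class),
            class = "reference_set")
}

#' Attach pixel indices to reference points for a grid
#'
#' @param points data.frame with `x`, `y` map coordinates.
#' @param grid a `raster_grid` or `scene_stack` defining the target grid.
#' @return the data.frame with `row` and `col` columns added; points beyond
#'   the grid get `NA`.
#' @export
locate_points <- function(points, grid) {
  px <- grid$pixel_size
  org <- grid$origin
  dims <- if (inherits(grid, "scene_stack")) dim(grid$bands[[1]]) else dim(grid$values)
  col <- as.integer(ceiling((points$x - org[1]) / px))
  row <- as.integer(ceiling((org[2] - points$y) / px))
  col[col < 1 | col > dims[2]] <- NA_integer_
  row[row < 1 | row > dims[1]] <- NA_integer_
  points$row <- row
  points$col <- col
  points
}
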