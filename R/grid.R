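#' Georeferenced raster grid
#'
#' A `raster_grid` is the substrate of all imagery in peatstack: a numeric
#' (or integer-coded categorical) matrix with square pixels of known size in
#' metres and a map origin at the top-left corner. Rows run north to south,
#' columns west to east; coordinates are pixel-centre. Missing values are
#' encoded as `NA` throughout.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param pixel_size pixel edge length in metres (> 0).
#' @param origin numeric length-2, map coordinates `(x, y)` of the top-left
#'   corner of the top-left pixel.
#' @param categorical logical; `TRUE` for class-index rasters.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, pixel_size, origin = c(0, 0),
                        categorical = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("pixel_size must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, pixel_size = pixel_size,
         origin = as.numeric(origin[1:2]), categorical = isTRUE(categorical)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d @ %g m, origin (%g, %g)%s\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              x$origin[1], x$origin[2],
              if (x$categorical) ", categorical" else ""))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_meta <- function(g) list(pixel_size = g$pixel_size, origin = g$origin)

same_grid <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Named co-registered bands at one timestamp
#'
#' A `scene_stack` holds named bands (matrices) sharing one grid, with an
#' optional per-pixel validity mask (`TRUE` = usable observation).
#'
#' @param bands named list of numeric matrices with identical dimensions.
#' @param pixel_size pixel size in metres.
#' @param origin top-left map coordinates.
#' @param time optional numeric timestamp.
#' @param valid optional logical matrix; defaults to all `TRUE`.
#' @return an object of class `scene_stack`.
#' @export
scene_stack <- function(bands, pixel_size, origin = c(0, 0), time = NA_real_,
                        valid = NULL) {
  if (length(bands) == 0 || is.null(names(bands)) || anyNA(names(bands)) ||
      any(names(bands) == "")) {
    stop("bands must be a non-empty named list", call. = FALSE)
  }
  dims <- lapply(bands, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("all bands must share one grid", call. = FALSE)
  }
  if (anyDuplicated(names(bands))) stop("band names must be unique", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(bands[[1]]), ncol(bands[[1]]))
  structure(
    list(bands = bands, pixel_size = pixel_size, origin = as.numeric(origin[1:2]),
         time = time, valid = valid),
    class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("<scene_stack> %d band(s) [%s] %d x %d @ %g m\n",
              length(x$bands), paste(names(x$bands), collapse = ", "),
              nrow(x$bands[[1]]), ncol(x$bands[[1]]), x$pixel_size))
  invisible(x)
}

stack_band <- function(stack, name) {
  if (!name %in% names(stack$bands)) {
    stop(sprintf("band '%s' is not present (have: %s)", name,
                 paste(names(stack$bands), collapse = ", ")), call. = FALSE)
  }
  stack$bands[[name]]
}

#' Time-ordered sequence of scene stacks
#'
#' @param stacks list of `scene_stack` objects sharing band names and grid.
#' @param times strictly increasing numeric timestamps (defaults to the
#'   stacks' own `time` fields, else `seq_along`).
#' @return an object of class `image_series`.
#' @export
image_series <- function(stacks, times = NULL) {
  if (length(stacks) == 0) stop("empty image series", call. = FALSE)
  nm <- lapply(stacks, function(s) names(s$bands))
  if (length(unique(vapply(nm, paste, "", collapse = "|"))) != 1) {
    stop("all stacks must share band names", call. = FALSE)
  }
  if (is.null(times)) {
    times <- vapply(stacks, function(s) s$time, 0)
    if (anyNA(times)) times <- seq_along(stacks)
  }
  if (any(diff(times) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  structure(list(stacks = stacks, times = as.numeric(times)),
            class = "image_series")
}

#' @export
length.image_series <- function(x) length(x$stacks)

#' Nearest-neighbour resampling to a new pixel size
#'
#' Output is aligned to the source origin; each output pixel takes the value
#' of the source pixel containing the output pixel centre. Categorical
#' rasters therefore never acquire new categories and no interpolation ever
#' occurs. Output dimensions cover the source extent
#' (`ceiling(extent / target)`), with centres beyond the source edge clamped
#' to the last source pixel.
#'
#' @param raster a `raster_grid`.
#' @param target_pixel_size_m output pixel size in metres.
#' @return a `raster_grid` on the new grid.
#' @export
resample_nearest <- function(raster, target_pixel_size_m) {
  stopifnot(inherits(raster, "raster_grid"))
  if (!is.numeric(target_pixel_size_m) || target_pixel_size_m <= 0) {
    stop("target pixel size must be positive", call. = FALSE)
  }
  src <- raster$values
  sp <- raster$pixel_size
  out_nr <- max(1L, as.integer(ceiling(nrow(src) * sp / target_pixel_size_m)))
  out_nc <- max(1L, as.integer(ceiling(ncol(src) * sp / target_pixel_size_m)))
  rg <- resample_index((seq_len(out_nr) - 0.5) * target_pixel_size_m, sp, nrow(src))
  cg <- resample_index((seq_len(out_nc) - 0.5) * target_pixel_size_m, sp, ncol(src))
  out <- src[rg, cg, drop = FALSE]
  raster_grid(out, target_pixel_size_m, raster$origin,
              categorical = raster$categorical)
}

resample_index <- function(centre_offset_m, src_pixel, src_n) {
  idx <- ceiling(centre_offset_m / src_pixel)
  pmin(pmax(idx, 1L), src_n)
}

#' Resample a raster onto the grid of another raster
#'
#' Nearest-neighbour alignment onto an explicit target grid (dimensions,
#' pixel size and origin taken from `target`). Origins must agree; peatstack
#' assumes a single CRS with pre-aligned inputs and raises an error rather
#' than silently shifting.
#'
#' @param raster a `raster_grid`.
#' @param target a `raster_grid` (or `scene_stack`) defining the output grid.
#' @return a `raster_grid` on the target grid.
#' @export
resample_to_grid <- function(raster, target) {
  tp <- target$pixel_size
  tdim <- if (inherits(target, "scene_stack")) dim(target$bands[[1]]) else dim(target$values)
  if (!isTRUE(all.equal(raster$origin, target$origin))) {
    stop("origins differ; inputs must be pre-aligned in one CRS", call. = FALSE)
  }
  src <- raster$values
  rg <- resample_index((seq_len(tdim[1]) - 0.5) * tp, raster$pixel_size, nrow(src))
  cg <- resample_index((seq_len(tdim[2]) - 0.5) * tp, raster$pixel_size, ncol(src))
  raster_grid(src[rg, cg, drop = FALSE], tp, raster$origin,
              categorical = raster$categorical)
}
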