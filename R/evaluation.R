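#' Confusion matrix and accuracy statistics
#'
#' Tallies reference classes by row and predicted classes by column over the
#' test points, then derives user's accuracy (UA, column-wise correctness),
#' producer's accuracy (PA, row-wise correctness), overall accuracy (OA) and
#' the per-class F-score. Points on nodata pixels are dropped and counted.
#' Classes with an empty column (never predicted) get `NA` UA; an empty row
#' gets `NA` PA.
#'
#' @param map a `class_map`.
#' @param test_points data.frame with columns `row`, `col`, `class` (as from
#'   a `reference_set`'s `testing`), or a `reference_set`.
#' @return an object of class `accuracy_report`: `matrix` (reference x
#'   predicted counts), `ua`, `pa` (named, percent), `oa` (percent),
#'   `f_score` (named, unitless), `n`, `dropped`.
#' @export
confusion <- function(map, test_points) {
  stopifnot(inherits(map, "raster_grid"))
  pts <- if (inherits(test_points, "reference_set")) test_points$testing else test_points
  if (is.null(pts) || nrow(pts) == 0) stop("empty test set", call. = FALSE)
  classes <- map$classes
  pred_idx <- map$values[cbind(pts$row, pts$col)]
  keep <- !is.na(pred_idx)
  dropped <- sum(!keep)
  if (!any(keep)) stop("all test points fall on nodata pixels", call. = FALSE)
  ref <- factor(pts$class[keep], levels = classes)
  pred <- factor(classes[pred_idx[keep]], levels = classes)
  cm <- table(reference = ref, predicted = pred)
  accuracy_from_matrix(unclass(cm), dropped = dropped)
}

#' Accuracy statistics from a raw confusion matrix
#'
#' @param cm square counts matrix, reference classes in rows, predictions in
#'   columns, with dimnames.
#' @param dropped number of points excluded before tallying.
#' @return an `accuracy_report`; see [confusion()].
#' @export
accuracy_from_matrix <- function(cm, dropped = 0) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  diagv <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  ua <- ifelse(colsum > 0, 100 * diagv / colsum, NA_real_)
  pa <- ifelse(rowsum > 0, 100 * diagv / rowsum, NA_real_)
  oa <- 100 * sum(diagv) / sum(cm)
  fs <- mapply(function(u, p) {
    if (is.na(u) || is.na(p) || u + p == 0) NA_real_ else f_score(u, p)
  }, ua, pa)
  structure(list(matrix = cm,
                 ua = stats::setNames(ua, rownames(cm)),
                 pa = stats::setNames(pa, rownames(cm)),
                 oa = oa,
                 f_score = stats::setNames(fs, rownames(cm)),
                 n = sum(cm), dropped = dropped),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> n = %d, OA = %.2f%%\n", x$n, x$oa))
  invisible(x)
}

#' Per-class F-score
#'
#' The harmonic mean of user's and producer's accuracy, rescaled from
#' percent to the unit interval: `2 UA PA / (UA + PA) / 100`. Symmetric in
#' its arguments and bounded by them (after the percent rescaling).
#'
#' @param ua,pa user's and producer's accuracy in percent, in `(0, 100]`.
#' @return unitless value in `(0, 1]`.
#' @export
f_score <- function(ua, pa) {
  if (any(ua + pa <= 0)) stop("UA + PA must be positive", call. = FALSE)
  2 * ua * pa / (ua + pa) / 100
}

#' McNemar's chi-squared test on discordant counts
#'
#' Compares two classifications over shared test points via the counts of
#' points each map got right and the other wrong: the statistic is
#' `(f12 - f21)^2 / (f12 + f21)`, referred to a chi-squared distribution
#' with one degree of freedom (no continuity correction). Symmetric under
#' swapping the two maps.
#'
#' @param f12 points correct in the first classification only.
#' @param f21 points correct in the second classification only.
#' @return list with `statistic` and `p_value`.
#' @export
mcnemar <- function(f12, f21) {
  if (f12 < 0 || f21 < 0) stop("discordant counts must be >= 0", call. = FALSE)
  if (f12 + f21 == 0) stop("undefined: no discordant samples", call. = FALSE)
  stat <- (f12 - f21)^2 / (f12 + f21)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Discordant counts between two class maps over shared test points
#'
#' Points nodata in either map are excluded.
#'
#' @param map1,map2 `class_map`s on one grid.
#' @param test_points data.frame with `row`, `col`, `class` or a
#'   `reference_set`.
#' @return list with `f12`, `f21`, `n_used`.
#' @export
discordant_counts <- function(map1, map2, test_points) {
  pts <- if (inherits(test_points, "reference_set")) test_points$testing else test_points
  i1 <- map1$values[cbind(pts$row, pts$col)]
  i2 <- map2$values[cbind(pts$row, pts$col)]
  keep <- !is.na(i1) & !is.na(i2)
  c1 <- map1$classes[i1[keep]] == pts$class[keep]
  c2 <- map2$classes[i2[keep]] == pts$class[keep]
  list(f12 = sum(c1 & !c2), f21 = sum(!c1 & c2), n_used = sum(keep))
}

#' UA/PA improvement analysis against a reference dataset
#'
#' For each class and metric (UA, PA), the difference between the reference
#' report and each other report (reference minus other) is tabulated, and
#' the strictly positive, strictly negative and zero cells are counted —
#' positive cells are class/metric/dataset combinations where the reference
#' dataset is the more accurate one.
#'
#' @param reference_report an `accuracy_report`.
#' @param other_reports named list of `accuracy_report`s.
#' @param digits differences are rounded to this many decimals before sign
#'   counting (default 1, the reporting precision of UA/PA).
#' @return an object of class `comparison_report`: `differences` (data.frame
#'   class x metric x dataset), `n_positive`, `n_negative`, `n_zero`,
#'   `n_cells`, and the corresponding percentages.
#' @export
improvement_analysis <- function(reference_report, other_reports, digits = 1) {
  stopifnot(inherits(reference_report, "accuracy_report"))
  classes <- rownames(reference_report$matrix)
  out <- list()
  for (nm in names(other_reports)) {
    rep_k <- other_reports[[nm]]
    if (!identical(rownames(rep_k$matrix), classes)) {
      stop(sprintf("class list of report '%s' differs from the reference", nm),
           call. = FALSE)
    }
    out[[nm]] <- data.frame(
      dataset = nm, class = classes,
      d_ua = round(reference_report$ua - rep_k$ua, digits),
      d_pa = round(reference_report$pa - rep_k$pa, digits),
      stringsAsFactors = FALSE)
  }
  diffs <- do.call(rbind, out)
  rownames(diffs) <- NULL
  cells <- c(diffs$d_ua, diffs$d_pa)
  cells <- cells[!is.na(cells)]
  n_pos <- sum(cells > 0); n_neg <- sum(cells < 0); n_zero <- sum(cells == 0)
  n_cells <- length(cells)
  structure(list(differences = diffs,
                 n_positive = n_pos, n_negative = n_neg, n_zero = n_zero,
                 n_cells = n_cells,
                 pct_positive = 100 * n_pos / n_cells,
                 pct_negative = 100 * n_neg / n_cells),
            class = "comparison_report")
}

#' Build an accuracy report from published UA/PA values
#'
#' For comparing against accuracy tables whose confusion matrices are not
#' available: wraps per-class UA/PA (percent) into an `accuracy_report` so
#' [f_score()] recomputation and [improvement_analysis()] apply. The
#' confusion matrix and OA are unavailable and set to `NA`.
#'
#' @param ua,pa named numeric vectors (percent) over the same classes.
#' @return an `accuracy_report` without counts.
#' @export
report_from_ua_pa <- function(ua, pa) {
  stopifnot(identical(names(ua), names(pa)))
  classes <- names(ua)
  fs <- mapply(function(u, p) {
    if (is.na(u) || is.na(p) || u + p == 0) NA_real_ else f_score(u, p)
  }, ua, pa)
  structure(list(matrix = matrix(NA_real_, length(classes), length(classes),
                                 dimnames = list(classes, classes)),
                 ua = ua, pa = pa, oa = NA_real_,
                 f_score = stats::setNames(fs, classes),
                 n = NA_integer_, dropped = 0L),
            class = "accuracy_report")
}

#' p-value of a McNemar chi-squared statistic
#'
#' One degree of freedom, upper tail; recovers the p-value printed alongside
#' a statistic.
#'
#' @param statistic chi-squared statistic (>= 0).
#' @return p-value in `(0, 1]`.
#' @export
mcnemar_p <- function(statistic) {
  if (any(statistic < 0)) stop("statistic must be >= 0", call. = FALSE)
  stats::pchisq(statistic, df = 1, lower.tail = FALSE)
}

#' Aggregate per-class areas into general classes
#'
#' The area-accounting arithmetic: general-class totals, the grand total,
#' percentages of the total, and percentages of the land area (total minus
#' the Hydrology general class).
#'
#' @param areas data.frame with columns `class` and `area_ha`.
#' @param catalogue a [class_catalogue()].
#' @return list: `classes` (with `pct` and `general` added), `general`
#'   (data.frame `general`, `area_ha`, `pct`, `pct_of_land`), `total_ha`,
#'   `land_ha` (total without Hydrology).
#' @export
aggregate_class_areas <- function(areas, catalogue = class_catalogue()) {
  unknown <- setdiff(areas$class, catalogue$class)
  if (length(unknown)) {
    stop(sprintf("unknown class(es): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  areas$general <- catalogue$general[match(areas$class, catalogue$class)]
  total <- sum(areas$area_ha)
  areas$pct <- 100 * areas$area_ha / total
  gen <- stats::aggregate(area_ha ~ general, data = areas, sum)
  gen$pct <- 100 * gen$area_ha / total
  land <- total - sum(gen$area_ha[gen$general == "Hydrology"])
  gen$pct_of_land <- ifelse(gen$general == "Hydrology", NA_real_,
                            100 * gen$area_ha / land)
  list(classes = areas, general = gen, total_ha = total, land_ha = land)
}

#' Per-class and per-general-class area accounting
#'
#' Area per class is the pixel count times the pixel area (a 20 m pixel is
#' 0.04 ha); percentages are over the total mapped (non-nodata) area.
#' General classes aggregate their member classes via the catalogue.
#'
#' @param map a `class_map` whose `classes` belong to the catalogue.
#' @param catalogue a [class_catalogue()] data.frame.
#' @return an object of class `area_report`: `classes` (data.frame with
#'   `class`, `general`, `pixels`, `area_ha`, `pct`), `general` (aggregated),
#'   `total_ha`, `pixel_area_ha`.
#' @export
area_report <- function(map, catalogue = class_catalogue()) {
  stopifnot(inherits(map, "raster_grid"))
  classes <- map$classes
  unknown <- setdiff(classes, catalogue$class)
  if (length(unknown)) {
    stop(sprintf("map classes not in catalogue: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  vals <- map$values[!is.na(map$values)]
  if (any(vals < 1 | vals > length(classes))) {
    stop("map contains an unknown class index", call. = FALSE)
  }
  pixel_area_ha <- (map$pixel_size^2) / 1e4
  px_count <- vapply(seq_along(classes), function(i) sum(vals == i), 0)
  area_ha <- px_count * pixel_area_ha
  total <- sum(area_ha)
  cls <- data.frame(class = classes,
                    general = catalogue$general[match(classes, catalogue$class)],
                    pixels = px_count,
                    area_ha = area_ha,
                    pct = 100 * area_ha / total,
                    stringsAsFactors = FALSE)
  gen <- stats::aggregate(cbind(pixels, area_ha, pct) ~ general, data = cls, sum)
  structure(list(classes = cls, general = gen, total_ha = total,
                 pixel_area_ha = pixel_area_ha),
            class = "area_report")
}
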