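#' Train the random forest classifier
#'
#' A bagged ensemble of Gini-split decision trees with `mtry` candidate
#' features per split (defaults ntree = 100, mtry = 2). Overall feature
#' importance is the mean decrease in Gini impurity per feature, normalised
#' to sum to one. Deterministic under the seed.
#'
#' @param table a standardised `training_table`.
#' @param ntree number of trees (>= 1).
#' @param mtry candidate features per split, `1 <= mtry <= n features`.
#' @param seed integer seed.
#' @return an object of class `trained_classifier`: `forest` (the fitted
#'   ensemble), `features`, `classes`, `importance` (named, sums to 1),
#'   `params`, and the standardisation parameters carried from the table.
#' @export
train_rf <- function(table, ntree = 100, mtry = 2, seed = 1) {
  stopifnot(inherits(table, "training_table"))
  if (mtry > ncol(table$x)) {
    stop("mtry cannot exceed the number of features", call. = FALSE)
  }
  if (ntree < 1) stop("ntree must be >= 1", call. = FALSE)
  fit <- withr::with_seed(seed, rf_fit(table$x, table$labels, ntree, mtry))
  imp <- rf_importance(fit, colnames(table$x))
  tot <- sum(imp)
  importance <- if (tot > 0) imp / tot else
    stats::setNames(rep(1 / length(imp), length(imp)), names(imp))
  structure(list(forest = fit,
                 features = colnames(table$x),
                 classes = levels(fit$y),
                 importance = importance,
                 params = list(ntree = ntree, mtry = mtry, seed = seed),
                 center = table$center, scale = table$scale),
            class = "trained_classifier")
}

#' Predict a class map from a feature stack
#'
#' Applies the model's standardisation parameters to the raw feature layers
#' and predicts every pixel by majority vote over trees. Pixels with any
#' nodata feature become nodata (no imputation).
#'
#' @param model a `trained_classifier`.
#' @param features a `feature_stack` containing (at least) the model's
#'   features on one grid.
#' @return an object of class `class_map`: a categorical `raster_grid` with
#'   `classes` levels and provenance (`tag`).
#' @export
predict_map <- function(model, features) {
  stopifnot(inherits(model, "trained_classifier"))
  missing_f <- setdiff(model$features, names(features$bands))
  if (length(missing_f)) {
    stop(sprintf("feature stack lacks model features: %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
  nr <- nrow(features$bands[[1]]); nc <- ncol(features$bands[[1]])
  x <- vapply(model$features, function(f) as.vector(features$bands[[f]]),
              numeric(nr * nc))
  x <- matrix(x, nr * nc, length(model$features),
              dimnames = list(NULL, model$features))
  keep <- stats::complete.cases(x)
  pred <- rep(NA_integer_, nr * nc)
  if (any(keep)) {
    xs <- sweep(sweep(x[keep, , drop = FALSE], 2, model$center[model$features]),
                2, model$scale[model$features], "/")
    p <- stats::predict(model$forest, xs)
    pred[keep] <- match(as.character(p), model$classes)
  }
  out <- raster_grid(matrix(pred, nr, nc), features$pixel_size, features$origin,
                     categorical = TRUE)
  out$classes <- model$classes
  out$tag <- features$tag
  class(out) <- c("class_map", class(out))
  out
}

#' Majority filter for class maps
#'
#' Single-pass post-classification smoothing: each pixel is replaced by the
#' modal class of its window (default 3x3, nodata neighbours excluded). Ties
#' retain the centre pixel's class, so the filter never invents a class and
#' is idempotent wherever every window already has a strict majority.
#'
#' @param map a `class_map` (or categorical `raster_grid`).
#' @param window odd window side (default 3).
#' @return the filtered map, same class and metadata.
#' @export
majority_filter <- function(map, window = 3) {
  stopifnot(inherits(map, "raster_grid"))
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  m <- map$values
  k <- (window - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  lv <- sort(unique(as.vector(m)))
  lv <- lv[!is.na(lv)]
  # per-class neighbour counts by box filtering the class indicator, with
  # zero padding so off-raster neighbours never vote
  counts <- array(0L, c(nr, nc, length(lv)))
  for (i in seq_along(lv)) {
    ind <- matrix(0, nr + 2 * k, nc + 2 * k)
    ind[k + seq_len(nr), k + seq_len(nc)] <- (m == lv[i] & !is.na(m)) * 1
    counts[, , i] <- box_sum_padded(ind, k, nr, nc)
  }
  best_n <- matrix(0, nr, nc)
  best_i <- matrix(NA_integer_, nr, nc)
  for (i in seq_along(lv)) {
    upd <- counts[, , i] > best_n
    best_n[upd] <- counts[, , i][upd]
    best_i[upd] <- i
  }
  n_at_max <- matrix(0L, nr, nc)
  for (i in seq_along(lv)) {
    n_at_max <- n_at_max + (counts[, , i] == best_n)
  }
  out <- m
  has_centre <- !is.na(m)
  # a unique modal class wins; any tie for the mode retains the centre class
  replace <- has_centre & n_at_max == 1L & !is.na(best_i)
  out[replace] <- lv[best_i[replace]]
  map$values <- out
  map
}

#' Per-class feature importance decomposition
#'
#' For class c and feature f, the score is the overall Gini importance of f
#' times the absolute standardised mean of f over the training pixels of c —
#' high scores mean the forest relies on the feature and the class sits far
#' from the landscape average in it. The per-class top five features are
#' ranked.
#'
#' @param model a `trained_classifier`.
#' @param table the standardised `training_table` the model was fit to.
#' @return an object of class `importance_table`: `overall` (named numeric
#'   summing to 1), `per_class` (matrix features x classes), `top5` (named
#'   list of character vectors).
#' @export
per_class_importance <- function(model, table) {
  stopifnot(inherits(model, "trained_classifier"),
            inherits(table, "training_table"))
  classes <- model$classes
  missing_c <- setdiff(classes, unique(table$labels))
  if (length(missing_c)) {
    stop(sprintf("classes absent from the table: %s",
                 paste(missing_c, collapse = ", ")), call. = FALSE)
  }
  per_class <- sapply(classes, function(cl) {
    zbar <- colMeans(table$x[table$labels == cl, model$features, drop = FALSE])
    model$importance[model$features] * abs(zbar)
  })
  per_class <- matrix(per_class, length(model$features), length(classes),
                      dimnames = list(model$features, classes))
  top5 <- lapply(classes, function(cl) {
    names(sort(per_class[, cl], decreasing = TRUE))[seq_len(min(5, nrow(per_class)))]
  })
  structure(list(overall = model$importance,
                 per_class = per_class,
                 top5 = stats::setNames(top5, classes)),
            class = "importance_table")
}
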