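#' Extract training pixels under reference polygons
#'
#' One row per pixel whose centre lies inside a training polygon, labelled
#' with the polygon's class. Rows containing any nodata feature are dropped
#' (the count is recorded in the result).
#'
#' @param features a `feature_stack`.
#' @param reference a `reference_set` (or a data.frame of polygons with
#'   columns `class`, `xmin`, `xmax`, `ymin`, `ymax`).
#' @return an object of class `training_table`: `x` (matrix pixels x
#'   features), `labels` (character), `tag`, `dropped` (nodata rows),
#'   `center` / `scale` (set by [standardize()]).
#' @export
extract_training_pixels <- function(features, reference) {
  polys <- if (inherits(reference, "reference_set")) reference$training else reference
  if (is.null(polys) || nrow(polys) == 0) stop("no training polygons", call. = FALSE)
  nr <- nrow(features$bands[[1]]); nc <- ncol(features$bands[[1]])
  px <- features$pixel_size; org <- features$origin
  rows <- list(); labs <- list()
  for (p in seq_len(nrow(polys))) {
    # pixel-centre containment in the polygon rectangle
    cols_in <- which(org[1] + (seq_len(nc) - 0.5) * px > polys$xmin[p] &
                       org[1] + (seq_len(nc) - 0.5) * px < polys$xmax[p])
    rows_in <- which(org[2] - (seq_len(nr) - 0.5) * px < polys$ymax[p] &
                       org[2] - (seq_len(nr) - 0.5) * px > polys$ymin[p])
    if (!length(cols_in) || !length(rows_in)) next
    cells <- as.matrix(expand.grid(row = rows_in, col = cols_in))
    vals <- vapply(features$bands,
                   function(b) b[cells], numeric(nrow(cells)))
    vals <- matrix(vals, nrow(cells), length(features$bands),
                   dimnames = list(NULL, names(features$bands)))
    rows[[p]] <- vals
    labs[[p]] <- rep(polys$class[p], nrow(cells))
  }
  if (!length(rows)) stop("zero extractable pixels under the polygons", call. = FALSE)
  x <- do.call(rbind, rows)
  labels <- unlist(labs)
  keep <- stats::complete.cases(x)
  dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  if (nrow(x) == 0) stop("zero extractable pixels after nodata filtering", call. = FALSE)
  structure(list(x = x, labels = labels, tag = features$tag, dropped = dropped,
                 center = NULL, scale = NULL),
            class = "training_table")
}

#' Standardise a training table
#'
#' Centres each feature to mean 0 and scales to unit population variance.
#' Zero-variance columns are centred but scaled by 1 and flagged. The
#' parameters are stored so the identical transform can later be applied to
#' full rasters at prediction time (the fit population is the training
#' pixels only).
#'
#' @param table a `training_table`.
#' @return the table with standardised `x`, plus `center`, `scale` and
#'   `zero_variance` fields.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "training_table"))
  mu <- colMeans(table$x)
  n <- nrow(table$x)
  v <- colMeans(sweep(table$x, 2, mu)^2)  # population variance
  sc <- sqrt(v)
  zv <- sc == 0
  sc[zv] <- 1
  table$x <- sweep(sweep(table$x, 2, mu), 2, sc, "/")
  table$center <- mu
  table$scale <- sc
  table$zero_variance <- names(mu)[zv]
  table
}

apply_standardization <- function(x, table) {
  if (is.null(table$center)) stop("table is not standardised", call. = FALSE)
  sweep(sweep(x, 2, table$center[colnames(x)]), 2, table$scale[colnames(x)], "/")
}

# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into n_folds folds
stratified_folds <- function(labels, n_folds = 2) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    if (length(i) < n_folds) {
      stop(sprintf("class '%s' has fewer than %d samples; cannot stratify",
                   cl, n_folds), call. = FALSE)
    }
    fold[i[sample.int(length(i))]] <- rep_len(seq_len(n_folds), length(i))
  }
  fold
}

rf_fit <- function(x, labels, ntree, mtry, seed = NULL) {
  f <- factor(labels)
  if (nlevels(f) == 1) {
    # degenerate single-class set: a constant classifier
    return(structure(list(y = f, level = levels(f), features = colnames(x)),
                     class = "constant_classifier"))
  }
  if (!is.null(seed)) set.seed(seed)
  randomForest::randomForest(x = x, y = f, ntree = ntree,
                             mtry = min(mtry, ncol(x)), importance = FALSE)
}

#' @export
predict.constant_classifier <- function(object, newdata, ...) {
  factor(rep(object$level, nrow(newdata)), levels = object$level)
}

rf_importance <- function(fit, features) {
  if (inherits(fit, "constant_classifier")) {
    return(stats::setNames(rep(0, length(features)), features))
  }
  raw <- randomForest::importance(fit, type = 2)
  imp <- stats::setNames(raw[, 1], rownames(raw))
  imp[features]
}

cv_accuracy <- function(x, labels, fold, ntree, mtry) {
  correct <- 0L
  for (k in sort(unique(fold))) {
    tr <- fold != k
    fit <- rf_fit(x[tr, , drop = FALSE], labels[tr], ntree, mtry)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == labels[!tr])
  }
  correct / length(labels)
}

#' Recursive feature elimination with stratified 2-fold cross-validation
#'
#' Starting from the full feature set, the forest is refit and the single
#' feature with the lowest overall Gini importance is dropped (step = 1),
#' recording the stratified 2-fold cross-validated overall accuracy at each
#' subset size down to one feature. The returned optimum maximises the CV
#' curve, with ties broken toward the smaller subset. Fold assignment is
#' drawn once (seeded, stratified by class) and kept fixed along the whole
#' elimination path so the curve is not confounded by fold noise.
#'
#' @param table a standardised `training_table`.
#' @param ntree,mtry forest parameters (defaults 100 and 2).
#' @param seed integer seed controlling folds and forests.
#' @param n_folds number of CV folds (default 2).
#' @return an object of class `selection_result`: `curve` (data.frame
#'   `size`, `cv_accuracy`), `optimal_size`, `selected` (feature names),
#'   `elimination_order` (first eliminated first), `seed`.
#' @export
rfe_select <- function(table, ntree = 100, mtry = 2, seed = 1, n_folds = 2) {
  stopifnot(inherits(table, "training_table"))
  if (ncol(table$x) < 2) stop("need at least 2 features", call. = FALSE)
  feats <- colnames(table$x)
  labels <- table$labels
  withr::with_seed(seed, {
    fold <- stratified_folds(labels, n_folds)
    sizes <- integer(0); accs <- numeric(0)
    elim <- character(0)
    current <- feats
    subsets <- list()
    while (length(current) >= 1) {
      xs <- table$x[, current, drop = FALSE]
      sizes <- c(sizes, length(current))
      accs <- c(accs, cv_accuracy(xs, labels, fold, ntree, mtry))
      subsets[[length(subsets) + 1L]] <- current
      if (length(current) == 1) break
      fit <- rf_fit(xs, labels, ntree, mtry)
      imp <- rf_importance(fit, current)
      worst <- names(imp)[which.min(imp)]
      elim <- c(elim, worst)
      current <- setdiff(current, worst)
    }
    # maximise accuracy; among ties prefer the smallest subset
    best_acc <- max(accs)
    cand <- which(accs >= best_acc - 1e-12)
    opt <- cand[which.min(sizes[cand])]
    structure(list(curve = data.frame(size = sizes, cv_accuracy = accs),
                   optimal_size = sizes[opt],
                   selected = subsets[[opt]],
                   elimination_order = elim,
                   seed = seed),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> optimal size %d of %d (CV accuracy %.3f)\n",
              x$optimal_size, max(x$curve$size),
              max(x$curve$cv_accuracy)))
  invisible(x)
}
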