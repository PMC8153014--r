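make_table <- function(x, labels) {
  structure(list(x = x, labels = labels, tag = "synthetic", dropped = 0,
                 center = NULL, scale = NULL),
            class = "training_table")
}

test_that("a single-class training set predicts only that class", {
  tab <- standardize(make_table(
    cbind(f1 = stats::rnorm(20), f2 = stats::rnorm(20)), rep("water", 20)))
  m <- train_rf(tab, ntree = 20, mtry = 1, seed = 1)
  fs <- feature_stack(list(f1 = matrix(0, 4, 4), f2 = matrix(1, 4, 4)), 20)
  map <- predict_map(m, fs)
  expect_true(all(map$classes[map$values] == "water"))
})

test_that("disjoint single-feature supports give perfect held-out accuracy", {
  withr::with_seed(1, {
    lab <- rep(c("a", "b"), each = 30)
    x <- cbind(f = ifelse(lab == "a", stats::runif(60, 0, 1),
                          stats::runif(60, 3, 4)),
               g = stats::rnorm(60))
    tr <- c(1:20, 31:50)
    tab <- standardize(make_table(x[tr, ], lab[tr]))
    m <- train_rf(tab, ntree = 50, mtry = 1, seed = 1)
    held <- sweep(sweep(x[-tr, ], 2, m$center), 2, m$scale, "/")
    pred <- as.character(stats::predict(m$forest, held))
    expect_equal(mean(pred == lab[-tr]), 1)
  })
})

test_that("the default 12-class scene is classified with high held-out accuracy", {
  sc <- default_scene()
  m <- default_model()
  expect_equal(sum(m$importance), 1, tolerance = 1e-9)
  expect_true(all(m$importance >= 0))
  map <- predict_map(m, default_features())
  acc <- confusion(map, sc$reference)
  expect_gte(acc$oa / 100, 0.90)
  # the majority filter should not hurt (and usually helps) accuracy
  accf <- confusion(majority_filter(map), sc$reference)
  expect_gte(accf$oa, acc$oa - 2)
})

test_that("map prediction is consistent between grid pixels and test points", {
  sc <- default_scene()
  m <- default_model()
  map <- predict_map(m, default_features())
  expect_true(all(map$values[!is.na(map$values)] %in%
                    seq_along(map$classes)))
  # training self-accuracy on separable synthetic data is near-perfect
  tab <- default_table()
  pred <- as.character(stats::predict(m$forest, tab$x))
  expect_gte(mean(pred == tab$labels), 0.99)
})

test_that("prediction rejects a feature stack missing model features", {
  m <- default_model()
  fs <- feature_stack(list(Blue = matrix(0, 3, 3)), 20)
  expect_error(predict_map(m, fs), "lacks model features")
  tab <- default_table()
  expect_error(train_rf(tab, ntree = 100, mtry = 99, seed = 1), "mtry")
})

test_that("pixels with nodata features stay nodata in the map", {
  m <- default_model()
  fs <- default_features()
  fs$bands$Blue[1, 1] <- NA
  map <- predict_map(m, fs)
  expect_true(is.na(map$values[1, 1]))
  expect_false(is.na(map$values[5, 5]))
})

class_map_of <- function(values, classes = c("a", "b", "c")) {
  g <- raster_grid(values, 20, categorical = TRUE)
  g$classes <- classes
  class(g) <- c("class_map", class(g))
  g
}

test_that("majority filter smooths salt pixels and honours the tie rule", {
  uni <- class_map_of(matrix(1L, 5, 5))
  expect_identical(majority_filter(uni)$values, uni$values)
  salt <- matrix(1L, 5, 5)
  salt[3, 3] <- 2L
  expect_equal(majority_filter(class_map_of(salt))$values[3, 3], 1L)
  # perfect two-class tie around a third-class centre: centre retained
  tie <- matrix(c(1L, 1L, 2L,
                  2L, 3L, 1L,
                  2L, 2L, 1L), 3, 3, byrow = TRUE)
  expect_equal(majority_filter(class_map_of(tie))$values[2, 2], 3L)
  # never introduces an absent class; idempotent under strict majorities
  withr::with_seed(6, {
    m <- matrix(sample(1:3, 144, replace = TRUE), 12, 12)
    f1 <- majority_filter(class_map_of(m))
    expect_true(all(f1$values %in% m))
    big <- matrix(1L, 10, 10); big[, 6:10] <- 2L
    once <- majority_filter(class_map_of(big))
    expect_identical(majority_filter(once)$values, once$values)
  })
})

test_that("per-class importance follows the product rule", {
  withr::with_seed(3, {
    lab <- rep(c("a", "b"), each = 25)
    x <- cbind(f = (lab == "a") * 2 + stats::rnorm(50, 0, 0.1))
    tab <- standardize(make_table(x, lab))
    m <- train_rf(tab, ntree = 30, mtry = 1, seed = 3)
    imp <- per_class_importance(m, tab)
    # single feature: overall importance 1, score = |class mean z|
    expect_equal(unname(imp$overall), 1)
    expect_equal(imp$per_class["f", "a"],
                 abs(mean(tab$x[lab == "a", "f"])), tolerance = 1e-12)
  })
})

test_that("an elevation shift makes elevation the top feature for that class", {
  withr::with_seed(7, {
    classes <- rep(paste0("c", 1:4), each = 25)
    n <- length(classes)
    # classes 2-4 are separable in their own band; class 1 is spectrally
    # plain and distinguished only by a +3 sd elevation shift
    x <- cbind(sapply(2:4, function(i) (classes == paste0("c", i)) * 2 +
                        stats::rnorm(n, 0, 0.3)),
               Elevation = stats::rnorm(n, 0, 1))
    colnames(x) <- c(paste0("band", 2:4), "Elevation")
    x[classes == "c1", "Elevation"] <- x[classes == "c1", "Elevation"] + 3
    tab <- standardize(make_table(x, classes))
    m <- train_rf(tab, ntree = 100, mtry = 2, seed = 7)
    imp <- per_class_importance(m, tab)
    expect_equal(imp$top5[["c1"]][1], "Elevation")
  })
})

test_that("per-class scores ignore the labels of other classes", {
  withr::with_seed(12, {
    lab <- rep(c("a", "b", "c"), each = 20)
    x <- matrix(stats::rnorm(60 * 3), 60, 3,
                dimnames = list(NULL, paste0("f", 1:3)))
    x[lab == "a", 1] <- x[lab == "a", 1] + 2
    tab <- standardize(make_table(x, lab))
    m <- train_rf(tab, ntree = 50, mtry = 2, seed = 12)
    base <- per_class_importance(m, tab)
    relab <- tab
    relab$labels[relab$labels == "c"] <- "b"  # merge two other classes
    m2 <- m
    expect_equal(base$per_class[, "a"],
                 (m$importance * abs(colMeans(tab$x[lab == "a", , drop = FALSE]))),
                 tolerance = 1e-12)
  })
})

test_that("dropping a pure-noise feature never costs held-out accuracy", {
  withr::with_seed(21, {
    drops <- vapply(1:5, function(s) {
      set.seed(100 + s)
      lab <- rep(c("a", "b", "c"), each = 30)
      n <- length(lab)
      x <- cbind(f1 = (lab == "a") * 3 + stats::rnorm(n, 0, 0.3),
                 f2 = (lab == "b") * 3 + stats::rnorm(n, 0, 0.3),
                 noise = stats::rnorm(n))
      tr <- sample(n, 60)
      fit_oa <- function(cols) {
        tab <- standardize(make_table(x[tr, cols, drop = FALSE], lab[tr]))
        m <- train_rf(tab, ntree = 60, mtry = 1, seed = s)
        held <- sweep(sweep(x[-tr, cols, drop = FALSE], 2, m$center), 2,
                      m$scale, "/")
        mean(as.character(stats::predict(m$forest, held)) == lab[-tr])
      }
      fit_oa(c("f1", "f2", "noise")) - fit_oa(c("f1", "f2"))
    }, 0)
    expect_true(all(drops <= 0.05))
  })
})
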