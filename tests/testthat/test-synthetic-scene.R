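test_that("scene generation is deterministic under a fixed seed", {
  cfg <- scene_config(rows = 40, cols = 40, seed = 11, n_optical = 3,
                      n_radar = 3)
  a <- simulate_scene(cfg, n_points_per_class = 10)
  b <- simulate_scene(cfg, n_points_per_class = 10)
  expect_identical(a$truth$values, b$truth$values)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$optical$stacks[[2]]$bands$NIR, b$optical$stacks[[2]]$bands$NIR)
  expect_identical(a$radar$stacks[[3]]$bands$VH, b$radar$stacks[[3]]$bands$VH)
  expect_identical(a$reference$testing, b$reference$testing)
})

test_that("a single-signature catalogue yields a single-class map", {
  cfg <- scene_config(rows = 30, cols = 30, seed = 3,
                      signatures = default_signatures()["water"])
  truth <- generate_class_map(cfg)
  expect_true(all(truth$values == 1L))
})

test_that("the 12-class default scene is patchy but balanced", {
  truth <- default_scene()$truth
  shares <- tabulate(truth$values, 12) / length(truth$values)
  expect_length(shares, 12)
  expect_true(all(shares >= 0.02))
  expect_true(all(shares <= 0.20))
  # spatial autocorrelation: neighbours agree far more often than chance
  v <- truth$values
  agree <- mean(v[-1, ] == v[-nrow(v), ])
  expect_gt(agree, 0.8)
})

test_that("water and peatland occupy the valley bottoms", {
  sc <- default_scene()
  dem20 <- resample_to_grid(sc$dem, sc$truth)$values
  low <- dem20 <= stats::quantile(dem20, 0.1)
  wet <- sc$truth$classes[sc$truth$values] %in% c(peatland_classes(), "water")
  expect_gte(mean(wet[low]), 0.8)
})

test_that("a flat configuration produces a constant DEM", {
  cfg <- scene_config(rows = 30, cols = 30, seed = 5, relief_m = 0,
                      roughness_m = 0)
  dem <- generate_dem(cfg)
  expect_true(all(is.finite(dem$values)))
  expect_equal(max(dem$values) - min(dem$values), 0)
})

test_that("degenerate optical noise reproduces class means on every date", {
  sigs <- default_signatures()
  sigs <- lapply(sigs, function(s) {
    s$optical_sd[] <- 0
    s$seasonal_amplitude[] <- 0
    s
  })
  cfg <- scene_config(rows = 30, cols = 30, seed = 9, n_optical = 3,
                      cloud_fraction = 0, signatures = sigs)
  truth <- generate_class_map(cfg)
  ser <- generate_optical_series(truth, cfg)
  expect_identical(ser$stacks[[1]]$bands$Red, ser$stacks[[3]]$bands$Red)
  mu <- vapply(sigs, function(s) s$optical_mean[["NIR"]], 0)
  expect_equal(ser$stacks[[2]]$bands$NIR, matrix(mu[truth$values], 30, 30))
  expect_false(any(ser$stacks[[1]]$cloud_truth))
})

test_that("optical class means are recovered from the time series", {
  sigs <- default_signatures()["water"]
  sigs$water$optical_mean[["NIR"]] <- 0.5
  sigs$water$optical_sd[] <- 0.01
  sigs$water$seasonal_amplitude[] <- 0
  cfg <- scene_config(rows = 20, cols = 20, seed = 3, n_optical = 20,
                      cloud_fraction = 0, signatures = sigs)
  truth <- generate_class_map(cfg)
  ser <- generate_optical_series(truth, cfg)
  nir_mean <- mean(vapply(ser$stacks, function(s) mean(s$bands$NIR), 0))
  expect_lt(abs(nir_mean - 0.5), 0.01)
})

test_that("cloud fraction 1 flags everything; budget tracks the setting", {
  cfg <- scene_config(rows = 50, cols = 50, seed = 2, n_optical = 2,
                      cloud_fraction = 1)
  truth <- generate_class_map(cfg)
  ser <- generate_optical_series(truth, cfg)
  expect_true(all(ser$stacks[[1]]$cloud_truth))
  sc <- default_scene()  # cloud_fraction 0.2 at 200x200
  fracs <- vapply(sc$optical$stacks, function(s) mean(s$cloud_truth), 0)
  expect_true(all(abs(fracs - 0.2) <= 0.05))
})

test_that("speckle has unit mean power and vanishes at high looks", {
  sigs <- default_signatures()["water"]
  sigs$water$sar_mean_db <- c(VV = -10, VH = -10)
  sigs$water$speckle_looks <- 5
  cfg <- scene_config(rows = 20, cols = 20, seed = 1, n_radar = 50,
                      signatures = sigs)
  truth <- generate_class_map(cfg)
  ser <- generate_sar_series(truth, cfg)
  pow <- vapply(ser$stacks, function(s) mean(10^(s$bands$VV / 10)), 0)
  expect_lt(abs(mean(pow) - 0.1) / 0.1, 0.02)
  sigs$water$speckle_looks <- 1e6
  cfg2 <- scene_config(rows = 10, cols = 10, seed = 1, n_radar = 1,
                       signatures = sigs)
  ser2 <- generate_sar_series(generate_class_map(cfg2), cfg2)
  expect_true(all(abs(ser2$stacks[[1]]$bands$VV - (-10)) < 0.1))
})

test_that("reference labels agree with the truth everywhere", {
  sc <- default_scene()
  te <- sc$reference$testing
  expect_equal(nrow(te), 12 * 50)
  expect_identical(sc$truth$classes[sc$truth$values[cbind(te$row, te$col)]],
                   te$class)
  tr <- sc$reference$training
  for (i in seq_len(nrow(tr))) {
    block <- sc$truth$values[tr$row0[i]:tr$row1[i], tr$col0[i]:tr$col1[i]]
    expect_true(all(sc$truth$classes[block] == tr$class[i]))
  }
})

test_that("reference sampling respects sizes and rejects absent classes", {
  sc <- default_scene()
  empty <- sample_reference(sc$truth, n_polygons_per_class = 1,
                            n_points_per_class = 0, seed = 4)
  expect_equal(nrow(empty$testing), 0)
  expect_gt(nrow(empty$training), 0)
  # a truth raster missing a catalogue class errors with its name
  t2 <- sc$truth
  t2$values[t2$values == 12L] <- 1L
  expect_error(sample_reference(t2, 1, 5, seed = 1), "water")
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(rows = 0), "positive")
  expect_error(scene_config(cloud_fraction = 1.5), "cloud_fraction")
  sigs <- default_signatures()
  names(sigs)[1] <- "swampy nonsense"
  expect_error(scene_config(signatures = sigs), "swampy nonsense")
  expect_error(class_signature("water", optical_mean = 1.5), "\\[0, 1\\]")
  expect_error(class_signature("water", 0.5, speckle_looks = 0.5), "looks")
  expect_error(class_signature("water", 0.5, elevation_range_m = c(5, 1)),
               "low <= high")
})

test_that("the class catalogue has 12 classes mapping onto 6 general classes", {
  cc <- class_catalogue()
  expect_equal(nrow(cc), 12)
  expect_equal(anyDuplicated(cc$class), 0)
  expect_setequal(unique(cc$general),
                  c("Peatland", "Forest", "Sparse", "Plantation",
                    "Artificial and bare areas", "Hydrology"))
  expect_length(peatland_classes(), 4)
})
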