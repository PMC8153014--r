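optical_stack_from <- function(vals) {
  # constant-valued bands from a named vector, 4x4 grid
  bands <- lapply(vals, function(v) matrix(v, 4, 4))
  need <- setdiff(c("Blue", "Green", "Red", "RedEdge1", "RedEdge2", "RedEdge3",
                    "RedEdge4", "NIR", "SWIR1", "SWIR2"), names(bands))
  for (b in need) bands[[b]] <- matrix(0.2, 4, 4)
  scene_stack(bands, 20)
}

test_that("vegetation indices match hand-evaluated formulas", {
  st <- optical_stack_from(c(NIR = 0.4, Red = 0.2, Blue = 0.1, Green = 0.3,
                             SWIR1 = 0.25, SWIR2 = 0.15,
                             RedEdge1 = 0.3, RedEdge2 = 0.5, RedEdge3 = 0.7))
  vi <- vegetation_indices(st)
  expect_equal(vi$NDVI[1, 1], (0.4 - 0.2) / 0.6)
  expect_equal(vi$NDWI[1, 1], (0.3 - 0.4) / 0.7)
  expect_equal(vi$LSWI[1, 1], (0.4 - 0.25) / 0.65)
  expect_equal(vi$NBR[1, 1], (0.4 - 0.15) / 0.55)
  expect_equal(vi$NBR2[1, 1], (0.25 - 0.15) / 0.4)
  expect_equal(vi$GNDVI[1, 1], (0.4 - 0.3) / 0.7)
  expect_equal(vi$EVI[1, 1], 2.5 * 0.2 / (0.4 + 6 * 0.2 - 7.5 * 0.1 + 1),
               tolerance = 1e-12)
  expect_equal(round(vi$EVI[1, 1], 4), 0.2703)
  expect_equal(vi$ARVI[1, 1], (0.4 - 0.3) / (0.4 + 0.3))
  expect_equal(vi$S2REP[1, 1], 705 + 35 * (((0.7 + 0.2) / 2 - 0.3) / 0.2))
  # red-edge position with Red 0.1: 705 + 35 * ((0.4 - 0.3) / (0.5 - 0.3))
  st2 <- optical_stack_from(c(Red = 0.1, RedEdge1 = 0.3, RedEdge2 = 0.5,
                              RedEdge3 = 0.7))
  expect_equal(vegetation_indices(st2)$S2REP[1, 1], 722.5)
  expect_equal(vi$MSAVI2[1, 1],
               (2 * 0.4 + 1 - sqrt((2 * 0.4 + 1)^2 - 8 * 0.2)) / 2)
})

test_that("degenerate index inputs yield zero or nodata, never infinities", {
  st <- optical_stack_from(c(NIR = 0.5, Red = 0.5))
  vi <- vegetation_indices(st)
  expect_equal(vi$NDVI[1, 1], 0)
  expect_equal(vi$MSAVI2[1, 1], 0)  # NIR - Red = 0 collapses the root term
  z <- optical_stack_from(c(NIR = 0, Red = 0, Green = 0, Blue = 0,
                            SWIR1 = 0, SWIR2 = 0, RedEdge1 = 0.3,
                            RedEdge2 = 0.3, RedEdge3 = 0.3, RedEdge4 = 0.3))
  vz <- vegetation_indices(z)
  expect_true(is.na(vz$NDVI[1, 1]))
  expect_true(is.na(vz$S2REP[1, 1]))
  expect_false(any(vapply(vz, function(m) any(is.infinite(m)), TRUE)))
})

test_that("normalised-difference indices stay in [-1, 1] on random reflectance", {
  withr::with_seed(5, {
    bands <- stats::setNames(lapply(1:10, function(i)
      matrix(stats::runif(100, 0.01, 1), 10, 10)),
      c("Blue", "Green", "Red", "RedEdge1", "RedEdge2", "RedEdge3",
        "RedEdge4", "NIR", "SWIR1", "SWIR2"))
    vi <- vegetation_indices(scene_stack(bands, 20))
    for (nm in c("NDVI", "NDWI", "LSWI", "NBR", "NBR2", "GNDVI")) {
      expect_true(all(abs(vi[[nm]]) <= 1), info = nm)
    }
  })
})

test_that("window standard deviation matches enumeration and the oracle", {
  expect_equal(window_stddev(matrix(7, 9, 9))[5, 5], 0)
  m <- matrix(0, 9, 9)
  m[5, 5] <- 1
  expect_equal(window_stddev(m)[5, 5], sqrt(24 / 625), tolerance = 1e-12)
  expect_equal(round(window_stddev(m)[5, 5], 3), 0.196)
  alt <- matrix(rep(c(0, 1), length.out = 9), 9, 9, byrow = TRUE)
  w <- as.vector(alt[3:7, 3:7])
  expect_equal(window_stddev(alt)[5, 5], stats::sd(w) * sqrt(24 / 25),
               tolerance = 1e-12)
  withr::with_seed(31, {
    r <- matrix(stats::rnorm(400), 20, 20)
    r[sample(400, 20)] <- NA
    got <- window_stddev(r, 5)
    ridx <- function(n) c(2:1, 1:n, n:(n - 1))
    pad <- r[ridx(20), ridx(20)]
    for (i in seq(1, 20, by = 3)) {
      for (j in seq(1, 20, by = 3)) {
        w <- as.vector(pad[i:(i + 4), j:(j + 4)])
        w <- w[!is.na(w)]
        want <- sqrt(mean((w - mean(w))^2))
        expect_equal(got[i, j], want, tolerance = 1e-12)
      }
    }
  })
  expect_error(window_stddev(matrix(0, 3, 3), 5), "larger")
  expect_error(window_stddev(matrix(0, 9, 9), 4), "odd")
})

test_that("GLCM statistics match the explicit-matrix oracle", {
  spec <- glcm_spec(kernel = 3, distance = 1, n_grey = 2, directions = "0")
  chk <- matrix(rep(c(0, 1), length.out = 10), 10, 10, byrow = TRUE)
  chk <- (row(chk) + col(chk)) %% 2
  out <- glcm_features(chk, spec)
  # every horizontal pair is (0,1) or (1,0): contrast exactly 1
  expect_equal(out$glcm_contrast[5, 5], 1)
  cst <- glcm_features(matrix(3.3, 12, 12), glcm_spec())
  expect_equal(cst$glcm_contrast[6, 6], 0)
  expect_equal(cst$glcm_variance[6, 6], 0)
  expect_equal(cst$glcm_correlation[6, 6], 0)  # zero variance -> defined as 0

  withr::with_seed(99, {
    r <- matrix(stats::runif(400), 20, 20)
    spec4 <- glcm_spec(kernel = 3, distance = 4, n_grey = 8)
    got <- glcm_features(r, spec4)
    q <- oracle_quantise(r, 8)
    for (p in list(c(1, 1), c(3, 17), c(10, 10), c(20, 5), c(7, 19))) {
      want <- oracle_glcm_pixel(q, p[1], p[2], spec4)
      expect_equal(got$glcm_contrast[p[1], p[2]], want[["contrast"]],
                   tolerance = 1e-12)
      expect_equal(got$glcm_correlation[p[1], p[2]], want[["correlation"]],
                   tolerance = 1e-12)
      expect_equal(got$glcm_variance[p[1], p[2]], want[["variance"]],
                   tolerance = 1e-12)
    }
    expect_true(all(got$glcm_contrast >= 0))
    expect_true(all(got$glcm_variance >= 0))
    expect_true(all(abs(got$glcm_correlation) <= 1 + 1e-12))
  })
  expect_error(glcm_spec(n_grey = 1), "n_grey")
})

test_that("temporal amplitude is the p90 - p10 range of the series", {
  st <- function(x) scene_stack(list(VV = matrix(x, 2, 2)), 20)
  ser <- image_series(lapply(0:10, st), 0:10 + 1)
  amp <- temporal_amplitude(ser, "VV")
  expect_equal(amp$values[1, 1], 8)
  two <- image_series(lapply(c(3, 10), st), 1:2)
  expect_equal(temporal_amplitude(two, "VV")$values[1, 1], 7 * 0.8)
  const <- image_series(lapply(c(4, 4, 4), st), 1:3)
  expect_equal(temporal_amplitude(const, "VV")$values[1, 1], 0)
  expect_true(all(amp$values >= 0))
  one <- image_series(list(st(5)), 1)
  expect_true(all(is.na(temporal_amplitude(one, "VV")$values)))
  expect_error(temporal_amplitude(ser, "VH"), "VH")
})

test_that("terrain features follow Horn's method and the aspect convention", {
  flat <- terrain_features(raster_grid(matrix(5, 8, 8), 30))
  expect_true(all(flat$Slope$values == 0))
  expect_true(all(is.na(flat$Aspect$values)))
  # plane z = x: one metre of rise per metre east
  px <- 10
  east <- raster_grid(matrix(rep((1:12) * px, each = 12), 12, 12), px)
  tf <- terrain_features(east)
  expect_equal(tf$Slope$values[6, 6], 45)
  expect_equal(tf$Aspect$values[6, 6], 270)  # downslope faces west
  north <- raster_grid(matrix(rep(rev(1:12) * px, times = 12), 12, 12), px)
  expect_equal(terrain_features(north)$Aspect$values[6, 6], 180)
  expect_equal(tf$Elevation$values, east$values)
})

test_that("dataset combinations carry exactly the canonical feature lists", {
  expect_identical(combination_features("S1"), c("VH", "VV"))
  counts <- c("S2" = 10, "S2+" = 21, "S1" = 2, "S1+" = 12,
              "S2+S1+" = 33, "S2+S1+DEM" = 36)
  for (tag in names(counts)) {
    expect_length(combination_features(tag), counts[[tag]])
  }
  expect_error(combination_features("S3"), "unknown")

  sc <- default_scene()
  cp <- default_composites()
  for (tag in c("S1", "S1+", "S2", "S2+S1+DEM")) {
    fs <- assemble_combination(tag, optical = cp$optical, radar = cp$radar,
                               radar_series = sc$radar, dem = sc$dem)
    expect_identical(names(fs$bands), combination_features(tag))
    expect_identical(fs$tag, tag)
  }
  expect_error(assemble_combination("S2+S1+DEM", optical = cp$optical,
                                    radar = cp$radar, radar_series = sc$radar),
               "dem")
  expect_error(assemble_combination("S2"), "optical")
})
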