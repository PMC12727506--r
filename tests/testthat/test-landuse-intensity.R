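# Land-use allocation, minmax scaling, contextual bins, intensity.

test_that("allocation follows the priority tree", {
  # pixel 1: settlement + crop conflict; pixel 2: crop inside a reserve;
  # pixel 3: nothing matches; pixel 4: pure protected
  layers <- list(
    population_density = matrix(c(5000, 10, 10, 10), 1),
    timber_cover       = matrix(0, 1, 4),
    tree_crop_cover    = matrix(0, 1, 4),
    crop_cover         = matrix(c(0.9, 0.9, 0.1, 0.1), 1),
    protected_strict   = matrix(c(0, 1, 0, 1), 1)
  )
  lu <- allocate_land_use(layers)
  expect_equal(as.vector(lu$class),
               c("settlement", "crop", "untransformed", "protected"))
})

test_that("allocation is order-dependent exactly as the priority predicts", {
  layers <- list(population_density = matrix(5000, 1, 1),
                 timber_cover = matrix(0, 1, 1),
                 tree_crop_cover = matrix(0, 1, 1),
                 crop_cover = matrix(0.9, 1, 1),
                 protected_strict = matrix(0, 1, 1))
  full <- allocate_land_use(layers)
  expect_equal(as.vector(full$class), "settlement")
  # removing the higher-priority rule hands the conflict pixel to crop
  cfg <- allocation_config()
  cfg$rules$settlement <- NULL
  expect_equal(as.vector(allocate_land_use(layers, cfg)$class), "crop")
})

test_that("misaligned layers are rejected with names and shapes", {
  layers <- list(population_density = matrix(0, 2, 2),
                 timber_cover = matrix(0, 2, 2),
                 tree_crop_cover = matrix(0, 2, 2),
                 crop_cover = matrix(0, 3, 2),
                 protected_strict = matrix(0, 2, 2))
  expect_error(allocate_land_use(layers), "misaligned")
  expect_error(allocate_land_use(layers), "crop_cover")
})

test_that("minmax scaling: linear map, cap, affine invariance, idempotence", {
  expect_equal(scale_minmax(c(0, 5, 10)), c(0, 0.5, 1))

  # 90th-percentile cap: values above the percentile clip to 1
  x <- 0:10
  capped <- scale_minmax(x, cap_percentile = 0.9)
  q90 <- quantile(x, 0.9, names = FALSE)
  expect_equal(capped, pmin(1, (x - 0) / (q90 - 0)))
  expect_equal(capped[11], 1)

  # positive-affine invariance, brute force on random vectors
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(30); a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(scale_minmax(a * v + b), scale_minmax(v), tolerance = 1e-12)
    expect_equal(scale_minmax(a * v + b, 0.9), scale_minmax(v, 0.9),
                 tolerance = 1e-12)
  }

  # idempotence without cap
  set.seed(12)
  v <- runif(50)
  expect_equal(scale_minmax(scale_minmax(v)), scale_minmax(v))

  # constant input maps to zeros, all-missing errors
  expect_equal(scale_minmax(rep(3, 4)), rep(0, 4))
  expect_error(scale_minmax(c(NA_real_, NA)), "all values missing")
})

test_that("contextual bins are half-open 400 mm bands crossed with soil", {
  expect_equal(contextual_bin(350, "low"), "mar0:low")
  expect_equal(contextual_bin(400, "low"), "mar1:low")
  expect_equal(contextual_bin(700, "high"), contextual_bin(750, "high"))
  expect_error(contextual_bin(-5, "low"), "negative rainfall")
  expect_error(contextual_bin(100, "sandy"), "soil")
})

test_that("intensity protocol: degenerate classes, single proxies, bounds", {
  # single-pixel class scores theta = 0
  lu1 <- land_use_grid(matrix(c("crop", "untransformed"), 1))
  prox1 <- list(nitrogen_input = matrix(c(50, 0), 1),
                field_size = matrix(c(5, 0), 1),
                livestock_density = matrix(c(0, 3), 1),
                mar = matrix(500, 1, 2), soil = matrix("low", 1, 2))
  th1 <- compute_intensity(lu1, prox1)$intensity
  expect_equal(th1[1, 1], 0)
  expect_equal(th1[1, 2], 0)

  # one proxy only: theta equals that proxy's rescaled minmax
  lu <- land_use_grid(matrix("settlement", 1, 5))
  pop <- matrix(c(0, 10, 20, 30, 40), 1)
  th <- compute_intensity(lu, list(population_density = pop))$intensity
  expect_equal(as.vector(th),
               scale_minmax(scale_minmax(as.vector(pop), 0.9)))

  # theta spans [0, 1] whenever a class has >= 2 distinct values
  expect_equal(min(th), 0)
  expect_equal(max(th), 1)
})

test_that("livestock theta is monotone within a contextual bin", {
  set.seed(21)
  n <- 40
  lu <- land_use_grid(matrix("untransformed", 1, n))
  mar <- matrix(c(rep(100, n / 2), rep(900, n / 2)), 1)
  soil <- matrix("medium", 1, n)
  ls <- matrix(runif(n, 0, 100), 1)
  th <- compute_intensity(lu, list(livestock_density = ls, mar = mar,
                                   soil = soil))$intensity
  for (half in list(1:(n / 2), (n / 2 + 1):n)) {
    o <- order(ls[1, half])
    expect_true(all(diff(th[1, half][o]) >= -1e-12))
  }

  # raising one pixel's density within its bin never decreases its theta
  ls2 <- ls; ls2[1, 3] <- ls[1, 3] + 20
  th2 <- compute_intensity(lu, list(livestock_density = ls2, mar = mar,
                                    soil = soil))$intensity
  expect_gte(th2[1, 3], th[1, 3] - 1e-12)
})

test_that("area-overlap resampling conserves mass and averages by overlap", {
  src <- grid_geom(2, 2, res = 1)
  dst <- grid_geom(1, 1, res = 2)
  v <- matrix(c(0.1, 0.3, 0.2, 0.4), 2)  # column-major: {0.1,0.2;0.3,0.4}
  expect_equal(resample_overlap(v, src, dst, "sum")[1, 1], 1.0)
  expect_equal(resample_overlap(v, src, dst, "weighted_mean")[1, 1], 0.25)

  # half-overlap weights {2/3, 1/3} on values {3, 9} -> 5
  src2 <- grid_geom(1, 2, xmin = 0, res = 3)          # cells [0,3), [3,6)
  dst2 <- grid_geom(1, 1, xmin = 1, res = 3)          # cell  [1,4)
  v2 <- matrix(c(3, 9), 1)
  expect_equal(resample_overlap(v2, src2, dst2, "weighted_mean")[1, 1], 5)

  dst3 <- grid_geom(1, 1, xmin = 100, res = 1)
  expect_error(resample_overlap(v2, src2, dst3), "disjoint")
})

test_that("nearest-neighbour imputation fills from the closest donor", {
  line <- matrix(c(5, NA, NA, 9), 1)
  expect_equal(as.vector(impute_missing(line)), c(5, 5, 9, 9))

  full <- matrix(1:6, 2)
  expect_identical(impute_missing(full), full)

  one <- matrix(c(NA, NA, 7, NA), 2)
  expect_equal(as.vector(impute_missing(one)), rep(7, 4))

  expect_error(impute_missing(matrix(NA_real_, 2, 2)), "fully missing")
})
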