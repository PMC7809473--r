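test_that("fwhm/sigma conversion matches the closed form and validates input", {
  expect_equal(fwhm_to_sigma(5), 2.1233045, tolerance = 1e-6)
  expect_equal(fwhm_to_sigma(2 * sqrt(2 * log(2))), 1, tolerance = 1e-12)
  expect_error(fwhm_to_sigma(0), class = "non_positive_error")
  expect_error(fwhm_to_sigma(-1), class = "non_positive_error")
})

test_that("gaussian smoothing preserves constants, mass, and peak height", {
  const <- gm_image(array(3.5, dim = c(12, 12, 12)))
  sm <- smooth_image(const, 5)
  expect_equal(sm$data, const$data, tolerance = 1e-12)

  set.seed(1)
  img <- gm_image(array(runif(20^3), dim = c(20, 20, 20)))
  sm <- smooth_image(img, 5)
  expect_equal(sum(sm$data), sum(img$data), tolerance = 1e-6)

  # point source: peak equals the 3-D gaussian normalization (2 pi sigma^2)^(-3/2)
  big <- array(0, dim = c(41, 41, 41))
  big[21, 21, 21] <- 1
  smp <- smooth_image(gm_image(big), 5)
  sigma <- fwhm_to_sigma(5)
  expect_equal(smp$data[21, 21, 21], (2 * pi * sigma^2)^(-3 / 2), tolerance = 0.01)
})

test_that("sphere offsets equal brute-force lattice enumeration", {
  brute <- function(d, v) {
    r <- d / 2
    m <- 10L
    g <- expand.grid(-m:m, -m:m, -m:m)
    sum((g[, 1] * v)^2 + (g[, 2] * v)^2 + (g[, 3] * v)^2 <= r^2)
  }
  expect_equal(nrow(sphere_voxel_offsets(5, 1)), brute(5, 1))     # 81
  expect_equal(nrow(sphere_voxel_offsets(2, 1)), brute(2, 1))     # 7
  expect_equal(nrow(sphere_voxel_offsets(0.5, 1)), brute(0.5, 1)) # 1
  set.seed(2)
  for (d in runif(5, 0.5, 9)) {
    expect_equal(nrow(sphere_voxel_offsets(d, 1.5)),
                 brute(d, 1.5), info = paste("diameter", d))
  }
  expect_error(sphere_voxel_offsets(0, 1), class = "non_positive_error")
  expect_error(sphere_voxel_offsets(5, -1), class = "non_positive_error")
})

test_that("extraction reproduces closed-form values on phantoms", {
  atlas <- toy_atlas(data.frame(
    name = c("C1", "C2"), hemisphere = "midline",
    x = c(6, 13), y = c(8, 12), z = c(9, 10),
    cluster = "limbic", stringsAsFactors = FALSE))
  # constant image -> constant extraction, any smoothing
  const <- gm_image(array(2, dim = c(20, 20, 20)))
  vm <- extract_region_volumes(list(const), atlas)
  expect_equal(unname(vm$values[1, ]), c(2, 2))
  # unsmoothed point of 81 at the exact center voxel -> sphere mean 1
  pt <- array(0, dim = c(20, 20, 20))
  pt[7, 9, 10] <- 81  # voxel (6, 8, 9) 0-based = C1 center
  vm <- extract_region_volumes(list(gm_image(pt)), atlas, diameter_mm = 5,
                               fwhm_mm = 0)
  expect_equal(unname(vm$values[1, 1]), 1)
  # intensity equivariance
  set.seed(3)
  arr <- array(runif(20^3), dim = c(20, 20, 20))
  v1 <- extract_region_volumes(list(gm_image(arr)), atlas)
  v3 <- extract_region_volumes(list(gm_image(3 * arr)), atlas)
  expect_equal(v3$values, 3 * v1$values, tolerance = 1e-12)
  # alternative sphere diameters run unchanged
  for (d in c(2.5, 7.5)) {
    expect_silent(extract_region_volumes(list(gm_image(arr)), atlas,
                                         diameter_mm = d))
  }
  # out-of-bounds sphere raises a named error
  edge <- toy_atlas(data.frame(name = "E", hemisphere = "midline",
                               x = 0, y = 0, z = 0, cluster = "limbic",
                               stringsAsFactors = FALSE))
  expect_error(extract_region_volumes(list(gm_image(arr)), edge),
               class = "out_of_bounds_error")
  # mismatched grids
  expect_error(
    extract_region_volumes(list(gm_image(arr),
                                gm_image(array(0, dim = c(10, 10, 10)))), atlas),
    class = "grid_mismatch_error")
})

test_that("z-scoring follows the population-SD convention and inverts exactly", {
  vm <- volume_matrix(matrix(c(1, 2, 3, 4, 6, 8), 3, 2),
                      regions = c("a", "b"))
  sc <- zscore_fit(vm)
  z <- zscore_apply(vm, sc)
  expect_equal(unname(z$values[, 1]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_equal(unname(colMeans(z$values)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(z$values, 2, function(x) sqrt(mean((x - mean(x))^2)))),
               c(1, 1), tolerance = 1e-8)
  back <- zscore_invert(z)
  expect_equal(back$values, vm$values, tolerance = 1e-10)
  # out-of-sample application need not center the held-out rows
  held <- volume_matrix(matrix(c(10, 11, 20, 22), 2, 2), regions = c("a", "b"))
  zh <- zscore_apply(held, sc)
  expect_true(all(abs(colMeans(zh$values)) > 1))
  # zero variance is a named error
  flat <- volume_matrix(matrix(c(1, 1, 1, 1, 2, 3), 3, 2),
                        regions = c("flat", "ok"))
  expect_error(zscore_fit(flat), class = "zero_variance_error")
})
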