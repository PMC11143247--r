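# Brute-force pixel-loop oracle for integrated intensity.
loop_sum <- function(image, cy, cx, h) {
  s <- if (is.integer(image)) 0L else 0
  for (y in (cy - h):(cy + h)) for (x in (cx - h):(cx + h)) {
    if (y >= 1 && y <= nrow(image) && x >= 1 && x <= ncol(image))
      s <- s + image[y, x]
  }
  s
}

test_that("integrated intensity equals a brute-force pixel loop on random ROIs", {
  set.seed(101)
  img <- matrix(sample(0:255, 120 * 150, replace = TRUE), 120, 150)
  for (k in 1:100) {
    cy <- sample(1:120, 1); cx <- sample(1:150, 1); h <- sample(2:9, 1)
    m <- measure_colony(img, c(cy - 1, cx - 1), h)   # 0-based node coords
    expect_identical(m$sum, loop_sum(img, cy, cx, h))
  }
})

test_that("the ROI statistic is the sum of pixel values, not their mean", {
  img <- matrix(rep(c(0, 2, 4), length.out = 11 * 11), 11, 11)
  m <- measure_colony(img, c(5, 5), 5)
  expect_identical(m$sum, sum(img))
  expect_false(isTRUE(all.equal(m$sum, mean(img))))
  # constant ROI: sum scales with area
  ones <- matrix(1, 21, 21)
  expect_identical(measure_colony(ones, c(10, 10), 4)$sum, 81)
})

test_that("ROIs running off the image are clipped and flagged", {
  img <- matrix(1, 20, 20)
  m <- measure_colony(img, c(0, 0), 3)
  expect_true(m$clipped)
  expect_identical(m$sum, 16)          # 4 x 4 pixels survive the clip
  expect_identical(m$area, 16L)
  inside <- measure_colony(img, c(10, 10), 3)
  expect_false(inside$clipped)
  expect_identical(inside$area, 49L)
})

test_that("background subtraction is the elementwise clipped difference", {
  expect_equal(subtract_background(matrix(10, 3, 3), matrix(10, 3, 3)),
               matrix(0, 3, 3))
  expect_equal(subtract_background(matrix(5, 3, 3), matrix(10, 3, 3)),
               matrix(0, 3, 3))
  set.seed(7)
  a <- matrix(runif(400, 0, 100), 20, 20)
  b <- matrix(runif(400, 0, 100), 20, 20)
  want <- matrix(0, 20, 20)
  for (y in 1:20) for (x in 1:20) want[y, x] <- max(a[y, x] - b[y, x], 0)
  expect_equal(subtract_background(a, b), want)
  expect_error(subtract_background(a, matrix(0, 5, 5)), "shapes differ")
})

test_that("background estimation recovers flat and planar surfaces", {
  expect_equal(estimate_background(matrix(10, 60, 60), 15),
               matrix(10, 60, 60), tolerance = 1e-9)
  expect_equal(estimate_background(matrix(0, 60, 60), 15),
               matrix(0, 60, 60))
  expect_error(estimate_background(matrix(1, 10, 10), 31), "exceeds image")
  # planar background + colonies: recovered within 2% on colony-free pixels
  spec <- spec_small()
  map <- generate_plate_map(spec, 70L, 10L, seed = 9)
  truth <- screen_truth(map, n_high = 0, n_low = 0, n_artifact = 0,
                        noise_cv = 0, strain_cv = 0, read_noise_sd = 0,
                        seed = 9)
  pair <- simulate_colony_plates(map, spec, truth, seed = 9,
                                 background_tilt = c(0.2, 0.1))
  img <- pair$biomass_image
  bg <- estimate_background(img, 37)
  plane <- truth$background_level *
    (1 + 0.2 * (row(img) - 1) / (nrow(img) - 1) +
         0.1 * (col(img) - 1) / (ncol(img) - 1))
  margin <- rbind(cbind(5L, seq_len(ncol(img))), cbind(seq_len(nrow(img)), 5L))
  expect_lt(max(abs(bg[margin] - plane[margin]) / plane[margin]), 0.02)
})

test_that("grid detection recovers planted pitch and translation", {
  spec <- spec_small()
  map <- generate_plate_map(spec, 70L, 10L, seed = 10)
  truth <- screen_truth(map, n_high = 0, n_low = 0, n_artifact = 0, seed = 10)
  pair <- simulate_colony_plates(map, spec, truth, seed = 10,
                                 offset_px = c(5, 7))
  g <- detect_grid(pair$biomass_image, spec)
  expect_lt(abs(g$pitch[["row"]] - spec$pitch_px), 0.2)
  expect_lt(abs(g$pitch[["col"]] - spec$pitch_px), 0.2)
  expect_lt(abs(g$origin[["row"]] - (spec$margin_px + 5)), 1)
  expect_lt(abs(g$origin[["col"]] - (spec$margin_px + 7)), 1)
  expect_length(g$row_centers, spec$n_rows)
  expect_length(g$col_centers, spec$n_cols)
  # an essentially colony-free image must fail with a diagnostic
  flat <- matrix(200 + rnorm(spec$image_height * spec$image_width, 0, 2),
                 spec$image_height, spec$image_width)
  expect_error(detect_grid(flat, spec), "grid detection failed")
})

test_that("plate quantification is linear and robust to sub-pitch translation", {
  spec <- spec_small()
  map <- generate_plate_map(spec, 70L, 10L, seed = 11)
  truth <- screen_truth(map, n_high = 0, n_low = 0, n_artifact = 0,
                        noise_cv = 0, strain_cv = 0, read_noise_sd = 0,
                        seed = 11)
  pair <- simulate_colony_plates(map, spec, truth, seed = 11)
  m1 <- quantify_plate(pair, map, spec)
  # linearity: scaling the images scales every background-subtracted sum
  pair2 <- pair
  pair2$biomass_image <- pair$biomass_image * 2
  pair2$fluor_image <- pair$fluor_image * 2
  m2 <- quantify_plate(pair2, map, spec)
  ne <- m1$strain_id != "EMPTY"
  expect_equal(m2$biomass_sum[ne], 2 * m1$biomass_sum[ne], tolerance = 0.01)
  # translation by < pitch/3 changes colony sums by < 2%
  pair3 <- simulate_colony_plates(map, spec, truth, seed = 11,
                                  offset_px = c(4, 5))
  m3 <- quantify_plate(pair3, map, spec)
  expect_lt(stats::median(abs(m3$biomass_sum[ne] / m1$biomass_sum[ne] - 1)),
            0.02)
  # EMPTY positions are flagged and essentially zero after subtraction
  expect_true(all(grepl("EMPTY", m1$flags[!ne])))
  expect_lt(stats::median(m1$fluor_sum[!ne]),
            0.05 * stats::median(m1$fluor_sum[ne]))
})
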