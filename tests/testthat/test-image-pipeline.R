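test_that("to_grey follows the luma weights and bit-depth normalization", {
  u <- matrix(0.4, 4, 4)
  expect_identical(to_grey(u), u)
  white <- array(1, c(2, 2, 3))
  expect_equal(to_grey(white), matrix(1, 2, 2), tolerance = 1e-12)
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 1
  expect_equal(to_grey(red), matrix(0.299, 2, 2))
  red8 <- array(0L, c(2, 2, 3)); red8[, , 1] <- 255L
  expect_equal(to_grey(red8), matrix(0.299, 2, 2))
  grey16 <- matrix(32768, 2, 2)
  expect_equal(to_grey(grey16), matrix(32768 / 65535, 2, 2))
  expect_error(to_grey(array(0, c(2, 2, 4))), "3 channels")
})

test_that("binarization uses a closed interval shared across frames", {
  f1 <- matrix(c(0.2, 0.5, 0.7, 1), 2, 2)
  f2 <- matrix(c(0.5, 0.5, 0.69, 0.71), 2, 2)
  ser <- image_series(list(f1, f2), c(0, 24))
  bin <- binarize_series(ser, threshold_range(0.5, 0.7))
  expect_identical(bin$white_counts, c(2L, 3L))  # boundaries included
  # full interval turns every pixel white
  full <- binarize_series(ser, threshold_range(0, 1))
  expect_identical(full$white_counts, c(4L, 4L))
  # [1, 1] with max grey < 1
  dim1 <- image_series(list(matrix(0.99, 3, 3)), 0)
  expect_identical(binarize_series(dim1, threshold_range(1, 1))$white_counts, 0L)
})

test_that("white counts respect the well mask", {
  f <- matrix(1, 4, 4)
  well <- matrix(FALSE, 4, 4); well[1:2, 1:2] <- TRUE
  ser <- image_series(list(f), 0, well = well)
  bin <- binarize_series(ser, threshold_range(0, 1))
  expect_identical(bin$white_counts, 4L)
  expect_false(any(bin$masks[[1]][!well]))
})

test_that("widening the threshold interval never decreases white counts", {
  ser <- simulate_image_series(tiny_scene(seed = 8, clean = FALSE),
                               logistic_trajectory(hours14d, 150))
  for (seed in 1:10) {
    b <- withr::with_seed(seed, sort(runif(2)))
    wider <- c(max(0, b[1] - 0.1), min(1, b[2] + 0.1))
    wp_narrow <- binarize_series(ser, threshold_range(b[1], b[2]))$white_counts
    wp_wide <- binarize_series(ser, threshold_range(wider[1], wider[2]))$white_counts
    expect_true(all(wp_wide >= wp_narrow))
  }
})

test_that("masks do not depend on frame processing order", {
  ser <- simulate_image_series(tiny_scene(seed = 9, clean = FALSE),
                               logistic_trajectory(hours14d, 150))
  thr <- threshold_range(0.6, 1)
  bin <- binarize_series(ser, thr)
  perm <- c(8, 3, 15, 1, 11, 2, 14, 5, 9, 4, 13, 6, 10, 7, 12)
  ser_perm <- ser
  ser_perm$frames <- ser$frames[perm]
  ser_perm$times <- seq_along(perm)  # placeholder increasing times
  ser_perm <- image_series(ser_perm$frames, ser_perm$times, well = ser$well)
  bin_perm <- binarize_series(ser_perm, thr)
  expect_identical(bin_perm$masks, bin$masks[perm])
})

test_that("suggested threshold separates a bimodal frame and fails on a constant one", {
  half <- matrix(0.2, 32, 32); half[, 17:32] <- 0.9
  ser <- image_series(list(half), 0)
  thr <- suggest_threshold(ser)
  expect_gt(thr$low, 0.2); expect_lt(thr$low, 0.9)
  expect_identical(thr$high, 1)
  flat <- image_series(list(matrix(0.5, 16, 16)), 0)
  expect_error(suggest_threshold(flat), "degenerate histogram")
})

test_that("threshold suggested at t0 rejects mycelium appearing later", {
  sc <- tiny_scene(seed = 10, clean = FALSE, grain_intensity = 0.9,
                   mycelium_intensity = 0.55, mycelium_growth_rate = 0.004,
                   noise_sd = 0.02, illumination_gradient = 0.05)
  ser <- simulate_image_series(sc, truth_trajectory(hours14d, rep(1, 15)))
  thr <- suggest_threshold(ser)
  bin <- binarize_series(ser, thr)
  last <- length(ser$frames)
  myc_pixels <- ser$well & !ser$truth_masks[[last]]
  # mycelium/background misclassified white in the final (worst) frame
  false_white <- sum(bin$masks[[last]] & myc_pixels)
  myc_count <- sum(ser$frames[[last]][myc_pixels] > 0.4)  # rendered mycelium
  expect_gt(myc_count, 500)          # mycelium is really there
  expect_lt(false_white / myc_count, 0.05)
  # and the grains themselves are still (mostly) captured
  expect_gt(sum(bin$masks[[1]]) / ser$truth$grain_px[1], 0.9)
})

test_that("degradation curve is 100 at t0 and proportional to counts", {
  mk <- function(counts) {
    structure(list(masks = NULL, white_counts = counts,
                   times = seq(0, by = 24, length.out = length(counts)),
                   sample_id = "s", blend_label = "b"),
              class = "binary_series")
  }
  expect_equal(degradation_curve(mk(c(4000L, 4000L)))$values, c(100, 100))
  expect_equal(degradation_curve(mk(c(4000L, 1000L)))$values, c(100, 25))
  expect_equal(degradation_curve(mk(c(4000L, 0L)))$values, c(100, 0))
  expect_error(degradation_curve(mk(c(0L, 10L))), "empty reference frame")
})

test_that("white counts match an explicit per-pixel loop", {
  for (seed in 1:6) {
    f <- withr::with_seed(seed, matrix(runif(32 * 32), 32, 32))
    b <- withr::with_seed(seed + 100, sort(runif(2)))
    ser <- image_series(list(f), 0)
    bin <- binarize_series(ser, threshold_range(b[1], b[2]))
    expect_identical(bin$white_counts, loop_count(f, b[1], b[2]))
  }
})

test_that("frames of differing shapes are rejected", {
  expect_error(image_series(list(matrix(0, 4, 4), matrix(0, 5, 5)), c(0, 1)),
               "same shape")
  expect_error(image_series(list(matrix(0, 4, 4)), c(0, 1)), "one time per frame")
  expect_error(threshold_range(0.5, 1.2), "0 <= low <= high <= 1")
  expect_error(threshold_range(-0.1, 0.5), "0 <= low <= high <= 1")
  expect_error(threshold_range(0.8, 0.4), "0 <= low <= high <= 1")
})

test_that("PNG round trip preserves a series to 8-bit precision", {
  dir <- withr::local_tempdir()
  ser <- simulate_image_series(tiny_scene(seed = 13, clean = FALSE),
                               logistic_trajectory(c(0, 100, 200), 150),
                               sample_id = "RT1", blend_label = "BDF20")
  man <- write_image_series(ser, dir)
  back <- read_image_series(man)
  expect_identical(back$sample_id, "RT1")
  expect_identical(back$times, c(0, 100, 200))
  for (i in 1:3)
    expect_lt(max(abs(back$frames[[i]] - ser$frames[[i]])), 1 / 255)
  # truth table written alongside
  expect_true(file.exists(file.path(dir, "RT1_truth.csv")))
})
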