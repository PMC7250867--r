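test_that("an 8200 ms segment at 600 Hz becomes 821 samples at 100 Hz", {
  fs <- 600
  times <- seq(-200, 8000, by = 1000 / fs)
  set.seed(41)
  dat <- array(rnorm(2 * 3 * length(times)), c(2, 3, length(times)))
  ep <- epoch_set(dat, times, fs, tibble::tibble(id = 1:2))
  pp <- preprocess(ep, new_rate = 100, highpass = 0.5)
  expect_equal(dim(pp$data), c(2, 3, 821))
  expect_equal(pp$sampling_rate, 100)
  expect_equal(diff(pp$times_ms)[1], 10)
})

test_that("high-pass filtering removes drift and passes the signal band", {
  fs <- 600
  times <- seq(-200, 8000, by = 1000 / fs)
  tt <- times / 1000
  dat <- array(0, c(1, 3, length(times)))
  dat[, 1, ] <- 5                          # DC
  dat[, 2, ] <- 3 * sin(2 * pi * 0.05 * tt) # slow drift, deep in the stop band
  dat[, 3, ] <- 3 * sin(2 * pi * 10 * tt)   # pass band
  ep <- epoch_set(dat, times, fs, tibble::tibble(id = 1))
  pp <- preprocess(ep, new_rate = 100, highpass = 0.5)
  mid <- 200:620                            # avoid filtfilt edge transients
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(pp$data[1, 1, mid]) / 5, 0.02)
  expect_lt(rms(pp$data[1, 2, mid]) / (3 / sqrt(2)), 0.15)
  expect_gt(rms(pp$data[1, 3, mid]) / (3 / sqrt(2)), 0.95)
})

test_that("cropping realigns the time axis and rejects short segments", {
  st <- test_epoch_study()
  ep <- st$epochs
  post <- crop_epochs(ep, 1500, 850, alignment = "post_onset")
  expect_equal(post$times_ms[1], 0)
  expect_equal(max(post$times_ms), 850)
  expect_equal(post$alignment, "post_onset")
  expect_error(crop_epochs(ep, 2800, 850), "too short")
  expect_error(preprocess(ep, new_rate = 70), "divide")
})

test_that("sliding features are clipped boxcar means, z-scored across trials", {
  # fixed toy array: 2 trials x 1 channel x 5 samples at 100 Hz
  dat <- array(0, c(2, 1, 5))
  dat[1, 1, ] <- c(1, 2, 3, 4, 5)
  dat[2, 1, ] <- c(5, 4, 3, 2, 1)
  ep <- epoch_set(dat, seq(0, 40, by = 10), 100, tibble::tibble(id = 1:2))
  raw <- sliding_features(ep, window_ms = 20, step_ms = 10,
                          standardize = FALSE)
  # right-aligned 20 ms window at t = 20 averages samples at 10 and 20 ms
  expect_equal(raw$x[[3]][, 1], c(mean(c(2, 3)), mean(c(4, 3))))
  # at t = 0 the window is clipped to the first sample
  expect_equal(raw$x[[1]][, 1], c(1, 5))

  st <- test_epoch_study()
  feats <- sliding_features(crop_epochs(st$epochs, 0, 850), step_ms = 100)
  for (k in c(1, 5, 9)) {
    expect_equal(colMeans(feats$x[[k]]), rep(0, ncol(feats$x[[k]])),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(apply(feats$x[[k]], 2, sd), rep(1, ncol(feats$x[[k]])),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # constant data standardizes to all zeros
  cst <- epoch_set(array(7, c(3, 2, 5)), seq(0, 40, 10), 100,
                   tibble::tibble(id = 1:3))
  fz <- sliding_features(cst, window_ms = 20, step_ms = 10)
  expect_true(all(vapply(fz$x, function(m) all(m == 0), TRUE)))
  expect_error(sliding_features(st$epochs, step_ms = 0), "positive")
})

test_that("epoch containers validate geometry and default dimensions hold", {
  expect_error(epoch_set(array(0, c(2, 3, 4)), c(0, 10, 20), 100,
                         tibble::tibble(id = 1:2)), "sample dimension")
  expect_error(epoch_set(array(0, c(2, 3, 4)), c(0, 10, 20, 31), 100,
                         tibble::tibble(id = 1:2)), "1/sampling_rate")
  expect_error(epoch_set(array(0, c(2, 3, 4)), seq(0, 30, 10), 100,
                         tibble::tibble(id = 1:3)), "one row per epoch")
  # default geometry: 273 channels x 821 samples
  tr <- dplyr::slice(test_epoch_study()$epochs$trials, 1:2)
  sim <- simulate_epochs(tr, epoch_ground_truth(noise_scale = 0), seed = 5)
  expect_equal(dim(sim$epochs$data), c(2, 273, 821))
  expect_error(simulate_epochs(dplyr::select(tr, -direction),
                               epoch_ground_truth(), seed = 1), "lacks")
})
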