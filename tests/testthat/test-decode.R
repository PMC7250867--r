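# build a dv_features object directly from a list of matrices
as_features <- function(mats, trials = NULL) {
  if (is.null(trials)) trials <- tibble::tibble(id = seq_len(nrow(mats[[1]])))
  structure(list(x = mats, times_ms = seq(0, by = 10,
                                          length.out = length(mats)),
                 channels = paste0("ch", seq_len(ncol(mats[[1]]))),
                 trials = trials),
            class = "dv_features")
}

test_that("separable classes are decoded perfectly; shuffled labels at chance", {
  set.seed(51)
  n <- 200
  y <- rep(c("left", "right"), each = n / 2)
  X <- matrix(rnorm(n * 6, sd = 0.2), n, 6)
  X[y == "right", 1] <- X[y == "right", 1] + 5   # zero overlap on channel 1
  X[y == "left", 1] <- X[y == "left", 1] - 5
  f <- as_features(list(X))
  ens <- train_decoders(f, y, scheme = "loo")
  dv <- decode_dv(ens, f)
  acc <- mean((dv$dv[, 1] > 0) == (y == "right"))
  expect_equal(acc, 1)

  y_perm <- sample(y)
  ens_p <- train_decoders(f, y_perm, scheme = "loo")
  acc_p <- mean((decode_dv(ens_p, f)$dv[, 1] > 0) == (y_perm == "right"))
  expect_lt(abs(acc_p - 0.5), 3 * sqrt(0.25 / n))
  expect_error(train_decoders(f, rep("left", n)), "both classes")
})

test_that("decision values are signed hyperplane distances, linear in the input", {
  set.seed(52)
  n <- 80
  y <- rep(c("left", "right"), each = n / 2)
  X <- matrix(rnorm(n * 4, sd = 0.5), n, 4)
  shift <- ifelse(y == "right", 2, -2)
  X[, 2] <- X[, 2] + shift
  f <- as_features(list(X))
  ens <- train_decoders(f, y, scheme = "full")
  r <- ens$rules[[1]]
  expect_equal(sqrt(sum(r$w^2)), 1, tolerance = 1e-9)  # unit normal
  # a point on the hyperplane scores 0 (solve for the channel-2 coordinate)
  x0 <- rep(0, 4)
  x0s <- (x0 - r$center) / ifelse(r$scale > 0, r$scale, 1)
  x0s[2] <- -(sum(x0s[-2] * r$w[-2]) + r$b) / r$w[2]
  expect_equal(sum(x0s * r$w) + r$b, 0, tolerance = 1e-12)
  # doubling the (standardized) features doubles the distance up to the offset
  Xs <- postbias:::.zscore_cols(X, r$center, r$scale)
  d1 <- Xs %*% r$w
  d2 <- (2 * Xs) %*% r$w
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # positive scores predict rightward
  dv <- decode_dv(ens, f)
  expect_gt(mean(sign(dv$dv[y == "right", 1])), 0.9)
  expect_lt(mean(sign(dv$dv[y == "left", 1])), -0.9)
  expect_error(decode_dv(ens, as_features(list(X, X))), "timepoint counts")
})

test_that("trend fitting is exact ordinary least squares per trial", {
  tms <- seq(0, 500, by = 10)
  tt <- tms / 1000
  dv1 <- 0.2 + 1.5 * tt
  dv2 <- rep(0.7, length(tt))
  series <- structure(list(dv = rbind(dv1, dv2), times_ms = tms,
                           trials = tibble::tibble(id = 1:2)),
                      class = "dv_series")
  tr <- dv_trend(series)
  expect_equal(tr$intercept, c(0.2, 0.7), tolerance = 1e-10)
  expect_equal(tr$slope, c(1.5, 0), tolerance = 1e-10)

  set.seed(53)
  dvr <- matrix(rnorm(100 * length(tt)), 100)
  sr <- structure(list(dv = dvr, times_ms = tms,
                       trials = tibble::tibble(id = 1:100)),
                  class = "dv_series")
  got <- dv_trend(sr)
  ref <- t(apply(dvr, 1, function(yy) coef(lm(yy ~ tt))))
  expect_equal(got$intercept, unname(ref[, 1]), tolerance = 1e-10)
  expect_equal(got$slope, unname(ref[, 2]), tolerance = 1e-10)
  expect_error(dv_trend(sr, window_ms = c(0, 15)), "at least 3")
})

test_that("unsigning flips leftward trials only and is an involution", {
  tr <- tibble::tibble(direction = c("right", "left"),
                       intercept = c(0.5, 0.2), slope = c(1, -0.3))
  u <- unsign(tr)
  expect_equal(u$slope, c(1, 0.3))
  expect_equal(u$intercept, c(0.5, -0.2))
  expect_equal(unsign(u), tr)
  expect_error(unsign(dplyr::mutate(tr, direction = c("up", "down"))),
               "left")
})

test_that("peak decodability maximizes the diagonal with earliest-tie rule", {
  mk_tg <- function(diagvals) {
    k <- length(diagvals)
    m <- matrix(0.5, k, k); diag(m) <- diagvals
    structure(list(auc = array(rep(m, 4), c(k, k, 4)), auc_overall = m,
                   times_pre = seq(0, by = 10, length.out = k),
                   times_post = seq(0, by = 10, length.out = k)),
              class = "tg_matrix")
  }
  expect_equal(as.numeric(peak_decodability(mk_tg(c(0.5, 0.6, 0.9, 0.7)))), 20)
  expect_equal(attr(peak_decodability(mk_tg(c(0.5, 0.8, 0.8, 0.6))), "index"), 2)
  expect_warning(pk <- peak_decodability(mk_tg(rep(0.6, 4))), "flat")
  expect_equal(as.numeric(pk), 0)
  # agrees with an exhaustive scan on random diagonals
  set.seed(54)
  for (i in 1:20) {
    d <- runif(15, 0.4, 1)
    expect_equal(attr(peak_decodability(mk_tg(d)), "index"),
                 which(d == max(d))[1])
  }
})
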