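make_labeled_features <- function(n, tps, signal, seed = 61) {
  # signal: function(timepoint index) -> per-trial mean shift on channel 1
  set.seed(seed)
  y <- rep(c("left", "right"), length.out = n)
  conf <- rep(c(0, 1), each = n / 2)
  com <- rep(c(0, 1, 0, 0), length.out = n)
  sgn <- ifelse(y == "right", 1, -1)
  mats <- lapply(seq_len(tps), function(k) {
    X <- matrix(rnorm(n * 5, sd = 0.3), n, 5)
    X[, 1] <- X[, 1] + sgn * signal(k)
    X
  })
  trials <- tibble::tibble(initial_choice = y, initial_confidence = conf,
                           change_of_mind = com)
  structure(list(x = mats, times_ms = seq(0, by = 10, length.out = tps),
                 channels = paste0("ch", 1:5), trials = trials),
            class = "dv_features")
}

test_that("temporal generalization is near-ceiling for separable data and chance for shuffled labels", {
  pre <- make_labeled_features(64, 4, function(k) 3)
  post <- make_labeled_features(64, 4, function(k) 3, seed = 62)
  post$trials <- pre$trials
  tg <- temporal_generalization(pre, post, folds = 4, reps = 2, seed = 63)
  expect_true(all(tg$auc > 0.95, na.rm = TRUE))
  expect_equal(dim(tg$auc), c(4, 4, 4))

  set.seed(64)
  shuf <- pre
  shuf$trials$initial_choice <- sample(shuf$trials$initial_choice)
  post_s <- post; post_s$trials <- shuf$trials
  tg0 <- temporal_generalization(shuf, post_s, folds = 4, reps = 4, seed = 65)
  # pooled-trial AUC under the null: within 3 SEs of 0.5
  se <- sqrt(1 / 12 * (1 / 32 + 1 / 32))   # normal approx of the null AUC SD
  expect_lt(max(abs(tg0$auc_overall - 0.5)), 3.5 * se)
})

test_that("a pattern present early in one phase and late in the other shows up off-diagonal", {
  pre <- make_labeled_features(64, 6, function(k) if (k <= 2) 3 else 0)
  post <- make_labeled_features(64, 6, function(k) if (k >= 5) 3 else 0,
                                seed = 66)
  post$trials <- pre$trials
  tg <- temporal_generalization(pre, post, folds = 4, reps = 2, seed = 67)
  hot <- tg$auc_overall[1, 6]    # train early, test late
  cold <- tg$auc_overall[5, 2]   # train late, test early
  diag_corner <- tg$auc_overall[6, 6]
  expect_gt(hot, 0.9)
  expect_lt(cold, 0.7)
  expect_lt(diag_corner, 0.7)
})

test_that("stratification errors name cells that are too small", {
  pre <- make_labeled_features(64, 2, function(k) 1)
  pre$trials$change_of_mind[pre$trials$change_of_mind == 1][-1] <- 0
  post <- pre
  expect_error(temporal_generalization(pre, post, folds = 4, reps = 1),
               "low_change|high_change")
})

test_that("AUC is rank-based: invariant under monotone transforms and matches pROC", {
  set.seed(68)
  for (i in 1:10) {
    sc <- rnorm(60)
    lab <- rbinom(60, 1, 0.5) == 1
    if (length(unique(lab)) < 2) next
    a0 <- postbias:::.auc(sc, lab)
    expect_equal(postbias:::.auc(exp(sc), lab), a0)
    expect_equal(postbias:::.auc(qlogis(plogis(sc)) * 3 + 2, lab), a0,
                 tolerance = 1e-12)
    expect_equal(a0, as.numeric(pROC::auc(pROC::roc(
      response = lab, predictor = sc, quiet = TRUE, direction = "<"))))
  }
})

test_that("sensor contributions rank signal-carrying channels at the top", {
  set.seed(69)
  n <- 80; C <- 40
  y <- rep(c("left", "right"), each = n / 2)
  X <- matrix(rnorm(n * C, sd = 1), n, C)
  sig_ch <- c(3, 11, 22, 30, 37)
  X[, sig_ch] <- X[, sig_ch] + ifelse(y == "right", 1.5, -1.5)
  sc <- sensor_contributions(X, y, subset_size = 10, reps = 400, seed = 70)
  top_decile <- rank(-sc$contribution) <= 4
  expect_gte(sum(which(top_decile) %in% sig_ch), 3)
  expect_true(all(sc$n_subsets > 0))
  # pure noise: contribution spread consistent with chance
  X0 <- matrix(rnorm(n * C), n, C)
  sc0 <- sensor_contributions(X0, y, subset_size = 10, reps = 400, seed = 71)
  expect_lt(diff(range(sc0$contribution)), 0.25)
  expect_lt(mean(sc0$contribution), 0.62)
  # reproducible under a seed; warns when coverage is impossible
  sc0b <- sensor_contributions(X0, y, subset_size = 10, reps = 400, seed = 71)
  expect_identical(sc0, sc0b)
  expect_warning(sensor_contributions(X0, y, subset_size = 10, reps = 2,
                                      seed = 72), "no subset")
})
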