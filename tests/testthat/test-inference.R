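make_mixed_data <- function(n_subj = 10, n_trial = 100, beta = 0.5,
                            subj_sd = 0.5, seed = 81) {
  set.seed(seed)
  n <- n_subj * n_trial
  tibble::tibble(
    subject_id = rep(sprintf("S%02d", seq_len(n_subj)), each = n_trial),
    x = rnorm(n),
    y = beta * x + rep(rnorm(n_subj, 0, subj_sd), each = n_trial) + rnorm(n)
  )
}

test_that("hierarchical regression recovers fixed effects and flags collinearity", {
  d <- make_mixed_data(25, 300)
  h <- hier_regress(d, "y", "x")
  td <- tidy(h)
  expect_lt(abs(td$estimate[td$term == "x"] - 0.5), 0.1)
  expect_equal(td$df[1], nrow(d) - 2)    # residual degrees of freedom
  d$ones <- d$x
  expect_error(hier_regress(d, "y", c("x", "ones")), "collinear")
  expect_error(hier_regress(d, "y", "missing_col"), "missing columns")
  expect_error(hier_regress(dplyr::filter(d, subject_id == "S01"), "y", "x"),
               "2 subjects")
})

test_that("intercept-only fit returns the grand mean and binary outcomes use logistic", {
  d <- make_mixed_data(8, 50, beta = 0)
  d$const <- 0  # placeholder: fit y on intercept only via a zero predictor
  h <- hier_regress(d, "y", "x")
  icpt <- tidy(h)$estimate[1]
  expect_lt(abs(icpt - mean(d$y)), 0.05)
  d$yb <- as.integer(d$y > 0)
  hb <- hier_regress(d, "yb", "x")
  expect_equal(hb$family, "binomial")
  expect_true(all(is.infinite(tidy(hb)$df)))
})

test_that("fixed-effect tests hold their nominal type-I error rate", {
  rejections <- vapply(1:300, function(i) {
    d <- make_mixed_data(8, 40, beta = 0, seed = 1000 + i)
    td <- tidy(hier_regress(d, "y", "x"))
    td$p.value[td$term == "x"] < 0.05
  }, logical(1))
  rate <- mean(rejections)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 300)
  expect_gte(rate, ci[1] - 1e-9)
  expect_lte(rate, ci[2] + 1e-9)
})

test_that("slope effects recover injected decision x confidence structure", {
  set.seed(83)
  n_subj <- 8; n_tr <- 80
  mk <- function(inter) {
    purrr::map(seq_len(n_subj), function(s) {
      d <- sample(c(-1, 1), n_tr, replace = TRUE)
      cf <- sample(c(-1, 1), n_tr, replace = TRUE)
      tibble::tibble(
        subject_id = sprintf("S%02d", s),
        initial_decision = d, confidence = cf,
        slope = 1 + 0.3 * d + inter * d * cf + rnorm(n_tr, 0, 0.5) +
          rnorm(1, 0, 0.2),
        intercept = 0.2 + rnorm(n_tr, 0, 0.3))
    }) |> dplyr::bind_rows()
  }
  eff <- slope_effects(mk(0.4))
  inter_row <- dplyr::filter(eff, outcome == "slope",
                             term == "decision_x_confidence")
  expect_lt(abs(inter_row$estimate - 0.4), 0.1)
  expect_lt(inter_row$p.value, 0.001)
  # no injected modulation: interaction t stays in the null range
  eff0 <- slope_effects(mk(0))
  t0 <- dplyr::filter(eff0, outcome == "slope",
                      term == "decision_x_confidence")$statistic
  expect_lt(abs(t0), 3.5)
  expect_error(slope_effects(dplyr::filter(mk(0), confidence == 1)),
               "cells")
})

make_mediation_data <- function(n_subj = 6, n_trial = 120, a = 1, b = 1.5,
                                direct = 0, seed = 84) {
  set.seed(seed)
  purrr::map(seq_len(n_subj), function(s) {
    x <- sample(1:2, n_trial, replace = TRUE)
    m <- a * x + rnorm(n_trial, 0, 0.7) + rnorm(1, 0, 0.3)
    eta <- -1 + b * (m - 1.5 * a) + direct * x
    tibble::tibble(subject_id = sprintf("S%02d", s), x = x, m = m,
                   y = rbinom(n_trial, 1, plogis(eta)))
  }) |> dplyr::bind_rows()
}

test_that("mediation detects a pure indirect path and its absence", {
  d <- make_mediation_data()
  med <- mediation(d, "x", "m", "y", n_boot = 1500, seed = 85)
  td <- tidy(med)
  ab <- dplyr::filter(td, path == "ab")
  cp <- dplyr::filter(td, path == "cprime")
  expect_gt(ab$conf.low, 0)              # mediated effect present
  expect_lt(cp$conf.low, 0); expect_gt(cp$conf.high, 0)  # no direct path
  expect_true(all(td$conf.low <= td$estimate + 1e-8 &
                    td$estimate <= td$conf.high + 1e-8))
  # swapping predictor and mediator abolishes the mediated effect
  swapped <- mediation(d, "m", "x", "y", n_boot = 1500, seed = 86)
  ab_s <- dplyr::filter(tidy(swapped), path == "ab")
  expect_gt(ab_s$p.value, ab$p.value)
  expect_true(ab_s$conf.low <= 0 || abs(ab_s$estimate) < abs(ab$estimate) / 3)
})

test_that("mediation validates inputs", {
  d <- make_mediation_data(n_subj = 3, n_trial = 40)
  expect_warning(mediation(d, "x", "m", "y", n_boot = 500, seed = 1),
                 "n_boot")
  d$m2 <- 1
  expect_error(mediation(d, "x", "m2", "y", n_boot = 1500), "variance")
  d$ybad <- d$y + 0.5
  expect_error(mediation(d, "x", "m", "ybad", n_boot = 1500), "binary")
})
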