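test_that("the ten-model family has the printed dependency structure", {
  m1 <- build_model(1)
  expect_equal(m1$z_terms, character(0))
  expect_equal(m1$v_terms, "post_evidence_strength")
  expect_equal(m1$a_terms, "confidence")

  m4 <- build_model(4)
  expect_equal(m4$z_terms, "confidence")
  expect_setequal(m4$v_terms, c("post_evidence_strength", "confidence"))

  m7 <- build_model(7)
  expect_equal(m7$z_terms, "initial_decision")
  expect_setequal(m7$v_terms, c("post_evidence_strength", "initial_decision"))

  m10 <- build_model(10)
  expect_setequal(m10$z_terms,
                  c("confidence", "initial_decision", "interaction"))
  expect_setequal(m10$v_terms,
                  c("post_evidence_strength", "confidence",
                    "initial_decision", "interaction"))

  for (id in 1:10) {
    m <- build_model(id)
    expect_equal(m$a_terms, "confidence")             # every model
    expect_true("post_evidence_strength" %in% m$v_terms)
  }
  # within-family variants: starting point only, drift only, both
  expect_equal(build_model(2)$v_terms, "post_evidence_strength")
  expect_equal(build_model(3)$z_terms, character(0))
  expect_equal(build_model(5)$z_terms, "initial_decision")
  expect_equal(build_model(6)$v_terms,
               c("post_evidence_strength", "initial_decision"))
  expect_error(build_model(11), "1..10")
  expect_error(build_model(0), "1..10")
})

test_that("trial log-likelihood reduces correctly at the mixture extremes", {
  p <- wiener_params(v = 1, a = 1.8, z = 0.55, t0 = 0.25)
  rt <- c(0.5, 0.8, 1.4); up <- c(1, 1, 0)
  pure <- sum(log(vapply(seq_along(rt), function(i)
    wiener_fpt_density(rt[i], p, if (up[i] == 1) "upper" else "lower"),
    numeric(1))))
  expect_equal(trial_loglik(rt, up, p, outlier_probability = 0), pure,
               tolerance = 1e-10)
  # pure contaminant: constant in the diffusion parameters
  l1 <- trial_loglik(rt, up, p, outlier_probability = 1, rt_range = 2)
  p2 <- wiener_params(v = -2, a = 3, z = 0.2, t0 = 0.1)
  l2 <- trial_loglik(rt, up, p2, outlier_probability = 1, rt_range = 2)
  expect_equal(l1, l2)
  expect_equal(l1, 3 * log(1 / (2 * 2)))
})

test_that("mixture log-likelihood matches an independent R-side evaluation", {
  set.seed(31)
  p <- wiener_params(v = 0.8, a = 2, z = 0.45, t0 = 0.2)
  rt <- runif(20, 0.3, 2); up <- rbinom(20, 1, 0.7)
  r_mix <- sum(log(vapply(seq_along(rt), function(i) {
    f <- r_wiener_density(rt[i], p$a, p$v, p$z, p$t0,
                          if (up[i] == 1) "upper" else "lower")
    0.95 * f + 0.05 / (2 * diff(range(rt)))
  }, numeric(1))))
  expect_equal(trial_loglik(rt, up, p, outlier_probability = 0.05), r_mix,
               tolerance = 1e-6)
})

test_that("maximum likelihood on simulated data recovers the generating parameters", {
  truth <- wiener_params(v = 1.2, a = 1.8, z = 0.4, t0 = 0.3)
  s <- simulate_wiener(truth, 5000, dt = 1e-3, seed = 33)
  nll <- function(par) {
    if (par[2] <= 0 || par[3] <= 0.02 || par[3] >= 0.98 || par[4] < 0 ||
        par[4] >= min(s$rt)) return(1e10)
    -trial_loglik(s$rt, s$upper,
                  wiener_params(par[1], par[2], par[3], par[4]),
                  outlier_probability = 0)
  }
  fit <- optim(c(1, 1.5, 0.5, 0.2), nll)
  expect_lt(abs(fit$par[1] - truth$v) / truth$v, 0.10)
  expect_lt(abs(fit$par[2] - truth$a) / truth$a, 0.10)
  expect_lt(abs(fit$par[3] - truth$z) / truth$z, 0.10)
  expect_lt(abs(fit$par[4] - truth$t0) / truth$t0, 0.10)
})
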