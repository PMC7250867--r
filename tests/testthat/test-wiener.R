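test_that("first-passage density is defective with the right mass at each bound", {
  grid <- expand.grid(v = c(-1, 0, 1.5), a = c(1, 2), z = c(0.3, 0.5, 0.7))
  for (i in seq_len(nrow(grid))) {
    p <- wiener_params(v = grid$v[i], a = grid$a[i], z = grid$z[i], t0 = 0.2)
    iu <- integrate(function(t) wiener_fpt_density(t, p, "upper"),
                    p$t0, 60, rel.tol = 1e-9)$value
    il <- integrate(function(t) wiener_fpt_density(t, p, "lower"),
                    p$t0, 60, rel.tol = 1e-9)$value
    expect_equal(iu + il, 1, tolerance = 1e-6)
    expect_equal(iu, choice_probability(p), tolerance = 1e-6)
  }
  # symmetry: no drift, central start
  p0 <- wiener_params(v = 0, a = 1.5, z = 0.5, t0 = 0.1)
  iu <- integrate(function(t) wiener_fpt_density(t, p0, "upper"), 0.1, 60,
                  rel.tol = 1e-9)$value
  expect_equal(iu, 0.5, tolerance = 1e-6)
  expect_equal(wiener_fpt_density(c(0, 0.05, 0.1), p0, "upper"), c(0, 0, 0))
})

test_that("compiled density matches an independent pure-R series implementation", {
  cases <- expand.grid(t = c(0.4, 0.7, 1.2, 2.5), v = c(-0.8, 0.5, 2),
                       a = c(1, 2.2), z = c(0.35, 0.6))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    p <- wiener_params(v = cs$v, a = cs$a, z = cs$z, t0 = 0.25)
    for (bound in c("upper", "lower")) {
      expect_equal(wiener_fpt_density(cs$t, p, bound),
                   r_wiener_density(cs$t, cs$a, cs$v, cs$z, 0.25, bound),
                   tolerance = 1e-6)
    }
  }
})

test_that("absorption probability has its closed-form limits and value", {
  expect_equal(choice_probability(wiener_params(v = 0, a = 2, z = 0.5)), 0.5)
  expect_equal(choice_probability(wiener_params(v = 1, a = 2, z = 0.5)),
               0.8807971, tolerance = 1e-6)
  expect_gt(choice_probability(wiener_params(v = -2, a = 2, z = 0.999)), 0.97)
  # agrees with simulation
  p <- wiener_params(v = 1, a = 2, z = 0.5, t0 = 0.3)
  s <- simulate_wiener(p, 4e4, dt = 5e-4, seed = 21)
  se <- sqrt(0.88 * 0.12 / 4e4)
  expect_lt(abs(mean(s$upper) - choice_probability(p)), 4 * se)
})

test_that("simulated walks respect non-decision time and match the density", {
  p <- wiener_params(v = 1, a = 2, z = 0.5, t0 = 0.3)
  s <- simulate_wiener(p, 2e5, dt = 1e-3, seed = 22)
  expect_gte(min(s$rt), p$t0)
  # histogram of upper-bound RTs against the (defective) density
  rts <- s$rt[s$upper == 1]
  breaks <- seq(0.3, 3.3, by = 0.15)
  h <- hist(rts[rts < 3.3], breaks = breaks, plot = FALSE)
  mass <- vapply(seq_len(length(breaks) - 1), function(i)
    integrate(function(t) wiener_fpt_density(t, p, "upper"),
              breaks[i], breaks[i + 1])$value, numeric(1))
  expected <- mass * 2e5
  sds <- sqrt(pmax(expected, 1))
  # Euler discretization introduces a small bias; 4 Monte-Carlo SDs plus 3%
  expect_true(all(abs(h$counts - expected) < 4 * sds + 0.03 * expected))
})

test_that("stronger drift speeds decisions monotonically", {
  mean_rt <- vapply(c(0.5, 1.5, 3), function(v) {
    mean(simulate_wiener(wiener_params(v = v, a = 2, z = 0.5, t0 = 0.3),
                         2e4, dt = 1e-3, seed = 23)$rt)
  }, numeric(1))
  expect_true(all(diff(mean_rt) < 0))
})

test_that("parameter containers validate their invariants", {
  expect_error(wiener_params(v = 1, a = -1), "`a`")
  expect_error(wiener_params(v = 1, a = 1, z = 1.2), "`z`")
  expect_error(wiener_params(v = 1, a = 1, t0 = -0.1), "`t0`")
})
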