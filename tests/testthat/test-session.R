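test_that("sessions are balanced factorial tables with consistent bookkeeping", {
  tr <- simulate_session(observer_spec(), n_subjects = 1, trials_per_cell = 90,
                         seed = 3)
  expect_equal(nrow(tr), 360)
  expect_true(all(table(tr$pe_condition, tr$post_strength) == 90))
  expect_identical(tr$change_of_mind,
                   as.integer(tr$final_choice != tr$initial_choice))
  expect_identical(tr$initial_correct,
                   as.integer(tr$initial_choice == tr$direction))
  expect_true(all(tr$initial_rt > 0 & tr$final_rt > 0))
  expect_true(all(tr$initial_confidence >= 0.5 & tr$initial_confidence <= 1))
  expect_error(simulate_session(observer_spec(), trials_per_cell = 0),
               "positive")
})

test_that("sessions are reproducible and zero pre-decision drift gives chance accuracy", {
  a <- simulate_session(observer_spec(), n_subjects = 2, trials_per_cell = 20,
                        seed = 9)
  b <- simulate_session(observer_spec(), n_subjects = 2, trials_per_cell = 20,
                        seed = 9)
  expect_identical(a, b)
  # a flat psychometric slope yields zero drift, hence chance initial accuracy
  obs0 <- observer_spec(psycho_slope = 1e-9)
  s <- make_stimulus_set(0.2, 0.3)
  tr <- simulate_session(obs0, trials_per_cell = 1000, stimuli = s, seed = 10)
  expect_lt(abs(mean(tr$initial_correct) - 0.5), 0.03)
})

test_that("positive evidence raises confidence while accuracy stays matched", {
  tr <- simulate_session(observer_spec(), n_subjects = 1,
                         trials_per_cell = 2500, seed = 12)
  hpe <- tr$pe_condition == "HPE"
  expect_gt(mean(tr$initial_confidence[hpe]) -
              mean(tr$initial_confidence[!hpe]), 0.01)
  expect_lt(abs(mean(tr$initial_correct[hpe]) -
                  mean(tr$initial_correct[!hpe])), 0.02)
})

test_that("a positive drift interaction makes high-confidence errors stickier", {
  obs <- observer_spec(post = c(v_cd = 0.8, z_cd = 0))
  tr <- simulate_session(obs, n_subjects = 1, trials_per_cell = 2500, seed = 13)
  err <- tr$initial_correct == 0
  hi <- tr$initial_confidence > median(tr$initial_confidence)
  p_hi <- mean(tr$change_of_mind[err & hi])
  p_lo <- mean(tr$change_of_mind[err & !hi])
  expect_lt(p_hi, p_lo)
})

test_that("binary confidence variant median-splits within subject", {
  tr <- simulate_session(observer_spec(), n_subjects = 2, trials_per_cell = 30,
                         confidence_format = "binary", seed = 14)
  expect_true(all(tr$initial_confidence %in% c(0, 1)))
  props <- tapply(tr$initial_confidence, tr$subject_id, mean)
  expect_true(all(props > 0.2 & props < 0.8))
})

test_that("RT filter drops fast trials, reports, and errors when empty", {
  toy <- tibble::tibble(final_rt = c(0.1, 0.15, 0.19, seq(0.25, 0.85, by = 0.1)))
  expect_message(out <- filter_rts(toy, 0.2), "discarded 3")
  expect_equal(nrow(out), 7)
  clean <- tibble::tibble(final_rt = c(0.3, 0.4))
  expect_identical(filter_rts(clean, 0.2), clean)
  expect_error(suppressMessages(filter_rts(toy, 2)), "all trials removed")
})

test_that("covariate coding maps ratings and conditions to the model scale", {
  expect_equal(scale_confidence(c(0.5, 0.75, 1)), c(-1, 0, 1))
  expect_error(scale_confidence(0.2), "\\[0.5, 1\\]")
  tr <- test_session()
  co <- code_covariates(tr)
  expect_true(all(co$confidence >= -1 & co$confidence <= 1))
  expect_setequal(unique(co$initial_decision), c(-1, 1))
  expect_setequal(unique(co$post_evidence_strength), c(-1, 1))
  expect_equal(co$interaction, co$confidence * co$initial_decision)
})
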