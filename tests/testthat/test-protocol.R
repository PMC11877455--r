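test_that("task input follows the linear coherence rule and clips at zero", {
  expect_equal(task_rate(1, "P1"), 80)
  expect_equal(task_rate(1, "P2"), 0)
  expect_equal(task_rate(0, "P1"), 40)
  expect_equal(task_rate(0, "P2"), 40)
  expect_equal(task_rate(-0.512, "P2"), 60.48)
  expect_equal(task_rate(-0.512, "P1"), 19.52)
  expect_error(task_rate(1.2, "P1"), "<= 1")
})

test_that("coherence grids are symmetric ladders clamped to [-1, 1]", {
  g <- coherence_grid(0)
  expect_equal(g, sort(-g))                    # symmetric about the center
  expect_equal(length(g), 13)
  g2 <- coherence_grid(-57)
  expect_true(all(g2 >= -1 & g2 <= 1))
  expect_true(-0.57 %in% g2)
})

test_that("decisions require one population above threshold and the other below", {
  # P1 sustained at ~25 spk/s from 1.5 s, P2 at ~3 spk/s
  rec <- fake_trial(list(regular_train(25, 1500), regular_train(3, 0, 3800)),
                    populations = c("P1", "P2"))
  d <- decide(rec)
  expect_equal(d$winner, "P1")
  expect_equal(d$decision_time_s, 1.5, tolerance = 0.05)
  expect_false(d$excluded_from_timing)

  # both high: ambiguous, no decision
  tie <- fake_trial(list(regular_train(20, 1000), regular_train(20, 1000)),
                    populations = c("P1", "P2"))
  expect_equal(decide(tie)$winner, "none")

  # decision reached after the task period is excluded from timing analyses
  late <- fake_trial(list(regular_train(25, 3300), regular_train(3, 0, 3200)),
                     populations = c("P1", "P2"))
  dl <- decide(late)
  expect_equal(dl$winner, "P1")
  expect_true(dl$excluded_from_timing)
  expect_gt(dl$decision_time_s, 3)
})

test_that("per-cell seeds are stable, distinct and 32-bit safe", {
  s1 <- derive_seed(1, "PS", -0.57, 1)
  expect_identical(s1, derive_seed(1, "PS", -0.57, 1))
  expect_false(s1 == derive_seed(1, "PS", -0.57, 2))
  expect_false(s1 == derive_seed(2, "PS", -0.57, 1))
  many <- vapply(1:200, function(tr) derive_seed(3, "CGS", 0.128, tr), 1L)
  expect_equal(length(unique(many)), 200)
  expect_true(all(many > 0 & many < 2^31))
})

test_that("a one-cell experiment plan yields exactly one trial result", {
  arch <- network_architecture(N = 250)
  plan <- experiment_plan("control", coherences = list(control = 0.512),
                          trials = 1, seed = 4)
  res <- run_experiment(plan, sim_config(network = arch, duration_s = 2))
  expect_equal(nrow(res), 1)
  expect_setequal(names(res), c("condition", "coherence", "trial", "seed",
                                "winner", "decision_time_s",
                                "excluded_from_timing"))
})

test_that("variant experiments report rates relative to the control mean", {
  ve <- variant_experiment("disconnected", "CGS", trials = 4, seed = 11)
  expect_equal(nrow(ve$trials), 4)
  expect_equal(ve$trials$delta_vs_control,
               ve$trials$pop_rate - ve$control_mean)
  expect_equal(nrow(ve$per_neuron), 120)
  # excitatory galvanic stimulation raises the population rate
  expect_gt(median(ve$trials$delta_vs_control), 0)

  # feedback inhibition suppresses spontaneous firing to below 1 spk/s
  fb <- variant_experiment("feedback_only", "control", trials = 2, seed = 11)
  expect_lt(mean(fb$trials$pop_rate), 1)
})

test_that("CGS calibration bisection converges on a monotone bias function", {
  # surrogate: bias falls linearly with amplitude magnitude
  surrogate <- function(a) -40 * a
  out <- calibrate_cgs(target_bias = -56, bounds = c(0.1, 10),
                       bias_fn = surrogate, tol_bias = 0.01)
  expect_equal(out$amplitude_uA, -1.4, tolerance = 1e-3)
  # fixed point: a target equal to an amplitude's own bias returns it
  out2 <- calibrate_cgs(target_bias = surrogate(2.5), bounds = c(0.1, 10),
                        bias_fn = surrogate, tol_bias = 0.01)
  expect_equal(out2$amplitude_uA, -2.5, tolerance = 1e-3)
  expect_error(calibrate_cgs(-1000, c(0.1, 10), bias_fn = surrogate),
               "bracket")
})
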