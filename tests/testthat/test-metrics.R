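test_that("binned rates conserve spike counts and track a constant train", {
  rec <- fake_trial(list(regular_train(100), regular_train(40), numeric(0)))
  raw <- smoothed_rates(rec, bin_ms = 5, window_ms = 5)   # no smoothing
  counts <- rowSums(raw$rate) * 5e-3
  expect_equal(unname(counts),
               c(length(regular_train(100)), length(regular_train(40)), 0))
  sm <- smoothed_rates(rec, bin_ms = 5, window_ms = 50)
  mid <- sm$t_ms > 500 & sm$t_ms < 3500
  expect_equal(mean(sm$rate[1, mid]), 100, tolerance = 0.01)
  expect_true(all(sm$rate[3, ] == 0))
  expect_error(smoothed_rates(rec, bin_ms = 5, window_ms = 12), "multiple")
})

test_that("psychometric fit matches a brute-force likelihood grid search", {
  results <- tibble::tibble(
    coherence = rep(c(-0.5, 0, 0.5), each = 10),
    winner = c(rep("P2", 10), rep(c("P1", "P2"), 5), rep("P1", 10)))
  fit <- psychometric_fit(results)
  expect_equal(fit$bias, 0, tolerance = 0.5)     # symmetric data, bias in %

  # independent oracle: exhaustive grid over the same penalized likelihood
  grid <- expand.grid(b0 = seq(-1, 1, by = 0.02), b1 = seq(0.1, 25, by = 0.02))
  agg <- dplyr::summarise(dplyr::group_by(results, coherence),
                          w = sum(winner == "P1"), l = sum(winner == "P2"))
  nll <- function(b0, b1) {
    eta <- b0 + b1 * agg$coherence
    -sum(agg$w * (eta - log1p(exp(eta))) - agg$l * log1p(exp(eta))) +
      1e-4 * (b0^2 + b1^2)
  }
  vals <- mapply(nll, grid$b0, grid$b1)
  best <- grid[which.min(vals), ]
  expect_equal(unname(fit$coefficients["b1"]), best$b1, tolerance = 5e-3)
  expect_equal(unname(fit$coefficients["b0"]), best$b0, tolerance = 0.05)

  # equivariance: shifting every coherence shifts the bias, not the slope
  shifted <- dplyr::mutate(results, coherence = coherence + 0.2)
  fit2 <- psychometric_fit(shifted)
  expect_equal(fit2$bias, fit$bias + 20, tolerance = 0.3)
  expect_equal(fit2$sensitivity, fit$sensitivity, tolerance = 0.01)

  expect_error(psychometric_fit(results[results$coherence == 0, ]),
               ">= 2 coherence")
})

test_that("tidy and glance return one-row broom-style summaries", {
  results <- tibble::tibble(
    coherence = rep(c(-0.5, 0.5), each = 8),
    winner = c(rep("P2", 8), rep("P1", 8)))
  fit <- psychometric_fit(results)
  td <- tidy(fit)
  expect_equal(td$term, c("b0", "b1"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("bias", "sensitivity", "n_decided") %in% names(gl)))
})

test_that("bootstrap comparison is null on identical data, decisive on separated", {
  set.seed(1)
  mk <- function(shift) tibble::tibble(
    coherence = rep(c(-0.4, -0.1, 0.1, 0.4), each = 15),
    winner = ifelse(stats::runif(60) <
                      stats::plogis(6 * (rep(c(-0.4, -0.1, 0.1, 0.4),
                                             each = 15) - shift)),
                    "P1", "P2"))
  a <- mk(0)
  null <- bootstrap_compare(a, a, "bias", n_boot = 300, seed = 2)
  expect_gt(null$p_value, 0.2)
  sep <- bootstrap_compare(a, mk(0.35), "bias", n_boot = 300, seed = 2)
  expect_lt(sep$p_value, 0.02)
  # row order cannot matter: resampling acts on per-coherence tallies
  perm <- a[sample(nrow(a)), ]
  expect_equal(bootstrap_compare(a, perm, "bias", n_boot = 100, seed = 3)$estimate, 0)
  # one-sample variant against zero bias
  one <- bootstrap_compare(a, NULL, "bias", n_boot = 300, seed = 4)
  expect_gt(one$p_value, 0.05)
})

test_that("trajectory statistics recover crossing times of a stepped ramp", {
  # 20 staggered neurons at 12 spk/s in [1.5, 2) s then 25 spk/s after 2 s
  trains <- lapply(seq_len(20), function(i) {
    off <- (i - 1) * 2
    c(seq(1500 + off, 1995, by = 1000 / 12),
      seq(2000 + off, 4000, by = 1000 / 25))
  })
  rec <- fake_trial(trains)
  ts <- trajectory_stats(rec)
  expect_equal(ts$t10_s, 1.5, tolerance = 0.05)
  expect_equal(ts$t20_s, 2.0, tolerance = 0.05)
  expect_equal(ts$slope, 10 / (ts$t20_s - ts$t10_s))
  expect_equal(ts$slope, 20, tolerance = 0.15)
  expect_equal(ts$start_rate, 0)              # silent in t = 1-1.1 s
  expect_equal(ts$end_rate, 25, tolerance = 0.1)
  expect_gte(ts$max_rate, 20)

  flat <- fake_trial(lapply(1:20, function(i) regular_train(5, i)))
  expect_true(is.na(trajectory_stats(flat)$slope))
})

test_that("raw kurtosis matches the hand example and the normal reference", {
  expect_equal(kurtosis_raw(c(0, 0, 0, 0, 100)), 3.25)
  expect_true(is.na(kurtosis_raw(rep(7, 10))))
  set.seed(9)
  expect_equal(kurtosis_raw(stats::rnorm(2e4)), 3, tolerance = 0.05)
  # heavy-tailed samples exceed matched-variance normal kurtosis
  ht <- stats::rt(2e4, df = 5)
  expect_gt(kurtosis_raw(ht), kurtosis_raw(stats::rnorm(2e4, sd = stats::sd(ht))))
})

test_that("kurtosis series applies the exclusion windows and rate floor", {
  trains <- lapply(seq_len(10), function(i) regular_train(2 * i, 600))
  rec <- fake_trial(trains)
  ks <- kurtosis_series(rec)
  expect_true(all(is.na(ks$kurtosis[ks$t_s < 0.5])))
  expect_true(all(is.na(ks$kurtosis[ks$t_s > 3.5])))
  expect_true(all(ks$excluded[ks$mean_rate < 1]))
  mid <- ks$t_s > 1 & ks$t_s < 3
  expect_true(any(!is.na(ks$kurtosis[mid])))
  # zero across-neuron variance is reported as excluded
  same <- fake_trial(lapply(1:10, function(i) regular_train(20, 600)))
  ks2 <- kurtosis_series(same)
  expect_true(all(is.na(ks2$kurtosis)))
  sm <- kurtosis_task_summary(ks)
  expect_true(is.finite(sm$begin_task) && is.finite(sm$end_task))
})

test_that("spike-timing statistics follow the coincidence and CV definitions", {
  # A fires 4 spikes in the epoch; both B spikes coincide within 300 us
  rec <- fake_trial(list(c(2600, 2700, 2800, 2900),
                         c(2600.1, 2700.2),
                         regular_train(40, 0)))
  st <- spike_timing_stats(rec, epoch_s = c(2.5, 3))
  expect_equal(st$synchrony["1", "2"], 100 * 2 / 4)   # higher-rate denominator
  expect_equal(st$synchrony["2", "1"], 100 * 2 / 4)
  expect_true(is.na(st$synchrony["1", "1"]))
  # identical trains are fully synchronous
  rec2 <- fake_trial(list(regular_train(30, 0), regular_train(30, 0)))
  expect_equal(spike_timing_stats(rec2)$synchrony["1", "2"], 100)
  # perfectly periodic firing has CV 0; < 3 epoch spikes gives NA
  per <- st$per_neuron
  expect_equal(per$cv[per$neuron_id == 3], 0, tolerance = 1e-10)
  expect_true(is.na(per$cv[per$neuron_id == 2]))
})

test_that("phase locking counts APs inside the biphasic pulse footprint", {
  ps <- stim_protocol("PS", amplitude_uA = -10)   # pulses at 5 ms intervals
  # one neuron locked just inside footprints, one firing between pulses
  locked <- seq(2500.3, 2999, by = 5)
  unlocked <- seq(2502.5, 2999, by = 5)
  rec <- fake_trial(list(locked, unlocked), stimulation = ps)
  st <- spike_timing_stats(rec)
  per <- st$per_neuron
  expect_equal(per$phase_locked_pct[1], 100)
  expect_equal(per$phase_locked_pct[2], 0)
})

test_that("network current index is the signed sum of recurrent currents", {
  rec <- fake_trial(list(numeric(0)))
  rec$currents <- list(neuron_id = 1:2, t_ms = c(0, 1),
                       I_ampa_rec = matrix(10, 2, 2),
                       I_nmda = matrix(5, 2, 2),
                       I_gaba = matrix(-20, 2, 2))
  idx <- network_current_index(rec)
  expect_equal(idx$population$index_pA, c(-5, -5))   # inhibition-dominant
  rec$currents$I_gaba[] <- 0
  expect_true(all(network_current_index(rec)$population$index_pA > 0))
  expect_error(network_current_index(fake_trial(list(numeric(0)))),
               "record_currents")
})

test_that("significance suite wraps the standard tests with Bonferroni", {
  set.seed(5)
  x <- stats::rnorm(40)
  same <- suppressWarnings(significance_suite(list(x, x), "t"))
  expect_equal(same$p_value, 1)
  for (tst in c("ks", "kruskal", "wilcox", "t", "anova")) {
    res <- suppressWarnings(
      significance_suite(list(x, x + 3), tst, n_comparisons = 5))
    expect_lt(res$p_value, 1e-4)
    expect_equal(res$p_bonferroni, pmin(1, res$p_value * 5))
  }
  # Kruskal-Wallis on two groups agrees with the rank-sum decision
  y <- stats::rnorm(40, mean = 1.2)
  kw <- significance_suite(list(x, y), "kruskal")
  ws <- significance_suite(list(x, y), "wilcox")
  expect_equal(kw$p_value < 0.05, ws$p_value < 0.05)
})
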