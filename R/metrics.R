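#' Binned and smoothed firing rates
#'
#' Per-neuron instantaneous rates: spike counts in `bin_ms` bins divided by
#' the bin width, followed by a centered moving average spanning `window_ms`
#' (taps at bin offsets within `window_ms / 2`, truncated at the edges).
#' Population series are the average over member neurons, silent neurons
#' included. Setting `window_ms = bin_ms` returns the raw binned rates.
#'
#' @param x A `wta_trial` from [run_trial()].
#' @param bin_ms Bin width (ms).
#' @param window_ms Moving-average span (ms; multiple of `bin_ms`).
#' @param populations Populations for which to compute population-average
#'   series (default: all present).
#' @return A `rate_timeseries` object: `t_ms` (bin centers), `rate` (matrix,
#'   neurons x bins, spk/s), `neuron_id`, `population` (per neuron), and
#'   `population` series tibble (`t_s`, `population`, `rate`).
#' @export
smoothed_rates <- function(x, bin_ms = 5, window_ms = 50, populations = NULL) {
  stopifnot(inherits(x, "wta_trial"), bin_ms > 0, window_ms >= bin_ms)
  if (abs(window_ms / bin_ms - round(window_ms / bin_ms)) > 1e-9) {
    stop("window_ms must be a multiple of bin_ms", call. = FALSE)
  }
  neurons <- x$neurons
  n <- nrow(neurons)
  n_bins <- ceiling(x$duration_ms / bin_ms)
  edges <- seq(0, n_bins * bin_ms, by = bin_ms)
  centers <- edges[-1] - bin_ms / 2

  idx_n <- match(x$spikes$neuron_id, neurons$neuron_id)
  idx_b <- pmin(n_bins, findInterval(x$spikes$t_ms, edges,
                                     left.open = TRUE, rightmost.closed = TRUE))
  counts <- matrix(0, n, n_bins)
  if (nrow(x$spikes) > 0) {
    tab <- table(factor(idx_n, levels = seq_len(n)),
                 factor(idx_b, levels = seq_len(n_bins)))
    counts <- matrix(as.numeric(tab), n, n_bins)
  }
  rate <- counts / (bin_ms / 1e3)

  half <- floor(window_ms / bin_ms / 2)
  if (half > 0) {
    acc <- matrix(0, n, n_bins)
    cnt <- numeric(n_bins)
    for (k in -half:half) {
      src <- seq_len(n_bins) + k
      ok <- src >= 1 & src <= n_bins
      acc[, ok] <- acc[, ok] + rate[, src[ok]]
      cnt[ok] <- cnt[ok] + 1
    }
    rate_s <- sweep(acc, 2, cnt, "/")
  } else {
    rate_s <- rate
  }

  pops <- as.character(neurons$population)
  if (is.null(populations)) populations <- unique(pops)
  pop_series <- purrr::map(populations, function(p) {
    members <- pops == p
    if (!any(members)) return(NULL)
    tibble::tibble(t_s = centers / 1e3, population = p,
                   rate = colMeans(rate_s[members, , drop = FALSE]))
  })
  structure(
    list(t_ms = centers, rate = rate_s, raw_rate = rate,
         neuron_id = neurons$neuron_id, neuron_population = pops,
         bin_ms = bin_ms, window_ms = window_ms,
         population = dplyr::bind_rows(pop_series)),
    class = "rate_timeseries"
  )
}

#' @export
print.rate_timeseries <- function(x, ...) {
  cat("<rate_timeseries> ", nrow(x$rate), " neurons x ", ncol(x$rate),
      " bins (", x$bin_ms, " ms bins, ", x$window_ms, " ms window)\n",
      sep = "")
  invisible(x)
}

# penalized Bernoulli logistic log-likelihood (aggregated per coherence)
logistic_negll <- function(beta, c_lvl, wins, losses, lambda) {
  eta <- beta[1] + beta[2] * c_lvl
  # log(1 + exp(eta)) computed stably
  lse <- ifelse(eta > 30, eta, log1p(exp(eta)))
  -sum(wins * (eta - lse) + losses * (-lse)) + lambda * sum(beta^2)
}

logistic_negll_grad <- function(beta, c_lvl, wins, losses, lambda) {
  eta <- beta[1] + beta[2] * c_lvl
  p <- stats::plogis(eta)
  r <- (wins + losses) * p - wins
  c(sum(r), sum(r * c_lvl)) + 2 * lambda * beta
}

#' Fit a psychometric curve
#'
#' Bernoulli logistic regression P(P1 wins) = logistic(b0 + b1 c) on decided
#' trials (no-decision trials excluded), with a weak ridge penalty so the fit
#' survives perfect separation at extreme coherence grids. The bias is the
#' coherence at 50% P1-win probability, `-b0/b1`, reported in percent; the
#' sensitivity is the slope `b1` per unit coherence.
#'
#' @param results Trial results tibble with columns `coherence` and `winner`
#'   (one condition), as produced by [run_experiment()].
#' @param lambda Ridge penalty weight.
#' @return A `psychometric_fit` object.
#' @export
psychometric_fit <- function(results, lambda = 1e-4) {
  dec <- results[results$winner %in% c("P1", "P2"), ]
  agg <- dplyr::summarise(
    dplyr::group_by(dec, .data$coherence),
    wins = sum(.data$winner == "P1"), losses = sum(.data$winner == "P2"),
    .groups = "drop")
  if (nrow(agg) < 2) stop("need >= 2 coherence levels with decisions",
                          call. = FALSE)
  fit <- stats::optim(c(0, 1), logistic_negll, gr = logistic_negll_grad,
                      c_lvl = agg$coherence, wins = agg$wins,
                      losses = agg$losses, lambda = lambda,
                      method = "BFGS", control = list(maxit = 500))
  b <- fit$par
  structure(
    list(coefficients = c(b0 = b[1], b1 = b[2]),
         bias = -b[1] / b[2] * 100, sensitivity = b[2],
         data = agg, n_trials = nrow(results), n_decided = nrow(dec),
         lambda = lambda, negll = fit$value,
         converged = fit$convergence == 0),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit> bias ", sprintf("%.2f%%", x$bias),
      ", sensitivity ", sprintf("%.2f", x$sensitivity),
      " (", x$n_decided, "/", x$n_trials, " decided trials)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("b0", "b1"),
                 estimate = unname(x$coefficients))
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(bias = x$bias, sensitivity = x$sensitivity,
                 n_trials = x$n_trials, n_decided = x$n_decided,
                 deviance = 2 * x$negll, converged = x$converged)
}

#' Non-parametric bootstrap comparison of psychometric parameters
#'
#' Trials are resampled with replacement within each coherence level
#' (no-decision trials participate in the resampling and are excluded from
#' each replicate fit), the psychometric model is refit per replicate, and a
#' two-sided p-value is read from the replicate distribution of the parameter
#' difference. With `results_b = NULL` the one-sample variant tests the
#' parameter against zero.
#'
#' @param results_a,results_b Trial results tibbles (one condition each).
#' @param statistic `"bias"` or `"sensitivity"`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List: `p_value`, `estimate` (observed difference), `replicates`,
#'   `n_failed`.
#' @export
bootstrap_compare <- function(results_a, results_b = NULL,
                              statistic = c("bias", "sensitivity"),
                              n_boot = 10000, seed = 1L) {
  statistic <- match.arg(statistic)
  stat_of <- function(fit) if (statistic == "bias") fit$bias else fit$sensitivity

  tallies <- function(res) {
    dplyr::summarise(
      dplyr::group_by(res, .data$coherence),
      wins = sum(.data$winner == "P1"), losses = sum(.data$winner == "P2"),
      none = sum(.data$winner == "none"), .groups = "drop")
  }
  fit_tally <- function(tl) {
    fake <- tibble::tibble(
      coherence = rep(tl$coherence, times = tl$wins + tl$losses),
      winner = unlist(purrr::map2(tl$wins, tl$losses,
                                  ~ c(rep("P1", .x), rep("P2", .y)))))
    psychometric_fit(fake)
  }
  resample <- function(tl) {
    n <- tl$wins + tl$losses + tl$none
    draws <- purrr::pmap(tl, function(coherence, wins, losses, none) {
      stats::rmultinom(1, wins + losses + none,
                       c(wins, losses, none) / (wins + losses + none))
    })
    m <- do.call(cbind, draws)
    tibble::tibble(coherence = tl$coherence, wins = m[1, ], losses = m[2, ],
                   none = m[3, ])
  }

  ta <- tallies(results_a)
  tb <- if (!is.null(results_b)) tallies(results_b)
  obs <- stat_of(fit_tally(ta)) -
    (if (is.null(tb)) 0 else stat_of(fit_tally(tb)))

  set.seed(seed)
  reps <- numeric(n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    r <- tryCatch({
      sa <- stat_of(fit_tally(resample(ta)))
      sb <- if (is.null(tb)) 0 else stat_of(fit_tally(resample(tb)))
      sa - sb
    }, error = function(e) NA_real_)
    if (is.na(r)) failed <- failed + 1L
    reps[b] <- r
  }
  reps_ok <- reps[!is.na(reps)]
  p <- 2 * min(mean(reps_ok <= 0), mean(reps_ok >= 0))
  list(p_value = min(1, max(p, 1 / length(reps_ok))), estimate = obs,
       replicates = reps_ok, n_failed = failed, statistic = statistic)
}

#' Firing-rate trajectory statistics for one trial
#'
#' Start- and end-of-task rates are direct spike counts of the P1 population
#' in t = 1-1.1 s and t = 2.9-3.0 s divided by the window and population
#' size. The threshold-crossing slope is m = (20 - 10) / (t20 - t10), where
#' t10 and t20 are the first times the smoothed P1 population rate exceeds 10
#' and 20 spk/s after task onset (NA when either threshold is never crossed).
#' The maximum rate is the maximum of the smoothed P1 series.
#'
#' @param recording A `wta_trial`.
#' @param bin_ms,window_ms Rate-estimation parameters (ms).
#' @return One-row tibble: `start_rate`, `end_rate`, `slope`, `t10_s`,
#'   `t20_s`, `max_rate`.
#' @export
trajectory_stats <- function(recording, bin_ms = 5, window_ms = 50) {
  task_on <- recording$config$task$onset_s
  task_off <- recording$config$task$offset_s
  p1 <- recording$neurons$population == "P1"
  n1 <- sum(p1)
  sp <- recording$spikes[recording$spikes$population == "P1", ]

  window_rate <- function(a_s, b_s) {
    sum(sp$t_ms > a_s * 1e3 & sp$t_ms <= b_s * 1e3) / (b_s - a_s) / n1
  }
  rts <- smoothed_rates(recording, bin_ms, window_ms, populations = "P1")
  series <- rts$population[rts$population$population == "P1", ]
  after <- series[series$t_s > task_on, ]
  first_cross <- function(th) {
    i <- which(after$rate > th)
    if (length(i) == 0) NA_real_ else after$t_s[min(i)]
  }
  t10 <- first_cross(10)
  t20 <- first_cross(20)
  tibble::tibble(
    start_rate = window_rate(task_on, task_on + 0.1),
    end_rate = window_rate(task_off - 0.1, task_off),
    t10_s = t10, t20_s = t20,
    slope = if (!is.na(t10) && !is.na(t20) && t20 > t10) 10 / (t20 - t10)
            else NA_real_,
    max_rate = max(series$rate)
  )
}

#' Raw (non-excess) kurtosis
#'
#' Fourth standardized moment m4 / m2^2 with biased moment estimators; a
#' normal sample gives ~3.
#'
#' @param x Numeric vector.
#' @return Kurtosis, or NA if the variance is zero.
#' @export
kurtosis_raw <- function(x) {
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  mean(d^4) / m2^2
}

#' Kurtosis of the across-neuron rate distribution over time
#'
#' Per-neuron rates in 50 ms bins with a 200 ms moving average (20 Hz
#' sampling), then at each time point the raw kurtosis of the distribution of
#' rates across the selected neurons. Time points in the first 0.5 s and last
#' 0.5 s of the trial, and points where the population mean rate is below
#' `min_rate`, are excluded (kurtosis NA, `excluded` flag set); zero-variance
#' points are reported as excluded too.
#'
#' @param recording A `wta_trial`.
#' @param population Population to analyze.
#' @param bin_ms,window_ms Rate parameters (ms).
#' @param min_rate Population-mean exclusion threshold (spk/s).
#' @return Tibble: `t_s`, `kurtosis`, `mean_rate`, `excluded`.
#' @export
kurtosis_series <- function(recording, population = "P1",
                            bin_ms = 50, window_ms = 200, min_rate = 1) {
  rts <- smoothed_rates(recording, bin_ms, window_ms,
                        populations = population)
  members <- rts$neuron_population == population
  if (sum(members) < 4) stop("need >= 4 neurons", call. = FALSE)
  m <- rts$rate[members, , drop = FALSE]
  t_s <- rts$t_ms / 1e3
  mean_rate <- colMeans(m)
  kur <- apply(m, 2, kurtosis_raw)
  dur_s <- recording$duration_ms / 1e3
  excl <- t_s < 0.5 | t_s > dur_s - 0.5 | mean_rate < min_rate | is.na(kur)
  tibble::tibble(t_s = t_s, kurtosis = ifelse(excl, NA_real_, kur),
                 mean_rate = mean_rate, excluded = excl)
}

#' Beginning- and end-of-task kurtosis
#'
#' Averages the retained kurtosis time points in t = 1.1-1.2 s
#' (beginning-of-task) and t = 2.9-3.0 s (end-of-task).
#'
#' @param series Output of [kurtosis_series()].
#' @return One-row tibble `begin_task`, `end_task`.
#' @export
kurtosis_task_summary <- function(series) {
  win_mean <- function(a, b) {
    v <- series$kurtosis[series$t_s >= a & series$t_s <= b]
    mean(v, na.rm = TRUE)
  }
  tibble::tibble(begin_task = win_mean(1.1, 1.2), end_task = win_mean(2.9, 3.0))
}

# greedy one-to-one nearest matching of two sorted spike trains
count_coincident <- function(a, b, tol_ms) {
  i <- 1L; j <- 1L; hits <- 0L
  na <- length(a); nb <- length(b)
  while (i <= na && j <= nb) {
    d <- a[i] - b[j]
    if (abs(d) <= tol_ms) {
      hits <- hits + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  hits
}

#' Spike-timing statistics: phase locking, CV and pairwise synchrony
#'
#' Within the analysis epoch (default the last 0.5 s of the task period):
#' * phase locking: percentage of a neuron's APs falling inside pulse
#'   presentations (the full biphasic footprint), when a pulsatile schedule
#'   applies;
#' * CV: sd(ISI) / mean(ISI) (sample standard deviation), NA below 2 ISIs;
#' * synchrony: percentage of coincident APs within `window_us` between each
#'   neuron pair, matched one-to-one (greedy nearest match) and normalized by
#'   the spike count of the higher-rate neuron.
#'
#' @param recording A `wta_trial`.
#' @param epoch_s Length-2 analysis window (s).
#' @param window_us Coincidence / pulse-phase window (us).
#' @param population Population to analyze.
#' @return List: `per_neuron` tibble (`neuron_id`, `distance_um`, `n_spikes`,
#'   `phase_locked_pct`, `cv`) and `synchrony` matrix (%, NA diagonal).
#' @export
spike_timing_stats <- function(recording, epoch_s = c(2.5, 3),
                               window_us = 300, population = "P1") {
  neurons <- recording$neurons[recording$neurons$population == population, ]
  sp <- recording$spikes[
    recording$spikes$population == population &
    recording$spikes$t_ms > epoch_s[1] * 1e3 &
    recording$spikes$t_ms <= epoch_s[2] * 1e3, ]
  trains <- split(sp$t_ms, factor(sp$neuron_id, levels = neurons$neuron_id))
  trains <- lapply(trains, sort)

  stim <- recording$config$stimulation
  in_pulse <- NULL
  if (stim$mode == "PS") {
    pw <- stim$pulse_width_us * 1e-3
    period <- 1e3 / stim$pulse_rate_pps
    onset <- stim$onset_s * 1e3
    offset <- stim$offset_s * 1e3
    in_pulse <- function(t) {
      t >= onset & t < offset & ((t - onset) %% period) < 2 * pw
    }
  }

  per <- purrr::imap(trains, function(tr, id) {
    nspk <- length(tr)
    cv <- NA_real_
    if (nspk >= 3) {
      isi <- diff(tr)
      cv <- stats::sd(isi) / mean(isi)
    }
    pl <- if (is.null(in_pulse) || nspk == 0) NA_real_
          else 100 * mean(in_pulse(tr))
    tibble::tibble(neuron_id = as.integer(id), n_spikes = nspk,
                   phase_locked_pct = pl, cv = cv)
  })
  per <- dplyr::left_join(dplyr::bind_rows(per),
                          neurons[, c("neuron_id", "distance_um")],
                          by = "neuron_id")

  nn <- length(trains)
  syn <- matrix(NA_real_, nn, nn,
                dimnames = list(names(trains), names(trains)))
  tol <- window_us * 1e-3
  for (i in seq_len(nn)) {
    for (j in seq_len(nn)) {
      if (i == j) next
      hi <- max(length(trains[[i]]), length(trains[[j]]))
      syn[i, j] <- if (hi == 0) NA_real_ else
        100 * count_coincident(trains[[i]], trains[[j]], tol) / hi
    }
  }
  list(per_neuron = per[, c("neuron_id", "distance_um", "n_spikes",
                            "phase_locked_pct", "cv")],
       synchrony = syn)
}

#' Network-current index
#'
#' Signed sum of the recurrent currents received by each recorded neuron,
#' I_AMPA_rec + I_NMDA + I_GABA, with depolarizing currents positive; since
#' the GABA current is hyperpolarizing at depolarized potentials, epochs
#' dominated by feedback inhibition give a negative index.
#'
#' @param recording A `wta_trial` run with `record_currents = TRUE`.
#' @return List: `population` tibble (`t_s`, `index_pA`, mean over recorded
#'   neurons) and `per_neuron` matrix (neurons x samples, pA).
#' @export
network_current_index <- function(recording) {
  cur <- recording$currents
  if (is.null(cur)) {
    stop("trial was not run with record_currents = TRUE", call. = FALSE)
  }
  idx <- cur$I_ampa_rec + cur$I_nmda + cur$I_gaba
  list(
    population = tibble::tibble(t_s = cur$t_ms / 1e3,
                                index_pA = colMeans(idx)),
    per_neuron = idx, neuron_id = cur$neuron_id
  )
}

#' Standard significance tests with Bonferroni correction
#'
#' Thin wrapper over the standard tests used throughout the analyses:
#' Kolmogorov-Smirnov, Kruskal-Wallis, Wilcoxon rank-sum, unpaired t, and
#' one-way ANOVA, with an optional Bonferroni correction across a family of
#' comparisons.
#'
#' @param groups List of >= 2 numeric vectors (KS, Wilcoxon and t use the
#'   first two).
#' @param test One of `"ks"`, `"kruskal"`, `"wilcox"`, `"t"`, `"anova"`.
#' @param n_comparisons Family size for the Bonferroni correction.
#' @param ... Passed to the underlying test (e.g. `alternative`).
#' @return One-row tibble: `test`, `statistic`, `p_value`, `p_bonferroni`.
#' @export
significance_suite <- function(groups,
                               test = c("ks", "kruskal", "wilcox", "t",
                                        "anova"),
                               n_comparisons = 1, ...) {
  test <- match.arg(test)
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  res <- switch(test,
    ks = stats::ks.test(groups[[1]], groups[[2]], ...),
    kruskal = stats::kruskal.test(groups),
    wilcox = stats::wilcox.test(groups[[1]], groups[[2]], ...),
    t = stats::t.test(groups[[1]], groups[[2]], ...),
    anova = {
      df <- data.frame(
        value = unlist(groups),
        group = factor(rep(seq_along(groups),
                           times = vapply(groups, length, 1L))))
      summary(stats::aov(value ~ group, data = df))[[1]]
    })
  if (test == "anova") {
    tibble::tibble(test = test, statistic = res[["F value"]][1],
                   p_value = res[["Pr(>F)"]][1],
                   p_bonferroni = pmin(1, res[["Pr(>F)"]][1] * n_comparisons))
  } else {
    tibble::tibble(test = test, statistic = unname(res$statistic),
                   p_value = res$p.value,
                   p_bonferroni = pmin(1, res$p.value * n_comparisons))
  }
}
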