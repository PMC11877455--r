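#' Task input rate for a selective population
#'
#' Linear task-input rule FR = gain * c + base (Hz) for the favored
#' population; the other population receives the rate at `-c`. Rates are
#' clipped at zero.
#'
#' @param coherence Signed coherence in `[-1, 1]` (positive favors P1).
#' @param population `"P1"` or `"P2"`.
#' @param base_rate_hz,gain_hz Intercept and slope (Hz).
#' @return Poisson event rate (Hz).
#' @export
#' @examples
#' task_rate(1, "P1")    # 80
#' task_rate(1, "P2")    # 0
task_rate <- function(coherence, population = c("P1", "P2"),
                      base_rate_hz = 40, gain_hz = 40) {
  population <- match.arg(population)
  if (any(abs(coherence) > 1)) stop("|coherence| must be <= 1", call. = FALSE)
  c_eff <- if (population == "P1") coherence else -coherence
  pmax(0, gain_hz * c_eff + base_rate_hz)
}

#' Extract the decision from a trial
#'
#' Population firing rates of P1 and P2 are estimated in 5 ms bins with a
#' 50 ms centered moving average. The trial is won by the population whose
#' final rate exceeds `threshold` while the other does not; the decision time
#' is the first time after task onset at which the winner's rate exceeds the
#' threshold. Decisions reached after the task period are flagged as excluded
#' from timing analyses.
#'
#' @param recording A `wta_trial` from [run_trial()].
#' @param threshold Decision threshold (spk/s).
#' @param bin_ms,window_ms Rate-estimation parameters (ms).
#' @return One-row tibble: `winner` (`"P1"`, `"P2"` or `"none"`),
#'   `decision_time_s` (NA if no winner), `excluded_from_timing`.
#' @export
decide <- function(recording, threshold = 15, bin_ms = 5, window_ms = 50) {
  task_off <- recording$config$task$offset_s
  task_on <- recording$config$task$onset_s
  rts <- smoothed_rates(recording, bin_ms = bin_ms, window_ms = window_ms,
                        populations = c("P1", "P2"))
  pr <- rts$population
  final <- dplyr::slice_max(pr, .data$t_s, n = 1, with_ties = TRUE)
  f1 <- final$rate[final$population == "P1"]
  f2 <- final$rate[final$population == "P2"]
  if (length(f2) == 0) f2 <- -Inf   # reduced variants without P2
  winner <- if (f1 > threshold && f2 <= threshold) "P1"
            else if (f2 > threshold && f1 <= threshold) "P2"
            else "none"
  dtime <- NA_real_
  if (winner != "none") {
    win <- dplyr::filter(pr, .data$population == winner,
                         .data$t_s > task_on, .data$rate > threshold)
    dtime <- if (nrow(win) > 0) min(win$t_s) else NA_real_
  }
  tibble::tibble(
    winner = winner,
    decision_time_s = dtime,
    excluded_from_timing = !is.na(dtime) && dtime > task_off
  )
}

#' Deterministic per-trial seed
#'
#' Derives an independent 32-bit seed for one (condition, coherence, trial)
#' cell from a master seed, so enlarging a grid never perturbs existing
#' trials.
#'
#' @param master Master seed (integer).
#' @param condition,coherence,trial Cell coordinates.
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(master, condition, coherence, trial) {
  key <- paste(condition, format(coherence, digits = 10), trial, sep = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1976943448
  as.integer((h + as.numeric(master) * 97) %% 2147483629 + 1)
}

#' Log-spaced coherence grid around a center
#'
#' The standard dot-motion ladder `center + c(0, +/-1.6, 3.2, 6.4, 12.8,
#' 25.6, 51.2)%` (as fractions), clamped to `[-1, 1]`.
#'
#' @param center_pct Grid center in percent coherence.
#' @param steps_pct Ladder steps in percent.
#' @return Sorted numeric vector of coherences (fractions).
#' @export
coherence_grid <- function(center_pct = 0,
                           steps_pct = c(1.6, 3.2, 6.4, 12.8, 25.6, 51.2)) {
  g <- (center_pct + c(0, steps_pct, -steps_pct)) / 100
  sort(pmin(1, pmax(-1, g)))
}

#' Experiment plan
#'
#' @param conditions Character subset of `"control"`, `"PS"`, `"CGS"`, `"AGS"`.
#' @param coherences Named list of coherence grids per condition (defaults to
#'   the per-condition centers 0%, -57%, -57%, +30%).
#' @param trials Trials per coherence level.
#' @param seed Master seed.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(conditions = c("control", "PS", "CGS", "AGS"),
                            coherences = NULL, trials = 100, seed = 1L) {
  stopifnot(trials >= 1,
            all(conditions %in% c("control", "PS", "CGS", "AGS")))
  centers <- c(control = 0, PS = -57, CGS = -57, AGS = 30)
  if (is.null(coherences)) {
    coherences <- lapply(centers[conditions], coherence_grid)
  }
  stopifnot(all(conditions %in% names(coherences)))
  structure(list(conditions = conditions, coherences = coherences,
                 trials = trials, seed = seed),
            class = "experiment_plan")
}

#' Standard stimulation protocol for a named condition
#'
#' Maps the experiment condition names to their stimulation settings:
#' `control` (none), `PS` (biphasic train, 300 us/phase, 200 pps), `CGS`
#' (cathodic galvanic) and `AGS` (anodic galvanic at the opposite amplitude).
#'
#' @param condition One of `"control"`, `"PS"`, `"CGS"`, `"AGS"`.
#' @param ps_amplitude_uA,gs_amplitude_uA Cathodic-phase / galvanic amplitudes
#'   (uA, cathodic negative).
#' @param ... Passed to [stim_protocol()].
#' @return A [stim_protocol()].
#' @export
condition_protocol <- function(condition,
                               ps_amplitude_uA = -10,
                               gs_amplitude_uA = -1.4, ...) {
  switch(condition,
    control = stim_protocol("none"),
    PS = stim_protocol("PS", amplitude_uA = ps_amplitude_uA, ...),
    CGS = stim_protocol("CGS", amplitude_uA = gs_amplitude_uA, ...),
    AGS = stim_protocol("AGS", amplitude_uA = -gs_amplitude_uA, ...),
    stop("unknown condition: ", condition, call. = FALSE)
  )
}

#' Run a decision-making experiment
#'
#' Executes `plan$trials` trials at every coherence of every condition, with
#' an independent derived seed per (condition, coherence, trial) cell, and
#' extracts the decision from each trial.
#'
#' @param plan An [experiment_plan()].
#' @param config Base [sim_config()] (task coherence and stimulation are
#'   overridden per cell).
#' @param network Optional fixed [build_network()]; built once from
#'   `config$network` with the plan seed otherwise.
#' @param ps_amplitude_uA,gs_amplitude_uA Condition amplitudes (uA; cathodic
#'   negative).
#' @param progress Print one line per completed cell.
#' @return Tibble: `condition`, `coherence`, `trial`, `seed`, `winner`,
#'   `decision_time_s`, `excluded_from_timing`.
#' @export
run_experiment <- function(plan, config = sim_config(), network = NULL,
                           ps_amplitude_uA = -10, gs_amplitude_uA = -1.4,
                           progress = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(network)) network <- build_network(config$network,
                                                 seed = plan$seed)
  cells <- purrr::map(plan$conditions, function(cond) {
    tibble::tibble(condition = cond, coherence = plan$coherences[[cond]])
  })
  cells <- dplyr::bind_rows(cells)
  res <- purrr::pmap(cells, function(condition, coherence) {
    cfg <- config
    cfg$task$coherence <- coherence
    cfg$stimulation <- condition_protocol(
      condition, ps_amplitude_uA = ps_amplitude_uA,
      gs_amplitude_uA = gs_amplitude_uA)
    rows <- purrr::map(seq_len(plan$trials), function(tr) {
      sd <- derive_seed(plan$seed, condition, coherence, tr)
      rec <- run_trial(cfg, seed = sd, network = network)
      dplyr::bind_cols(tibble::tibble(trial = tr, seed = sd), decide(rec))
    })
    out <- dplyr::bind_rows(rows)
    if (progress) {
      message(sprintf("%s c=%+.3f: P1 wins %d/%d", condition, coherence,
                      sum(out$winner == "P1"), nrow(out)))
    }
    dplyr::bind_cols(tibble::tibble(condition = condition,
                                    coherence = coherence), out)
  })
  dplyr::bind_rows(res)
}

#' Task firing rates in a reduced network variant
#'
#' Runs stimulated and control trials in one of the reduced networks
#' (disconnected, feedback-only, recurrent-only) at 0% coherence, computes
#' each P1 neuron's task-period (t = 1-3 s) firing rate by direct spike
#' binning, and the per-trial population average. Changes are reported
#' relative to the mean of the control group.
#'
#' @param variant `"disconnected"`, `"feedback_only"` or `"recurrent_only"`.
#' @param condition `"control"`, `"PS"`, `"CGS"` or `"AGS"`.
#' @param trials Number of trials.
#' @param seed Master seed (also fixes placement).
#' @param config Base [sim_config()]; the architecture variant and
#'   stimulation are set from the arguments.
#' @param control_mean Optional precomputed control population-average mean
#'   (spk/s); when supplied, control trials are not rerun.
#' @param ps_amplitude_uA,gs_amplitude_uA Condition amplitudes (uA).
#' @return A list with `trials` (tibble: `trial`, `pop_rate`,
#'   `delta_vs_control`), `per_neuron` (tibble: `neuron_id`, `distance_um`,
#'   `rate`, mean across trials), and `control_mean`.
#' @export
variant_experiment <- function(variant, condition, trials = 100, seed = 1L,
                               config = sim_config(), control_mean = NULL,
                               ps_amplitude_uA = -10, gs_amplitude_uA = -1.4,
                               protocol_args = list()) {
  arch <- config$network
  arch$variant <- variant
  config$network <- arch
  config$task$coherence <- 0
  net <- build_network(arch, seed = seed)
  p1 <- net$neurons$population == "P1"

  run_group <- function(cond) {
    cfg <- config
    cfg$stimulation <- do.call(condition_protocol, c(
      list(cond, ps_amplitude_uA = ps_amplitude_uA,
           gs_amplitude_uA = gs_amplitude_uA),
      if (cond != "control") protocol_args))
    on_ms <- cfg$task$onset_s * 1e3
    off_ms <- cfg$task$offset_s * 1e3
    dur_s <- cfg$task$offset_s - cfg$task$onset_s
    rates <- matrix(0, nrow = sum(p1), ncol = trials)
    for (tr in seq_len(trials)) {
      sd <- derive_seed(seed, paste0(variant, ":", cond), 0, tr)
      rec <- run_trial(cfg, seed = sd, network = net)
      sp <- rec$spikes[rec$spikes$population == "P1" &
                       rec$spikes$t_ms > on_ms & rec$spikes$t_ms <= off_ms, ]
      counts <- tabulate(match(sp$neuron_id, net$neurons$neuron_id[p1]),
                         nbins = sum(p1))
      rates[, tr] <- counts / dur_s
    }
    rates
  }

  if (is.null(control_mean) && condition != "control") {
    ctrl <- run_group("control")
    control_mean <- mean(colMeans(ctrl))
  }
  rates <- run_group(condition)
  pop_rate <- colMeans(rates)
  cm <- if (condition == "control") {
    if (is.null(control_mean)) mean(pop_rate) else control_mean
  } else control_mean

  list(
    trials = tibble::tibble(
      trial = seq_len(trials), pop_rate = pop_rate,
      delta_vs_control = pop_rate - cm),
    per_neuron = tibble::tibble(
      neuron_id = net$neurons$neuron_id[p1],
      distance_um = net$neurons$distance_um[p1],
      rate = rowMeans(rates)),
    control_mean = cm, variant = variant, condition = condition
  )
}

#' Calibrate the galvanic amplitude against a target psychometric bias
#'
#' Monotone bisection on the CGS amplitude magnitude until the CGS
#' psychometric bias matches `target_bias` (the PS bias), the procedure used
#' to put the two modalities on an equal behavioral footing.
#'
#' @param target_bias Target bias (% coherence).
#' @param bounds Amplitude magnitude search interval (uA), which must bracket
#'   the target.
#' @param bias_fn Function `amplitude_magnitude -> bias` (% coherence). The
#'   default runs a CGS experiment with `plan` and fits the psychometric
#'   curve; injecting a surrogate makes the search unit-testable.
#' @param tol_bias Convergence tolerance on the bias (% coherence).
#' @param max_iter Maximum bisection steps.
#' @param plan,config Used by the default `bias_fn`.
#' @return List: `amplitude_uA` (signed, cathodic), `bias`, `iterations`,
#'   `trace` tibble.
#' @export
calibrate_cgs <- function(target_bias, bounds = c(0.1, 10),
                          bias_fn = NULL, tol_bias = 1, max_iter = 25,
                          plan = experiment_plan("CGS", trials = 20),
                          config = sim_config()) {
  if (is.null(bias_fn)) {
    bias_fn <- function(a_mag) {
      res <- run_experiment(plan, config, gs_amplitude_uA = -a_mag)
      psychometric_fit(res[res$condition == "CGS", ])$bias
    }
  }
  lo <- min(bounds); hi <- max(bounds)
  f_lo <- bias_fn(lo); f_hi <- bias_fn(hi)
  # stronger cathodic amplitude -> more negative bias
  if ((f_lo - target_bias) * (f_hi - target_bias) > 0) {
    stop("bounds do not bracket the target bias", call. = FALSE)
  }
  trace <- list(tibble::tibble(amplitude = c(lo, hi), bias = c(f_lo, f_hi)))
  mid <- NA_real_; f_mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- bias_fn(mid)
    trace[[length(trace) + 1]] <- tibble::tibble(amplitude = mid, bias = f_mid)
    if (abs(f_mid - target_bias) < tol_bias) break
    if ((f_lo - target_bias) * (f_mid - target_bias) <= 0) {
      hi <- mid; f_hi <- f_mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  list(amplitude_uA = -mid, bias = f_mid, iterations = it,
       trace = dplyr::bind_rows(trace))
}
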