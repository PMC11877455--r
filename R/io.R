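#' Write / read delimited output tables
#'
#' Tables are written as plain CSV. `read_table_csv(write_table_csv(x))` is
#' the identity for the column types the package emits (numeric, integer,
#' logical, character).
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv`
#'   returns a tibble.
#' @export
write_table_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  x[] <- lapply(x, function(col) if (is.factor(col)) as.character(col) else col)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Spike-table writer
#'
#' Long spike table with columns `trial_id`, `neuron_id`, `population`,
#' `distance_um`, `spike_time_ms`.
#'
#' @param recordings A `wta_trial` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(recordings, path) {
  if (inherits(recordings, "wta_trial")) recordings <- list(recordings)
  tab <- purrr::imap(recordings, function(rec, i) {
    dplyr::transmute(rec$spikes,
                     trial_id = as.integer(i),
                     neuron_id = .data$neuron_id,
                     population = as.character(.data$population),
                     distance_um = .data$distance_um,
                     spike_time_ms = .data$t_ms)
  })
  write_table_csv(dplyr::bind_rows(tab), path)
}

#' Run manifest
#'
#' Records the configuration hash, seeds, package version, runtime and the
#' inventory of written files, so a finished experiment directory is
#' self-describing and replayable.
#'
#' @param out_dir Experiment output directory.
#' @param name Experiment name.
#' @param seed Master seed.
#' @param config The configuration object the run used.
#' @param files Character vector of files (relative to `out_dir`).
#' @param runtime_s Wall-clock runtime (s).
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
write_manifest <- function(out_dir, name, seed, config, files, runtime_s,
                           extra = list()) {
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing) > 0) {
    stop("manifest references missing files: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  man <- c(list(
    name = name, seed = seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("wtastim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    runtime_s = round(runtime_s, 2),
    files = files
  ), extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"),
                      simplifyVector = TRUE)
}

canned_names <- c("fig2_psychometrics", "fig3_variants", "fig4_trajectories",
                  "fig5_kurtosis", "fig6_timing")

#' Run a canned experiment
#'
#' Reproduces one of the headline experiment designs at full size or at a
#' documented scaled-down size, writing result tables and a manifest to
#' `out_dir`. Seeds are derived per (condition, coherence, trial), so the
#' scaled runs are cell-wise subsets of the full runs.
#'
#' Scaled sizes: psychometrics 20 trials x 7 coherences (full: 100 x 13);
#' variants 20 trials (full: 100); trajectories / kurtosis / timing 10 trials
#' per condition (full: 100).
#'
#' @param name One of `"fig2_psychometrics"`, `"fig3_variants"`,
#'   `"fig4_trajectories"`, `"fig5_kurtosis"`, `"fig6_timing"`.
#' @param scale `"full"` or `"scaled"`.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param config Base [sim_config()].
#' @param trials_override Optional trial count overriding the scale preset.
#' @return Invisibly, the manifest list.
#' @export
run_canned_experiment <- function(name, scale = c("scaled", "full"),
                                  seed = 1L, out_dir,
                                  config = sim_config(),
                                  trials_override = NULL) {
  name <- match.arg(name, canned_names)
  scale <- match.arg(scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  files <- character(0)
  emit <- function(x, fname) {
    write_table_csv(x, file.path(out_dir, fname))
    files <<- c(files, fname)
  }

  if (name == "fig2_psychometrics") {
    trials <- trials_override %||% if (scale == "full") 100 else 20
    steps <- if (scale == "full") c(1.6, 3.2, 6.4, 12.8, 25.6, 51.2)
             else c(12.8, 25.6, 51.2)
    centers <- c(control = 0, PS = -57, CGS = -57, AGS = 30)
    plan <- experiment_plan(
      names(centers),
      coherences = lapply(centers, coherence_grid, steps_pct = steps),
      trials = trials, seed = seed)
    res <- run_experiment(plan, config)
    emit(res, "results.csv")
    n_boot <- if (scale == "full") 10000 else 1000
    fits <- purrr::map(unique(res$condition), function(cond) {
      sub <- res[res$condition == cond, ]
      fit <- psychometric_fit(sub)
      bs_bias <- bootstrap_compare(sub, NULL, "bias", n_boot = n_boot,
                                   seed = seed)
      ci <- stats::quantile(bs_bias$replicates, c(0.025, 0.975))
      dplyr::bind_cols(tibble::tibble(condition = cond), glance(fit),
                       tibble::tibble(bias_ci_lo = ci[1], bias_ci_hi = ci[2]))
    })
    emit(dplyr::bind_rows(fits), "psychometric.csv")
    dt <- res[res$winner != "none" & !res$excluded_from_timing, ]
    dtimes <- dplyr::summarise(
      dplyr::group_by(dt, .data$condition, .data$coherence),
      mean_decision_time_s = mean(.data$decision_time_s - 1),
      sem = stats::sd(.data$decision_time_s) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
    emit(dtimes, "decision_times.csv")
  } else if (name == "fig3_variants") {
    trials <- trials_override %||% if (scale == "full") 100 else 20
    rows <- list(); profs <- list()
    for (variant in c("disconnected", "feedback_only", "recurrent_only")) {
      ctrl <- variant_experiment(variant, "control", trials = trials,
                                 seed = seed, config = config)
      for (cond in c("PS", "CGS", "AGS")) {
        ve <- variant_experiment(variant, cond, trials = trials, seed = seed,
                                 config = config,
                                 control_mean = ctrl$control_mean)
        rows[[paste(variant, cond)]] <- tibble::tibble(
          variant = variant, condition = cond,
          control_mean = ve$control_mean,
          median_delta = stats::median(ve$trials$delta_vs_control),
          iqr_lo = stats::quantile(ve$trials$delta_vs_control, 0.25),
          iqr_hi = stats::quantile(ve$trials$delta_vs_control, 0.75))
        profs[[paste(variant, cond)]] <- dplyr::mutate(
          ve$per_neuron, variant = variant, condition = cond)
      }
      profs[[paste(variant, "control")]] <- dplyr::mutate(
        ctrl$per_neuron, variant = variant, condition = "control")
    }
    emit(dplyr::bind_rows(rows), "variant_medians.csv")
    emit(dplyr::bind_rows(profs), "activation_profiles.csv")
  } else {
    # trajectory / kurtosis / timing experiments share the trial design:
    # coherence at the per-condition psychometric center, fixed trial count
    trials <- trials_override %||% if (scale == "full") 100 else 10
    centers <- c(control = 0, PS = -0.57, CGS = -0.57, AGS = 0.30)
    net <- build_network(config$network, seed = seed)
    rows <- list()
    for (cond in names(centers)) {
      cfg <- config
      cfg$task$coherence <- centers[[cond]]
      cfg$stimulation <- condition_protocol(cond)
      for (tr in seq_len(trials)) {
        sd <- derive_seed(seed, cond, centers[[cond]], tr)
        rec <- run_trial(cfg, seed = sd, network = net,
                         record_currents = name == "fig4_trajectories")
        d <- decide(rec)
        base <- tibble::tibble(condition = cond, trial = tr, seed = sd,
                               winner = d$winner)
        rows[[paste(cond, tr)]] <- switch(
          name,
          fig4_trajectories = {
            nci <- network_current_index(rec)$population
            dplyr::bind_cols(base, trajectory_stats(rec), tibble::tibble(
              baseline_net_current_pA =
                mean(nci$index_pA[nci$t_s < cfg$task$onset_s])))
          },
          fig5_kurtosis = dplyr::bind_cols(
            base, kurtosis_task_summary(kurtosis_series(rec))),
          fig6_timing = {
            st <- spike_timing_stats(rec)
            dplyr::bind_cols(base, tibble::tibble(
              mean_phase_locked_pct =
                mean(st$per_neuron$phase_locked_pct, na.rm = TRUE),
              mean_cv = mean(st$per_neuron$cv, na.rm = TRUE),
              mean_synchrony_pct = mean(st$synchrony, na.rm = TRUE)))
          })
      }
    }
    emit(dplyr::bind_rows(rows), paste0(sub("fig[0-9]+_", "", name), ".csv"))
  }

  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  invisible(write_manifest(out_dir, name, seed, config, files, runtime,
                           extra = list(scale = scale)))
}
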