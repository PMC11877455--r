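#!/usr/bin/env Rscript
# Thin command-line wrapper over the wtastim package.
#
#   Rscript scripts/wtastim.R simulate   --seed 1 --coherence 0.256 --mode PS --out-dir out/
#   Rscript scripts/wtastim.R experiment --name fig2_psychometrics --scale scaled --seed 1 --out-dir out/
#   Rscript scripts/wtastim.R variants   --trials 20 --seed 1 --out-dir out/
#   Rscript scripts/wtastim.R calibrate  --target-bias -54.3 --trials 20 --seed 1

suppressPackageStartupMessages({
  library(optparse)
  library(wtastim)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: wtastim.R <simulate|experiment|variants|calibrate> [options]")
cmd <- argv[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--coherence", type = "double", default = 0),
  make_option("--mode", type = "character", default = "none"),
  make_option("--amplitude", type = "double", default = NA),
  make_option("--name", type = "character", default = "fig3_variants"),
  make_option("--scale", type = "character", default = "scaled"),
  make_option("--trials", type = "integer", default = 20L),
  make_option("--target-bias", type = "double", default = -54.3,
              dest = "target_bias"),
  make_option("--out-dir", type = "character", default = "wtastim_out",
              dest = "out_dir"),
  make_option("--record-currents", action = "store_true", default = FALSE,
              dest = "record_currents")
)), args = argv[-1])

dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)

if (cmd == "simulate") {
  amp <- if (is.na(opts$amplitude)) {
    switch(opts$mode, PS = -10, CGS = -1.4, AGS = 1.4, 0)
  } else opts$amplitude
  stim <- if (opts$mode == "none") stim_protocol("none")
          else stim_protocol(opts$mode, amplitude_uA = amp)
  cfg <- sim_config(task = task_config(opts$coherence), stimulation = stim)
  t0 <- Sys.time()
  rec <- run_trial(cfg, seed = opts$seed,
                   record_currents = opts$record_currents)
  write_spike_table(rec, file.path(opts$out_dir, "spikes.csv"))
  write_table_csv(decide(rec), file.path(opts$out_dir, "decision.csv"))
  files <- c("spikes.csv", "decision.csv")
  if (opts$record_currents) {
    nci <- network_current_index(rec)$population
    write_table_csv(nci, file.path(opts$out_dir, "network_current.csv"))
    files <- c(files, "network_current.csv")
  }
  write_manifest(opts$out_dir, "simulate", opts$seed, cfg, files,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
  d <- decide(rec)
  message(sprintf("winner=%s decision_time=%.2fs spikes=%d",
                  d$winner, d$decision_time_s, nrow(rec$spikes)))
} else if (cmd == "experiment") {
  run_canned_experiment(opts$name, opts$scale, seed = opts$seed,
                        out_dir = opts$out_dir)
  message("wrote ", opts$out_dir)
} else if (cmd == "variants") {
  run_canned_experiment("fig3_variants", "scaled", seed = opts$seed,
                        out_dir = opts$out_dir,
                        trials_override = opts$trials)
  message("wrote ", opts$out_dir)
} else if (cmd == "calibrate") {
  plan <- experiment_plan("CGS", trials = opts$trials, seed = opts$seed)
  out <- calibrate_cgs(opts$target_bias, plan = plan)
  write_table_csv(out$trace, file.path(opts$out_dir, "calibration_trace.csv"))
  message(sprintf("CGS amplitude %.3f uA (bias %.1f%%, %d iterations)",
                  out$amplitude_uA, out$bias, out$iterations))
} else {
  stop("unknown subcommand: ", cmd)
}
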