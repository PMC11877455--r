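#' @useDynLib wtastim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

#' Simulate one trial
#'
#' Integrates the network with forward Euler at `dt_ms`, with background and
#' task Poisson input, recurrent AMPA/NMDA/GABA synapses and (optionally)
#' electrode stimulation of the P1 pyramidal population. Deterministic for a
#' given `(config, network, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for all Poisson input streams.
#' @param network Optional prebuilt [build_network()] (so placement stays fixed
#'   across trials); built from `config$network` with `seed` otherwise.
#' @param record_currents If `TRUE`, record recurrent AMPA, NMDA and GABA
#'   currents for every P1 neuron, down-sampled to `record_every_ms`.
#' @param record_every_ms Current-trace sampling interval (ms).
#' @return A `wta_trial` object: `spikes` (tibble `neuron_id`, `population`,
#'   `distance_um`, `t_ms`), `neurons`, optional current traces, and trial
#'   metadata.
#' @export
run_trial <- function(config, seed, network = NULL,
                      record_currents = FALSE, record_every_ms = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(network)) network <- build_network(config$network, seed = seed)
  neurons <- network$neurons
  n <- nrow(neurons)
  pyr <- neurons$class == "pyr"
  np <- config$neurons_pyr
  ni <- config$neurons_int
  syn <- config$synapses
  stim <- config$stimulation
  el <- config$electrode

  pick <- function(p_val, i_val) ifelse(pyr, p_val, i_val)
  cls_idx <- ifelse(pyr, 1L, 2L)

  task <- config$task
  rate_hz <- rep(0, n)
  rate_hz[neurons$population == "P1"] <-
    task_rate(task$coherence, "P1", task$base_rate_hz, task$gain_hz)
  rate_hz[neurons$population == "P2"] <-
    task_rate(task$coherence, "P2", task$base_rate_hz, task$gain_hz)

  # electrode coupling (stimulated neurons: P1 pyramidal cells only)
  stim_mask <- neurons$population == "P1" & pyr
  istim_gs <- istim_cath <- tpp <- tps <- rep(0, n)
  mode_int <- 0L
  if (stim$mode != "none") {
    vmss <- vapply(neurons$distance_um[stim_mask], mirror_vmss,
                   numeric(1), electrode = el, I_uA = 1)
    if (stim$mode %in% c("CGS", "AGS")) {
      mode_int <- 2L
      istim_gs[stim_mask] <- el$k_gs * vmss * stim$amplitude_uA
    } else {
      mode_int <- 1L
      istim_cath[stim_mask] <- el$k_ps * vmss * stim$amplitude_uA
      amp_eff <- abs(extracellular_potential(neurons$distance_um[stim_mask],
                                             abs(stim$amplitude_uA),
                                             el$rho_ext))
      tpp[stim_mask] <- refractory_time(amp_eff, stim$refractory_table)
      tps[stim_mask] <- stim$t_ps_scale * tpp[stim_mask]
    }
  }

  dt <- config$dt_ms
  n_steps <- round(config$duration_s * 1e3 / dt)
  rec_idx <- if (record_currents) which(stim_mask | neurons$population == "P1") - 1L
             else integer(0)
  rec_every <- max(1L, round(record_every_ms / dt))

  set.seed(seed)
  raw <- simulate_trial_cpp(
    n = n, pop = as.integer(neurons$population) - 1L, is_pyr = pyr,
    W = network$W * network$exists,
    Cm = pick(np$Cm, ni$Cm), gL = pick(np$gL, ni$gL),
    EL = pick(np$EL, ni$EL), Vth = pick(np$Vthreshold, ni$Vthreshold),
    Vr = pick(np$Vr, ni$Vr), tau_r = pick(np$tau_r, ni$tau_r),
    g_ext = syn$g_ampa_ext[cls_idx], g_arec = syn$g_ampa_rec[cls_idx],
    g_nmda = syn$g_nmda[cls_idx], g_gaba = syn$g_gaba[cls_idx],
    E_ampa = syn$E_AMPA, E_nmda = syn$E_NMDA, E_gaba = syn$E_GABA,
    tau_ampa = syn$tau_AMPA, tau_gaba = syn$tau_GABA,
    tau_x = syn$tau_NMDA_rise, tau_s = syn$tau_NMDA_decay,
    alpha = syn$alpha, c_mg = syn$C_Mg,
    delay_steps = round(syn$tau_delay / dt),
    bg_rate_ms = config$background_rate_hz / 1e3,
    task_rate_ms = rate_hz / 1e3,
    task_on_ms = task$onset_s * 1e3, task_off_ms = task$offset_s * 1e3,
    stim_mode = mode_int,
    stim_on_ms = stim$onset_s * 1e3, stim_off_ms = stim$offset_s * 1e3,
    istim_gs = istim_gs, istim_cath = istim_cath,
    pulse_period_ms = 1e3 / stim$pulse_rate_pps,
    phase_ms = stim$pulse_width_us * 1e-3,
    tpp_full = tpp, tps_full = tps,
    block_cap = stim$block_cap_pA, block_on_total = stim$block_on_total,
    dt = dt, n_steps = n_steps,
    refractory_clamp = config$refractory_clamp,
    rec_idx = rec_idx, rec_every = rec_every
  )

  spikes <- tibble::tibble(
    neuron_id = raw$neuron_id,
    population = neurons$population[raw$neuron_id],
    distance_um = neurons$distance_um[raw$neuron_id],
    t_ms = raw$t_ms
  )
  spikes <- dplyr::arrange(spikes, .data$neuron_id, .data$t_ms)

  out <- list(
    spikes = spikes, neurons = neurons,
    gated = tibble::tibble(neuron_id = neurons$neuron_id,
                           gated_pulse = raw$gated_pulse,
                           gated_spont = raw$gated_spont),
    condition = stim$mode, coherence = task$coherence, seed = seed,
    dt_ms = dt, duration_ms = n_steps * dt, config = config
  )
  if (record_currents) {
    out$currents <- list(
      neuron_id = which(stim_mask | neurons$population == "P1"),
      t_ms = raw$rec_t_ms,
      I_ampa_rec = raw$I_ampa_rec, I_nmda = raw$I_nmda, I_gaba = raw$I_gaba
    )
  }
  structure(out, class = "wta_trial")
}

#' @export
print.wta_trial <- function(x, ...) {
  cat("<wta_trial> ", nrow(x$neurons), " neurons, ",
      nrow(x$spikes), " spikes, condition ", x$condition,
      ", coherence ", x$coherence, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pure-R reference dynamics. These are the module's single-step contracts,
# used directly in unit tests as the oracle for the compiled engine.

#' One forward-Euler step of the synaptic gating variables
#'
#' Exponential Euler decay of `s_ampa_ext`, `s_ampa_rec`, `s_gaba` and
#' `x_nmda`; saturating NMDA channel ds/dt = alpha x (1 - s) - s / tau_decay
#' (using the pre-decay `x`); unit increments for arriving spikes applied
#' after the decay.
#'
#' @param gating List with numeric fields `s_ampa_ext`, `s_ampa_rec`,
#'   `x_nmda`, `s_nmda`, `s_gaba`.
#' @param params A [synapse_params()].
#' @param dt Time step (ms).
#' @param arrivals List of index vectors: `ext`, `rec_exc`, `rec_inh`
#'   (neurons whose events are due this step).
#' @return Updated gating list.
#' @export
step_gating <- function(gating, params, dt,
                        arrivals = list(ext = integer(0),
                                        rec_exc = integer(0),
                                        rec_inh = integer(0))) {
  stopifnot(dt > 0)
  g <- gating
  x_old <- g$x_nmda
  g$s_ampa_ext <- g$s_ampa_ext * (1 - dt / params$tau_AMPA)
  g$s_ampa_rec <- g$s_ampa_rec * (1 - dt / params$tau_AMPA)
  g$s_gaba <- g$s_gaba * (1 - dt / params$tau_GABA)
  g$x_nmda <- x_old * (1 - dt / params$tau_NMDA_rise)
  g$s_nmda <- g$s_nmda +
    dt * (params$alpha * x_old * (1 - g$s_nmda) - g$s_nmda / params$tau_NMDA_decay)
  g$s_ampa_ext[arrivals$ext] <- g$s_ampa_ext[arrivals$ext] + 1
  g$s_ampa_rec[arrivals$rec_exc] <- g$s_ampa_rec[arrivals$rec_exc] + 1
  g$x_nmda[arrivals$rec_exc] <- g$x_nmda[arrivals$rec_exc] + 1
  g$s_gaba[arrivals$rec_inh] <- g$s_gaba[arrivals$rec_inh] + 1
  g
}

#' Synaptic currents onto each neuron
#'
#' Evaluates the AMPA (external + recurrent), NMDA and GABA current equations
#' with weighted presynaptic sums over the network connectivity
#' (self-connections excluded). The NMDA magnesium term uses the membrane
#' potential in volts: 1 + C_Mg exp(-62 Vm) / 3.57.
#'
#' @param gating Gating list as in [step_gating()], one entry per neuron
#'   (source-attached).
#' @param params A [synapse_params()].
#' @param vm Per-neuron membrane potentials (mV).
#' @param net A [build_network()] connectivity.
#' @return Tibble with per-neuron `I_ampa_ext`, `I_ampa_rec`, `I_gaba`,
#'   `I_nmda` (pA).
#' @export
synaptic_currents <- function(gating, params, vm, net) {
  neurons <- net$neurons
  n <- nrow(neurons)
  pyr <- neurons$class == "pyr"
  cls <- ifelse(pyr, 1L, 2L)
  pops <- as.integer(neurons$population)
  W <- net$W * net$exists

  agg <- function(s, keep) {
    v <- ifelse(keep, s, 0)
    tapply(v, factor(pops, levels = 1:4), sum, default = 0)
  }
  agg_a <- agg(gating$s_ampa_rec, pyr)
  agg_n <- agg(gating$s_nmda, pyr)
  agg_g <- agg(gating$s_gaba, !pyr)

  wsum <- function(aggv, own, keep) {
    tot <- as.numeric(t(W) %*% aggv)[pops]
    self_w <- diag(W)[pops]
    tot - ifelse(keep, self_w * own, 0)
  }
  wa <- wsum(agg_a, gating$s_ampa_rec, pyr)
  wn <- wsum(agg_n, gating$s_nmda, pyr)
  wg <- wsum(agg_g, gating$s_gaba, !pyr)

  mg <- 1 + params$C_Mg * exp(-62 * vm * 1e-3) / 3.57
  tibble::tibble(
    I_ampa_ext = params$g_ampa_ext[cls] * gating$s_ampa_ext * (params$E_AMPA - vm),
    I_ampa_rec = params$g_ampa_rec[cls] * wa * (params$E_AMPA - vm),
    I_gaba = params$g_gaba[cls] * wg * (params$E_GABA - vm),
    I_nmda = params$g_nmda[cls] * wn * (params$E_NMDA - vm) / mg
  )
}

#' One forward-Euler membrane step
#'
#' Integrates dVm/dt = (-gL (Vm - EL) + Isyn + Istim) / Cm, records threshold
#' crossings, resets to `Vr` and starts the absolute refractory period. While
#' refractory the membrane is clamped at `Vr`.
#'
#' @param vm Membrane potentials (mV).
#' @param ref_clock Remaining refractory time (ms).
#' @param params A [neuron_params()] shared by these neurons.
#' @param Isyn,Istim Input currents (pA).
#' @param dt Time step (ms).
#' @return List with `vm`, `ref_clock` and logical `spiked`.
#' @export
step_membrane <- function(vm, ref_clock, params, Isyn, Istim, dt) {
  stopifnot(dt > 0, all(ref_clock >= 0))
  refr <- ref_clock > 0
  # pA / nF = 1 mV/s, so the mV/ms step carries a 1e-3 factor
  v_new <- vm + dt * 1e-3 * (-params$gL * (vm - params$EL) + Isyn + Istim) /
    params$Cm
  if (any(!is.finite(v_new))) {
    stop("non-finite membrane potential (check parameters / step size)",
         call. = FALSE)
  }
  spiked <- !refr & v_new > params$Vthreshold
  vm_out <- ifelse(refr, params$Vr, ifelse(spiked, params$Vr, v_new))
  clock <- ifelse(refr, pmax(0, ref_clock - dt),
                  ifelse(spiked, params$tau_r, 0))
  list(vm = vm_out, ref_clock = clock, spiked = spiked)
}
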