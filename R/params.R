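#' Membrane parameters for one neuron class
#'
#' Leaky integrate-and-fire constants. Defaults follow the canonical
#' winner-take-all decision network at N = 1000: pyramidal cells have a 20 ms
#' membrane time constant (Cm/gL = 0.5 nF / 25 nS), interneurons 10 ms.
#'
#' @param Cm Membrane capacitance (nF).
#' @param gL Leak conductance (nS).
#' @param EL Resting (leak reversal) potential (mV).
#' @param Vthreshold Spike threshold (mV).
#' @param Vr Post-spike reset potential (mV).
#' @param tau_r Absolute refractory period (ms).
#' @return A `neuron_params` list.
#' @export
#' @examples
#' neuron_params()               # pyramidal defaults
#' neuron_params_interneuron()   # interneuron defaults
neuron_params <- function(Cm = 0.5, gL = 25, EL = -70, Vthreshold = -50,
                          Vr = -55, tau_r = 2) {
  stopifnot(Cm > 0, gL > 0, tau_r >= 0)
  if (!(Vr < Vthreshold)) {
    stop("reset potential Vr must lie below Vthreshold", call. = FALSE)
  }
  structure(
    list(Cm = Cm, gL = gL, EL = EL, Vthreshold = Vthreshold,
         Vr = Vr, tau_r = tau_r),
    class = "neuron_params"
  )
}

#' @rdname neuron_params
#' @export
neuron_params_interneuron <- function(Cm = 0.2, gL = 20, EL = -70,
                                      Vthreshold = -50, Vr = -55, tau_r = 1) {
  neuron_params(Cm, gL, EL, Vthreshold, Vr, tau_r)
}

#' Synaptic parameters
#'
#' Conductances, reversal potentials and kinetic constants for AMPA
#' (external + recurrent), NMDA and GABA-A synapses. Conductances are
#' per-synapse values scaled for the N = 1000 network and differ by target
#' class (pyramidal vs interneuron); kinetics are shared.
#'
#' @param g_ampa_ext,g_ampa_rec,g_nmda,g_gaba Conductances (nS) onto a target
#'   neuron, length-2 numeric `c(pyramidal, interneuron)`.
#' @param E_AMPA,E_NMDA,E_GABA Reversal potentials (mV).
#' @param tau_AMPA,tau_GABA Exponential decay constants (ms).
#' @param tau_NMDA_rise,tau_NMDA_decay NMDA rise and decay constants (ms).
#' @param alpha NMDA saturation rate (1/ms).
#' @param C_Mg Extracellular magnesium concentration (mM).
#' @param tau_delay Recurrent synaptic transmission delay (ms).
#' @return A `synapse_params` list.
#' @export
synapse_params <- function(g_ampa_ext = c(pyr = 2.1, int = 1.62),
                           g_ampa_rec = c(pyr = 0.1, int = 0.08),
                           g_nmda = c(pyr = 0.33, int = 0.26),
                           g_gaba = c(pyr = 2.6, int = 2.0),
                           E_AMPA = 0, E_NMDA = 0, E_GABA = -70,
                           tau_AMPA = 2, tau_GABA = 5,
                           tau_NMDA_rise = 2, tau_NMDA_decay = 100,
                           alpha = 0.5, C_Mg = 1, tau_delay = 0.5) {
  stopifnot(
    tau_AMPA > 0, tau_GABA > 0, tau_NMDA_rise > 0, tau_NMDA_decay > 0,
    tau_delay >= 0, C_Mg >= 0, alpha >= 0,
    length(g_ampa_ext) == 2, length(g_ampa_rec) == 2,
    length(g_nmda) == 2, length(g_gaba) == 2
  )
  structure(
    list(g_ampa_ext = g_ampa_ext, g_ampa_rec = g_ampa_rec,
         g_nmda = g_nmda, g_gaba = g_gaba,
         E_AMPA = E_AMPA, E_NMDA = E_NMDA, E_GABA = E_GABA,
         tau_AMPA = tau_AMPA, tau_GABA = tau_GABA,
         tau_NMDA_rise = tau_NMDA_rise, tau_NMDA_decay = tau_NMDA_decay,
         alpha = alpha, C_Mg = C_Mg, tau_delay = tau_delay),
    class = "synapse_params"
  )
}

#' Network architecture
#'
#' Population sizes and the three-level connection-weight scheme of the
#' winner-take-all network, plus reduced variants used to isolate network
#' motifs. At the default N = 1000 the populations are P1 = P2 = 120,
#' NS = 560 and Int = 200 (80/20 excitatory/inhibitory split, selective
#' fraction f = 0.12 per pool), and the weak weight satisfies
#' w_weak = 1 - f_sel (w_strong - 1) / (1 - f_sel) with f_sel = 0.15 of the
#' excitatory pool.
#'
#' Variants:
#' * `"full"`: the complete four-population network.
#' * `"disconnected"`: P1 neurons only, no recurrent connections.
#' * `"feedback_only"`: P1 plus `n_int_feedback` interneurons (80/20 ratio),
#'   all connections at `w_medium`.
#' * `"recurrent_only"`: P1 neurons with excitatory P1 to P1 connections at
#'   weight `w_rec`.
#'
#' @param N Total neuron count for the full variant.
#' @param f_P1,f_P2,f_NS,f_Int Population fractions (must sum to 1).
#' @param w_weak,w_medium,w_strong Dimensionless connection weights.
#' @param variant One of `"full"`, `"disconnected"`, `"feedback_only"`,
#'   `"recurrent_only"`.
#' @param w_rec Recurrent weight for the `"recurrent_only"` variant.
#' @param n_int_feedback Interneuron count for the `"feedback_only"` variant.
#' @return A `network_architecture` list.
#' @export
network_architecture <- function(N = 1000,
                                 f_P1 = 0.12, f_P2 = 0.12, f_NS = 0.56,
                                 f_Int = 0.20,
                                 w_weak = 0.8765, w_medium = 1,
                                 w_strong = 1.7,
                                 variant = c("full", "disconnected",
                                             "feedback_only",
                                             "recurrent_only"),
                                 w_rec = 0.25, n_int_feedback = 30) {
  variant <- match.arg(variant)
  sizes <- round(N * c(P1 = f_P1, P2 = f_P2, NS = f_NS, Int = f_Int))
  if (sum(sizes) != N) {
    stop("population fractions do not resolve to integer sizes summing to N",
         call. = FALSE)
  }
  if (variant == "full" && abs(sum(sizes[1:3]) / N - 0.8) > 1e-9) {
    stop("full variant requires an 80/20 pyramidal/interneuron split",
         call. = FALSE)
  }
  structure(
    list(N = N, sizes = sizes,
         w_weak = w_weak, w_medium = w_medium, w_strong = w_strong,
         variant = variant, w_rec = w_rec, n_int_feedback = n_int_feedback),
    class = "network_architecture"
  )
}

#' Electrode and coupling model
#'
#' Point-source electrode in a homogeneous medium, with a mirror-estimate
#' coupling from extracellular potential to injected LIF current. The axon
#' used for the mirror estimate is a line of `axon_nodes` nodes spaced
#' `axon_spacing_um` apart, with the electrode at perpendicular distance r
#' from the closest (first) node.
#'
#' Default coupling constants `k_gs`, `k_ps` and the pulse refractory anchor
#' table are calibration results; see the methods vignette for the anchors
#' used.
#'
#' @param rho_ext Extracellular resistivity (Ohm m).
#' @param axon_nodes Number of axon nodes (>= 2).
#' @param axon_spacing_um Internode spacing (um).
#' @param k_gs,k_ps Coupling constants (pA per mV of steady-state membrane
#'   polarization) for galvanic and pulsatile stimulation.
#' @return An `electrode_model` list.
#' @export
electrode_model <- function(rho_ext = 3.0, axon_nodes = 11,
                            axon_spacing_um = 100,
                            k_gs = 45, k_ps = 350) {
  stopifnot(rho_ext > 0, axon_nodes >= 2, axon_spacing_um > 0,
            k_gs > 0, k_ps > 0)
  structure(
    list(rho_ext = rho_ext, axon_nodes = axon_nodes,
         axon_spacing_um = axon_spacing_um, k_gs = k_gs, k_ps = k_ps),
    class = "electrode_model"
  )
}

#' Stimulation protocol
#'
#' Waveform and gating rules for one stimulation condition. Amplitude follows
#' the cathodic-negative sign convention; pulsatile trains are charge-balanced
#' biphasic rectangular pulses, cathodic phase first.
#'
#' `refractory_table` maps the local extracellular voltage magnitude
#' experienced by a neuron (mV, at the protocol's pulse amplitude) to the
#' pulse-pulse refractory period t_pp (ms) by linear interpolation, clamped at
#' the extreme anchors. A pulse arriving during an ongoing pulse-pulse
#' refractory period renews it at t_pp / 2. The pulse-spontaneous refractory
#' period t_ps is the same table scaled by `t_ps_scale`.
#'
#' @param mode One of `"none"`, `"PS"`, `"CGS"`, `"AGS"`.
#' @param amplitude_uA Electrode current (uA). Cathodic currents are negative;
#'   for PS this is the cathodic-phase current (so also negative).
#' @param pulse_width_us Pulse width per phase (us), PS only.
#' @param pulse_rate_pps Pulse rate (pulses per second), PS only.
#' @param onset_s,offset_s Stimulation window (s).
#' @param refractory_table Two-column matrix or data frame
#'   `(amplitude_mV, t_pp_ms)` with at least 2 rows, monotone in amplitude.
#' @param t_ps_scale Scale factor from t_pp to t_ps.
#' @param block_cap_pA Instantaneous input-current cap for the galvanic
#'   depolarizing-block gate (pA).
#' @param block_on_total If `TRUE` (default) the cap is tested against
#'   Istim + Isyn; if `FALSE` against Istim alone.
#' @return A `stim_protocol` list.
#' @export
stim_protocol <- function(mode = c("none", "PS", "CGS", "AGS"),
                          amplitude_uA = 0,
                          pulse_width_us = 300, pulse_rate_pps = 200,
                          onset_s = 1, offset_s = 3,
                          refractory_table = default_refractory_table(),
                          t_ps_scale = 1,
                          block_cap_pA = 1135, block_on_total = TRUE) {
  mode <- match.arg(mode)
  refractory_table <- as.matrix(refractory_table)
  stopifnot(block_cap_pA > 0, offset_s >= onset_s)
  if (mode == "PS") {
    stopifnot(pulse_width_us > 0, pulse_rate_pps > 0)
    if (pulse_rate_pps * 2 * pulse_width_us * 1e-6 > 1) {
      stop("pulse footprint exceeds the inter-pulse period (overlapping pulses)",
           call. = FALSE)
    }
  }
  if (nrow(refractory_table) < 2 ||
      is.unsorted(refractory_table[, 1], strictly = TRUE)) {
    stop("refractory_table needs >= 2 anchors, strictly increasing in amplitude",
         call. = FALSE)
  }
  structure(
    list(mode = mode, amplitude_uA = amplitude_uA,
         pulse_width_us = pulse_width_us, pulse_rate_pps = pulse_rate_pps,
         onset_s = onset_s, offset_s = offset_s,
         refractory_table = refractory_table, t_ps_scale = t_ps_scale,
         block_cap_pA = block_cap_pA, block_on_total = block_on_total),
    class = "stim_protocol"
  )
}

#' Default pulse-pulse refractory anchor table
#'
#' Linear two-anchor table spanning 0-132 ms over the extracellular-voltage
#' range at which direct pulse activation occurs; anchors are a calibration
#' result (see the methods vignette).
#'
#' @return Matrix with columns `amplitude_mV`, `t_pp_ms`.
#' @export
default_refractory_table <- function() {
  cbind(amplitude_mV = c(42, 240), t_pp_ms = c(0, 132))
}

#' Perceptual task configuration
#'
#' Random-dot-motion style task input: two selective populations receive
#' Poisson input at rates set by the linear rule FR = 40 c + 40 (Hz), with
#' the sign of the coherence c selecting the favored population.
#'
#' @param coherence Signed motion coherence, in `[-1, 1]`.
#' @param onset_s,offset_s Task window (s).
#' @param base_rate_hz,gain_hz Intercept and slope of the task-input rule (Hz).
#' @return A `task_config` list.
#' @export
task_config <- function(coherence = 0, onset_s = 1, offset_s = 3,
                        base_rate_hz = 40, gain_hz = 40) {
  if (abs(coherence) > 1) stop("|coherence| must be <= 1", call. = FALSE)
  structure(
    list(coherence = coherence, onset_s = onset_s, offset_s = offset_s,
         base_rate_hz = base_rate_hz, gain_hz = gain_hz),
    class = "task_config"
  )
}

#' Full trial configuration
#'
#' Bundles network, neuron, synapse, electrode, stimulation and task settings
#' together with the integration step and trial duration.
#'
#' @param network A [network_architecture()].
#' @param neurons_pyr,neurons_int [neuron_params()] per class.
#' @param synapses A [synapse_params()].
#' @param electrode An [electrode_model()].
#' @param stimulation A [stim_protocol()].
#' @param task A [task_config()].
#' @param background_rate_hz Total background Poisson event rate per neuron (Hz).
#' @param dt_ms Integration step (ms).
#' @param duration_s Trial duration (s).
#' @param refractory_clamp If `TRUE` (default) the membrane is clamped at `Vr`
#'   during the spontaneous refractory period; if `FALSE` it integrates freely
#'   with threshold crossings suppressed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(network = network_architecture(),
                       neurons_pyr = neuron_params(),
                       neurons_int = neuron_params_interneuron(),
                       synapses = synapse_params(),
                       electrode = electrode_model(),
                       stimulation = stim_protocol("none"),
                       task = task_config(),
                       background_rate_hz = 2400,
                       dt_ms = 0.05, duration_s = 4,
                       refractory_clamp = TRUE) {
  stopifnot(dt_ms > 0, duration_s > 0, background_rate_hz >= 0)
  structure(
    list(network = network, neurons_pyr = neurons_pyr,
         neurons_int = neurons_int, synapses = synapses,
         electrode = electrode, stimulation = stimulation, task = task,
         background_rate_hz = background_rate_hz,
         dt_ms = dt_ms, duration_s = duration_s,
         refractory_clamp = refractory_clamp),
    class = "sim_config"
  )
}
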